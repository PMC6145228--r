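test_that("per-fish aggregation averages available points and keeps counts", {
  d <- data.frame(fish_id = rep(c("A", "B"), each = 2),
                  treatment = "IQF", point = c(1, 2, 1, 2),
                  hardness1 = c(100, 200, 150, NA))
  agg <- aggregate_fish(d)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$hardness1[agg$fish_id == "A"], 150)
  # missing point simply omitted, not imputed
  expect_equal(agg$hardness1[agg$fish_id == "B"], 150)

  co <- simulate_cohort(cohort_spec(seed = 17))
  expect_equal(nrow(aggregate_fish(co)), 94)
})

test_that("fish with no valid points are dropped with a warning", {
  d <- data.frame(fish_id = c("A", "A", "B"), treatment = "IQF",
                  point = c(1, 2, 1), hardness1 = c(1, 3, NA))
  expect_warning(agg <- aggregate_fish(d), "dropped")
  expect_equal(agg$fish_id, "A")
})

test_that("two-group ANOVA matches the closed-form worked example", {
  d <- data.frame(treatment = rep(c("a", "b"), each = 3),
                  y = c(1, 2, 3, 4, 5, 6))
  cmp <- compare_groups(d, "y")
  expect_equal(cmp$F, 13.5)
  expect_equal(cmp$p, stats::pf(13.5, 1, 4, lower.tail = FALSE))
  expect_lt(abs(cmp$p - 0.0213), 5e-4)
  expect_true(cmp$significant)
})

test_that("identical groups give F = 0 and p = 1", {
  d <- data.frame(treatment = rep(c("a", "b"), each = 4),
                  y = rep(c(1, 2, 3, 4), 2))
  cmp <- compare_groups(d, "y")
  expect_equal(cmp$F, 0)
  expect_equal(cmp$p, 1)
  expect_false(cmp$significant)
})

test_that("F equals the squared pooled-variance t statistic exactly", {
  set.seed(5)
  for (r in 1:10) {
    d <- data.frame(treatment = rep(c("a", "b"), c(8, 13)),
                    y = c(rnorm(8, 10, 2), rnorm(13, 12, 2)))
    cmp <- compare_groups(d, "y")
    tt <- stats::t.test(y ~ treatment, data = d, var.equal = TRUE)
    expect_equal(cmp$F, unname(tt$statistic)^2, tolerance = 1e-12)
    expect_equal(cmp$p, tt$p.value, tolerance = 1e-12)
    ow <- stats::oneway.test(y ~ treatment, data = d, var.equal = TRUE)
    expect_equal(cmp$F, unname(ow$statistic), tolerance = 1e-12)
  }
})

test_that("null p-values give a calibrated type-I error rate", {
  set.seed(99)
  rejections <- 0L
  n_sim <- 1000L
  for (r in seq_len(n_sim)) {
    d <- data.frame(treatment = rep(c("a", "b"), c(10, 10)),
                    y = rnorm(20))
    if (compare_groups(d, "y")$p < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / n_sim, 0.03)
  expect_lte(rejections / n_sim, 0.07)
})

test_that("group size and level-count preconditions are enforced", {
  d <- data.frame(treatment = c("a", "a", "b"), y = c(1, 2, 3))
  expect_error(compare_groups(d, "y"), "at least 2")
  d3 <- data.frame(treatment = c("a", "a", "b", "b", "c", "c"),
                   y = rnorm(6))
  expect_error(compare_groups(d3, "y"), "exactly 2")
  expect_error(compare_groups(d, "nope"), "no column")
})

test_that("cohort summary mirrors the two-group table layout", {
  co <- simulate_cohort(cohort_spec(seed = 23))
  agg <- aggregate_fish(co)
  s <- summarize_cohort(agg, c("springiness", "hardness1", "thickness2"))
  expect_equal(nrow(s), 3)
  expect_named(s, c("attribute", "IQF_mean", "IQF_sd", "IQF_n",
                    "fresh-frozen_mean", "fresh-frozen_sd",
                    "fresh-frozen_n", "p_value"))
  expect_equal(s[["fresh-frozen_n"]], rep(34L, 3))
  expect_equal(s[["IQF_n"]], rep(60L, 3))
  # an absent attribute yields a row of NA, not an error
  s2 <- summarize_cohort(agg, c("springiness", "unobtainium"))
  expect_equal(nrow(s2), 2)
  expect_true(is.na(s2$p_value[2]))
})

test_that("large calibrated cohorts reproduce the printed group means", {
  co <- simulate_cohort(cohort_spec(
    n_fish = c("IQF" = 400, "fresh-frozen" = 400),
    points_per_fillet = 1, seed = 311))
  agg <- aggregate_fish(co$tpa)
  s <- summarize_cohort(agg, "springiness")
  expect_lt(abs(s[["IQF_mean"]] - 69.77), 0.3)
  expect_lt(abs(s[["fresh-frozen_mean"]] - 73.84), 0.3)
})
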