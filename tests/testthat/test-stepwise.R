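make_candidates <- function(n, k = 10, seed = 1) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * k), n, k))
  names(X) <- c("hardness1", "hardness2", "cohesiveness", "springiness",
                "resilience", "adhesiveness", "thickness1", "thickness2",
                "chewiness1", "chewiness1b")[seq_len(k)]
  X
}

test_that("forward selection recovers a single strong predictor", {
  X <- make_candidates(500, seed = 2)
  X$hardness1 <- rnorm(500, 200, 40)
  y <- 2 * X$hardness1 + rnorm(500, 0, 0.1)
  fit <- stepwise_fit(y, X, target = "firmness")
  expect_equal(fit$terms[[1]]$vars, "hardness1")
  expect_equal(names(fit$report$entry_p)[1], "hardness1")
  expect_lt(abs(fit$terms[[1]]$coef - 2) / 2, 0.05)
  expect_gt(fit$report$r_squared, 0.99)
})

test_that("null responses admit a predictor at about 1 - 0.95^k", {
  set.seed(77)
  k <- 10
  n <- 50
  reps <- 600
  entered <- 0L
  for (r in seq_len(reps)) {
    X <- as.data.frame(matrix(rnorm(n * k), n, k))
    names(X) <- paste0("v", seq_len(k))
    y <- rnorm(n)
    fit <- stepwise_fit(y, X, interactions = FALSE)
    if (length(fit$terms)) entered <- entered + 1L
  }
  rate <- entered / reps
  expect_gt(rate, 1 - 0.95^k - 0.06)
  expect_lt(rate, 1 - 0.95^k + 0.06)
})

test_that("phase 2 recovers a constructed interaction", {
  set.seed(12)
  n <- 400
  X <- data.frame(hardness1 = rnorm(n, 200, 40),
                  thickness2 = rnorm(n, 11, 1),
                  resilience = rnorm(n, 22, 3))
  y <- 0.01 * X$hardness1 * X$thickness2 + rnorm(n, 0, 0.3)
  main_only <- stepwise_fit(y, X, interactions = FALSE)
  fit <- stepwise_fit(y, X)
  kinds <- vapply(fit$terms, `[[`, character(1), "kind")
  vars <- lapply(fit$terms, `[[`, "vars")
  has_cross <- any(kinds == "cross" & vapply(vars, function(v)
    setequal(v, c("hardness1", "thickness2")), logical(1)))
  expect_true(has_cross)
  expect_gt(fit$report$r_squared, main_only$report$r_squared)
})

test_that("every entered term beats the stopping rule", {
  co <- tiny_cohort(seed = 41, iqf = 40, ff = 30)
  agg <- add_residuals(aggregate_fish(co))
  fit <- fit_sensory_equation(agg, "flaky", group = "IQF")
  expect_true(all(fit$report$entry_p < 0.05))
  # OLS mean identity on the fitting sample
  expect_lt(abs(mean(fitted(fit)) - mean(fit$y)), 1e-10)
  expect_lt(abs(mean(residuals(fit))), 1e-10)
})

test_that("an uninformative pool yields an intercept-only model", {
  set.seed(3)
  X <- data.frame(a = rnorm(30), b = rnorm(30))
  y <- rep(c(5.2, 5.3), 15)
  # with pure-noise candidates most seeds select nothing; force alpha tiny
  fit <- stepwise_fit(y, X, alpha = 1e-6)
  expect_length(fit$terms, 0)
  expect_equal(fit$intercept, mean(y))
  expect_equal(fit$report$r_squared, 0)
})

test_that("collinear candidates are skipped with a warning", {
  set.seed(4)
  X <- data.frame(a = rnorm(50))
  X$b <- 2 * X$a  # exact copy up to scale
  y <- X$a + rnorm(50, 0, 0.01)
  expect_warning(fit <- stepwise_fit(y, X, interactions = FALSE),
                 "collinear")
  expect_length(fit$terms, 1)
})

test_that("constant candidates and degenerate inputs error", {
  X <- data.frame(a = rnorm(20), b = rep(1, 20))
  expect_error(stepwise_fit(rnorm(20), X), "constant")
  expect_error(stepwise_fit(rnorm(3), data.frame(a = rnorm(3))), "too few")
})

test_that("a cohort with a known sensory link is recovered end to end", {
  links <- list(firmness = list(intercept = 0.5,
                                coefs = c(hardness1 = 0.02),
                                noise_sd = 0.3))
  co <- simulate_cohort(cohort_spec(
    n_fish = c("IQF" = 150, "fresh-frozen" = 150),
    points_per_fillet = 1, sensory_links = links, seed = 55))
  agg <- add_residuals(aggregate_fish(co))
  fit <- fit_sensory_equation(agg, "firmness", group = "IQF")
  expect_equal(fit$terms[[1]]$vars, "hardness1")
  expect_lt(abs(fit$terms[[1]]$coef - 0.02) / 0.02, 0.15)
})
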