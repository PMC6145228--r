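test_that("the published equation sets are complete and verbatim", {
  ff <- builtin_equations("fresh-frozen")
  iqf <- builtin_equations("IQF")
  expect_length(ff, 10)
  expect_length(iqf, 10)
  expect_false(any(vapply(ff, function(e) e$absent, logical(1))))
  # IQF moisture retention: explicit absent-model marker
  expect_true(iqf$moisture_retention$absent)
  expect_equal(sum(!vapply(iqf, function(e) e$absent, logical(1))), 9)

  expect_equal(ff$flaky$intercept, 7.533)
  expect_length(ff$flaky$terms, 1)
  expect_equal(ff$flaky$terms[[1]]$coef, -0.0124)
  expect_equal(ff$flaky$terms[[1]]$vars, "hardness1")

  expect_equal(iqf$springiness$intercept, 1.284)
  expect_equal(iqf$springiness$terms[[1]]$coef, 0.0122)
  expect_equal(iqf$springiness$terms[[1]]$vars, "res_hardness1b")

  mr <- ff$moisture_retention
  expect_equal(mr$intercept, 1.301)
  expect_length(mr$terms, 5)
  kinds <- vapply(mr$terms, `[[`, character(1), "kind")
  expect_equal(sort(kinds), sort(c("linear", "linear", "cross", "square",
                                   "square")))
  expect_error(builtin_equations("steamed"), "arg")
})

test_that("prediction evaluates linear, squared and cross terms", {
  ff <- builtin_equations("fresh-frozen")
  expect_equal(predict(ff$flaky, c(hardness1 = 220.51)),
               7.533 - 0.0124 * 220.51)
  iqf <- builtin_equations("IQF")
  expect_equal(predict(iqf$res_cohesiveness_of_mass,
                       c(res_chewiness1 = -4.326)),
               0.0936 + 0.016 * -4.326)
  # square and cross arithmetic
  expect_equal(predict(ff$firmness, c(thickness1 = 10, hardness1 = 100)),
               -0.305 + 0.322 * 10 - 0.001 * 100 + 0.0003 * 100^2)
  expect_equal(predict(iqf$firmness, c(hardness2 = 10, chewiness2 = 5)),
               2.566 + 0.0138 * 10 - 0.0128 * 5 - 0.0006 * 100 +
                 0.0013 * 50)
  # all-zero input returns the intercept
  zeros <- stats::setNames(as.list(rep(0, 17)),
                           c(tpa_attribute_names(),
                             paste0("res_", c("chewiness1", "chewiness1b",
                                              "cohesiveness", "hardness1b",
                                              "springiness"))))
  expect_equal(predict(ff$moisture_retention, zeros), 1.301)
})

test_that("prediction errors name the missing attribute and absent models", {
  ff <- builtin_equations("fresh-frozen")
  expect_error(predict(ff$firmness, c(thickness1 = 10)), "hardness1")
  iqf <- builtin_equations("IQF")
  expect_error(predict(iqf$moisture_retention, c(hardness1 = 200)),
               "no model")
})

test_that("duplicate terms are rejected at construction", {
  expect_error(prediction_equation("x", "IQF", 0, list(
    fishtpa:::eq_term(1, "hardness1"), fishtpa:::eq_term(2, "hardness1"))),
    "duplicate")
})

test_that("fit reports follow the regression conventions", {
  d <- data.frame(hardness1 = c(180, 200, 220, 240, 260))
  d$flaky <- 7.533 - 0.0124 * d$hardness1
  rep1 <- evaluate_equation(builtin_equations("fresh-frozen")$flaky, d)
  expect_equal(rep1$r_squared, 1)
  expect_equal(rep1$RMSE, 0)
  expect_equal(rep1$r, 1)

  # intercept-only model: R2 = 0 and RMSE = sample SD
  set.seed(31)
  y <- rnorm(30, 5, 1.3)
  eq0 <- prediction_equation("y", "IQF", mean(y), list(),
                             provenance = "fitted")
  rep0 <- evaluate_equation(eq0, data.frame(y = y))
  expect_equal(rep0$r_squared, 0, tolerance = 1e-12)
  expect_equal(rep0$RMSE, stats::sd(y))
})

test_that("five-point fit statistics match the normal-equations oracle", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2.1, 3.9, 6.2, 7.8, 10.3)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)  # brute-force normal equations
  eq <- prediction_equation("y", "IQF", beta[1],
                            list(fishtpa:::eq_term(beta[2], "hardness1")),
                            provenance = "fitted")
  rep_ <- evaluate_equation(eq, data.frame(hardness1 = x, y = y))
  res <- y - X %*% beta
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  expect_equal(rep_$r_squared, 1 - sse / sst, tolerance = 1e-10)
  expect_equal(rep_$RMSE, sqrt(sse / (5 - 1 - 1)), tolerance = 1e-10)
  expect_equal(rep_$adj_r_squared,
               1 - (1 - rep_$r_squared) * 4 / 3, tolerance = 1e-10)
  expect_error(evaluate_equation(eq, data.frame(hardness1 = x[1:2],
                                                y = y[1:2])), "n > p")
})
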