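# Term constructors for prediction equations. A term is a coefficient on a
# linear, squared, or cross-product function of TPA attributes.
eq_term <- function(coef, var1, var2 = NULL) {
  vars <- c(var1, var2)
  kind <- if (length(vars) == 1L) "linear"
          else if (vars[1] == vars[2]) "square" else "cross"
  list(kind = kind, vars = vars, coef = coef)
}

#' Construct a sensory prediction equation
#'
#' An intercept plus linear, squared and cross-product terms over TPA
#' attributes (and their thickness residuals), mapping an instrumental
#' profile to one descriptive sensory attribute on the 0-15 intensity
#' scale.
#'
#' @param target sensory attribute the equation predicts
#' @param group treatment group the equation was derived on
#'   (`"fresh-frozen"` or `"IQF"`)
#' @param intercept model intercept
#' @param terms list of terms, each `list(kind, vars, coef)`
#' @param provenance `"builtin"` (published constants) or `"fitted"`
#' @param report optional fit report (RMSE, r_squared, r, ...)
#' @return an object of class `prediction_equation`
#' @export
prediction_equation <- function(target, group, intercept, terms,
                                provenance = c("builtin", "fitted"),
                                report = NULL) {
  sig <- vapply(terms, function(tm) paste(sort(tm$vars), collapse = ":"),
                character(1))
  if (anyDuplicated(sig))
    stop_fishtpa("duplicate terms in equation for '", target, "'")
  structure(list(target = target, group = group, intercept = intercept,
                 terms = terms, provenance = match.arg(provenance),
                 report = report, absent = FALSE),
            class = "prediction_equation")
}

absent_equation <- function(target, group) {
  structure(list(target = target, group = group, intercept = NA_real_,
                 terms = list(), provenance = "builtin", report = NULL,
                 absent = TRUE),
            class = "prediction_equation")
}

#' Published sensory-prediction equations
#'
#' The printed group-specific equations that predict each descriptive
#' sensory attribute from TPA attributes: ten for the fresh-frozen group
#' and nine for the IQF group, whose moisture-retention model is an
#' explicit absent-model marker (no TPA attribute qualified to enter).
#' Coefficients are verbatim constants; predictor abbreviations map to
#' canonical names (H1 = hardness1, C1b = chewiness1b, T2 = thickness2,
#' H1br = res_hardness1b, Sr = res_springiness, Cor = res_cohesiveness,
#' C1r = res_chewiness1, ...).
#'
#' @param group `"fresh-frozen"` or `"IQF"`
#' @return named list of [prediction_equation()] objects, one per sensory
#'   attribute (including `res_*` residual sensory targets)
#' @examples
#' builtin_equations("fresh-frozen")$flaky
#' @export
builtin_equations <- function(group = c("fresh-frozen", "IQF")) {
  group <- match.arg(group)
  rep_ <- function(rmse, r2, r) list(RMSE = rmse, r_squared = r2, r = r)
  eq <- function(target, intercept, terms, rmse, r2, r)
    prediction_equation(target, group, intercept, terms,
                        provenance = "builtin",
                        report = rep_(rmse, r2, r))
  if (group == "fresh-frozen") {
    list(
      cohesiveness_of_mass = eq("cohesiveness_of_mass", 1.758, list(
        eq_term(-0.0073, "chewiness1b"), eq_term(0.426, "thickness2"),
        eq_term(0.0274, "chewiness1b", "thickness2"),
        eq_term(-0.349, "thickness2", "thickness2")), 0.646, 0.240, 0.490),
      fibrous = eq("fibrous", 6.955, list(
        eq_term(-0.725, "adhesiveness"), eq_term(-0.118, "resilience")),
        0.694, 0.136, 0.369),
      firmness = eq("firmness", -0.305, list(
        eq_term(0.322, "thickness1"), eq_term(-0.001, "hardness1"),
        eq_term(0.0003, "hardness1", "hardness1")), 0.814, 0.280, 0.530),
      flaky = eq("flaky", 7.533, list(
        eq_term(-0.0124, "hardness1")), 0.680, 0.270, 0.520),
      moisture_release = eq("moisture_release", 5.126, list(
        eq_term(-0.0334, "res_hardness1"),
        eq_term(0.001, "hardness1", "hardness1")), 1.014, 0.210, 0.400),
      moisture_retention = eq("moisture_retention", 1.301, list(
        eq_term(0.354, "thickness2"), eq_term(-0.0247, "res_hardness1b"),
        eq_term(0.014, "thickness2", "res_hardness1b"),
        eq_term(-0.0004, "res_hardness1b", "res_hardness1b"),
        eq_term(-0.0723, "thickness2", "thickness2")), 0.648, 0.302, 0.549),
      springiness = eq("springiness", 3.437, list(
        eq_term(-0.094, "res_springiness"),
        eq_term(-0.0309, "res_springiness", "res_springiness")),
        0.615, 0.190, 0.430),
      res_cohesiveness_of_mass = eq("res_cohesiveness_of_mass", -10.05, list(
        eq_term(12.69, "cohesiveness"), eq_term(-0.048, "chewiness1b"),
        eq_term(0.62, "thickness2"),
        eq_term(-14.73, "cohesiveness", "thickness2"),
        eq_term(0.073, "chewiness1b", "thickness2"),
        eq_term(-0.736, "thickness2", "thickness2")), 0.590, 0.270, 0.520),
      res_firmness = eq("res_firmness", -3.723, list(
        eq_term(0.303, "thickness1"), eq_term(-0.0114, "chewiness1b"),
        eq_term(0.0018, "chewiness1b", "chewiness1b"),
        eq_term(-0.062, "thickness1", "thickness1")), 0.870, 0.097, 0.310),
      res_flaky = eq("res_flaky", 1.938, list(
        eq_term(-0.0102, "hardness2")), 0.708, 0.174, 0.417)
    )
  } else {
    list(
      cohesiveness_of_mass = eq("cohesiveness_of_mass", 1.909, list(
        eq_term(0.0043, "hardness1"), eq_term(6.512, "cohesiveness"),
        eq_term(-0.00004, "hardness1", "hardness1"),
        eq_term(315.4, "cohesiveness", "cohesiveness")),
        0.698, 0.094, 0.307),
      fibrous = eq("fibrous", 4.188, list(
        eq_term(0.0162, "hardness1"), eq_term(-0.0279, "chewiness1"),
        eq_term(-0.0003, "hardness1", "hardness1"),
        eq_term(0.0015, "chewiness1", "chewiness1")), 0.708, 0.160, 0.400),
      firmness = eq("firmness", 2.566, list(
        eq_term(0.0138, "hardness2"), eq_term(-0.0128, "chewiness2"),
        eq_term(-0.0006, "hardness2", "hardness2"),
        eq_term(0.0013, "hardness2", "chewiness2")), 0.866, 0.102, 0.319),
      flaky = eq("flaky", 6.239, list(
        eq_term(-0.0192, "hardness1b"), eq_term(0.0272, "chewiness1b"),
        eq_term(0.00006, "hardness1b", "hardness1b")), 0.862, 0.124, 0.352),
      moisture_release = eq("moisture_release", 5.577, list(
        eq_term(23.32, "res_cohesiveness"),
        eq_term(274.3, "res_cohesiveness", "res_cohesiveness")),
        1.050, 0.141, 0.375),
      moisture_retention = absent_equation("moisture_retention", group),
      springiness = eq("springiness", 1.284, list(
        eq_term(0.0122, "res_hardness1b")), 0.800, 0.117, 0.342),
      res_cohesiveness_of_mass = eq("res_cohesiveness_of_mass", 0.0936, list(
        eq_term(0.0160, "res_chewiness1")), 0.704, 0.069, 0.263),
      res_firmness = eq("res_firmness", 1.589, list(
        eq_term(-0.0761, "resilience"), eq_term(0.0761, "res_chewiness1"),
        eq_term(0.0047, "resilience", "res_chewiness1")),
        0.863, 0.100, 0.316),
      res_flaky = eq("res_flaky", -1.065, list(
        eq_term(-0.0093, "res_hardness1b"), eq_term(0.1168, "resilience"),
        eq_term(-0.0075, "resilience", "resilience")), 0.842, 0.141, 0.375)
    )
  }
}

#' Predict a sensory attribute from TPA attributes
#'
#' Evaluates a prediction equation: intercept + sum of coefficient × term,
#' where squared terms use the attribute squared and cross terms the
#' product of the two attributes.
#'
#' @param object a `prediction_equation`
#' @param newdata data frame, named list or named vector holding every
#'   attribute the equation references
#' @param ... ignored
#' @return numeric vector of predicted intensities
#' @examples
#' eq <- builtin_equations("fresh-frozen")$flaky
#' predict(eq, c(hardness1 = 220.51))
#' @export
predict.prediction_equation <- function(object, newdata, ...) {
  if (isTRUE(object$absent))
    stop_fishtpa("no model exists for '", object$target, "' in group '",
                 object$group, "'")
  if (is.numeric(newdata)) newdata <- as.list(newdata)
  needed <- unique(unlist(lapply(object$terms, `[[`, "vars")))
  miss <- needed[!vapply(needed, function(v) !is.null(newdata[[v]]),
                         logical(1))]
  if (length(miss))
    stop_fishtpa("missing attribute(s) for prediction: ",
                 paste(miss, collapse = ", "))
  n <- if (length(needed)) length(newdata[[needed[1]]]) else 1L
  out <- rep(object$intercept, n)
  for (tm in object$terms) {
    val <- newdata[[tm$vars[1]]]
    if (length(tm$vars) == 2L) val <- val * newdata[[tm$vars[2]]]
    out <- out + tm$coef * val
  }
  out
}

format_equation_terms <- function(eq) {
  abbrev <- function(v) v
  parts <- vapply(eq$terms, function(tm) {
    lbl <- if (tm$kind == "linear") tm$vars[1]
           else paste(tm$vars[1], tm$vars[2], sep = " x ")
    sprintf("%+g(%s)", tm$coef, lbl)
  }, character(1))
  paste(c(sprintf("%g", eq$intercept), parts), collapse = " ")
}

#' @export
print.prediction_equation <- function(x, ...) {
  if (isTRUE(x$absent)) {
    cat(sprintf("%s [%s]: no model (no predictor qualified)\n",
                x$target, x$group))
    return(invisible(x))
  }
  cat(sprintf("%s [%s, %s]:\n  %s\n", x$target, x$group, x$provenance,
              format_equation_terms(x)))
  if (!is.null(x$report))
    cat(sprintf("  RMSE %.3f | R2 %.3f | R %.3f\n", x$report$RMSE,
                x$report$r_squared, x$report$r))
  invisible(x)
}

#' @export
coef.prediction_equation <- function(object, ...) {
  labels <- vapply(object$terms, function(tm)
    paste(tm$vars, collapse = ":"), character(1))
  stats::setNames(c(object$intercept,
                    vapply(object$terms, `[[`, numeric(1), "coef")),
                  c("(Intercept)", labels))
}

#' Fit statistics of a prediction equation on a data set
#'
#' Computes the regression fit report for an equation evaluated against
#' observed sensory scores: `RMSE = sqrt(SSE / (n - p - 1))` (the
#' regression root-mean-square-error convention, `p` = number of terms),
#' `R^2 = 1 - SSE/SST`, `R = sqrt(R^2)` and
#' `adjusted R^2 = 1 - (1 - R^2)(n - 1)/(n - p - 1)`.
#'
#' @param eq a `prediction_equation`
#' @param data data frame holding the target column and every predictor
#' @param target observed column name (default: the equation's target)
#' @return a list of class `fit_report` with RMSE, r_squared, adj_r_squared,
#'   r, n, p
#' @examples
#' d <- data.frame(hardness1 = c(180, 200, 220, 240, 260))
#' d$flaky <- 7.533 - 0.0124 * d$hardness1
#' evaluate_equation(builtin_equations("fresh-frozen")$flaky, d)
#' @export
evaluate_equation <- function(eq, data, target = eq$target) {
  if (!target %in% names(data))
    stop_fishtpa("no observed column '", target, "' in data")
  y <- data[[target]]
  ok <- is.finite(y)
  pred <- predict(eq, data[ok, , drop = FALSE])
  y <- y[ok]
  n <- length(y)
  p <- length(eq$terms)
  if (n <= p + 1)
    stop_fishtpa("need n > p + 1 observations (n = ", n, ", p = ", p, ")")
  sse <- sum((y - pred)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  if (!is.na(r2) && r2 < 0) {
    warning("negative R-squared: equation fits worse than the mean",
            call. = FALSE)
  }
  r <- if (!is.na(r2) && r2 >= 0) sqrt(r2) else NA_real_
  structure(list(RMSE = sqrt(sse / (n - p - 1)),
                 r_squared = r2,
                 adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - p - 1),
                 r = r, n = n, p = p),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("fit report: n=%d p=%d RMSE=%.4f R2=%.4f adjR2=%.4f R=%.4f\n",
              x$n, x$p, x$RMSE, x$r_squared, x$adj_r_squared, x$r))
  invisible(x)
}
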