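#' Published thickness-residualization lines
#'
#' The fixed linear relations used to remove the fillet-thickness
#' contribution from an attribute: each residual attribute is
#' `value - (slope * thickness2 + intercept)`. Five TPA attributes
#' (chewiness-1, chewiness-1b, cohesiveness, hardness-1b, springiness) and
#' three sensory attributes (cohesiveness of mass, firmness, flaky) have
#' published lines; residual hardness-1 has none and must be cohort-fitted
#' with [fit_thickness_line()].
#'
#' @return named list of `residual_line` objects
#' @examples
#' builtin_lines()$springiness
#' @export
builtin_lines <- function() {
  mk <- function(attribute, slope, intercept)
    new_residual_line(attribute, slope, intercept, source = "builtin")
  list(
    chewiness1 = mk("chewiness1", 8.215, -17.386),
    chewiness1b = mk("chewiness1b", 9.807, -54.626),
    cohesiveness = mk("cohesiveness", 0.005, 0.421),
    hardness1b = mk("hardness1b", 26.845, -138.455),
    springiness = mk("springiness", 1.008, 60.275),
    cohesiveness_of_mass = mk("cohesiveness_of_mass", 0.147, 4.332),
    firmness = mk("firmness", 0.151, 2.531),
    flaky = mk("flaky", -0.159, 6.546)
  )
}

new_residual_line <- function(attribute, slope, intercept,
                              source = c("builtin", "fitted"),
                              n = NA_integer_, r_squared = NA_real_) {
  if (!is.finite(slope) || !is.finite(intercept))
    stop_fishtpa("residual line needs finite slope and intercept")
  structure(list(attribute = attribute, slope = slope,
                 intercept = intercept, source = match.arg(source),
                 n = n, r_squared = r_squared),
            class = "residual_line")
}

#' @export
print.residual_line <- function(x, ...) {
  cat(sprintf("residual %s = %s - (%g * thickness2 %s %g)  [%s%s]\n",
              x$attribute, x$attribute, x$slope,
              if (x$intercept >= 0) "+" else "-", abs(x$intercept),
              x$source,
              if (x$source == "fitted")
                sprintf(", n=%d, R2=%.3f", x$n, x$r_squared) else ""))
  invisible(x)
}

#' Remove the thickness contribution from an attribute value
#'
#' @param value attribute value(s)
#' @param thickness2 post-compression fillet thickness, mm (same length as
#'   `value` or length 1)
#' @param line a `residual_line` (from [builtin_lines()] or
#'   [fit_thickness_line()])
#' @return `value - (slope * thickness2 + intercept)`
#' @examples
#' residualize(78.07, 10.69, builtin_lines()$chewiness1)
#' @export
residualize <- function(value, thickness2, line) {
  stopifnot(inherits(line, "residual_line"))
  if (!all(is.finite(value)) || !all(is.finite(thickness2)))
    stop_fishtpa("residualize needs finite inputs")
  value - (line$slope * thickness2 + line$intercept)
}

#' Fit a thickness-residualization line by ordinary least squares
#'
#' Regresses an attribute on thickness-2 across fish and returns the line
#' whose residuals have mean zero on the fitting sample.
#'
#' @param values attribute values, one per fish (fish means)
#' @param thickness2 thickness-2 per fish, mm
#' @param attribute name recorded on the line
#' @return a `residual_line` with `source = "fitted"` and fit diagnostics
#' @examples
#' t2 <- c(9, 10, 11, 12)
#' fit_thickness_line(8.215 * t2 - 17.386, t2)
#' @export
fit_thickness_line <- function(values, thickness2, attribute = "attribute") {
  ok <- is.finite(values) & is.finite(thickness2)
  values <- values[ok]; thickness2 <- thickness2[ok]
  if (length(values) < 3)
    stop_fishtpa("need at least 3 fish to fit a thickness line, got ",
                 length(values))
  if (stats::sd(thickness2) == 0)
    stop_fishtpa("thickness2 is constant: singular fit")
  fit <- stats::lm(values ~ thickness2)
  sst <- sum((values - mean(values))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  new_residual_line(attribute, slope = unname(stats::coef(fit)[2]),
                    intercept = unname(stats::coef(fit)[1]),
                    source = "fitted", n = length(values), r_squared = r2)
}

#' Residualize attribute columns of a cohort table
#'
#' Applies either the published lines (`mode = "builtin"`) or cohort-fitted
#' lines (`mode = "fit"`) to the named attribute columns, adding
#' `res_<attribute>` columns. Residual hardness-1 has no published line and
#' is always cohort-fitted; a message notes this whenever it is requested
#' in builtin mode.
#'
#' @param data data frame with a `thickness2` column and the attribute
#'   columns
#' @param attributes attribute names to residualize (default: all with a
#'   published line that are present in `data`)
#' @param mode `"builtin"` (published constants) or `"fit"` (OLS on `data`)
#' @return `data` with `res_*` columns appended
#' @export
add_residuals <- function(data, attributes = NULL,
                          mode = c("builtin", "fit")) {
  mode <- match.arg(mode)
  if (!"thickness2" %in% names(data))
    stop_fishtpa("data lacks a thickness2 column")
  lines <- builtin_lines()
  if (is.null(attributes))
    attributes <- intersect(names(lines), names(data))
  for (a in attributes) {
    if (!a %in% names(data))
      stop_fishtpa("data lacks attribute column '", a, "'")
    line <- if (mode == "fit" || is.null(lines[[a]])) {
      if (mode == "builtin")
        message("no published line for '", a, "'; fitting from the cohort")
      fit_thickness_line(data[[a]], data$thickness2, attribute = a)
    } else lines[[a]]
    data[[paste0("res_", a)]] <- residualize(data[[a]], data$thickness2,
                                             line)
  }
  data
}
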