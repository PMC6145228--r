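#' Forward stepwise regression with squared and cross-product augmentation
#'
#' Two-phase forward selection used to derive sensory-prediction equations
#' from TPA attributes. Phase 1 considers the main-effect candidates: at
#' each step the candidate with the smallest partial-F p-value (given the
#' current model) enters if that p-value is below `alpha` (the stopping
#' rule), otherwise selection stops. Phase 2 restricts the candidate pool
#' to the squares and pairwise cross products of the phase-1 survivors and
#' applies the same forward rule. Ties on the entry p-value are broken by
#' the larger R-squared gain, then alphabetically.
#'
#' @param y numeric response (per-fish sensory scores)
#' @param X data frame of candidate predictors (per-fish TPA attributes and
#'   residuals)
#' @param alpha entry threshold on the partial-F p-value (default 0.05)
#' @param target name of the response recorded on the equation
#' @param group treatment-group label recorded on the equation
#' @param interactions if `FALSE`, skip phase 2
#' @return an object of class `tpa_stepwise` (inheriting
#'   `prediction_equation`) with elements `terms`, `report` (RMSE,
#'   r_squared, adj_r_squared, r, n, p, per-term entry p-values), `fitted`
#'   and `residuals`. If no candidate qualifies the model is
#'   intercept-only.
#' @examples
#' set.seed(1)
#' X <- data.frame(hardness1 = rnorm(100, 200, 40),
#'                 resilience = rnorm(100, 22, 3))
#' y <- 2 + 0.02 * X$hardness1 + rnorm(100, 0, 0.5)
#' stepwise_fit(y, X)
#' @export
stepwise_fit <- function(y, X, alpha = 0.05, target = "sensory",
                         group = NA_character_, interactions = TRUE) {
  X <- as.data.frame(X)
  ok <- is.finite(y) & stats::complete.cases(X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y)
  if (n < 4) stop_fishtpa("too few observations for stepwise selection")
  const <- vapply(X, function(v) stats::sd(v) == 0, logical(1))
  if (any(const))
    stop_fishtpa("constant candidate column(s): ",
                 paste(names(X)[const], collapse = ", "))

  # candidate columns keyed by term signature
  cand1 <- stats::setNames(lapply(names(X), function(v) list(
    vars = v, col = X[[v]])), names(X))

  sel <- forward_pass(y, Z = matrix(1, n, 1), selected = list(),
                      candidates = cand1, alpha = alpha)

  if (interactions && length(sel$selected)) {
    vars1 <- vapply(sel$selected, function(s) s$vars[1], character(1))
    cand2 <- list()
    for (i in seq_along(vars1)) for (j in i:length(vars1)) {
      vi <- vars1[i]; vj <- vars1[j]
      key <- paste(sort(c(vi, vj)), collapse = ":")
      if (is.null(cand2[[key]]))
        cand2[[key]] <- list(vars = c(vi, vj), col = X[[vi]] * X[[vj]])
    }
    sel <- forward_pass(y, Z = sel$Z, selected = sel$selected,
                        candidates = cand2, alpha = alpha)
  }

  fit <- stats::lm.fit(sel$Z, y)
  beta <- fit$coefficients
  terms <- list()
  for (k in seq_along(sel$selected)) {
    s <- sel$selected[[k]]
    terms[[k]] <- eq_term(unname(beta[k + 1L]), s$vars[1],
                          if (length(s$vars) == 2L) s$vars[2] else NULL)
  }
  p <- length(terms)
  sse <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 0
  report <- list(
    RMSE = sqrt(sse / (n - p - 1)),
    r_squared = r2,
    adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - p - 1),
    r = sqrt(max(r2, 0)),
    n = n, p = p,
    entry_p = stats::setNames(vapply(sel$selected, `[[`, numeric(1),
                                     "entry_p"),
                              vapply(sel$selected, function(s)
                                paste(s$vars, collapse = ":"),
                                character(1))))
  out <- prediction_equation(target = target, group = group,
                             intercept = unname(beta[1]), terms = terms,
                             provenance = "fitted", report = report)
  out$fitted <- unname(fit$fitted.values)
  out$residuals <- unname(fit$residuals)
  out$y <- y
  class(out) <- c("tpa_stepwise", class(out))
  out
}

# One forward-selection pass: repeatedly add the candidate with the
# smallest partial-F p-value while it is below alpha.
forward_pass <- function(y, Z, selected, candidates, alpha) {
  n <- length(y)
  remaining <- candidates
  sse0 <- sum(stats::lm.fit(Z, y)$residuals^2)
  repeat {
    if (!length(remaining)) break
    best <- NULL
    for (key in sort(names(remaining))) {
      cc <- remaining[[key]]
      Zc <- cbind(Z, cc$col)
      fit <- stats::lm.fit(Zc, y)
      if (fit$rank < ncol(Zc)) {
        warning("candidate '", key,
                "' is collinear with the current model; skipped",
                call. = FALSE)
        remaining[[key]] <- NULL
        next
      }
      df2 <- n - ncol(Zc)
      if (df2 < 1) next
      sse1 <- sum(fit$residuals^2)
      fstat <- if (sse1 <= 0) Inf else (sse0 - sse1) / (sse1 / df2)
      pval <- stats::pf(fstat, 1, df2, lower.tail = FALSE)
      # ties on p broken by larger R2 gain (smaller SSE), then by the
      # alphabetical order of the sorted loop
      if (is.null(best) || pval < best$p - 1e-12 ||
          (abs(pval - best$p) <= 1e-12 && sse1 < best$sse - 1e-12)) {
        best <- list(key = key, p = pval, sse = sse1, Z = Zc, cand = cc)
      }
    }
    if (is.null(best) || !(best$p < alpha)) break
    s <- best$cand
    s$entry_p <- best$p
    selected[[length(selected) + 1L]] <- s
    Z <- best$Z
    sse0 <- best$sse
    remaining[[best$key]] <- NULL
  }
  list(Z = Z, selected = selected)
}

#' @export
print.tpa_stepwise <- function(x, ...) {
  cat(sprintf("Forward-stepwise equation for '%s'%s (n = %d):\n  %s\n",
              x$target,
              if (!is.na(x$group)) paste0(" [", x$group, "]") else "",
              x$report$n, format_equation_terms(x)))
  cat(sprintf("  RMSE %.3f | R2 %.3f | adj R2 %.3f | R %.3f\n",
              x$report$RMSE, x$report$r_squared, x$report$adj_r_squared,
              x$report$r))
  invisible(x)
}

#' @export
summary.tpa_stepwise <- function(object, ...) {
  cat(sprintf("Forward stepwise selection, stopping rule p < alpha\n"))
  print(object)
  if (length(object$report$entry_p)) {
    cat("  entry p-values:\n")
    ep <- object$report$entry_p
    for (k in seq_along(ep))
      cat(sprintf("    %d. %-30s %.4g\n", k, names(ep)[k], ep[k]))
  } else {
    cat("  no candidate qualified; intercept-only model\n")
  }
  invisible(object)
}

#' @export
residuals.tpa_stepwise <- function(object, ...) object$residuals

#' @export
fitted.tpa_stepwise <- function(object, ...) object$fitted

#' Derive a sensory-prediction equation from a cohort table
#'
#' Convenience wrapper around [stepwise_fit()] using the canonical
#' candidate pool: the twelve TPA attributes plus the five TPA thickness
#' residuals (res_chewiness1, res_chewiness1b, res_cohesiveness,
#' res_hardness1b, res_springiness) — the union of predictors appearing in
#' the published equations. Fitting is group-specific by default; pass
#' `group = NULL` to pool the treatments.
#'
#' @param data per-fish data frame (see [aggregate_fish()] and
#'   [add_residuals()]) with a `treatment` column when `group` is given
#' @param target sensory column to predict
#' @param group treatment to subset on, or `NULL` for pooled fitting
#' @param alpha entry threshold (default 0.05)
#' @param ... passed to [stepwise_fit()]
#' @return a `tpa_stepwise` object
#' @export
fit_sensory_equation <- function(data, target, group = NULL, alpha = 0.05,
                                 ...) {
  if (!is.null(group)) {
    if (!"treatment" %in% names(data))
      stop_fishtpa("data lacks a treatment column")
    data <- data[data$treatment == group, , drop = FALSE]
    if (!nrow(data)) stop_fishtpa("no rows for treatment '", group, "'")
  }
  pool <- c(tpa_attribute_names(),
            paste0("res_", c("chewiness1", "chewiness1b", "cohesiveness",
                             "hardness1b", "springiness")))
  pool <- intersect(pool, names(data))
  if (!target %in% names(data))
    stop_fishtpa("no sensory column '", target, "' in data")
  stepwise_fit(data[[target]], data[pool], alpha = alpha, target = target,
               group = if (is.null(group)) "pooled" else group, ...)
}
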