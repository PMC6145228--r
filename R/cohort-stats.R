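#' Aggregate repeated measures to one row per fish
#'
#' Unweighted arithmetic mean of the available test points for every
#' numeric attribute column; missing points are simply omitted, so
#' unbalanced data are tolerated. Fish with no valid measurement of any
#' attribute are dropped with a warning. When a per-fish sensory table is
#' supplied it is merged on `fish_id`.
#'
#' @param tpa per-point data frame with `fish_id`, `treatment` and numeric
#'   attribute columns (e.g. the `$tpa` element of [simulate_cohort()], or
#'   the `$tpa` of [read_cohort()])
#' @param sensory optional per-fish data frame keyed by `fish_id`
#' @return data frame with one row per fish
#' @examples
#' co <- simulate_cohort(cohort_spec(n_fish = c(IQF = 3, "fresh-frozen" = 2),
#'                                   seed = 2))
#' nrow(aggregate_fish(co$tpa, co$sensory))
#' @export
aggregate_fish <- function(tpa, sensory = NULL) {
  if (inherits(tpa, "tpa_cohort")) {
    if (is.null(sensory)) sensory <- tpa$sensory
    tpa <- tpa$tpa
  }
  if (!"fish_id" %in% names(tpa)) stop_fishtpa("tpa lacks a fish_id column")
  num <- names(tpa)[vapply(tpa, is.numeric, logical(1))]
  num <- setdiff(num, "point")
  ids <- unique(tpa$fish_id)
  rows <- lapply(ids, function(id) {
    sub <- tpa[tpa$fish_id == id, , drop = FALSE]
    means <- vapply(num, function(a) mean(sub[[a]], na.rm = TRUE),
                    numeric(1))
    if (all(is.nan(means))) return(NULL)
    out <- data.frame(fish_id = id)
    if ("treatment" %in% names(sub)) out$treatment <- sub$treatment[1]
    cbind(out, as.data.frame(as.list(means)))
  })
  empty <- vapply(rows, is.null, logical(1))
  if (any(empty))
    warning(sum(empty), " fish with no valid measurements dropped",
            call. = FALSE)
  agg <- do.call(rbind, rows[!empty])
  agg[num] <- lapply(agg[num], function(v) ifelse(is.nan(v), NA, v))
  if (!is.null(sensory)) {
    keep <- setdiff(names(sensory), "treatment")
    # a sensory attribute sharing a TPA name (springiness) gets "_sens"
    agg <- merge(agg, sensory[keep], by = "fish_id", all.x = TRUE,
                 sort = FALSE, suffixes = c("", "_sens"))
  }
  agg
}

#' Compare one attribute between two treatment groups
#'
#' One-way fixed-effects ANOVA on per-fish means. With two groups the F
#' statistic equals the square of the pooled-variance two-sample t
#' statistic, and the p-value is the usual two-sided one.
#'
#' @param data per-fish data frame (see [aggregate_fish()])
#' @param attribute column to compare
#' @param group_col grouping column (default `"treatment"`)
#' @return an object of class `group_comparison`: per-group n/mean/sd
#'   (across fish), F statistic, p-value and the 0.05 significance flag
#' @examples
#' d <- data.frame(treatment = rep(c("A", "B"), each = 3),
#'                 y = c(1, 2, 3, 4, 5, 6))
#' compare_groups(d, "y")
#' @export
compare_groups <- function(data, attribute, group_col = "treatment") {
  if (!attribute %in% names(data))
    stop_fishtpa("no column '", attribute, "' in data")
  y <- data[[attribute]]
  gv <- as.character(data[[group_col]])
  g <- factor(gv, levels = sort(unique(gv), method = "radix"))
  ok <- is.finite(y) & !is.na(g)
  y <- y[ok]; g <- droplevels(g[ok])
  if (nlevels(g) != 2)
    stop_fishtpa("compare_groups needs exactly 2 groups, found ",
                 nlevels(g))
  n <- tapply(y, g, length)
  if (any(n < 2)) stop_fishtpa("each group needs at least 2 fish")
  means <- tapply(y, g, mean)
  sds <- tapply(y, g, stats::sd)
  grand <- mean(y)
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum((y - means[g])^2)
  df1 <- 1L
  df2 <- length(y) - 2L
  if (ss_within == 0) {
    f <- if (ss_between == 0) 0 else Inf
  } else {
    f <- (ss_between / df1) / (ss_within / df2)
  }
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  structure(list(attribute = attribute,
                 groups = levels(g), n = as.vector(n),
                 mean = as.vector(means), sd = as.vector(sds),
                 F = f, p = p, df = c(df1, df2),
                 significant = is.finite(p) && p < 0.05),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s %.3f±%.3f (n=%d) vs %s %.3f±%.3f (n=%d)\n",
              x$attribute, x$groups[1], x$mean[1], x$sd[1], x$n[1],
              x$groups[2], x$mean[2], x$sd[2], x$n[2]))
  cat(sprintf("  F(1,%d) = %.3f, p = %.4g%s\n", x$df[2], x$F, x$p,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Summary table of group means, SDs and p-values per attribute
#'
#' One row per attribute, mirroring the layout of published cohort tables:
#' per-group mean and SD across fish, and the two-group ANOVA p-value.
#' Attributes that are absent or all-missing get a row of `NA`s.
#'
#' @param data per-fish data frame (see [aggregate_fish()])
#' @param attributes columns to summarize (default: all numeric)
#' @param group_col grouping column (default `"treatment"`)
#' @return data frame with columns attribute, `<group1>_mean`, `<group1>_sd`,
#'   `<group1>_n`, likewise for group 2, and `p_value`
#' @export
summarize_cohort <- function(data, attributes = NULL,
                             group_col = "treatment") {
  if (is.null(attributes)) {
    attributes <- names(data)[vapply(data, is.numeric, logical(1))]
    attributes <- setdiff(attributes, c("point"))
  }
  gl <- sort(unique(as.character(data[[group_col]])), method = "radix")
  rows <- lapply(attributes, function(a) {
    out <- data.frame(attribute = a,
                      g1_mean = NA_real_, g1_sd = NA_real_, g1_n = NA_integer_,
                      g2_mean = NA_real_, g2_sd = NA_real_, g2_n = NA_integer_,
                      p_value = NA_real_)
    cmp <- tryCatch(compare_groups(data, a, group_col), error = function(e) NULL)
    if (!is.null(cmp)) {
      out[1, 2:8] <- c(cmp$mean[1], cmp$sd[1], cmp$n[1],
                       cmp$mean[2], cmp$sd[2], cmp$n[2], cmp$p)
    }
    out
  })
  res <- do.call(rbind, rows)
  names(res) <- c("attribute",
                  paste0(gl[1], c("_mean", "_sd", "_n")),
                  paste0(gl[2], c("_mean", "_sd", "_n")),
                  "p_value")
  res
}
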