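# Default per-group calibration of the eight base attributes: published
# cohort moments for commercially processed (IQF) and fresh-frozen catfish.
# thickness-2 and the chewiness family are derived, not drawn.
default_attribute_targets <- function() {
  base <- c("adhesiveness", "cohesiveness", "hardness1", "hardness1b",
            "hardness2", "resilience", "springiness", "thickness1")
  data.frame(
    attribute = rep(base, 2),
    treatment = rep(c("IQF", "fresh-frozen"), each = length(base)),
    mean = c(-1.13, 0.48, 200.34, 151.22, 178.06, 21.73, 69.77, 15.73,
             -1.17, 0.47, 220.51, 158.15, 194.68, 23.50, 73.84, 14.47),
    sd = c(0.35, 0.02, 42.19, 42.45, 38.16, 2.84, 2.51, 1.53,
           0.28, 0.03, 34.81, 29.31, 34.05, 1.79, 2.65, 1.09),
    stringsAsFactors = FALSE
  )
}

# Default linear maps from fish-mean TPA attributes to the seven descriptive
# sensory attributes (0-15 intensity scale), calibrated so group means land
# near the published sensory panel means.
default_sensory_links <- function(noise_sd = 0.7) {
  mk <- function(intercept, coefs) list(intercept = intercept, coefs = coefs,
                                        noise_sd = noise_sd)
  list(
    cohesiveness_of_mass = mk(1.17, c(cohesiveness = 10)),
    fibrous = mk(9.025, c(resilience = -0.17)),
    firmness = mk(1.08, c(hardness1 = 0.015)),
    flaky = mk(7.533, c(hardness1 = -0.0124)),
    moisture_release = mk(13.52, c(hardness1 = -0.0387)),
    moisture_retention = mk(-21.44, c(cohesiveness = 56)),
    springiness = mk(4.632, c(springiness = -0.0221))
  )
}

#' Specification of a synthetic two-treatment cohort
#'
#' Defines the study design the simulator emulates: two processing
#' treatments (commercial IQF and fresh-frozen), a number of fish per
#' treatment, eight probe points per fillet, per-treatment target moments
#' for the base TPA attributes, and a linear sensory link.
#'
#' @param n_fish named integer vector: fish per treatment (default
#'   `c(IQF = 60, "fresh-frozen" = 34)`)
#' @param points_per_fillet test points per fillet (default 8)
#' @param targets data frame with columns attribute/treatment/mean/sd; the
#'   default calibrates the eight base attributes to the published cohort
#'   moments (see `fishtpa::default`s in the vignette)
#' @param within_sd_frac within-fish (point-to-point) SD as a fraction of
#'   the between-fish SD (default 0.5)
#' @param sensory_links named list of linear links (intercept, coefs,
#'   noise_sd) from TPA attributes to each sensory attribute
#' @param seed integer seed making the cohort fully reproducible
#' @return an object of class `cohort_spec`
#' @examples
#' cohort_spec(n_fish = c(IQF = 10, "fresh-frozen" = 6), seed = 1)
#' @export
cohort_spec <- function(n_fish = c("IQF" = 60, "fresh-frozen" = 34),
                        points_per_fillet = 8,
                        targets = default_attribute_targets(),
                        within_sd_frac = 0.5,
                        sensory_links = default_sensory_links(),
                        seed = 1) {
  if (is.null(names(n_fish)) || any(!nzchar(names(n_fish))))
    stop_fishtpa("n_fish must be a named vector of treatment sizes")
  if (any(n_fish < 2)) stop_fishtpa("need at least 2 fish per treatment")
  check_number(points_per_fillet, "points_per_fillet", lower = 1)
  stopifnot(all(c("attribute", "treatment", "mean", "sd") %in% names(targets)))
  if (any(targets$sd < 0)) stop_fishtpa("target SDs must be >= 0")
  coh <- targets[targets$attribute == "cohesiveness", ]
  if (nrow(coh) && any(coh$mean <= 0 | coh$mean >= 1))
    stop_fishtpa("cohesiveness target mean must lie in (0, 1)")
  check_number(within_sd_frac, "within_sd_frac", lower = 0)
  structure(list(n_fish = n_fish, points_per_fillet = points_per_fillet,
                 targets = targets, within_sd_frac = within_sd_frac,
                 sensory_links = sensory_links, seed = seed),
            class = "cohort_spec")
}

#' Simulate a whole cohort of fish with TPA and linked sensory profiles
#'
#' Draws per-fish Gaussian means of the base TPA attributes at the
#' spec's target moments, adds within-fish point-to-point noise for the
#' `points_per_fillet` probe positions, derives thickness-2
#' (= thickness-1 × springiness/100) and the chewiness family by the TPA
#' formulas at every point, and generates sensory scores from the linear
#' link at the fish-mean TPA values (Gaussian noise, clipped to the 0-15
#' intensity scale). Fully reproducible from the spec's seed.
#'
#' @param spec a [cohort_spec()]
#' @param curves if `TRUE`, also simulate one force-time curve per test
#'   point (calibrated to that point's attribute values); slower
#' @return an object of class `tpa_cohort`: `tpa` (per-point attribute data
#'   frame with fish_id, treatment, side, point), `sensory` (per-fish
#'   scores), `truth` (per-fish latent attribute means), and `curves`
#'   (list of `tpa_curve`, when requested)
#' @examples
#' co <- simulate_cohort(cohort_spec(n_fish = c(IQF = 4, "fresh-frozen" = 3),
#'                                   seed = 7))
#' head(co$tpa)
#' @export
simulate_cohort <- function(spec, curves = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    base <- unique(spec$targets$attribute)
    fish <- list(); pts <- list(); sens <- list()
    fid <- 0L
    for (tr in names(spec$n_fish)) {
      tg <- spec$targets[spec$targets$treatment == tr, ]
      if (!nrow(tg)) stop_fishtpa("no targets for treatment '", tr, "'")
      for (i in seq_len(spec$n_fish[[tr]])) {
        fid <- fid + 1L
        mu <- stats::setNames(stats::rnorm(nrow(tg), tg$mean, tg$sd),
                              tg$attribute)
        npt <- spec$points_per_fillet
        pt <- vapply(tg$attribute, function(a) {
          mu[[a]] + stats::rnorm(npt, 0, spec$within_sd_frac *
                                   tg$sd[tg$attribute == a])
        }, numeric(npt))
        pt <- as.data.frame(matrix(pt, nrow = npt,
                                   dimnames = list(NULL, tg$attribute)))
        pt <- derive_composites(pt)
        pt <- cbind(data.frame(fish_id = sprintf("F%03d", fid),
                               treatment = tr,
                               side = "left",
                               point = seq_len(npt)), pt)
        pts[[fid]] <- pt
        truth <- derive_composites(as.data.frame(as.list(mu)))
        truth <- cbind(data.frame(fish_id = sprintf("F%03d", fid),
                                  treatment = tr), truth)
        fish[[fid]] <- truth
        # sensory from the fish-mean TPA of this fish
        tpa_mean <- colMeans(pt[tpa_attribute_names()])
        sc <- lapply(spec$sensory_links, function(lk)
          eval_link(tpa_mean, lk))
        sens[[fid]] <- cbind(data.frame(fish_id = sprintf("F%03d", fid),
                                        treatment = tr),
                             as.data.frame(sc))
      }
    }
    tpa <- do.call(rbind, pts)
    out <- list(tpa = tpa,
                sensory = do.call(rbind, sens),
                truth = do.call(rbind, fish),
                spec = spec)
    if (curves) {
      out$curves <- lapply(seq_len(nrow(tpa)), function(i) {
        r <- tpa[i, ]
        fp <- fillet_from_attributes(
          thickness1 = r$thickness1, hardness1 = r$hardness1,
          hardness2 = r$hardness2, cohesiveness = r$cohesiveness,
          springiness = r$springiness, resilience = r$resilience,
          adhesiveness = r$adhesiveness)
        simulate_curve(tpa_protocol(), fp,
                       meta = list(fish_id = r$fish_id,
                                   treatment = r$treatment,
                                   side = r$side, point = r$point))
      })
    }
    class(out) <- "tpa_cohort"
    out
  })
}

# thickness-2 and the chewiness family follow from the base attributes by
# the TPA formulas, keeping every row internally consistent
derive_composites <- function(d) {
  d$thickness2 <- d$thickness1 * d$springiness / 100
  d$chewiness1 <- d$hardness1 * d$cohesiveness * d$springiness / 100
  d$chewiness1b <- d$hardness1b * d$cohesiveness * d$springiness / 100
  d$chewiness2 <- d$hardness2 * d$cohesiveness * d$springiness / 100
  d[tpa_attribute_names()]
}

eval_link <- function(tpa_values, link) {
  miss <- setdiff(names(link$coefs), names(tpa_values))
  if (length(miss))
    stop_fishtpa("sensory link references unknown attribute '", miss[1], "'")
  raw <- link$intercept +
    sum(link$coefs * unlist(tpa_values[names(link$coefs)])) +
    stats::rnorm(1, 0, link$noise_sd)
  min(max(raw, 0), 15)
}

#' Generate one sensory profile from a TPA profile via a linear link
#'
#' score = intercept + sum(coef × attribute) + Gaussian(0, noise_sd),
#' clipped to the 0-15 descriptive intensity scale.
#'
#' @param tpa a `tpa_profile`, or a named list/vector of attribute values
#' @param links named list of links, each `list(intercept, coefs, noise_sd)`
#'   with `coefs` a named vector over TPA attributes
#' @param seed optional integer seed
#' @return named numeric vector of sensory scores
#' @examples
#' sensory_link(c(hardness1 = 200),
#'              list(firmness = list(intercept = 0,
#'                                   coefs = c(hardness1 = 0.02),
#'                                   noise_sd = 0)))
#' @export
sensory_link <- function(tpa, links, seed = NULL) {
  vals <- if (inherits(tpa, "tpa_profile"))
    unlist(tpa[tpa_attribute_names()]) else unlist(tpa)
  with_seed(seed,
            vapply(links, function(lk) eval_link(vals, lk), numeric(1)))
}

#' @export
print.tpa_cohort <- function(x, ...) {
  cat(sprintf("Synthetic TPA cohort: %d fish (%s), %d test points\n",
              nrow(x$truth),
              paste(names(table(x$truth$treatment)),
                    table(x$truth$treatment), sep = "=", collapse = ", "),
              nrow(x$tpa)))
  invisible(x)
}
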