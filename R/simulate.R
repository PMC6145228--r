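# fixed geometry of the simulated test: approach gap above the sample, toe
# width over which force climbs to the trigger, and adhesion-dip duration
.GAP_MM <- 2.0
.TOE_MM <- 0.1
.TAU_ADH <- 1.0

#' Simulate a double-compression force-time curve
#'
#' Emits a complete TPA trace for one test point: approach, first
#' compression to `strain` of the initial thickness, withdrawal with an
#' optional negative adhesion dip, a pause during which the surface partially
#' recovers, and a second compression to the same absolute probe depth.
#' Because the compression limb is defined to cross the trigger force exactly
#' at nominal contact, the ground-truth attributes attached to the curve are
#' exact closed forms of the generator parameters.
#'
#' @param protocol a [tpa_protocol()]
#' @param fillet a [fillet_params()]
#' @param seed optional integer seed for the force noise (restores the
#'   caller's RNG state afterwards)
#' @param meta optional named list of metadata (fish_id, treatment, point,
#'   side) carried on the curve
#' @return an object of class `tpa_curve`: numeric vectors `time` (s),
#'   `force` (N) and `displacement` (mm of probe travel from approach start),
#'   plus `protocol`, `meta` and `truth` — the closed-form attribute values
#'   of the noiseless curve (see [tpa_attribute_names()])
#' @examples
#' cv <- simulate_curve(tpa_protocol(), fillet_params(15), seed = 1)
#' cv$truth$springiness
#' @export
simulate_curve <- function(protocol = tpa_protocol(),
                           fillet = fillet_params(15),
                           seed = NULL, meta = list()) {
  stopifnot(inherits(protocol, "tpa_protocol"),
            inherits(fillet, "fillet_params"))
  g <- curve_geometry(protocol, fillet)

  v_pre <- protocol$pretest_speed
  v <- protocol$test_speed
  v_post <- protocol$posttest_speed

  # phases: duration, start depth, speed (signed, mm/s down), force function
  # of depth z and time-within-phase dt
  F_t <- g$F_t; S <- g$S; S2 <- g$S2
  d1 <- g$d1; d2 <- g$d2; du <- g$du; du2 <- g$du2
  z_c <- g$z_c; z_b <- g$z_b; z_s2 <- g$z_s2
  p <- fillet$stiffness_shape; p2 <- g$p2
  A <- fillet$adhesion_depth

  z_adh_end <- z_b - du - v_post * .TAU_ADH
  if (z_adh_end < 0)
    stop_fishtpa("fillet too thin for the withdrawal adhesion dip; ",
                 "increase thickness_mm or posttest_speed")

  phases <- list(
    list(dur = z_c / v_pre, z0 = 0, sp = v_pre,
         f = function(z, dt) ifelse(z < .GAP_MM, 0,
                                    F_t * (z - .GAP_MM) / .TOE_MM)),
    list(dur = d1 / v, z0 = z_c, sp = v,
         f = function(z, dt) F_t + (S - F_t) * ((z - z_c) / d1)^p),
    list(dur = du / v_post, z0 = z_b, sp = -v_post,
         f = function(z, dt) S * pmax(0, 1 - (z_b - z) / du)^p),
    list(dur = .TAU_ADH, z0 = z_b - du, sp = -v_post,
         f = function(z, dt) -A * sin(pi * dt / .TAU_ADH)),
    list(dur = z_adh_end / v_post, z0 = z_adh_end, sp = -v_post,
         f = function(z, dt) 0),
    list(dur = protocol$pause_s, z0 = 0, sp = 0, f = function(z, dt) 0),
    list(dur = (z_s2 - .TOE_MM) / v, z0 = 0, sp = v,
         f = function(z, dt) 0),
    list(dur = .TOE_MM / v, z0 = z_s2 - .TOE_MM, sp = v,
         f = function(z, dt) F_t * (z - (z_s2 - .TOE_MM)) / .TOE_MM),
    list(dur = d2 / v, z0 = z_s2, sp = v,
         f = function(z, dt) F_t + (S2 - F_t) * ((z - z_s2) / d2)^p2),
    list(dur = du2 / v_post, z0 = z_b, sp = -v_post,
         f = function(z, dt) S2 * pmax(0, 1 - (z_b - z) / du2)^p2),
    list(dur = (z_b - du2) / v_post, z0 = z_b - du2, sp = -v_post,
         f = function(z, dt) 0)
  )

  t_ends <- cumsum(vapply(phases, `[[`, numeric(1), "dur"))
  t_starts <- c(0, t_ends[-length(t_ends)])
  tt <- seq(0, t_ends[length(t_ends)], by = 1 / protocol$sample_rate)
  ph <- findInterval(tt, t_ends, left.open = TRUE) + 1L
  ph[ph > length(phases)] <- length(phases)

  z <- numeric(length(tt))
  f <- numeric(length(tt))
  for (i in seq_along(phases)) {
    idx <- which(ph == i)
    if (!length(idx)) next
    dt <- tt[idx] - t_starts[i]
    zi <- phases[[i]]$z0 + phases[[i]]$sp * dt
    z[idx] <- zi
    f[idx] <- phases[[i]]$f(zi, dt)
  }
  if (fillet$noise_sd > 0)
    f <- f + with_seed(seed, stats::rnorm(length(f), 0, fillet$noise_sd))

  new_tpa_curve(time = tt, force = f, displacement = z,
                protocol = protocol, meta = meta, truth = g$truth)
}

# Closed-form geometry and ground-truth attributes shared by the simulator
# and its calibration inverse.
curve_geometry <- function(protocol, fillet) {
  F_t <- gf_to_newton(protocol$trigger_force)
  S <- fillet$stiffness_scale
  if (F_t >= S)
    stop_fishtpa("trigger force exceeds the peak force; no contact possible")
  S2 <- fillet$hardness2_ratio * S
  p <- fillet$stiffness_shape
  d1 <- protocol$strain * fillet$thickness_mm
  d2 <- fillet$recovery_fraction * d1
  if (d2 <= .TOE_MM)
    stop_fishtpa("recovery_fraction and strain leave a nonpositive ",
                 "second-compression distance")
  du <- fillet$unload_fraction * d1
  du2 <- fillet$unload_fraction * d2
  v <- protocol$test_speed
  v_post <- protocol$posttest_speed

  area1 <- (F_t * d1 + (S - F_t) * d1 / (p + 1)) / v
  area2 <- S * du / ((p + 1) * v_post)

  p2 <- fillet$stiffness_shape2
  if (is.null(p2)) {
    denom <- fillet$cohesiveness_target * area1 * v - F_t * d2
    if (denom <= 0)
      stop_fishtpa("cohesiveness_target unreachable for these parameters")
    p2 <- (S2 - F_t) * d2 / denom - 1
    if (p2 < 1) p2 <- 1
  }
  area4 <- (F_t * d2 + (S2 - F_t) * d2 / (p2 + 1)) / v
  area3 <- -2 * fillet$adhesion_depth * .TAU_ADH / pi

  coh <- area4 / area1
  spr <- 100 * d2 / d1
  truth <- list(
    adhesiveness = area3,
    chewiness1 = S * coh * spr / 100,
    chewiness1b = area1 * coh * spr / 100,
    chewiness2 = S2 * coh * spr / 100,
    cohesiveness = coh,
    hardness1 = S,
    hardness1b = area1,
    hardness2 = S2,
    resilience = 100 * area2 / area1,
    springiness = spr,
    thickness1 = 2 * d1,
    thickness2 = 2 * d2
  )
  list(F_t = F_t, S = S, S2 = S2, d1 = d1, d2 = d2, du = du, du2 = du2,
       p2 = p2, z_c = .GAP_MM + .TOE_MM, z_b = .GAP_MM + .TOE_MM + d1,
       z_s2 = .GAP_MM + .TOE_MM + d1 - d2, truth = truth)
}

#' Solve generator parameters that emit prescribed attribute values
#'
#' Inverts the curve generator: given target values of thickness-1,
#' hardness-1, hardness-2, cohesiveness, springiness, resilience and
#' adhesiveness, returns the [fillet_params()] whose noiseless simulated
#' curve has exactly those ground-truth attributes (the chewiness family and
#' hardness-1b follow from the others).
#'
#' @param thickness1,hardness1,hardness2,cohesiveness,springiness,resilience,adhesiveness
#'   target attribute values on the usual scales (springiness and resilience
#'   in percent, adhesiveness negative, N·s)
#' @param noise_sd additive force noise, N
#' @param protocol a [tpa_protocol()]
#' @return a [fillet_params()] object
#' @examples
#' fp <- fillet_from_attributes(thickness1 = 14.47, hardness1 = 220.5,
#'                              hardness2 = 194.7, cohesiveness = 0.47,
#'                              springiness = 73.84, resilience = 23.5,
#'                              adhesiveness = -1.17)
#' simulate_curve(tpa_protocol(), fp)$truth$cohesiveness
#' @export
fillet_from_attributes <- function(thickness1, hardness1, hardness2,
                                   cohesiveness, springiness, resilience,
                                   adhesiveness, noise_sd = 0,
                                   protocol = tpa_protocol()) {
  p <- 2.5
  F_t <- gf_to_newton(protocol$trigger_force)
  t_mm <- thickness1 / (2 * protocol$strain)
  d1 <- thickness1 / 2
  area1 <- (F_t * d1 + (hardness1 - F_t) * d1 / (p + 1)) / protocol$test_speed
  unload <- resilience / 100 * area1 * (p + 1) * protocol$posttest_speed /
    hardness1 / d1
  fillet_params(thickness_mm = t_mm,
                stiffness_scale = hardness1,
                stiffness_shape = p,
                recovery_fraction = springiness / 100,
                adhesion_depth = abs(adhesiveness) * pi / (2 * .TAU_ADH),
                noise_sd = noise_sd,
                hardness2_ratio = hardness2 / hardness1,
                unload_fraction = unload,
                cohesiveness_target = cohesiveness)
}

new_tpa_curve <- function(time, force, displacement, protocol,
                          meta = list(), truth = NULL) {
  validate_curve_channels(time, force, displacement)
  structure(list(time = time, force = force, displacement = displacement,
                 protocol = protocol, meta = meta, truth = truth),
            class = "tpa_curve")
}

validate_curve_channels <- function(time, force, displacement) {
  if (length(time) < 100L)
    stop_fishtpa("curve too short: need at least 100 samples, got ",
                 length(time))
  if (length(force) != length(time) || length(displacement) != length(time))
    stop_fishtpa("time, force and displacement must have equal length")
  bad <- which(diff(time) <= 0)
  if (length(bad))
    stop_fishtpa("time must be strictly increasing; first violation at row ",
                 bad[1] + 1L)
  if (anyNA(time) || anyNA(force) || anyNA(displacement))
    stop_fishtpa("curve channels contain missing values")
  invisible(TRUE)
}

#' @export
print.tpa_curve <- function(x, ...) {
  cat(sprintf("TPA curve: %d samples, %.1f s, peak force %.2f N\n",
              length(x$time), max(x$time), max(x$force)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  if (!is.null(x$truth))
    cat(sprintf("  truth: hardness1=%.2f cohesiveness=%.3f springiness=%.2f\n",
                x$truth$hardness1, x$truth$cohesiveness,
                x$truth$springiness))
  invisible(x)
}

#' Plot a TPA curve
#'
#' Force against time, optionally overlaying detected anchor points.
#'
#' @param x a `tpa_curve`
#' @param anchors optional `tpa_anchors` object from [detect_anchors()]
#' @param ... passed to [graphics::plot()]
#' @return invisibly, `x`
#' @export
plot.tpa_curve <- function(x, anchors = NULL, ...) {
  graphics::plot(x$time, x$force, type = "l", xlab = "time (s)",
                 ylab = "force (N)", ...)
  graphics::abline(h = 0, col = "grey70", lty = 2)
  if (!is.null(anchors)) {
    graphics::points(anchors$times, anchors$forces, pch = 19, col = "red3")
    graphics::text(anchors$times, anchors$forces, labels = seq_along(anchors$times),
                   pos = 3, col = "red3", cex = 0.8)
  }
  invisible(x)
}
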