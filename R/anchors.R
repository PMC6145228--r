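#' Detect the eight TPA anchor points on a double-compression curve
#'
#' Locates the anchors that bound the areas and distances of texture profile
#' analysis: a1/a6 where force crosses the trigger threshold upward on each
#' compression (linearly interpolated between bracketing samples), a2/a7 at
#' the cycle maxima, a3 where force first returns to zero after the first
#' peak, a4/a5 bounding the negative adhesion region (collapsed onto a3 when
#' no dip is present), and a8 at the end of the trace.
#'
#' Cycles are segmented by the longest below-trigger gap, with a 3-sample
#' debounce on threshold crossings; anchor *location* uses a 5-sample median
#' filter of the force channel, while all reported forces and integrals use
#' the raw samples.
#'
#' @param curve a `tpa_curve`
#' @param protocol a [tpa_protocol()]; defaults to the one carried on the
#'   curve
#' @return an object of class `tpa_anchors` with integer sample `index`,
#'   interpolated `times`, `forces` and `displacement` at the eight anchors
#' @examples
#' cv <- simulate_curve(tpa_protocol(), fillet_params(15))
#' detect_anchors(cv)
#' @export
detect_anchors <- function(curve, protocol = curve$protocol) {
  stopifnot(inherits(curve, "tpa_curve"))
  if (is.null(protocol))
    stop_fishtpa("no protocol: pass one or attach it to the curve")
  tt <- curve$time
  raw <- curve$force
  sm <- stats::runmed(raw, 5, endrule = "constant")
  F_t <- gf_to_newton(protocol$trigger_force)
  # first-difference MAD: robust to the (piecewise-smooth) signal itself
  noise_est <- stats::mad(diff(raw)) / sqrt(2)

  # cycles are detected above a threshold clear of the noise floor; the
  # trigger-crossing anchors are then localized by walking back to F_t
  det_thr <- max(F_t, 5 * noise_est)
  above <- sm > det_thr
  r <- rle(above)
  # 3-sample debounce: flip runs shorter than 3 samples (except the ends)
  if (length(r$lengths) > 1) {
    short <- r$lengths < 3 & seq_along(r$lengths) > 1 &
      seq_along(r$lengths) < length(r$lengths)
    r$values[short] <- NA
    above <- inverse.rle(r)
    above <- fill_na_runs(above)
    r <- rle(above)
  }
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  up_runs <- which(r$values)
  if (length(up_runs) == 0L)
    stop_fishtpa("no contact detected: force never exceeds the trigger")
  if (length(up_runs) == 1L)
    stop_fishtpa("second compression missing: only one cycle found")
  # split the cycles at the longest below-trigger gap between above-runs
  gaps <- run_start[up_runs[-1]] - run_end[up_runs[-length(up_runs)]]
  split_after <- which.max(gaps)
  cyc1_runs <- up_runs[seq_len(split_after)]
  cyc2_runs <- up_runs[(split_after + 1L):length(up_runs)]
  c1_from <- run_start[cyc1_runs[1]]
  c1_to <- run_end[cyc1_runs[length(cyc1_runs)]]
  c2_from <- run_start[cyc2_runs[1]]
  c2_to <- run_end[cyc2_runs[length(cyc2_runs)]]

  i2 <- refine_peak(raw, c1_from - 1L + which.max(sm[c1_from:c1_to]),
                    c1_from, c1_to)
  i7 <- refine_peak(raw, c2_from - 1L + which.max(sm[c2_from:c2_to]),
                    c2_from, c2_to)

  a1 <- trigger_onset(tt, sm, c1_from, F_t, floor_idx = 1L)
  a6 <- trigger_onset(tt, sm, c2_from, F_t, floor_idx = c1_to + 1L)

  # a3: first return of force to <= 0 after the first peak; if the force
  # plateaus above zero, fall back to the last sub-trigger point of cycle 1
  below0 <- which(sm[i2:(c2_from - 1L)] <= 0)
  if (length(below0)) {
    i3 <- i2 - 1L + below0[1]
    a3 <- zero_cross_time(tt, sm, i3, downward = TRUE)
  } else {
    i3 <- c1_to
    a3 <- tt[i3]
  }

  # adhesion region: a dip is real when the minimum between a3 and cycle 2
  # falls clearly below zero relative to both the trigger and the noise floor
  seg <- i3:(c2_from - 1L)
  imin <- seg[which.min(sm[seg])]
  if (sm[imin] < -max(2 * F_t, 4 * noise_est)) {
    j4 <- imin - 1L + 1L
    while (j4 > i3 && sm[j4 - 1L] <= 0) j4 <- j4 - 1L
    a4 <- zero_cross_time(tt, sm, j4, downward = TRUE)
    j5 <- imin
    while (j5 < c2_from - 1L && sm[j5 + 1L] <= 0) j5 <- j5 + 1L
    a5 <- zero_cross_time(tt, sm, j5 + 1L, downward = FALSE)
    i4 <- j4; i5 <- j5 + 1L
  } else {
    a4 <- a5 <- a3
    i4 <- i5 <- i3
  }

  idx <- c(which(tt >= a1)[1], i2, i3, i4, i5, which(tt >= a6)[1], i7,
           length(tt))
  times <- c(a1, tt[i2], a3, a4, a5, a6, tt[i7], tt[length(tt)])
  if (any(diff(times) < 0))
    stop_fishtpa("internal anchor ordering violated; curve is not a ",
                 "valid two-cycle trace")
  forces <- c(F_t, raw[i2], 0, 0, 0, F_t, raw[i7], raw[length(tt)])
  disp <- stats::approx(tt, curve$displacement, xout = times)$y
  structure(list(index = idx, times = times, forces = forces,
                 displacement = disp, trigger_N = F_t),
            class = "tpa_anchors")
}

# Interpolated time at which the (smoothed) force crosses `thr` going up,
# bracketed by samples i-1 and i.
cross_time <- function(tt, f, i, thr, up = TRUE) {
  if (i <= 1L) return(tt[1])
  f0 <- f[i - 1L]; f1 <- f[i]
  if (f1 == f0) return(tt[i])
  w <- (thr - f0) / (f1 - f0)
  w <- min(max(w, 0), 1)
  tt[i - 1L] + w * (tt[i] - tt[i - 1L])
}

zero_cross_time <- function(tt, f, i, downward = TRUE) {
  cross_time(tt, f, i, 0)
}

# Walk back from a cycle's detection onset to the last sub-trigger sample
# and interpolate the upward F_t crossing there.
trigger_onset <- function(tt, sm, onset, F_t, floor_idx) {
  j <- onset
  while (j > floor_idx && sm[j - 1L] > F_t) j <- j - 1L
  cross_time(tt, sm, j, F_t)
}

# The median filter flattens the apex into a plateau whose earliest tie wins;
# refine to the raw maximum in a small window (ties broken by earliest index).
refine_peak <- function(raw, i, lo, hi) {
  w <- max(lo, i - 5L):min(hi, i + 5L)
  w[which.max(raw[w])]
}

fill_na_runs <- function(x) {
  # replace NA entries with the preceding non-NA value
  for (i in seq_along(x)) if (is.na(x[i])) x[i] <- x[i - 1L]
  x
}

#' @export
print.tpa_anchors <- function(x, ...) {
  cat("TPA anchors (times in s):\n")
  print(round(stats::setNames(x$times, paste0("a", 1:8)), 3))
  invisible(x)
}

#' Integrate areas and distances between anchor points
#'
#' Computes the four work areas (trapezoidal rule on force over time, with
#' interpolated partial segments at the anchor times) and the two
#' compression travel distances of a TPA curve.
#'
#' @param curve a `tpa_curve`
#' @param anchors a `tpa_anchors` from [detect_anchors()]
#' @return an object of class `tpa_measures`: `area1` (cycle-1 compression
#'   work, N·s), `area2` (cycle-1 decompression work), `area3` (adhesion
#'   work, `<= 0`), `area4` (cycle-2 compression work), `distance1`,
#'   `distance2` (mm) and the peak forces `force1_max`, `force2_max` (N)
#' @examples
#' cv <- simulate_curve(tpa_protocol(), fillet_params(15))
#' integrate_measures(cv, detect_anchors(cv))
#' @export
integrate_measures <- function(curve, anchors) {
  stopifnot(inherits(curve, "tpa_curve"), inherits(anchors, "tpa_anchors"))
  a <- anchors$times
  if (any(diff(a) < 0))
    stop_fishtpa("anchors out of order")
  tt <- curve$time
  f <- curve$force
  m <- list(
    area1 = trap_between(tt, f, a[1], a[2]),
    area2 = trap_between(tt, f, a[2], a[3]),
    area3 = if (a[5] > a[4]) trap_between(tt, f, a[4], a[5]) else 0,
    area4 = trap_between(tt, f, a[6], a[7]),
    distance1 = anchors$displacement[2] - anchors$displacement[1],
    distance2 = anchors$displacement[7] - anchors$displacement[6],
    force1_max = anchors$forces[2],
    force2_max = anchors$forces[7]
  )
  if (m$area1 <= 0 || m$area4 <= 0)
    stop_fishtpa("nonpositive compression work: curve is not a valid trace")
  if (m$area3 > 0) m$area3 <- 0
  if (m$distance2 > m$distance1)
    warning("distance2 exceeds distance1 (springiness > 100%)",
            call. = FALSE)
  structure(m, class = "tpa_measures")
}

#' @export
print.tpa_measures <- function(x, ...) {
  cat(sprintf(paste0("TPA measures: area1=%.2f area2=%.2f area3=%.3f ",
                     "area4=%.2f N·s | d1=%.2f d2=%.2f mm\n"),
              x$area1, x$area2, x$area3, x$area4,
              x$distance1, x$distance2))
  invisible(x)
}

# Trapezoidal integral of y(t) between t_from and t_to, interpolating the
# endpoint values.
trap_between <- function(tt, y, t_from, t_to) {
  if (t_to <= t_from) return(0)
  inside <- which(tt > t_from & tt < t_to)
  y_from <- stats::approx(tt, y, xout = t_from)$y
  y_to <- stats::approx(tt, y, xout = t_to)$y
  xs <- c(t_from, tt[inside], t_to)
  ys <- c(y_from, y[inside], y_to)
  sum(diff(xs) * (ys[-length(ys)] + ys[-1]) / 2)
}
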