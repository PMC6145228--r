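# Hand-built curves with known geometry, used to exercise the anchor
# detector and integrator independently of the simulator.

# Two symmetric triangular force cycles (peak `peak` N, rise/fall `half` s
# each), separated by a pause at zero force. Displacement ramps down and up
# with the probe so distances are well defined.
make_triangle_curve <- function(peak = 100, half = 5, pause = 5,
                                rate = 200, peak2 = peak, dip = NULL) {
  h <- 1 / rate
  up <- seq(0, half, by = h)
  rise <- peak * up / half
  fall <- rev(rise)[-1]
  cyc1 <- c(rise, fall)
  t_dip <- seq(h, 1, by = h)
  dip_f <- if (is.null(dip)) rep(0, length(t_dip)) else -dip * sin(pi * t_dip)
  gap <- rep(0, round(pause * rate))
  rise2 <- peak2 * up / half
  cyc2 <- c(rise2, rev(rise2)[-1])
  force <- c(cyc1, dip_f, gap, cyc2, 0)
  n <- length(force)
  tt <- seq(0, by = h, length.out = n)
  # probe goes down during each rise, up during each fall; distance mapped
  # 1 mm per second of travel
  v <- numeric(n)
  i <- 1
  seg <- function(len, dir) rep(dir, len)
  dirs <- c(seg(length(rise), 1), seg(length(fall), -1),
            seg(length(t_dip), -1), seg(length(gap), 0),
            seg(length(rise2), 1), seg(length(cyc2) - length(rise2), -1), 0)
  z <- cumsum(dirs * h)
  z <- z - min(z)
  fishtpa:::new_tpa_curve(time = tt, force = force, displacement = z,
                          protocol = tpa_protocol(), meta = list())
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-12), rel_tol)
}

ff_fillet <- function(noise_sd = 0, ...) {
  fillet_params(thickness_mm = 14.47, stiffness_scale = 220.51,
                recovery_fraction = 0.7384, hardness2_ratio = 0.883,
                cohesiveness_target = 0.47, noise_sd = noise_sd, ...)
}

tiny_cohort <- function(seed = 11, iqf = 4, ff = 3, ...) {
  simulate_cohort(cohort_spec(n_fish = c("IQF" = iqf, "fresh-frozen" = ff),
                              seed = seed, ...))
}
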