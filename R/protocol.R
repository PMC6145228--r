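#' Texture-analyzer probe protocol
#'
#' Acquisition settings of a double-compression (TPA) test: the probe
#' approaches at `pretest_speed`, starts recording at the `trigger_force`
#' crossing, compresses to `strain` of the initial sample height at
#' `test_speed`, withdraws at `posttest_speed`, pauses `pause_s` seconds, and
#' repeats the compression to the same absolute depth.
#'
#' @param trigger_force contact trigger threshold, gram-force (default 5 g,
#'   about 0.049 N)
#' @param strain compression depth as a fraction of initial sample height
#'   (default 0.50)
#' @param pretest_speed approach speed, mm/s (default 3)
#' @param test_speed compression speed, mm/s (default 1)
#' @param posttest_speed withdrawal speed, mm/s (default 1)
#' @param pause_s pause between the two cycles, seconds (default 5)
#' @param sample_rate acquisition rate, Hz (default 200, minimum 50)
#' @return an object of class `tpa_protocol`
#' @examples
#' tpa_protocol()
#' @export
tpa_protocol <- function(trigger_force = 5, strain = 0.50,
                         pretest_speed = 3, test_speed = 1,
                         posttest_speed = 1, pause_s = 5,
                         sample_rate = 200) {
  check_number(trigger_force, "trigger_force", lower = 0, strict_lower = TRUE)
  check_number(strain, "strain", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(pretest_speed, "pretest_speed", lower = 0, strict_lower = TRUE)
  check_number(test_speed, "test_speed", lower = 0, strict_lower = TRUE)
  check_number(posttest_speed, "posttest_speed", lower = 0,
               strict_lower = TRUE)
  check_number(pause_s, "pause_s", lower = 0)
  check_number(sample_rate, "sample_rate", lower = 50)
  structure(list(trigger_force = trigger_force, strain = strain,
                 pretest_speed = pretest_speed, test_speed = test_speed,
                 posttest_speed = posttest_speed, pause_s = pause_s,
                 sample_rate = sample_rate),
            class = "tpa_protocol")
}

#' @export
print.tpa_protocol <- function(x, ...) {
  cat("TPA probe protocol\n")
  cat(sprintf("  trigger %.1f g | strain %.0f%% | speeds %g/%g/%g mm/s | pause %g s | %g Hz\n",
              x$trigger_force, 100 * x$strain, x$pretest_speed,
              x$test_speed, x$posttest_speed, x$pause_s, x$sample_rate))
  invisible(x)
}

#' Mechanical parameters of one simulated fillet test point
#'
#' Describes the local mechanical response of a cooked fillet under a ball
#' probe. The compression limb follows a power law in depth,
#' `F = F_trig + (S - F_trig) * (x / d)^shape`, where `S` is
#' `stiffness_scale` (the peak force at full depth) and `d` the compression
#' distance; the second cycle uses `hardness2_ratio * S` as its peak and its
#' own exponent `stiffness_shape2`. Withdrawal relaxes the force to zero over
#' `unload_fraction` of the compression depth, then a half-sine adhesion dip
#' of magnitude `adhesion_depth` (N) follows. After the pause the surface has
#' recovered `recovery_fraction` of the compressed depth.
#'
#' @param thickness_mm initial local fillet thickness, mm
#' @param stiffness_scale peak force of the first compression, N (default 200)
#' @param stiffness_shape power-law exponent of the force rise (default 2.5)
#' @param recovery_fraction fraction of the compressed depth recovered during
#'   the pause; equals springiness/100 of the emitted curve (default 0.70)
#' @param adhesion_depth magnitude of the negative adhesion dip, N
#'   (default 1.73, giving adhesiveness near -1.1 N·s with the 1 s dip)
#' @param noise_sd additive Gaussian force noise, N (default 0)
#' @param hardness2_ratio peak force of cycle 2 relative to cycle 1
#'   (default 0.89)
#' @param unload_fraction fraction of the compression depth over which force
#'   relaxes to zero on withdrawal; approximately resilience/100
#'   (default 0.22)
#' @param stiffness_shape2 power-law exponent of the second compression;
#'   `NULL` (default) solves it so the emitted cohesiveness is
#'   `cohesiveness_target`
#' @param cohesiveness_target cohesiveness used to solve `stiffness_shape2`
#'   when it is `NULL` (default 0.48)
#' @return an object of class `fillet_params`
#' @examples
#' fillet_params(thickness_mm = 15.7)
#' @export
fillet_params <- function(thickness_mm, stiffness_scale = 200,
                          stiffness_shape = 2.5, recovery_fraction = 0.70,
                          adhesion_depth = 1.73, noise_sd = 0,
                          hardness2_ratio = 0.89, unload_fraction = 0.22,
                          stiffness_shape2 = NULL,
                          cohesiveness_target = 0.48) {
  check_number(thickness_mm, "thickness_mm", lower = 0, strict_lower = TRUE)
  check_number(stiffness_scale, "stiffness_scale", lower = 0,
               strict_lower = TRUE)
  check_number(stiffness_shape, "stiffness_shape", lower = 1)
  check_number(recovery_fraction, "recovery_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(adhesion_depth, "adhesion_depth", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(hardness2_ratio, "hardness2_ratio", lower = 0,
               strict_lower = TRUE)
  check_number(unload_fraction, "unload_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  if (!is.null(stiffness_shape2))
    check_number(stiffness_shape2, "stiffness_shape2", lower = 1)
  else
    check_number(cohesiveness_target, "cohesiveness_target",
                 lower = 0, upper = 1.5, strict_lower = TRUE)
  if (unload_fraction >= recovery_fraction)
    stop_fishtpa("unload_fraction must be smaller than recovery_fraction: ",
                 "the surface cannot sit higher right after withdrawal than ",
                 "after the pause")
  structure(list(thickness_mm = thickness_mm,
                 stiffness_scale = stiffness_scale,
                 stiffness_shape = stiffness_shape,
                 recovery_fraction = recovery_fraction,
                 adhesion_depth = adhesion_depth,
                 noise_sd = noise_sd,
                 hardness2_ratio = hardness2_ratio,
                 unload_fraction = unload_fraction,
                 stiffness_shape2 = stiffness_shape2,
                 cohesiveness_target = cohesiveness_target),
            class = "fillet_params")
}
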