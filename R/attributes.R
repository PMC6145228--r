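#' Compute the twelve TPA attributes from curve measures
#'
#' Applies the standard texture-profile formulas: hardness-1/-2 are the peak
#' forces of the two compressions, hardness-1b the first-compression work;
#' cohesiveness = area4/area1, resilience = 100·area2/area1, springiness =
#' 100·distance2/distance1; adhesiveness = area3; thickness-1/-2 are twice
#' the respective compression distances (50% strain geometry); and each
#' chewiness variant is hardness × cohesiveness × springiness/100.
#'
#' @param measures a `tpa_measures` from [integrate_measures()]
#' @param meta optional named list of metadata carried on the profile
#' @return an object of class `tpa_profile` — a named list with the twelve
#'   attributes of [tpa_attribute_names()] plus `meta`
#' @examples
#' m <- structure(list(area1 = 250, area2 = 55, area3 = -1.1, area4 = 120,
#'                     distance1 = 7.5, distance2 = 5.25,
#'                     force1_max = 200, force2_max = 178),
#'                class = "tpa_measures")
#' compute_attributes(m)
#' @export
compute_attributes <- function(measures, meta = list()) {
  stopifnot(inherits(measures, "tpa_measures"))
  if (measures$area1 == 0)
    stop_fishtpa("area1 is zero: cohesiveness and resilience are undefined")
  if (measures$distance1 == 0)
    stop_fishtpa("distance1 is zero: springiness is undefined")
  coh <- measures$area4 / measures$area1
  spr <- 100 * measures$distance2 / measures$distance1
  p <- list(
    adhesiveness = measures$area3,
    chewiness1 = measures$force1_max * coh * spr / 100,
    chewiness1b = measures$area1 * coh * spr / 100,
    chewiness2 = measures$force2_max * coh * spr / 100,
    cohesiveness = coh,
    hardness1 = measures$force1_max,
    hardness1b = measures$area1,
    hardness2 = measures$force2_max,
    resilience = 100 * measures$area2 / measures$area1,
    springiness = spr,
    thickness1 = 2 * measures$distance1,
    thickness2 = 2 * measures$distance2
  )
  if (coh > 1.5)
    warning(sprintf("cohesiveness = %.3f exceeds 1.5; check the trace", coh),
            call. = FALSE)
  p$meta <- meta
  structure(p, class = "tpa_profile")
}

#' Extract a full TPA profile from one curve
#'
#' Convenience pipeline: [detect_anchors()], [integrate_measures()],
#' [compute_attributes()].
#'
#' @param curve a `tpa_curve`
#' @param protocol a [tpa_protocol()]; defaults to the one on the curve
#' @return a `tpa_profile`
#' @examples
#' cv <- simulate_curve(tpa_protocol(), fillet_params(15))
#' extract_tpa(cv)
#' @export
extract_tpa <- function(curve, protocol = curve$protocol) {
  anchors <- detect_anchors(curve, protocol)
  measures <- integrate_measures(curve, anchors)
  compute_attributes(measures, meta = curve$meta)
}

#' @export
print.tpa_profile <- function(x, ...) {
  cat("TPA profile:\n")
  v <- unlist(x[tpa_attribute_names()])
  print(round(v, 3))
  invisible(x)
}

#' @export
as.data.frame.tpa_profile <- function(x, ...) {
  d <- as.data.frame(x[tpa_attribute_names()])
  for (k in names(x$meta)) d[[k]] <- x$meta[[k]]
  d
}
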