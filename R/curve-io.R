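#' Column dialect for curve files
#'
#' Describes how to read a force-time trace exported as delimited text:
#' which columns hold time, force and displacement, and what units they are
#' in. Units are normalized on read to the canonical s / N / mm.
#'
#' @param time,force,distance column names in the file header
#' @param force_unit `"N"` or `"g"` (gram-force; divided by 101.97 g/N)
#' @param distance_unit `"mm"` or `"cm"`
#' @param sep field separator (default `","`)
#' @return a `curve_dialect` object
#' @export
curve_dialect <- function(time = "time_s", force = "force_N",
                          distance = "distance_mm",
                          force_unit = c("N", "g"),
                          distance_unit = c("mm", "cm"),
                          sep = ",") {
  structure(list(time = time, force = force, distance = distance,
                 force_unit = match.arg(force_unit),
                 distance_unit = match.arg(distance_unit), sep = sep),
            class = "curve_dialect")
}

#' Read a force-time curve from a delimited text file
#'
#' The canonical format is comma-separated with header
#' `time_s,force_N,distance_mm` and optional `# key: value` metadata comment
#' lines; other layouts and units are declared through a [curve_dialect()].
#' Malformed rows are rejected (with the offending row number), never
#' silently coerced.
#'
#' @param path file to read
#' @param dialect a [curve_dialect()]
#' @param protocol optional [tpa_protocol()] to attach
#' @return a `tpa_curve`
#' @examples
#' cv <- simulate_curve(tpa_protocol(), fillet_params(15))
#' f <- tempfile(fileext = ".csv")
#' write_curve(cv, f)
#' cv2 <- read_curve(f)
#' @export
read_curve <- function(path, dialect = curve_dialect(), protocol = NULL) {
  if (!file.exists(path)) stop_fishtpa("file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- parse_meta(meta_lines)
  d <- utils::read.table(text = lines[!startsWith(lines, "#")],
                         header = TRUE, sep = dialect$sep,
                         stringsAsFactors = FALSE)
  for (col in c("time", "force", "distance"))
    if (!dialect[[col]] %in% names(d))
      stop_fishtpa("format error: missing column '", dialect[[col]], "'")
  tt <- d[[dialect$time]]
  ff <- d[[dialect$force]]
  zz <- d[[dialect$distance]]
  for (v in list(tt, ff, zz))
    if (!is.numeric(v)) stop_fishtpa("format error: non-numeric data column")
  bad <- which(is.na(tt) | is.na(ff) | is.na(zz))
  if (length(bad))
    stop_fishtpa("malformed row ", bad[1], ": missing or non-numeric value")
  if (dialect$force_unit == "g") ff <- gf_to_newton(ff)
  if (dialect$distance_unit == "cm") zz <- zz * 10
  if (is.null(protocol) && !is.null(meta$protocol))
    protocol <- meta$protocol
  meta$protocol <- NULL
  new_tpa_curve(time = tt, force = ff, displacement = zz,
                protocol = protocol, meta = meta)
}

parse_meta <- function(lines) {
  meta <- list()
  proto <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) next
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    if (startsWith(key, "protocol.")) {
      proto[[sub("^protocol\\.", "", key)]] <- num
    } else {
      meta[[key]] <- if (is.na(num)) val else num
    }
  }
  if (length(proto)) meta$protocol <- do.call(tpa_protocol, proto)
  meta
}

#' Write a curve to the canonical CSV format
#'
#' @param curve a `tpa_curve`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "tpa_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(curve$meta))
    writeLines(sprintf("# %s: %s", k, curve$meta[[k]]), con)
  if (!is.null(curve$protocol))
    for (k in names(unclass(curve$protocol)))
      writeLines(sprintf("# protocol.%s: %.10g", k, curve$protocol[[k]]), con)
  writeLines("time_s,force_N,distance_mm", con)
  writeLines(sprintf("%.6g,%.6g,%.6g", curve$time, curve$force,
                     curve$displacement), con)
  invisible(path)
}

#' Write TPA profiles to a flat attribute table
#'
#' One row per test point; columns are the twelve attributes of
#' [tpa_attribute_names()] plus any shared metadata fields. Values
#' round-trip at six significant digits.
#'
#' @param profiles a list of `tpa_profile` objects
#' @param path output CSV file
#' @return invisibly, the written data frame
#' @export
write_attributes <- function(profiles, path) {
  attrs <- tpa_attribute_names()
  if (!length(profiles)) {
    warning("no profiles: writing header only", call. = FALSE)
    d <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(attrs)),
                                       attrs))
    utils::write.csv(d, path, row.names = FALSE)
    return(invisible(d))
  }
  rows <- lapply(profiles, function(p) {
    miss <- attrs[!vapply(attrs, function(a)
      !is.null(p[[a]]) && is.finite(p[[a]]), logical(1))]
    if (length(miss))
      stop_fishtpa("profile missing attribute '", miss[1], "'")
    as.data.frame.tpa_profile(p)
  })
  common <- Reduce(intersect, lapply(rows, names))
  d <- do.call(rbind, lapply(rows, function(r) r[common]))
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], signif, digits = 6)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(d)
}

#' Read an attribute table written by [write_attributes()]
#' @param path CSV file
#' @return data frame with one row per test point
#' @export
read_attributes <- function(path) {
  if (!file.exists(path)) stop_fishtpa("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(tpa_attribute_names(), names(d))
  if (length(miss))
    stop_fishtpa("attribute table missing column '", miss[1], "'")
  d
}

#' Join TPA and sensory tables into one cohort
#'
#' Inner join on `fish_id`: repeated TPA measures (one row per test point)
#' are preserved for later per-fish aggregation; fish present in only one
#' table are reported via a message and dropped.
#'
#' @param tpa_table data frame (or CSV path) of per-point TPA attributes
#'   with columns `fish_id` and `point`
#' @param sensory_table data frame (or CSV path) of per-fish sensory scores
#'   keyed by `fish_id`
#' @return a list of class `tpa_cohort_tables`: `tpa` (per-point rows),
#'   `sensory` (per-fish rows), `dropped` (fish ids present in only one
#'   table)
#' @export
read_cohort <- function(tpa_table, sensory_table) {
  tpa <- if (is.character(tpa_table)) utils::read.csv(tpa_table) else tpa_table
  sens <- if (is.character(sensory_table)) utils::read.csv(sensory_table)
          else sensory_table
  for (nm in c("fish_id")) {
    if (!nm %in% names(tpa)) stop_fishtpa("TPA table lacks column '", nm, "'")
    if (!nm %in% names(sens))
      stop_fishtpa("sensory table lacks column '", nm, "'")
  }
  if ("point" %in% names(tpa)) {
    key <- paste(tpa$fish_id, tpa$point)
    if (anyDuplicated(key))
      stop_fishtpa("duplicate (fish_id, point) keys in TPA table: ",
                   key[anyDuplicated(key)])
  }
  common <- intersect(unique(tpa$fish_id), unique(sens$fish_id))
  if (!length(common)) stop_fishtpa("no overlapping fish between the tables")
  dropped <- setdiff(union(unique(tpa$fish_id), unique(sens$fish_id)), common)
  if (length(dropped))
    message(length(dropped), " fish present in only one table were dropped: ",
            paste(utils::head(dropped, 10), collapse = ", "))
  structure(list(tpa = tpa[tpa$fish_id %in% common, , drop = FALSE],
                 sensory = sens[sens$fish_id %in% common, , drop = FALSE],
                 dropped = dropped),
            class = "tpa_cohort_tables")
}
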