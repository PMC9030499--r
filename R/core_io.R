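# Containers and plain-text readers/writers shared by every analysis stage.
#
# Unit conventions are fixed package-wide: force pN, piezo distance um,
# height nm, time s, spring constant N/m. Conversions happen only at the
# parser boundary.

#' Force-vs-piezo-position curve
#'
#' Constructs a segmented force curve as recorded by an AFM force-spectroscopy
#' cycle. Each segment is a named list with elements `label` (one of
#' `"approach"`, `"pause"`, `"retract"`), `piezo_um` (piezo position, um) and
#' `force_pN` (cantilever force, pN). Force is stored already converted from
#' deflection via the calibrated spring constant; raw-deflection data must be
#' converted before construction (F = k * d).
#'
#' @param segments list of segments, each `list(label=, piezo_um=, force_pN=)`.
#' @param spring_constant cantilever spring constant, N/m (> 0).
#' @param approach_speed piezo speed, um/s.
#' @param z_length total ramp length, um.
#' @param metadata free-form named list (cell id, condition, date, ...).
#' @return object of class `force_curve`.
#' @export
force_curve <- function(segments, spring_constant, approach_speed = NA_real_,
                        z_length = NA_real_, metadata = list()) {
  if (length(segments) == 0L) stop("no segments")
  if (!is.numeric(spring_constant) || spring_constant <= 0)
    stop("spring_constant must be > 0")
  for (s in segments) {
    if (!s$label %in% c("approach", "pause", "retract"))
      stop("unknown segment label: ", s$label)
    if (length(s$piezo_um) != length(s$force_pN))
      stop("segment '", s$label, "': piezo/force length mismatch")
    if (length(s$piezo_um) < 2L)
      stop("segment '", s$label, "': fewer than 2 samples")
    d <- diff(s$piezo_um)
    if (!(all(d > 0) || all(d < 0)))
      stop("segment '", s$label, "': piezo position not strictly monotonic")
  }
  structure(list(segments = segments, spring_constant = spring_constant,
                 approach_speed = approach_speed, z_length = z_length,
                 metadata = metadata),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat("<force_curve> k =", x$spring_constant, "N/m;",
      length(x$segments), "segment(s):\n")
  for (s in x$segments)
    cat(sprintf("  %-8s n=%d  z=[%.3f, %.3f] um  F=[%.1f, %.1f] pN\n",
                s$label, length(s$piezo_um), min(s$piezo_um), max(s$piezo_um),
                min(s$force_pN), max(s$force_pN)))
  invisible(x)
}

#' Extract one segment of a force curve
#' @param curve a [force_curve()].
#' @param label segment label to extract.
#' @return the segment list, or error when absent.
#' @export
get_segment <- function(curve, label) {
  for (s in curve$segments) if (s$label == label) return(s)
  stop("curve has no '", label, "' segment")
}

#' Time series container
#'
#' Holds a strictly increasing time grid with one value per time point.
#' Used for relative cell volume traces (dimensionless V/V0) and for
#' fluorescence intensity traces (counts).
#'
#' @param time time, s; strictly increasing, length >= 3.
#' @param value values; same length as `time`.
#' @param label free-text label.
#' @return object of class `time_series`.
#' @export
time_series <- function(time, value, label = "") {
  if (length(time) != length(value)) stop("time/value length mismatch")
  if (length(time) < 3L) stop("time series needs >= 3 points")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  structure(list(time = as.numeric(time), value = as.numeric(value),
                 label = label),
            class = "time_series")
}

#' Two-channel Laurdan intensity image
#'
#' Stores the blue (400-460 nm) and red (470-530 nm) emission channels after
#' dark-count subtraction. Intensities are clipped at zero.
#'
#' @param blue,red 2-D intensity matrices (counts), identical shape.
#' @param pixel_size pixel edge, um.
#' @param dark_count dark counts already subtracted (provenance; length 1 or 2).
#' @return object of class `channel_image`.
#' @export
channel_image <- function(blue, red, pixel_size, dark_count = 0) {
  if (!all(dim(blue) == dim(red))) stop("blue/red shape mismatch")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(blue = pmax(blue, 0), red = pmax(red, 0),
                 pixel_size = pixel_size, dark_count = dark_count),
            class = "channel_image")
}

#' Calibrated AFM height map
#'
#' @param height 2-D matrix of heights, nm; all finite.
#' @param pixel_size pixel edge, um.
#' @param mask optional logical matrix (cell footprint), same shape.
#' @return object of class `topograph`.
#' @export
topograph <- function(height, pixel_size, mask = NULL) {
  if (!all(is.finite(height))) stop("height must be finite")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (!is.null(mask) && !all(dim(mask) == dim(height)))
    stop("mask shape mismatch")
  structure(list(height = height, pixel_size = pixel_size, mask = mask),
            class = "topograph")
}

# Exchange dialect for force curves: a header block of `key: value` lines
# followed by a CSV body with columns segment,piezo_um,force_pN. Numeric
# values are printed with %.17g so write-then-read is the identity.

#' Write a force curve as delimited text
#'
#' @param curve a [force_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path) {
  if (!inherits(curve, "force_curve")) stop("not a force_curve")
  if (length(curve$segments) == 0L) stop("no segments")
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) sprintf("%.17g", x)
  writeLines("# cellbiophys force curve v1", con)
  writeLines(paste0("spring_constant_N_per_m: ", num(curve$spring_constant)), con)
  if (is.finite(curve$approach_speed))
    writeLines(paste0("approach_speed_um_per_s: ", num(curve$approach_speed)), con)
  if (is.finite(curve$z_length))
    writeLines(paste0("z_length_um: ", num(curve$z_length)), con)
  for (k in names(curve$metadata))
    writeLines(paste0("meta.", k, ": ", as.character(curve$metadata[[k]])), con)
  writeLines("segment,piezo_um,force_pN", con)
  for (s in curve$segments)
    writeLines(paste(s$label, num(s$piezo_um), num(s$force_pN), sep = ","), con)
  invisible(path)
}

#' Read a force curve from delimited text
#'
#' Parses the package exchange dialect: `key: value` header lines followed by
#' a `segment,piezo_um,force_pN` table. Vendor binary formats are not parsed.
#'
#' @param path file path.
#' @param dialect format name; only `"delimited-text"` is implemented.
#' @return a [force_curve()].
#' @export
read_force_curve <- function(path, dialect = "delimited-text") {
  if (!identical(dialect, "delimited-text"))
    stop("unknown dialect: ", dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  hdr_idx <- grep("^[A-Za-z_.][A-Za-z0-9_.]*:", lines)
  header <- list()
  for (ln in lines[hdr_idx]) {
    kv <- regmatches(ln, regexpr(":", ln), invert = TRUE)[[1]]
    header[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body <- lines[setdiff(seq_along(lines), hdr_idx)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("parse error: no data rows")
  cols <- strsplit(body[1], ",")[[1]]
  need <- c("segment", "piezo_um", "force_pN")
  for (nm in need) if (!nm %in% cols)
    stop("parse error: missing column '", sub("_.*", "", nm), " column'")
  tab <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  if (is.null(header$spring_constant_N_per_m))
    stop("parse error: missing spring_constant_N_per_m header")
  meta_keys <- grep("^meta\\.", names(header), value = TRUE)
  metadata <- stats::setNames(as.list(unlist(header[meta_keys])),
                              sub("^meta\\.", "", meta_keys))
  segs <- list()
  for (lab in unique(tab$segment)) {
    sub <- tab[tab$segment == lab, , drop = FALSE]
    segs[[length(segs) + 1L]] <- list(label = lab,
                                      piezo_um = as.numeric(sub$piezo_um),
                                      force_pN = as.numeric(sub$force_pN))
  }
  force_curve(segs,
              spring_constant = as.numeric(header$spring_constant_N_per_m),
              approach_speed = if (is.null(header$approach_speed_um_per_s))
                NA_real_ else as.numeric(header$approach_speed_um_per_s),
              z_length = if (is.null(header$z_length_um)) NA_real_
                else as.numeric(header$z_length_um),
              metadata = metadata)
}

#' Read a two-channel image pair from TIFF
#'
#' Reads the blue and red Laurdan channels, subtracts the dark count and clips
#' negative values at zero (the downstream GP computation assumes dark counts
#' are already removed).
#'
#' @param path_blue,path_red single-plane grayscale TIFF paths.
#' @param pixel_size pixel edge, um.
#' @param dark_count dark count to subtract, counts; length 1 (both channels)
#'   or 2 (blue, red).
#' @param plane plane index when the TIFF holds a multi-page stack.
#' @return a [channel_image()].
#' @export
read_channel_image <- function(path_blue, path_red, pixel_size,
                               dark_count = 0, plane = 1L) {
  rd <- function(p) {
    img <- tiff::readTIFF(p, as.is = TRUE, all = TRUE)
    m <- img[[plane]]
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m
  }
  blue <- rd(path_blue); red <- rd(path_red)
  if (!all(dim(blue) == dim(red))) stop("shape mismatch between channels")
  dk <- rep_len(dark_count, 2L)
  channel_image(blue - dk[1], red - dk[2], pixel_size = pixel_size,
                dark_count = dark_count)
}

#' Write an assay result table or summary
#'
#' Tables (data frames) are written as CSV with their column order preserved;
#' nested list summaries are written as JSON.
#'
#' @param records a data frame, or a (possibly nested) list.
#' @param path output path; extension does not matter, the type of `records`
#'   decides the format.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  if (is.data.frame(records)) {
    utils::write.csv(records, path, row.names = FALSE)
  } else {
    jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read back an assay result file
#'
#' @param path a CSV or JSON file written by [write_results()].
#' @return data frame (CSV) or list (JSON).
#' @export
read_results <- function(path) {
  first <- readChar(path, 1L)
  if (first %in% c("{", "[")) jsonlite::read_json(path, simplifyVector = TRUE)
  else utils::read.csv(path, stringsAsFactors = FALSE)
}
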