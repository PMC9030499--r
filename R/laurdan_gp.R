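# Laurdan generalized polarization (GP) imaging.
#
# GP = (I_blue - G * I_red) / (I_blue + G * I_red), with I_blue the
# 400-460 nm and I_red the 470-530 nm emission channel. G calibrates the
# detection path so that Laurdan in DMSO returns the literature value
# GP_DMSO = 0.0357. GP is bounded in [-1, 1] for non-negative intensities
# and any G > 0; higher GP means a more ordered, less hydrated bilayer.

#' Calibration factor from a DMSO reference measurement
#'
#' Solves the GP equation for the unique G that makes the measured DMSO
#' intensities return the reference GP:
#' `g = (blue/red) * (1 - gp_ref) / (1 + gp_ref)`.
#'
#' @param blue_dmso,red_dmso DMSO channel intensities, counts (> 0); scalars
#'   or equal-shape aggregates (means are taken).
#' @param gp_reference reference GP of Laurdan in DMSO; default 0.0357.
#' @return list of class `gp_calibration` with `g`, `gp_reference`,
#'   `source_intensities`.
#' @export
calibrate_g <- function(blue_dmso, red_dmso, gp_reference = 0.0357) {
  b <- mean(blue_dmso); r <- mean(red_dmso)
  if (b <= 0 || r <= 0) stop("DMSO intensities must be positive")
  if (abs(gp_reference) >= 1) stop("|gp_reference| must be < 1")
  g <- (b / r) * (1 - gp_reference) / (1 + gp_reference)
  structure(list(g = g, gp_reference = gp_reference,
                 source_intensities = c(blue = b, red = r)),
            class = "gp_calibration")
}

#' Pixel-wise generalized polarization image
#'
#' Applies the GP formula pixel by pixel in double precision. Pixels whose
#' denominator `blue + g*red` falls below `min_denominator` carry no usable
#' signal; they are flagged invalid (NA in the GP map), never silently zeroed.
#'
#' @param image a [channel_image()] (dark counts already subtracted).
#' @param calibration a `gp_calibration` from [calibrate_g()], or a bare
#'   positive number used as G.
#' @param min_denominator validity threshold on `blue + g*red`, counts. A
#'   practical choice is ~5x the dark-count noise SD.
#' @return list of class `gp_image` with `gp` (matrix, NA where invalid),
#'   `valid_mask`, `n_invalid`, `calibration`.
#' @export
compute_gp_image <- function(image, calibration, min_denominator = 0) {
  g <- if (inherits(calibration, "gp_calibration")) calibration$g
       else as.numeric(calibration)
  if (g <= 0) stop("calibration factor must be > 0")
  b <- image$blue; r <- image$red
  den <- b + g * r
  valid <- den >= max(min_denominator, .Machine$double.eps)
  gp <- matrix(NA_real_, nrow(b), ncol(b))
  gp[valid] <- (b[valid] - g * r[valid]) / den[valid]
  structure(list(gp = gp, valid_mask = valid,
                 n_invalid = sum(!valid), calibration = calibration),
            class = "gp_image")
}

#' Plasma-membrane ROI masks from a two-channel image
#'
#' Automates the membrane ROI selection: the summed channels are smoothed,
#' thresholded (Otsu), connected components above a size floor are labelled
#' (interior holes filled), and for each cell the mask is the inward band of
#' `rim_width` pixels from the component boundary -- the rim where the
#' plasma-membrane signal of an adherent cell concentrates.
#'
#' @param image a [channel_image()].
#' @param smoothing_sigma Gaussian smoothing sigma, px.
#' @param rim_width membrane band width, px.
#' @param min_size component size floor, px.
#' @return list of logical rim masks, one per detected cell (possibly empty,
#'   with a warning).
#' @export
segment_membrane_roi <- function(image, smoothing_sigma = 1, rim_width = 5,
                                 min_size = 200) {
  total <- image$blue + image$red
  rng <- range(total)
  if (diff(rng) <= 0) {
    warning("no cells detected (flat image)")
    return(list())
  }
  sc <- (total - rng[1]) / diff(rng)
  sm <- if (smoothing_sigma > 0) EBImage::gblur(sc, sigma = smoothing_sigma)
        else sc
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  bw <- sm > thr
  lab <- EBImage::bwlabel(EBImage::fillHull(bw))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  if (length(keep) == 0L) {
    warning("no component above the size floor")
    return(list())
  }
  kern <- EBImage::makeBrush(2L * rim_width + 1L, shape = "disc")
  masks <- lapply(keep, function(k) {
    comp <- lab == k
    inner <- EBImage::erode(comp, kern)
    m <- comp & !inner
    matrix(as.logical(m), nrow(total), ncol(total))
  })
  masks
}

#' Summarize GP per cell and per condition
#'
#' Per-cell mean GP is the arithmetic mean of pixel GP values within the
#' cell's mask (restricted to valid pixels), not the GP of mean intensities.
#' Cells whose mask holds no valid pixel are dropped and reported.
#'
#' @param gp a `gp_image` from [compute_gp_image()].
#' @param masks list of logical per-cell masks.
#' @param min_cells advisory design floor on cell count; a warning is issued
#'   below it (the reference protocol analyzes at least 50 cells).
#' @return list of class `gp_summary` with `per_cell_mean`, `condition_mean`,
#'   `sem`, `n_cells`, `n_dropped`.
#' @export
summarize_gp <- function(gp, masks, min_cells = 50) {
  if (length(masks) == 0L) stop("no cell masks supplied")
  per_cell <- vapply(masks, function(m) {
    px <- gp$gp[m & gp$valid_mask]
    if (length(px) == 0L) NA_real_ else mean(px)
  }, numeric(1))
  dropped <- sum(is.na(per_cell))
  if (dropped > 0L)
    warning(dropped, " cell(s) dropped: no valid GP pixels in mask")
  per_cell <- per_cell[!is.na(per_cell)]
  n <- length(per_cell)
  if (n == 0L) stop("no cell with valid GP pixels")
  if (n < min_cells)
    warning("only ", n, " cells analyzed (design floor ", min_cells, ")")
  sem <- if (n > 1L) stats::sd(per_cell) / sqrt(n) else 0
  structure(list(per_cell_mean = per_cell, condition_mean = mean(per_cell),
                 sem = sem, n_cells = n, n_dropped = dropped),
            class = "gp_summary")
}
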