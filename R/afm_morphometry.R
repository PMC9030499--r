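# Cell morphometry from AFM topography: projected area, volume,
# elongation (short/long equivalent-ellipse axis ratio) and surface
# roughness after detrending.

#' Segment the cell footprint from a topograph
#'
#' Levels the substrate (least-squares plane through the lowest-decile
#' pixels), then masks the largest connected component above a height floor.
#'
#' @param topo a [topograph()].
#' @param height_floor floor above the levelled substrate, nm, or `"auto"`
#'   (3x the substrate residual SD).
#' @return a [topograph()] with levelled `height` and the cell `mask` set.
#' @export
segment_cell <- function(topo, height_floor = "auto") {
  h <- topo$height
  lev <- .level_plane(h, quantile_cut = 0.1)
  if (identical(height_floor, "auto"))
    height_floor <- max(3 * lev$substrate_sd,
                        0.01 * max(lev$height)) # guard against a noiseless
                                                # substrate (sd ~ 0)
  bw <- lev$height > height_floor
  if (!any(bw)) stop("empty mask: no pixels above the height floor (",
                     signif(height_floor, 3), " nm)")
  lab <- EBImage::bwlabel(bw)
  sizes <- tabulate(lab[lab > 0])
  mask <- matrix(lab == which.max(sizes), nrow(h), ncol(h))
  topograph(lev$height, topo$pixel_size, mask = mask)
}

# least-squares plane through the pixels below the given height quantile
.level_plane <- function(h, quantile_cut = 0.1) {
  nr <- nrow(h); nc <- ncol(h)
  x <- rep(seq_len(nr), nc); y <- rep(seq_len(nc), each = nr)
  cut <- stats::quantile(h, quantile_cut)
  sel <- as.vector(h) <= cut
  fit <- stats::lm.fit(cbind(1, x[sel], y[sel]), as.vector(h)[sel])
  plane <- matrix(cbind(1, x, y) %*% fit$coefficients, nr, nc)
  lev <- h - plane
  list(height = lev, substrate_sd = stats::sd(lev[sel]))
}

#' Projected cell area
#'
#' @param mask logical footprint mask.
#' @param pixel_size pixel edge, um.
#' @return area, um^2 (pixel count x pixel_size^2).
#' @export
cell_area <- function(mask, pixel_size) {
  n <- sum(mask)
  if (n == 0L) stop("empty mask")
  n * pixel_size^2
}

#' Cell volume above the substrate
#'
#' @param topo a levelled [topograph()] (heights in nm above substrate).
#' @param mask logical footprint mask.
#' @return volume, um^3 (sum of heights x pixel area; nm converted to um).
#' @export
cell_volume <- function(topo, mask = topo$mask) {
  if (is.null(mask) || sum(mask) == 0L) stop("empty mask")
  sum(pmax(topo$height[mask], 0)) * 1e-3 * topo$pixel_size^2
}

#' Elongation: minor/major equivalent-ellipse axis ratio
#'
#' Ratio of the minor to the major axis length of the second-central-moment
#' equivalent ellipse of the footprint; 1 for a disk, smaller for more
#' elongated cells. Rotation- and reflection-invariant by construction.
#'
#' @param mask logical footprint mask with >= 5 pixels.
#' @return elongation in (0, 1].
#' @export
elongation <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 5L) stop("mask too small for moments")
  cc <- stats::cov(idx)
  ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0 || ev[2] <= 0) stop("degenerate (collinear) mask")
  sqrt(ev[2] / ev[1])
}

#' Surface roughness over the cell mask
#'
#' Removes a fitted detrend surface within the mask -- a 2nd-order polynomial
#' by default, which absorbs the cell's own curvature and leaves membrane
#' texture -- then reports Rq (RMS residual) and Ra (mean absolute residual).
#'
#' @param topo a [topograph()] (heights nm).
#' @param mask logical mask; defaults to the topograph's.
#' @param detrend `"polynomial-2"` or `"plane"`.
#' @return list with `rq_nm` and `ra_nm`.
#' @export
roughness <- function(topo, mask = topo$mask,
                      detrend = c("polynomial-2", "plane")) {
  detrend <- match.arg(detrend)
  if (is.null(mask) || sum(mask) == 0L) stop("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 1]; y <- idx[, 2]; h <- topo$height[mask]
  X <- if (detrend == "plane") cbind(1, x, y)
       else cbind(1, x, y, x^2, y^2, x * y)
  if (length(h) <= ncol(X)) stop("mask smaller than detrend degrees of freedom")
  res <- stats::lm.fit(X, h)$residuals
  list(rq_nm = sqrt(mean(res^2)), ra_nm = mean(abs(res)))
}

#' Full morphometry of one topograph
#'
#' @param topo a [topograph()].
#' @param detrend roughness detrend model (see [roughness()]).
#' @return one-row data frame: `area_um2`, `volume_um3`, `elongation`,
#'   `rq_nm`, `ra_nm`.
#' @export
analyze_topograph <- function(topo, detrend = "polynomial-2") {
  seg <- segment_cell(topo)
  r <- roughness(seg, detrend = detrend)
  data.frame(area_um2 = cell_area(seg$mask, seg$pixel_size),
             volume_um3 = cell_volume(seg),
             elongation = elongation(seg$mask),
             rq_nm = r$rq_nm, ra_nm = r$ra_nm)
}
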