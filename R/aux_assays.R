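# Wound-closure migration quantification and efficiency-corrected qPCR
# relative expression / knockdown.

#' Wound area from a binary wound mask
#'
#' @param mask logical image marking the cell-free wound region.
#' @param pixel_size pixel edge, um.
#' @return area, um^2; 0 with a "wound closed" warning for an empty mask.
#' @export
wound_area_from_mask <- function(mask, pixel_size) {
  n <- sum(mask)
  if (n == 0L) warning("wound closed: empty wound mask")
  n * pixel_size^2
}

#' Wound series container
#'
#' @param times observation times, h, increasing from 0 (reference design:
#'   0, 12, 24 h).
#' @param areas wound areas at each time (um^2 or px^2, any consistent unit).
#' @param condition condition label.
#' @return object of class `wound_series`.
#' @export
wound_series <- function(times, areas, condition = "") {
  if (length(times) != length(areas)) stop("times/areas length mismatch")
  if (times[1] != 0 || any(diff(times) <= 0))
    stop("times must increase from 0")
  if (any(areas < 0)) stop("areas must be >= 0")
  structure(list(times = times, areas = areas, condition = condition),
            class = "wound_series")
}

#' Wound closure fractions normalized to t = 0
#'
#' closure(t) = (A0 - A_t) / A0. Negative closures (wound apparently opening,
#' e.g. segmentation noise) are clipped at 0 with a warning.
#'
#' @param series a [wound_series()] with `areas[1] > 0`.
#' @return list of class `migration_result` with `times`, `closure_fraction`,
#'   `rate` (1/h, through-origin slope of closure vs time), and
#'   `rate_percent_of_control` (NA until [migration_rate()] is applied).
#' @export
closure_series <- function(series) {
  a0 <- series$areas[1]
  if (a0 <= 0) stop("initial wound area must be > 0")
  cl <- (a0 - series$areas) / a0
  if (any(cl < 0)) {
    warning("negative closure clipped at 0")
    cl <- pmax(cl, 0)
  }
  rate <- sum(cl * series$times) / sum(series$times^2)
  structure(list(times = series$times, closure_fraction = cl, rate = rate,
                 rate_percent_of_control = NA_real_,
                 condition = series$condition),
            class = "migration_result")
}

#' Migration rate as percent of control
#'
#' The migration rate is the through-origin least-squares slope of closure
#' fraction versus time; the result is expressed relative to the control's
#' rate.
#'
#' @param result a `migration_result` (see [closure_series()]).
#' @param control the control condition's `migration_result`.
#' @return `result` with `rate_percent_of_control` filled in.
#' @export
migration_rate <- function(result, control) {
  if (length(result$times) < 2L) stop("need >= 2 time points")
  if (control$rate <= 0) stop("control migration rate must be > 0")
  result$rate_percent_of_control <- 100 * result$rate / control$rate
  result
}

#' Ct table for qPCR relative quantification
#'
#' @param data data frame with columns `sample`, `gene`, `ct` (cycles),
#'   and optionally `replicate`.
#' @param reference_gene housekeeping gene label (default `"HPRT1"`).
#' @param efficiencies named per-gene amplification factors in (1, 2.2];
#'   genes absent from the list default to 2 (perfect doubling).
#' @return object of class `ct_table`.
#' @export
ct_table <- function(data, reference_gene = "HPRT1", efficiencies = list()) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(data)))
  if (any(data$ct <= 0)) stop("ct values must be > 0")
  eff <- unlist(efficiencies)
  if (length(eff) && any(eff <= 1 | eff > 2.2))
    stop("efficiencies must be in (1, 2.2]")
  for (s in unique(data$sample))
    if (!reference_gene %in% data$gene[data$sample == s])
      stop("reference gene missing for sample ", s)
  structure(list(data = data, reference_gene = reference_gene,
                 efficiencies = efficiencies),
            class = "ct_table")
}

.gene_efficiency <- function(table, gene) {
  e <- table$efficiencies[[gene]]
  if (is.null(e)) 2.0 else e
}

.mean_ct <- function(table, sample, gene) {
  ct <- table$data$ct[table$data$sample == sample & table$data$gene == gene]
  if (length(ct) == 0L)
    stop("no Ct for sample '", sample, "', gene '", gene, "'")
  mean(ct)
}

#' Efficiency-corrected relative expression
#'
#' Pfaffl-style generalization of the Livak ddCt method: replicate Cts are
#' averaged first, then
#' `ratio = E_target^(Ct_cal,t - Ct_sam,t) / E_ref^(Ct_cal,ref - Ct_sam,ref)`.
#' With both efficiencies equal to 2 this reduces exactly to `2^(-ddCt)`.
#'
#' @param table a [ct_table()].
#' @param target_gene gene of interest.
#' @param sample sample (condition) to quantify.
#' @param calibrator calibrator sample (e.g. the scrambled-siRNA control).
#' @return expression ratio relative to the calibrator, dimensionless.
#' @export
relative_expression <- function(table, target_gene, sample, calibrator) {
  e_t <- .gene_efficiency(table, target_gene)
  e_r <- .gene_efficiency(table, table$reference_gene)
  d_t <- .mean_ct(table, calibrator, target_gene) -
    .mean_ct(table, sample, target_gene)
  d_r <- .mean_ct(table, calibrator, table$reference_gene) -
    .mean_ct(table, sample, table$reference_gene)
  e_t^d_t / e_r^d_r
}

#' Knockdown percentage from an expression ratio
#'
#' @param ratio relative expression versus the calibrator (>= 0).
#' @return 100 * (1 - ratio), floored at 0 (with a warning when ratio > 1,
#'   i.e. apparent up-regulation).
#' @export
knockdown_percent <- function(ratio) {
  if (ratio < 0) stop("ratio must be >= 0")
  if (ratio > 1) {
    warning("ratio > 1 (apparent up-regulation); knockdown floored at 0%")
    return(0)
  }
  100 * (1 - ratio)
}

#' Mean wound gap width per image row
#'
#' Helper for distance-style wound readouts: mean cell-free gap width per row
#' of the wound mask, in um.
#'
#' @param mask logical wound mask (rows perpendicular to the scratch).
#' @param pixel_size pixel edge, um.
#' @return mean gap width, um.
#' @export
wound_width_profile <- function(mask, pixel_size) {
  mean(rowSums(mask)) * pixel_size
}
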