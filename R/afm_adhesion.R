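# Single-cell force spectroscopy: retraction-curve adhesion analysis.
#
# Canonical retraction convention: piezo position increasing away from the
# surface; adhesive force is negative. Unbinding events are discrete force
# steps toward zero; a step preceded by a force plateau longer than
# 0.25 um is a membrane tether (a lipid tube extruded before rupture),
# shorter plateaus are jumps (cytoskeleton-anchored receptor bonds).

#' Detect unbinding force steps in a retraction trace
#'
#' A step is a rise of the force (toward zero) by more than
#' `step_threshold * noise_sd` within a window of at most 5 samples. For each
#' step the preceding plateau length is measured: the distance back from the
#' step over which the local force slope stays below the plateau tolerance
#' (default 2 noise SD per 0.1 um), bounded by the previous step.
#'
#' @param force_pN retraction forces, pN (baseline-corrected).
#' @param position_um piezo positions, um, increasing.
#' @param noise_sd force noise SD, pN (> 0).
#' @param step_threshold detection threshold in noise SD units.
#' @param plateau_tolerance maximum force deviation from the plateau level
#'   still counted as plateau, pN; default `4 * noise_sd`.
#' @return data frame with one row per step: `index`, `position_um`,
#'   `step_force_pN`, `plateau_length_um`.
#' @export
detect_steps <- function(force_pN, position_um, noise_sd,
                         step_threshold = 4,
                         plateau_tolerance = 4 * noise_sd) {
  n <- length(force_pN)
  stopifnot(length(position_um) == n, noise_sd > 0)
  if (n < 10L) return(.empty_steps())
  thr <- step_threshold * noise_sd
  w <- 5L
  # forward-looking maximum rise within w samples
  fmax <- rep(-Inf, n)
  for (k in seq_len(w)) {
    shifted <- c(force_pN[-seq_len(k)], rep(force_pN[n], k))
    fmax <- pmax(fmax, shifted)
  }
  rise <- fmax - force_pN
  cand <- which(rise > thr)
  if (length(cand) == 0L) return(.empty_steps())
  # group candidates separated by > w samples; the step sits at the last
  # candidate of each run (the sample just before the jump)
  run_end <- cand[c(diff(cand) > w, TRUE)]
  # confirm each candidate as a sustained level change: median force after
  # the jump minus median before must also clear the threshold (rejects
  # single noise excursions that pass the raw-rise test)
  mw <- 6L
  conf <- vapply(run_end, function(i) {
    lo <- max(1L, i - mw); hi <- min(n, i + 2L + mw)
    bf <- lo:i; af <- min(i + 2L, n):hi
    lvl_diff <- stats::median(force_pN[af]) - stats::median(force_pN[bf])
    # discount the rise a smooth local trend (e.g. the detachment ramp)
    # would produce over the same distance: a step must exceed it
    lo2 <- max(1L, i - 2L * mw)
    sl <- if (i - lo2 >= 3L)
      stats::coef(stats::lm.fit(cbind(1, position_um[lo2:i]),
                                force_pN[lo2:i]))[2] else 0
    trend <- max(sl, 0) * (stats::median(position_um[af]) -
                             stats::median(position_um[bf]))
    lvl_diff - trend
  }, numeric(1))
  keep <- conf > 0.9 * thr
  run_end <- run_end[keep]; conf <- conf[keep]
  if (length(run_end) == 0L) return(.empty_steps())

  out <- lapply(seq_along(run_end), function(j) {
    i <- run_end[j]
    step_force <- conf[j] # robust level difference across the jump
    lower <- if (j > 1L) min(run_end[j - 1L] + w, i) else 1L
    # walk back while the force stays within the plateau tolerance of the
    # pre-step level (the sample at i precedes the jump, so it is clean)
    lvl <- stats::median(force_pN[max(lower, i - mw):i])
    s <- i
    while (s > lower && abs(force_pN[s - 1L] - lvl) < plateau_tolerance)
      s <- s - 1L
    data.frame(index = i, position_um = position_um[i],
               step_force_pN = step_force,
               plateau_length_um = position_um[i] - position_um[s])
  })
  do.call(rbind, out)
}

.empty_steps <- function() {
  data.frame(index = integer(), position_um = numeric(),
             step_force_pN = numeric(), plateau_length_um = numeric())
}

#' Classify an unbinding event as jump or membrane tether
#'
#' Deterministic threshold rule on the plateau preceding the force step:
#' plateaus of at least `tether_min_plateau` um mark tethers, shorter ones
#' jumps. The boundary value is assigned to tether (closed upper set); the
#' threshold itself is a parameter.
#'
#' @param step one-row data frame (or list) with `position_um`,
#'   `step_force_pN`, `plateau_length_um`.
#' @param tether_min_plateau plateau threshold, um.
#' @return list of class `unbinding_event` with `position`, `step_force`,
#'   `plateau_length`, `kind`.
#' @export
classify_event <- function(step, tether_min_plateau = 0.25) {
  pl <- step$plateau_length_um
  if (pl < 0) stop("plateau_length must be >= 0")
  structure(list(position = step$position_um,
                 step_force = step$step_force_pN,
                 plateau_length = pl,
                 kind = if (pl >= tether_min_plateau) "tether" else "jump"),
            class = "unbinding_event")
}

#' Analyze a single-cell adhesion retraction curve
#'
#' Computes the maximum detachment force (magnitude of the most negative
#' force), the work of detachment (trapezoidal integral of -force over the
#' adhesive, negative-force region, in aJ = pN um), and the inventory of
#' unbinding events classified into jumps and tethers.
#'
#' @param curve a [force_curve()] with a retract segment.
#' @param step_threshold step-detection threshold, noise SD units.
#' @param tether_min_plateau tether plateau threshold, um.
#' @param noise_sd force noise SD, pN, or `"auto"` (robust SD of the trailing
#'   non-adhesive 20% after baseline correction).
#' @return list of class `adhesion_result`: `max_detachment_force_pN`,
#'   `work_aJ`, `events` (list of `unbinding_event`), `n_jumps`, `n_tethers`,
#'   `baseline_sd`.
#' @export
analyze_retraction <- function(curve, step_threshold = 4,
                               tether_min_plateau = 0.25, noise_sd = "auto") {
  seg <- get_segment(curve, "retract")
  if (seg$piezo_um[1] > seg$piezo_um[length(seg$piezo_um)]) {
    # canonical direction first: piezo increasing away from the surface,
    # so the trailing baseline region really is non-adhesive
    seg$piezo_um <- rev(seg$piezo_um)
    seg$force_pN <- rev(seg$force_pN)
    curve$segments <- list(seg)
  }
  curve <- correct_baseline(curve, "retract", fraction = 0.2,
                            region = "trailing")
  seg <- get_segment(curve, "retract")
  z <- seg$piezo_um; f <- seg$force_pN
  if (identical(noise_sd, "auto")) {
    tail_idx <- seq(floor(0.8 * length(f)) + 1L, length(f))
    noise_sd <- max(stats::mad(f[tail_idx]), 1e-3)
  }
  max_det <- max(c(-f, 0))
  neg <- pmax(-f, 0)
  work <- sum(diff(z) * (neg[-1] + neg[-length(neg)]) / 2)
  steps <- detect_steps(f, z, noise_sd, step_threshold)
  events <- lapply(seq_len(nrow(steps)), function(i)
    classify_event(steps[i, ], tether_min_plateau))
  kinds <- vapply(events, `[[`, character(1), "kind")
  structure(list(max_detachment_force_pN = max_det, work_aJ = work,
                 events = events,
                 n_jumps = sum(kinds == "jump"),
                 n_tethers = sum(kinds == "tether"),
                 baseline_sd = noise_sd),
            class = "adhesion_result")
}

#' Summarize adhesion results for one condition
#'
#' Means and SEMs of work, detachment force, per-event jump and tether forces
#' and per-curve event counts, with a completeness check against the declared
#' sampling design (reference design: 36 cells per condition, 5 curves each).
#'
#' @param results list of `adhesion_result`.
#' @param design named list declaring the design, e.g.
#'   `list(cells = 36, curves_per_cell = 5)`; the expected number of curves is
#'   the product of its elements.
#' @return one-row data frame of condition summaries (attribute `complete`
#'   records the design check).
#' @export
summarize_adhesion <- function(results,
                               design = list(cells = 36, curves_per_cell = 5)) {
  if (length(results) == 0L) stop("no adhesion results")
  expected <- prod(unlist(design))
  complete <- length(results) >= expected
  if (!complete)
    warning("incomplete design: ", length(results), " curves analyzed, ",
            expected, " declared")
  gv <- function(field) vapply(results, `[[`, numeric(1), field)
  ev_force <- function(kind) {
    unlist(lapply(results, function(r) {
      ks <- vapply(r$events, `[[`, character(1), "kind")
      vapply(r$events[ks == kind], `[[`, numeric(1), "step_force")
    }))
  }
  m_sem <- function(x) {
    if (length(x) == 0L) return(c(NA_real_, NA_real_))
    c(mean(x), if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0)
  }
  work <- m_sem(gv("work_aJ")); det <- m_sem(gv("max_detachment_force_pN"))
  jf <- m_sem(ev_force("jump")); tf <- m_sem(ev_force("tether"))
  out <- data.frame(n_curves = length(results),
                    work_aJ_mean = work[1], work_aJ_sem = work[2],
                    detachment_pN_mean = det[1], detachment_pN_sem = det[2],
                    jump_force_pN_mean = jf[1], jump_force_pN_sem = jf[2],
                    tether_force_pN_mean = tf[1], tether_force_pN_sem = tf[2],
                    jumps_per_curve = mean(gv("n_jumps")),
                    tethers_per_curve = mean(gv("n_tethers")))
  attr(out, "complete") <- complete
  out
}
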