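# Osmotic volume kinetics and peroxide influx kinetics.
#
# The cell is treated as a single well-mixed compartment with an
# osmotically inactive volume fraction beta, ideal dilute solutions and
# constant membrane area (the classical two-compartment osmotic model).
# With volumes expressed relative to the initial cell volume V0:
#
#   d(vw)/dt = -Pf * (A/V0) * Vw * (Osm_out - Osm_in)        (water)
#   d(ns)/dt =  Pgly * (A/V0) * (c_out - ns/vw)              (permeant solute)
#   Osm_in   = (N_imp + ns)/vw,   N_imp = Osm_iso * (1 - beta)
#   V_rel    = beta + vw + vs * ns
#
# Pf, Pgly in cm/s; A/V0 in 1/cm; Vw = 18 cm^3/mol; osmolarities in mOsM
# (converted internally to mol/cm^3). ns is measured in mOsM x relative
# volume so concentrations are ns/vw directly. The partial molar volume of
# the permeant solute (vs) defaults to zero: over a 300 mM glycerol
# challenge its volume contribution is ~2% and the canonical V_rel -> 1
# re-swelling endpoint is exact with vs = 0.

MOSM_TO_MOL_CM3 <- 1e-6 # 1 mOsM = 1e-3 mol/L = 1e-6 mol/cm^3

#' Osmotic challenge description
#'
#' @param added_solute `"mannitol"` (impermeant) or `"glycerol"` (permeant).
#' @param baseline_osmolarity isotonic external osmolarity, mOsM.
#' @param added_concentration concentration of added solute, mM.
#' @return object of class `osmotic_challenge`; `final_external_osmolarity`
#'   is `baseline + added` under the ideal dilute assumption.
#' @export
osmotic_challenge <- function(added_solute = c("mannitol", "glycerol"),
                              baseline_osmolarity = 300,
                              added_concentration = 300) {
  added_solute <- match.arg(added_solute)
  if (baseline_osmolarity <= 0 || added_concentration < 0)
    stop("osmolarities must be positive")
  structure(list(added_solute = added_solute,
                 baseline_osmolarity = baseline_osmolarity,
                 added_concentration = added_concentration,
                 final_external_osmolarity =
                   baseline_osmolarity + added_concentration),
            class = "osmotic_challenge")
}

#' Osmotic model parameters
#'
#' Defaults describe a spherical cell of radius 10 um: A/V0 = 3/r =
#' 3 / 1e-3 cm = 3000 cm^-1, with no osmotically inactive volume.
#'
#' @param area_to_volume cell surface-to-volume ratio A/V0, 1/cm.
#' @param molar_volume_water partial molar volume of water, cm^3/mol.
#' @param nonosmotic_fraction osmotically inactive volume fraction beta in
#'   `[0, 1)`.
#' @param internal_osmolarity_initial initial internal osmolarity, mOsM
#'   (isosmotic with the baseline bath).
#' @param molar_volume_solute partial molar volume of the permeant solute,
#'   cm^3/mol; 0 neglects its volume contribution.
#' @return object of class `osmotic_params`.
#' @export
osmotic_params <- function(area_to_volume = 3 / 1e-3,
                           molar_volume_water = 18.0,
                           nonosmotic_fraction = 0,
                           internal_osmolarity_initial = 300,
                           molar_volume_solute = 0) {
  if (area_to_volume <= 0 || molar_volume_water <= 0 ||
      internal_osmolarity_initial <= 0)
    stop("parameters must be positive")
  if (nonosmotic_fraction < 0 || nonosmotic_fraction >= 1)
    stop("nonosmotic_fraction must be in [0, 1)")
  structure(list(area_to_volume = area_to_volume,
                 molar_volume_water = molar_volume_water,
                 nonosmotic_fraction = nonosmotic_fraction,
                 internal_osmolarity_initial = internal_osmolarity_initial,
                 molar_volume_solute = molar_volume_solute),
            class = "osmotic_params")
}

#' Simulate relative cell volume under an osmotic challenge
#'
#' Integrates the two-compartment osmotic model with a stiff-capable adaptive
#' solver (`deSolve::lsoda`, relative tolerance 1e-8) and returns the relative
#' volume V/V0 on the requested time grid; V_rel(0) = 1.
#'
#' @param params [osmotic_params()].
#' @param challenge [osmotic_challenge()]; the added solute is applied as a
#'   step at t = 0.
#' @param p_f osmotic water permeability, cm/s (>= 0).
#' @param p_gly permeant-solute permeability, cm/s (>= 0; ignored for
#'   mannitol, which never enters).
#' @param time_grid increasing time grid starting at 0, s.
#' @return a [time_series()] of V_rel.
#' @export
osmotic_forward_model <- function(params, challenge, p_f, p_gly,
                                  time_grid) {
  if (p_f < 0 || p_gly < 0) stop("permeabilities must be >= 0")
  if (time_grid[1] != 0 || any(diff(time_grid) <= 0))
    stop("time_grid must increase from 0")
  beta <- params$nonosmotic_fraction
  av <- params$area_to_volume
  vw_mol <- params$molar_volume_water
  osm_iso <- params$internal_osmolarity_initial
  n_imp <- osm_iso * (1 - beta)
  osm_out <- challenge$final_external_osmolarity
  c_out <- if (challenge$added_solute == "glycerol")
    challenge$added_concentration else 0
  p_s <- if (challenge$added_solute == "glycerol") p_gly else 0

  deriv <- function(t, y, parms) {
    vw <- y[1]; ns <- y[2]
    osm_in <- (n_imp + ns) / vw
    dvw <- -p_f * av * vw_mol * (osm_out - osm_in) * MOSM_TO_MOL_CM3
    dns <- p_s * av * (c_out - ns / vw)
    list(c(dvw, dns))
  }
  sol <- deSolve::lsoda(c(vw = 1 - beta, ns = 0), time_grid, deriv, NULL,
                        rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0)
    stop("osmotic model integration failed (lsoda istate ",
         attr(sol, "istate")[1], ")")
  v_rel <- beta + sol[, "vw"] +
    params$molar_volume_solute * sol[, "ns"] * MOSM_TO_MOL_CM3
  time_series(time_grid, v_rel,
              label = paste0(challenge$added_solute, " challenge"))
}

#' Closed-form equilibrium relative volume
#'
#' For an impermeant challenge the cell behaves as a linear osmometer:
#' V_rel(inf) = beta + (1 - beta) * Osm_iso / Osm_final. A permeant solute
#' equilibrates across the membrane, so the osmotic gradient vanishes and
#' V_rel(inf) = 1 (neglecting the solute's own volume).
#'
#' @param params [osmotic_params()].
#' @param challenge [osmotic_challenge()].
#' @return equilibrium V_rel, dimensionless.
#' @export
equilibrium_relative_volume <- function(params, challenge) {
  beta <- params$nonosmotic_fraction
  if (challenge$added_solute == "glycerol") {
    ns_inf <- challenge$added_concentration *
      (1 - beta) # c_in = c_out with vw back at (1 - beta)
    1 + params$molar_volume_solute * ns_inf * MOSM_TO_MOL_CM3
  } else {
    beta + (1 - beta) * params$internal_osmolarity_initial /
      challenge$final_external_osmolarity
  }
}

# Sum of squares between a measured trace and the forward model.
.osmotic_sse <- function(trace, params, challenge, p_f, p_gly) {
  pred <- osmotic_forward_model(params, challenge, p_f, p_gly, trace$time)
  sum((pred$value - trace$value)^2)
}

#' Fit osmotic water permeability from a shrinkage trace
#'
#' Least-squares fit of the forward model over Pf (Pgly fixed at 0) for an
#' impermeant (mannitol) challenge. The search is on log10(Pf) over
#' `[1e-6, 1e-1]` cm/s with a golden-section optimizer.
#'
#' @param trace a [time_series()] of V_rel starting near 1 at t = 0.
#' @param challenge [osmotic_challenge()] with `added_solute = "mannitol"`.
#' @param params [osmotic_params()].
#' @return list of class `permeability_fit` with `p_f`, `p_gly` (0),
#'   `residual_rms`, `converged`, and `diagnostic` when not converged.
#' @export
fit_water_permeability <- function(trace, challenge, params = osmotic_params()) {
  if (challenge$added_solute != "mannitol")
    stop("water permeability is fitted from the impermeant (mannitol) challenge")
  # no-response guard: shrinkage must exceed trace noise
  noise <- stats::mad(diff(trace$value)) / sqrt(2)
  drop_depth <- trace$value[1] - min(trace$value)
  if (drop_depth < max(5 * noise, 0.01)) {
    return(structure(list(p_f = NA_real_, p_gly = 0, residual_rms = NA_real_,
                          converged = FALSE,
                          diagnostic = "no osmotic response"),
                     class = "permeability_fit"))
  }
  obj <- function(lp) .osmotic_sse(trace, params, challenge, 10^lp, 0)
  opt <- stats::optimize(obj, interval = c(-6, -1), tol = 1e-6)
  p_f <- 10^opt$minimum
  structure(list(p_f = p_f, p_gly = 0,
                 residual_rms = sqrt(opt$objective / length(trace$time)),
                 converged = TRUE, diagnostic = NULL),
            class = "permeability_fit")
}

#' Fit glycerol permeability from a shrink--re-swell trace
#'
#' Fits Pgly with Pf held fixed at the value obtained from the matched
#' mannitol challenge. The trace must show the characteristic fast shrinkage
#' followed by re-swelling as the permeant solute (and water) enters.
#'
#' @param trace a [time_series()] of V_rel.
#' @param challenge [osmotic_challenge()] with `added_solute = "glycerol"`.
#' @param params [osmotic_params()].
#' @param p_f water permeability from the matched mannitol fit, cm/s.
#' @return a `permeability_fit` (see [fit_water_permeability()]).
#' @export
fit_glycerol_permeability <- function(trace, challenge, params = osmotic_params(),
                                      p_f) {
  if (challenge$added_solute != "glycerol")
    stop("glycerol permeability requires the glycerol challenge")
  i_min <- which.min(trace$value)
  noise <- stats::mad(diff(trace$value)) / sqrt(2)
  reswell <- trace$value[length(trace$value)] - trace$value[i_min]
  if (i_min >= length(trace$value) - 1L || reswell < max(5 * noise, 0.005)) {
    return(structure(list(p_f = p_f, p_gly = NA_real_, residual_rms = NA_real_,
                          converged = FALSE,
                          diagnostic = "no re-swelling detected"),
                     class = "permeability_fit"))
  }
  obj <- function(lp) .osmotic_sse(trace, params, challenge, p_f, 10^lp)
  opt <- stats::optimize(obj, interval = c(-8, -3), tol = 1e-6)
  structure(list(p_f = p_f, p_gly = 10^opt$minimum,
                 residual_rms = sqrt(opt$objective / length(trace$time)),
                 converged = TRUE, diagnostic = NULL),
            class = "permeability_fit")
}

#' First-order rate constant from a semi-log fluorescence fit
#'
#' Computes the least-squares slope of ln(F) versus time over a window. With
#' `window = "auto"` the window starts at the onset of the fluorescence rise
#' (first time the local slope of ln F reaches half its maximum) and ends
#' where the local slope falls below half its initial (at-onset) value, i.e.
#' it tracks the quasi-linear region of the semi-log plot.
#'
#' @param trace a [time_series()] of fluorescence (counts, > 0 in window).
#' @param window numeric `c(t_start, t_end)` in s, or `"auto"`.
#' @return list of class `rate_fit` with `k` (1/s), `fit_window`, `r_squared`.
#' @export
fit_h2o2_rate_constant <- function(trace, window = "auto") {
  t <- trace$time; v <- trace$value
  if (identical(window, "auto")) {
    if (any(v <= 0)) stop("non-positive fluorescence in trace")
    n <- length(t)
    lf <- log(v)
    # local slope of ln F on a median+mean smoothed trace, over a wide
    # centered difference, so the estimate survives measurement noise
    lf_s <- stats::runmed(lf, max(3L, 2L * (n %/% 30) + 1L))
    h <- max(3L, n %/% 20)
    ip <- pmin(seq_len(n) + h, n); im <- pmax(seq_len(n) - h, 1L)
    slope <- (lf_s[ip] - lf_s[im]) / (t[ip] - t[im])
    s_max <- max(slope)
    if (s_max <= 0) {
      window <- range(t) # flat/decaying trace: fit the whole thing
    } else {
      i0 <- which(slope >= s_max / 2)[1]
      s0 <- mean(slope[i0:min(i0 + h, n)])
      after <- which(seq_along(slope) > i0 + h & slope < s0 / 2)
      i1 <- if (length(after)) after[1] else n
      i1 <- max(i1, min(i0 + max(5L, h), n))
      window <- c(t[i0], t[i1])
    }
  }
  sel <- t >= window[1] & t <= window[2]
  if (sum(sel) < 3L) stop("fit window shorter than 3 samples")
  if (any(v[sel] <= 0)) stop("non-positive fluorescence in fit window")
  fit <- stats::lm(log(v[sel]) ~ t[sel])
  y <- log(v[sel])
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst <= 0) 1 else max(0, min(1, 1 - sum(stats::resid(fit)^2) / sst))
  structure(list(k = unname(stats::coef(fit)[2]),
                 fit_window = as.numeric(window), r_squared = r2),
            class = "rate_fit")
}

#' Express an influx rate constant as percent of control
#'
#' @param k_condition rate constant of the condition, 1/s.
#' @param k_control rate constant of the control, 1/s (> 0).
#' @return percent of control, 100 * k_condition / k_control.
#' @export
normalize_influx_to_control <- function(k_condition, k_control) {
  if (k_control <= 0) stop("k_control must be > 0")
  100 * k_condition / k_control
}

#' Projected area to relative volume (approximation)
#'
#' Converts a projected 2-D cell area trace to a relative volume trace under
#' the isotropic scaling approximation V_rel = (A/A0)^(3/2). This is an
#' approximation: adherent cells do not rescale isotropically.
#'
#' @param area_px projected areas (any consistent unit).
#' @return relative volumes.
#' @export
area_to_vrel <- function(area_px) {
  if (any(area_px <= 0)) stop("areas must be positive")
  (area_px / area_px[1])^1.5
}
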