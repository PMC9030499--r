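# AFM indentation elasticity.
#
# Piezo convention: during approach the piezo position decreases toward the
# sample, so contact happens at the low-z end of the approach segment and
# the indentation is delta = (z_c - z) - F/k (cantilever deflection
# subtracted), clipped at >= 0.

#' Tip-sample contact geometry
#'
#' @param model `"paraboloid"` (blunt tip apex, default), `"cone"` or
#'   `"pyramid"`.
#' @param tip_radius tip apex radius, nm (paraboloid).
#' @param half_angle half-opening angle, degrees (cone/pyramid).
#' @param poisson_ratio Poisson ratio of the cell; 0.5 treats it as
#'   incompressible.
#' @return object of class `contact_geometry`.
#' @export
contact_geometry <- function(model = c("paraboloid", "cone", "pyramid"),
                             tip_radius = 15, half_angle = 20,
                             poisson_ratio = 0.5) {
  model <- match.arg(model)
  if (tip_radius <= 0) stop("tip_radius must be > 0")
  if (poisson_ratio < 0 || poisson_ratio > 0.5)
    stop("poisson_ratio must be in [0, 0.5]")
  structure(list(model = model, tip_radius = tip_radius,
                 half_angle = half_angle, poisson_ratio = poisson_ratio),
            class = "contact_geometry")
}

# Hertz force (pN) at E = 1 Pa for indentation depth delta (nm).
.hertz_unit_force <- function(delta_nm, geometry) {
  nu <- geometry$poisson_ratio
  d_m <- delta_nm * 1e-9
  f_N <- switch(geometry$model,
    paraboloid = (4 / 3) / (1 - nu^2) * sqrt(geometry$tip_radius * 1e-9) *
      d_m^1.5,
    cone = (2 / pi) / (1 - nu^2) * tan(geometry$half_angle * pi / 180) * d_m^2,
    pyramid = (1 / sqrt(2)) / (1 - nu^2) *
      tan(geometry$half_angle * pi / 180) * d_m^2)
  f_N * 1e12
}

#' Hertz force-indentation law
#'
#' Forward model: paraboloid `F = (4/3) E/(1-nu^2) sqrt(R) delta^(3/2)`,
#' cone `F = (2/pi) E/(1-nu^2) tan(a) delta^2`, pyramid
#' `F = (1/sqrt(2)) E/(1-nu^2) tan(a) delta^2`.
#'
#' @param delta_nm indentation depth, nm.
#' @param youngs_modulus Young's modulus, Pa.
#' @param geometry a [contact_geometry()].
#' @return force, pN.
#' @export
hertz_force <- function(delta_nm, youngs_modulus, geometry = contact_geometry()) {
  youngs_modulus * .hertz_unit_force(delta_nm, geometry)
}

#' Remove a linear baseline (tilt/offset) from a force curve
#'
#' Fits force ~ piezo position over the non-contact fraction of the chosen
#' segment and subtracts the fitted line from every segment (optical
#' interference tilt is a function of z common to the whole cycle).
#'
#' @param curve a [force_curve()].
#' @param segment segment whose non-contact region defines the baseline.
#' @param fraction fraction of the segment's samples used, from the
#'   non-contact end.
#' @param region `"leading"` (first samples in acquisition order; approach
#'   curves) or `"trailing"` (last samples; retraction curves, where the tip
#'   ends far from the surface).
#' @return baseline-corrected [force_curve()].
#' @export
correct_baseline <- function(curve, segment = "approach", fraction = 0.4,
                             region = c("leading", "trailing")) {
  region <- match.arg(region)
  seg <- get_segment(curve, segment)
  n <- length(seg$piezo_um)
  k <- max(3L, floor(fraction * n))
  if (n < 5L) stop("segment too short for baseline estimation")
  idx <- if (region == "leading") seq_len(k) else seq(n - k + 1L, n)
  fit <- stats::lm(seg$force_pN[idx] ~ seg$piezo_um[idx])
  co <- stats::coef(fit)
  curve$segments <- lapply(curve$segments, function(s) {
    s$force_pN <- s$force_pN - (co[1] + co[2] * s$piezo_um)
    s
  })
  curve
}

#' Contact point of a baseline-corrected approach segment
#'
#' The contact point is the piezo position where the force first exceeds
#' `3 * noise_sd` and stays above that threshold for the remainder of the
#' approach (i.e. the onset of sustained repulsive contact).
#'
#' @param curve baseline-corrected [force_curve()] with an approach segment.
#' @param noise_sd force noise SD, pN, or `"auto"` (robust SD of the leading
#'   40% of the approach).
#' @return contact piezo position `z_c`, um. Errors with a "no contact"
#'   diagnostic when the force never sustains the threshold.
#' @export
detect_contact_point <- function(curve, noise_sd = "auto") {
  seg <- get_segment(curve, "approach")
  f <- seg$force_pN; z <- seg$piezo_um
  n <- length(f)
  if (identical(noise_sd, "auto")) {
    lead <- seq_len(max(3L, floor(0.4 * n)))
    noise_sd <- max(stats::mad(f[lead]), 1e-6)
  }
  above <- f > 3 * noise_sd
  # first index from which 'above' holds to the end
  run <- rev(cumprod(rev(above)))
  i <- which(run == 1)[1]
  if (is.na(i) || i == 1L) {
    if (is.na(i)) stop("no contact: force never sustains 3 sigma (",
                       signif(3 * noise_sd, 3), " pN)")
  }
  z[i]
}

#' Indentation depth and force past contact
#'
#' `delta = (z_c - z) - F/k` (piezo travel past contact minus cantilever
#' deflection), clipped at 0, in nm.
#'
#' @param curve a baseline-corrected [force_curve()].
#' @param z_c contact point, um.
#' @return list with `indentation_nm` and `force_pN` over the contact region.
#' @export
compute_indentation <- function(curve, z_c) {
  seg <- get_segment(curve, "approach")
  sel <- seg$piezo_um <= z_c
  z <- seg$piezo_um[sel]; f <- seg$force_pN[sel]
  defl_um <- f * 1e-6 / curve$spring_constant # pN/(N/m) -> 1e-6 um
  delta_nm <- pmax(((z_c - z) - defl_um) * 1000, 0)
  list(indentation_nm = delta_nm, force_pN = f)
}

#' Fit the Hertz model to indentation data
#'
#' The Hertz law is linear in E at fixed geometry, so the least-squares
#' estimate is the closed-form through-origin regression of force on the
#' unit-modulus model curve. The fit domain is capped at `max_depth` nm to
#' stay within small-deformation validity.
#'
#' @param indentation_nm indentation depths, nm.
#' @param force_pN forces, pN (same length).
#' @param geometry a [contact_geometry()].
#' @param max_depth fit-domain cap, nm.
#' @return list of class `indentation_fit`: `youngs_modulus` (Pa),
#'   `max_indentation` (nm), `residual_rms` (pN), `converged`.
#' @export
fit_hertz <- function(indentation_nm, force_pN, geometry = contact_geometry(),
                      max_depth = 500) {
  sel <- indentation_nm > 0 & indentation_nm <= max_depth
  if (sum(sel) < 10L)
    return(structure(list(youngs_modulus = NA_real_,
                          max_indentation = max(c(indentation_nm, 0)),
                          residual_rms = NA_real_, converged = FALSE),
                     class = "indentation_fit"))
  d <- indentation_nm[sel]; f <- force_pN[sel]
  m <- .hertz_unit_force(d, geometry)
  e_hat <- sum(f * m) / sum(m^2)
  if (!is.finite(e_hat) || e_hat <= 0)
    return(structure(list(youngs_modulus = NA_real_,
                          max_indentation = max(indentation_nm),
                          residual_rms = sqrt(mean(f^2)), converged = FALSE),
                     class = "indentation_fit"))
  res <- f - e_hat * m
  structure(list(youngs_modulus = e_hat, max_indentation = max(indentation_nm),
                 residual_rms = sqrt(mean(res^2)), converged = TRUE),
            class = "indentation_fit")
}

#' Full elasticity analysis of one approach curve
#'
#' Baseline correction, contact-point detection, indentation computation and
#' Hertz fit in one call.
#'
#' The threshold-based contact point is accurate to about one sample; when
#' `refine_contact` is on (default) it is refined by minimizing the Hertz-fit
#' residual over z_c within +/- 0.05 um of the initial estimate, which
#' removes the one-sample discretization bias.
#'
#' @param curve a [force_curve()] with an approach segment.
#' @param geometry a [contact_geometry()].
#' @param setpoint force setpoint for the penetration-depth readout, pN;
#'   `NA` skips it.
#' @param refine_contact refine z_c by residual minimization.
#' @param ... passed to [fit_hertz()].
#' @return an `indentation_fit` with added `contact_point` (um) and
#'   `penetration_depth_nm` (at the setpoint, or NA).
#' @export
analyze_indentation <- function(curve, geometry = contact_geometry(),
                                setpoint = 300, refine_contact = TRUE, ...) {
  cc <- correct_baseline(curve, "approach")
  z_c <- detect_contact_point(cc)
  if (refine_contact) {
    # fixed fit window (contact region plus a slice of baseline) so the
    # objective compares candidate contact points on identical data
    seg <- get_segment(cc, "approach")
    sel <- seg$piezo_um <= z_c + 0.2
    z <- seg$piezo_um[sel]; f <- seg$force_pN[sel]
    obj <- function(zc) {
      d <- pmax(((zc - z) - f * 1e-6 / cc$spring_constant) * 1000, 0)
      m <- .hertz_unit_force(d, geometry)
      e_hat <- sum(f * m) / max(sum(m^2), 1e-300)
      if (!is.finite(e_hat) || e_hat <= 0) return(1e12)
      sum((f - e_hat * m)^2)
    }
    # threshold detection always lags true contact (force must climb to
    # 3 sigma), so search mostly upward of the initial estimate
    z_c <- stats::optimize(obj, c(z_c - 0.05, z_c + 0.25), tol = 1e-7)$minimum
  }
  ind <- compute_indentation(cc, z_c)
  fit <- fit_hertz(ind$indentation_nm, ind$force_pN, geometry, ...)
  fit$contact_point <- z_c
  fit$penetration_depth_nm <- if (is.na(setpoint)) NA_real_ else {
    # noise can leave the observed maximum a fraction below the nominal
    # setpoint; read the depth at the attained force when within 5%
    eff <- min(setpoint, max(ind$force_pN))
    if (eff < 0.95 * setpoint) NA_real_ else
      tryCatch(penetration_depth_at_force(ind$indentation_nm, ind$force_pN,
                                          eff),
               error = function(e) NA_real_)
  }
  fit
}

#' Penetration depth at a force setpoint
#'
#' Indentation depth at the first crossing of the setpoint force, linearly
#' interpolated between samples. The reference protocol indents to a maximum
#' applied force of 300 pN.
#'
#' @param indentation_nm indentation depths, nm (ordered with force).
#' @param force_pN forces, pN.
#' @param setpoint force setpoint, pN.
#' @return depth at the setpoint, nm.
#' @export
penetration_depth_at_force <- function(indentation_nm, force_pN,
                                       setpoint = 300) {
  o <- order(indentation_nm)
  d <- indentation_nm[o]; f <- force_pN[o]
  if (max(f) < setpoint)
    stop("setpoint ", setpoint, " pN not reached (max force ",
         signif(max(f), 4), " pN)")
  i <- which(f >= setpoint)[1]
  if (i == 1L) return(d[1])
  w <- (setpoint - f[i - 1L]) / (f[i] - f[i - 1L])
  d[i - 1L] + w * (d[i] - d[i - 1L])
}

#' Population stiffness histogram and Gaussian peak
#'
#' Builds a histogram of converged Young's moduli (Freedman-Diaconis bins by
#' default) and fits a Gaussian to bin centers/counts; the population peak is
#' the fitted mean. A degenerate spread falls back to the sample median,
#' flagged; a poor Gaussian fit (R^2 < 0.9, e.g. bimodal populations) is
#' flagged too.
#'
#' @param moduli Young's moduli, Pa (NA dropped).
#' @param binning passed to [graphics::hist()] `breaks`; default `"FD"`.
#' @param min_n advisory floor on population size (warning below it).
#' @return list of class `population_stiffness`: `moduli`, `breaks`, `counts`,
#'   `gaussian_peak` (Pa), `peak_sd` (Pa), `gaussian_r2`, `degenerate`,
#'   `poor_fit`.
#' @export
population_peak <- function(moduli, binning = "FD", min_n = 30) {
  moduli <- moduli[is.finite(moduli)]
  n <- length(moduli)
  if (n == 0L) stop("no converged moduli")
  if (n < min_n) warning("only ", n, " moduli (advisory floor ", min_n, ")")
  if (stats::sd(moduli) < 1e-9 * max(abs(moduli), 1)) {
    return(structure(list(moduli = moduli, breaks = range(moduli),
                          counts = n, gaussian_peak = moduli[1],
                          peak_sd = 0, gaussian_r2 = NA_real_,
                          degenerate = TRUE, poor_fit = FALSE),
                     class = "population_stiffness"))
  }
  h <- graphics::hist(moduli, breaks = binning, plot = FALSE)
  x <- h$mids; y <- h$counts
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / (2 * s^2)),
                      start = list(a = max(y), mu = mean(moduli),
                                   s = stats::sd(moduli)),
                      lower = c(0, min(x), 1e-12 * max(abs(x), 1)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(moduli = moduli, breaks = h$breaks, counts = y,
                          gaussian_peak = stats::median(moduli),
                          peak_sd = stats::sd(moduli), gaussian_r2 = NA_real_,
                          degenerate = TRUE, poor_fit = TRUE),
                     class = "population_stiffness"))
  }
  co <- stats::coef(fit)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  structure(list(moduli = moduli, breaks = h$breaks, counts = y,
                 gaussian_peak = unname(co["mu"]),
                 peak_sd = unname(abs(co["s"])), gaussian_r2 = r2,
                 degenerate = FALSE, poor_fit = r2 < 0.9),
            class = "population_stiffness")
}
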