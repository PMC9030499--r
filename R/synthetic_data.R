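# Seeded synthetic-data generation for every assay in the pipeline.
#
# Every generator stores its ground truth next to the generated object, and
# every generator is inverted by its analysis stage at zero noise. Condition
# presets encode, as configuration, the effect directions of an
# AQP3/AQP5-silencing experiment in a ductal adenocarcinoma line: silenced
# presets carry lower peroxide influx (~30%/30%/15% of control), lower
# migration rates (11%/14%/8% of control), AQP3 silencing reduces glycerol
# permeability, AQP5 and double silencing reduce GP, stiffness, cell
# area/volume and raise elongation and roughness, and all silenced presets
# reduce adhesion work and event counts.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
           else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  }
  force(expr)
}

#' Condition presets for the synthetic generator
#'
#' Ground-truth parameter sets mirroring a control vs siAQP3 / siAQP5 /
#' siAQP3/5 silencing design. Effect magnitudes are free configuration:
#' ratios printed as numbers in the reference work (influx 30%/30%/15%,
#' migration 11%/14%/8% of control) are used as defaults; figure-only
#' contrasts default to round +/-30--50% shifts in the reported direction.
#'
#' @return named list of per-condition truth-parameter lists.
#' @export
condition_presets <- function() {
  control <- list(
    p_f = 2e-3, p_gly = 5e-6,          # cm/s
    k_h2o2 = 0.02,                      # 1/s
    gp_membrane = 0.35, gp_cytosol = 0.10,
    youngs_modulus = 2000, modulus_sd = 300,  # Pa
    detachment_force = 500,             # pN
    jumps_per_curve = 4, tethers_per_curve = 3,
    jump_force = 60, tether_force = 45, # pN
    cap_a_um = 12, cap_axis_ratio = 0.85, cap_height_nm = 3000,
    texture_rq_nm = 30,
    migration_rate = 0.030,             # closure fraction / h
    knockdown = c(AQP3 = 0, AQP5 = 0))
  tweak <- function(base, ...) utils::modifyList(base, list(...))
  list(
    control = control,
    siAQP3 = tweak(control,
      p_f = control$p_f * 0.8, p_gly = control$p_gly * 0.3,
      k_h2o2 = control$k_h2o2 * 0.30,
      cap_height_nm = control$cap_height_nm * 1.15,
      detachment_force = 350, jumps_per_curve = 3, tethers_per_curve = 2,
      jump_force = 45, tether_force = 35,
      migration_rate = control$migration_rate * 0.11,
      knockdown = c(AQP3 = 0.75, AQP5 = 0)),
    siAQP5 = tweak(control,
      p_f = control$p_f * 0.5,
      k_h2o2 = control$k_h2o2 * 0.30,
      gp_membrane = 0.25,
      youngs_modulus = 1400,
      cap_a_um = 10, cap_axis_ratio = 0.60, cap_height_nm = 2400,
      texture_rq_nm = 45,
      detachment_force = 320, jumps_per_curve = 2, tethers_per_curve = 2,
      jump_force = 42, tether_force = 33,
      migration_rate = control$migration_rate * 0.14,
      knockdown = c(AQP3 = 0, AQP5 = 0.5)),
    siAQP3_5 = tweak(control,
      p_f = control$p_f * 0.45, p_gly = control$p_gly * 0.3,
      k_h2o2 = control$k_h2o2 * 0.15,
      gp_membrane = 0.25,
      youngs_modulus = 1400,
      cap_a_um = 10, cap_axis_ratio = 0.60, cap_height_nm = 2400,
      texture_rq_nm = 45,
      detachment_force = 280, jumps_per_curve = 2, tethers_per_curve = 1,
      jump_force = 40, tether_force = 32,
      migration_rate = control$migration_rate * 0.08,
      knockdown = c(AQP3 = 0.75, AQP5 = 0.5)))
}

#' Synthetic relative-volume trace
#'
#' Forward osmotic model plus multiplicative Gaussian noise.
#'
#' @param p_f,p_gly permeabilities, cm/s.
#' @param challenge an [osmotic_challenge()].
#' @param params an [osmotic_params()].
#' @param time_grid time grid, s.
#' @param noise multiplicative noise SD (fraction of V_rel).
#' @param seed optional RNG seed.
#' @return a [time_series()] with attribute `truth` (list with `p_f`, `p_gly`).
#' @export
gen_volume_trace <- function(p_f, p_gly = 0,
                             challenge = osmotic_challenge("mannitol"),
                             params = osmotic_params(),
                             time_grid = seq(0, 120, by = 1),
                             noise = 0.01, seed = NULL) {
  .with_seed(seed, {
    tr <- osmotic_forward_model(params, challenge, p_f, p_gly, time_grid)
    if (noise > 0)
      tr$value <- tr$value * (1 + stats::rnorm(length(tr$value), 0, noise))
    attr(tr, "truth") <- list(p_f = p_f, p_gly = p_gly)
    tr
  })
}

#' Synthetic dye-oxidation fluorescence trace
#'
#' Flat baseline for `baseline_time` seconds (probe-loaded cells before the
#' peroxide challenge), then first-order exponential growth
#' `F = f0 * exp(k (t - t0))` with multiplicative Gaussian noise.
#'
#' @param k first-order rate constant, 1/s (>= 0).
#' @param f0 baseline fluorescence, counts.
#' @param baseline_time challenge onset, s.
#' @param t_end trace end, s.
#' @param dt sampling interval, s.
#' @param noise multiplicative noise SD (fraction of F).
#' @param seed optional RNG seed.
#' @return a [time_series()] with attribute `truth` (list with `k`, `onset`).
#' @export
gen_dcf_trace <- function(k, f0 = 100, baseline_time = 40, t_end = 160,
                          dt = 1, noise = 0.02, seed = NULL) {
  stopifnot(k >= 0)
  .with_seed(seed, {
    t <- seq(0, t_end, by = dt)
    v <- ifelse(t <= baseline_time, f0, f0 * exp(k * (t - baseline_time)))
    if (noise > 0) v <- v * (1 + stats::rnorm(length(v), 0, noise))
    tr <- time_series(t, pmax(v, 1e-6), label = "DCF fluorescence")
    attr(tr, "truth") <- list(k = k, onset = baseline_time)
    tr
  })
}

#' Synthetic two-channel Laurdan image
#'
#' Ring-shaped cells (bright membrane rim, dimmer interior) on a dark
#' background. Channel intensities are solved from the target GP and a total
#' brightness T: `blue = T (1 + gp)/2`, `red = T (1 - gp)/(2g)`, so the GP
#' formula with the same g returns the target exactly. Optional Poisson
#' photon noise and a dark-count offset are applied to the raw counts; the
#' returned [channel_image()] is dark-subtracted (the reader's contract).
#'
#' @param n_cells number of cells.
#' @param gp_membrane,gp_cytosol target GP in rim and interior.
#' @param g calibration factor the intensities are solved for.
#' @param dark dark-count offset added to the raw counts.
#' @param dim image edge, px.
#' @param pixel_size um per px.
#' @param rim_width rim width, px.
#' @param brightness total (blue + g*red) counts: named vector with `rim`,
#'   `interior`, `background`.
#' @param noise `"poisson"` or `"none"`.
#' @param seed optional RNG seed.
#' @return list: `image` (a [channel_image()]), `raw_blue`, `raw_red`
#'   (counts including dark), `truth` (list with `gp_membrane`, `g`,
#'   `rim_masks`, `cell_masks`).
#' @export
gen_laurdan_image <- function(n_cells = 4, gp_membrane = 0.35,
                              gp_cytosol = 0.10, g = 1, dark = 10,
                              dim = 256, pixel_size = 0.2, rim_width = 5,
                              brightness = c(rim = 2000, interior = 600,
                                             background = 0),
                              noise = c("poisson", "none"), seed = NULL) {
  noise <- match.arg(noise)
  .with_seed(seed, {
    xs <- matrix(rep(seq_len(dim), dim), dim, dim)
    ys <- t(xs)
    radius <- round(dim / (2 * max(2, ceiling(sqrt(n_cells))) + 1))
    radius <- max(radius, 4 * rim_width)
    gp_px <- matrix(NA_real_, dim, dim)
    total <- matrix(brightness[["background"]], dim, dim)
    rim_masks <- list(); cell_masks <- list()
    per_row <- ceiling(sqrt(max(n_cells, 1)))
    pitch <- dim / max(per_row, 1)
    i <- 0L
    for (cy in seq_len(per_row)) for (cx in seq_len(per_row)) {
      if (i >= n_cells) break
      i <- i + 1L
      x0 <- (cx - 0.5) * pitch + stats::runif(1, -2, 2)
      y0 <- (cy - 0.5) * pitch + stats::runif(1, -2, 2)
      r <- sqrt((xs - x0)^2 + (ys - y0)^2)
      cell <- r <= radius
      rim <- cell & r > radius - rim_width
      interior <- cell & !rim
      gp_px[interior] <- gp_cytosol
      gp_px[rim] <- gp_membrane
      total[interior] <- brightness[["interior"]]
      total[rim] <- brightness[["rim"]]
      rim_masks[[i]] <- rim
      cell_masks[[i]] <- cell
    }
    gp_fill <- ifelse(is.na(gp_px), 0, gp_px)
    blue <- total * (1 + gp_fill) / 2
    red <- total * (1 - gp_fill) / (2 * g)
    raw_blue <- blue + dark; raw_red <- red + dark
    if (noise == "poisson") {
      raw_blue <- matrix(stats::rpois(length(raw_blue), raw_blue), dim, dim)
      raw_red <- matrix(stats::rpois(length(raw_red), raw_red), dim, dim)
    }
    img <- channel_image(raw_blue - dark, raw_red - dark,
                         pixel_size = pixel_size, dark_count = dark)
    list(image = img, raw_blue = raw_blue, raw_red = raw_red,
         truth = list(gp_membrane = gp_membrane, gp_cytosol = gp_cytosol,
                      g = g, rim_masks = rim_masks, cell_masks = cell_masks))
  })
}

#' Synthetic Hertzian indentation curve
#'
#' Approach segment: flat non-contact region, then a Hertzian rise to the
#' force setpoint. The piezo positions in contact are solved
#' deflection-consistently, z = z_c - delta - F/k, so the full analysis
#' chain (baseline, contact point, indentation, fit) inverts the generator.
#'
#' @param E Young's modulus, Pa.
#' @param geometry a [contact_geometry()].
#' @param contact_z contact piezo position, um.
#' @param setpoint maximum applied force, pN.
#' @param spring_constant cantilever spring constant, N/m.
#' @param noncontact_um non-contact approach length, um.
#' @param dz non-contact sampling step, um.
#' @param n_contact samples in the contact region.
#' @param tilt linear baseline `c(offset_pN, slope_pN_per_um)` added to the
#'   whole curve.
#' @param noise additive force noise SD, pN.
#' @param seed optional RNG seed.
#' @return a [force_curve()] with attribute `truth` (list with `E`, `z_c`,
#'   `indentation_nm`, `setpoint`).
#' @export
gen_indentation_curve <- function(E, geometry = contact_geometry(),
                                  contact_z = 5, setpoint = 300,
                                  spring_constant = 0.02,
                                  noncontact_um = 2, dz = 0.01,
                                  n_contact = 120, tilt = c(0, 0),
                                  noise = 0, seed = NULL) {
  stopifnot(E > 0, setpoint > 0)
  .with_seed(seed, {
    d_max <- stats::uniroot(function(d) hertz_force(d, E, geometry) - setpoint,
                            c(1e-6, 1e7), tol = 1e-10)$root
    delta <- seq(0, d_max, length.out = n_contact)[-1]
    f_c <- hertz_force(delta, E, geometry)
    z_c <- contact_z
    z_contact <- z_c - delta * 1e-3 - f_c * 1e-6 / spring_constant
    z_nc <- seq(z_c + noncontact_um, z_c + dz, by = -dz)
    z <- c(z_nc, z_contact)
    f <- c(rep(0, length(z_nc)), f_c)
    f <- f + tilt[1] + tilt[2] * z
    if (noise > 0) f <- f + stats::rnorm(length(f), 0, noise)
    cur <- force_curve(list(list(label = "approach", piezo_um = z,
                                 force_pN = f)),
                       spring_constant = spring_constant,
                       approach_speed = 2, z_length = noncontact_um +
                         (z_c - min(z_contact)),
                       metadata = list(generator = "gen_indentation_curve"))
    attr(cur, "truth") <- list(E = E, z_c = z_c, indentation_nm = delta,
                               setpoint = setpoint)
    cur
  })
}

#' Synthetic single-cell adhesion retraction curve
#'
#' Builds a retraction trace: a triangular adhesion well down to
#' -`detachment_force`, then for each unbinding event a short loading ramp,
#' a force plateau of the requested length, and a discrete force step toward
#' zero; flat baseline to the end of the ramp (z-length 50 um, 2 um/s
#' metadata, matching the reference protocol).
#'
#' @param events data frame with columns `plateau_length_um` and
#'   `step_force_pN` (possibly 0 rows).
#' @param detachment_force well depth, pN; raised automatically if the event
#'   staircase needs a deeper starting level.
#' @param z_length total ramp length, um.
#' @param dz sampling step, um.
#' @param well_width adhesion-well width, um.
#' @param ramp_depth,ramp_length pre-plateau loading ramp depth (pN) and
#'   length (um); its slope must exceed the plateau tolerance.
#' @param spring_constant cantilever spring constant, N/m.
#' @param noise additive force noise SD, pN.
#' @param seed optional RNG seed.
#' @return a [force_curve()] (retract segment only) with attribute `truth`:
#'   `events` (with `kind` per the 0.25 um rule), `detachment_force`,
#'   `work_aJ` (trapezoid of the noise-free adhesive force).
#' @export
gen_retraction_curve <- function(events = data.frame(plateau_length_um = numeric(),
                                                     step_force_pN = numeric()),
                                 detachment_force = 0, z_length = 50,
                                 dz = 0.002, well_width = 1,
                                 ramp_depth = 30, ramp_length = 0.1,
                                 spring_constant = 0.03,
                                 noise = 0, seed = NULL) {
  .with_seed(seed, {
    n_ev <- nrow(events)
    # plateau levels, built backwards so the staircase ends at force 0
    levels <- numeric(n_ev)
    lvl_after <- 0
    for (i in rev(seq_len(n_ev))) {
      levels[i] <- lvl_after - events$step_force_pN[i]
      lvl_after <- levels[i] + ramp_depth
    }
    well_exit <- if (n_ev > 0) levels[1] + ramp_depth else 0
    det <- if (n_ev > 0) max(detachment_force, -well_exit + 10)
           else detachment_force

    z_pieces <- list(); f_pieces <- list()
    push <- function(z0, z1, f0, f1) {
      nz <- max(2L, ceiling((z1 - z0) / dz))
      zz <- seq(z0, z1, length.out = nz + 1L)[-1]
      ff <- f0 + (f1 - f0) * (zz - z0) / (z1 - z0)
      z_pieces[[length(z_pieces) + 1L]] <<- zz
      f_pieces[[length(f_pieces) + 1L]] <<- ff
    }
    z_cur <- 0
    if (det > 1e-6 || n_ev > 0) {
      push(0, well_width / 2, 0, -det)
      push(well_width / 2, well_width, -det, well_exit)
      z_cur <- well_width
    }
    for (i in seq_len(n_ev)) {
      push(z_cur, z_cur + ramp_length, levels[i] + ramp_depth, levels[i])
      z_cur <- z_cur + ramp_length
      push(z_cur, z_cur + events$plateau_length_um[i], levels[i], levels[i])
      z_cur <- z_cur + events$plateau_length_um[i]
      # instantaneous step toward zero (one sample)
      z_pieces[[length(z_pieces) + 1L]] <- z_cur + dz / 10
      f_pieces[[length(f_pieces) + 1L]] <- levels[i] + events$step_force_pN[i]
      z_cur <- z_cur + dz / 10
    }
    if (z_cur < z_length) push(z_cur, z_length, 0, 0)
    z <- c(0, unlist(z_pieces)); f <- c(0, unlist(f_pieces))
    neg <- pmax(-f, 0)
    work <- sum(diff(z) * (neg[-1] + neg[-length(neg)]) / 2)
    if (noise > 0) f <- f + stats::rnorm(length(f), 0, noise)
    truth_ev <- events
    if (n_ev > 0)
      truth_ev$kind <- ifelse(events$plateau_length_um >= 0.25,
                              "tether", "jump")
    cur <- force_curve(list(list(label = "retract", piezo_um = z,
                                 force_pN = f)),
                       spring_constant = spring_constant,
                       approach_speed = 2, z_length = z_length,
                       metadata = list(generator = "gen_retraction_curve"))
    attr(cur, "truth") <- list(events = truth_ev, detachment_force = det,
                               work_aJ = work)
    cur
  })
}

#' Synthetic AFM topography
#'
#' An elliptical paraboloid cap (height `H (1 - (u/a)^2 - (v/b)^2)`, clipped
#' at 0) on a flat substrate, plus band-limited surface texture of a target
#' Rq and an optional substrate tilt plane. The paraboloid cap has the
#' closed-form volume `pi a b H / 2` and is removed exactly by a 2nd-order
#' polynomial detrend, so texture Rq is recovered directly.
#'
#' @param cap_a_um major footprint semi-axis, um.
#' @param axis_ratio minor/major semi-axis ratio in (0, 1].
#' @param height_nm cap apex height, nm.
#' @param rotation footprint rotation, degrees.
#' @param texture_rq_nm target texture Rq on the cell, nm.
#' @param dim image edge, px.
#' @param pixel_size um per px.
#' @param tilt substrate tilt `c(slope_x, slope_y)` in nm/px.
#' @param seed optional RNG seed.
#' @return a [topograph()] with attribute `truth`: `mask`, `area_um2`,
#'   `volume_um3`, `elongation`, `texture_rq_nm`.
#' @export
gen_topography <- function(cap_a_um = 12, axis_ratio = 0.85,
                           height_nm = 3000, rotation = 0,
                           texture_rq_nm = 30, dim = 256,
                           pixel_size = 0.15, tilt = c(0, 0), seed = NULL) {
  stopifnot(cap_a_um > 0, height_nm > 0, axis_ratio > 0, axis_ratio <= 1)
  .with_seed(seed, {
    a <- cap_a_um; b <- cap_a_um * axis_ratio
    cx <- (dim + 1) / 2 * pixel_size
    x <- (seq_len(dim) - 0.5) * pixel_size - cx
    X <- matrix(rep(x, dim), dim, dim); Y <- t(X)
    th <- rotation * pi / 180
    U <- X * cos(th) + Y * sin(th); V <- -X * sin(th) + Y * cos(th)
    q <- 1 - (U / a)^2 - (V / b)^2
    h <- height_nm * pmax(q, 0)
    mask <- q > 0
    if (texture_rq_nm > 0) {
      tex <- matrix(stats::rnorm(dim * dim), dim, dim)
      tex <- as.matrix(EBImage::gblur(tex, sigma = 1.5))
      tex <- tex / stats::sd(tex[mask]) * texture_rq_nm
      h[mask] <- h[mask] + tex[mask] - mean(tex[mask])
    }
    ix <- matrix(rep(seq_len(dim), dim), dim, dim)
    h <- h + tilt[1] * ix + tilt[2] * t(ix)
    topo <- topograph(h, pixel_size)
    attr(topo, "truth") <- list(mask = mask,
                                area_um2 = pi * a * b,
                                volume_um3 = pi * a * b * height_nm * 1e-3 / 2,
                                elongation = axis_ratio,
                                texture_rq_nm = texture_rq_nm)
    topo
  })
}

#' Synthetic wound-closure series
#'
#' Linear closure at the configured rate, observed at 0/12/24 h with additive
#' noise on the closure fraction.
#'
#' @param rate closure fraction per hour.
#' @param a0 initial wound area, um^2.
#' @param times observation times, h.
#' @param noise additive SD on closure fraction.
#' @param condition label.
#' @param seed optional RNG seed.
#' @return a [wound_series()] with attribute `truth` (list with `rate`).
#' @export
gen_wound_series <- function(rate, a0 = 1e5, times = c(0, 12, 24),
                             noise = 0.01, condition = "", seed = NULL) {
  .with_seed(seed, {
    cl <- pmin(pmax(rate * times +
                      c(0, stats::rnorm(length(times) - 1, 0, noise)), 0), 1)
    ws <- wound_series(times, a0 * (1 - cl), condition = condition)
    attr(ws, "truth") <- list(rate = rate)
    ws
  })
}

#' Synthetic qPCR Ct table
#'
#' Builds replicate Cts for the target genes and the housekeeping reference
#' in a calibrator (control) and a silenced sample, with the configured
#' knockdown fractions encoded as dCt shifts (perfect-doubling chemistry)
#' plus Gaussian Ct noise.
#'
#' @param knockdown named vector of knockdown fractions in `[0, 1)` per gene.
#' @param sample silenced-sample label.
#' @param calibrator calibrator label.
#' @param replicates technical replicates per well.
#' @param ct_noise Ct noise SD, cycles.
#' @param seed optional RNG seed.
#' @return a [ct_table()] with attribute `truth` (the knockdown vector).
#' @export
gen_ct_table <- function(knockdown = c(AQP3 = 0.75, AQP5 = 0.5),
                         sample = "silenced", calibrator = "control",
                         replicates = 3, ct_noise = 0.15, seed = NULL) {
  .with_seed(seed, {
    base_ct <- c(AQP3 = 22, AQP5 = 24, HPRT1 = 20)
    genes <- c(names(knockdown), "HPRT1")
    rows <- list()
    for (smp in c(calibrator, sample)) for (g in genes) {
      ct0 <- if (g == "HPRT1") base_ct[["HPRT1"]]
             else base_ct[[g]] + if (smp == sample)
               -log2(1 - knockdown[[g]] + 1e-12) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        sample = smp, gene = g, replicate = seq_len(replicates),
        ct = ct0 + stats::rnorm(replicates, 0, ct_noise))
    }
    tab <- ct_table(do.call(rbind, rows), reference_gene = "HPRT1")
    attr(tab, "truth") <- list(knockdown = knockdown)
    tab
  })
}

#' Generate a full multi-condition assay suite
#'
#' Produces every input the pipeline consumes for each condition preset, at
#' counts mirroring the reference design (600 indentation curves, 36 adhesion
#' cells x 5 curves, >= 50 GP cells per condition) scaled by `size_factor`,
#' together with a truth bundle.
#'
#' @param seed RNG seed; a fixed seed makes the suite reproducible.
#' @param presets subset of [condition_presets()] names.
#' @param size_factor scaling applied to per-condition counts.
#' @param noise list of per-assay noise levels: `volume` (fraction), `dcf`
#'   (fraction), `force` (pN), `ct` (cycles).
#' @return list of class `assay_suite`: per condition, `volume_mannitol`,
#'   `volume_glycerol`, `dcf`, `laurdan`, `indentation`, `adhesion`,
#'   `topography`, `wound`, `ct`, `truth`.
#' @export
gen_assay_suite <- function(seed = 1, presets = names(condition_presets()),
                            size_factor = 0.1,
                            noise = list(volume = 0.01, dcf = 0.02,
                                         force = 5, ct = 0.15)) {
  all_presets <- condition_presets()
  stopifnot(all(presets %in% names(all_presets)))
  n_of <- function(full, floor_n) max(floor_n, ceiling(full * size_factor))
  .with_seed(seed, {
    suite <- lapply(presets, function(cond) {
      p <- all_presets[[cond]]
      man <- osmotic_challenge("mannitol")
      gly <- osmotic_challenge("glycerol")
      list(
        condition = cond,
        volume_mannitol = lapply(seq_len(n_of(10, 6)), function(i)
          gen_volume_trace(p$p_f, 0, man, noise = noise$volume)),
        volume_glycerol = lapply(seq_len(n_of(10, 6)), function(i)
          gen_volume_trace(p$p_f, p$p_gly, gly,
                           time_grid = seq(0, 300, by = 1),
                           noise = noise$volume)),
        dcf = lapply(seq_len(n_of(10, 6)), function(i)
          gen_dcf_trace(p$k_h2o2, noise = noise$dcf)),
        laurdan = lapply(seq_len(n_of(13, 2)), function(i)
          gen_laurdan_image(n_cells = 4, gp_membrane = p$gp_membrane,
                            gp_cytosol = p$gp_cytosol)),
        indentation = lapply(seq_len(n_of(600, 30)), function(i)
          gen_indentation_curve(
            E = max(stats::rnorm(1, p$youngs_modulus, p$modulus_sd), 200),
            noise = noise$force)),
        adhesion = {
          n_cells <- n_of(36, 4)
          unlist(lapply(seq_len(n_cells), function(ci)
            lapply(seq_len(5), function(cv) {
              nj <- stats::rpois(1, p$jumps_per_curve)
              nt <- stats::rpois(1, p$tethers_per_curve)
              ev <- data.frame(
                plateau_length_um = c(stats::runif(nj, 0.03, 0.15),
                                      stats::runif(nt, 0.35, 0.80)),
                step_force_pN = c(pmax(stats::rnorm(nj, p$jump_force, 8), 35),
                                  pmax(stats::rnorm(nt, p$tether_force, 6), 33)))
              ev <- ev[sample.int(nrow(ev)), , drop = FALSE]
              gen_retraction_curve(ev,
                detachment_force = stats::rnorm(1, p$detachment_force, 40),
                z_length = 20, dz = 0.004, noise = noise$force)
            })), recursive = FALSE)
        },
        topography = lapply(seq_len(n_of(10, 6)), function(i)
          gen_topography(cap_a_um = p$cap_a_um * stats::runif(1, 0.9, 1.1),
                         axis_ratio = min(p$cap_axis_ratio *
                                            stats::runif(1, 0.92, 1.08), 1),
                         height_nm = p$cap_height_nm * stats::runif(1, 0.9, 1.1),
                         rotation = stats::runif(1, 0, 180),
                         texture_rq_nm = p$texture_rq_nm)),
        wound = lapply(seq_len(6), function(i)
          gen_wound_series(p$migration_rate, condition = cond)),
        ct = if (any(p$knockdown > 0))
          gen_ct_table(p$knockdown[p$knockdown > 0], sample = cond,
                       ct_noise = noise$ct) else NULL,
        truth = p)
    })
    names(suite) <- presets
    structure(suite, class = "assay_suite", seed = seed,
              size_factor = size_factor)
  })
}

#' Write an assay suite to disk with a manifest
#'
#' Serializes every generated object in the core exchange formats (force
#' curves as delimited text, traces and tables as CSV, images as TIFF) and
#' writes a JSON manifest linking each file to its condition, assay and MD5
#' checksum.
#'
#' @param suite an `assay_suite` from [gen_assay_suite()].
#' @param dir output directory (created).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
write_assay_suite <- function(suite, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  add <- function(path, cond, assay) {
    entries[[length(entries) + 1L]] <<-
      list(file = basename(path), condition = cond, assay = assay,
           md5 = unname(tools::md5sum(path)))
  }
  w_trace <- function(tr, path) {
    utils::write.csv(data.frame(time_s = tr$time, value = tr$value), path,
                     row.names = FALSE)
  }
  for (cond in names(suite)) {
    cdir <- file.path(dir, cond)
    dir.create(cdir, showWarnings = FALSE)
    s <- suite[[cond]]
    for (assay in c("volume_mannitol", "volume_glycerol", "dcf")) {
      for (i in seq_along(s[[assay]])) {
        p <- file.path(cdir, sprintf("%s_%02d.csv", assay, i))
        w_trace(s[[assay]][[i]], p); add(p, cond, assay)
      }
    }
    for (i in seq_along(s$laurdan)) {
      li <- s$laurdan[[i]]
      pb <- file.path(cdir, sprintf("laurdan_%02d_blue.tif", i))
      pr <- file.path(cdir, sprintf("laurdan_%02d_red.tif", i))
      tiff::writeTIFF(li$raw_blue / 65535, pb, bits.per.sample = 16)
      tiff::writeTIFF(li$raw_red / 65535, pr, bits.per.sample = 16)
      add(pb, cond, "laurdan"); add(pr, cond, "laurdan")
    }
    for (assay in c("indentation", "adhesion")) {
      for (i in seq_along(s[[assay]])) {
        p <- file.path(cdir, sprintf("%s_%03d.csv", assay, i))
        write_force_curve(s[[assay]][[i]], p); add(p, cond, assay)
      }
    }
    for (i in seq_along(s$topography)) {
      p <- file.path(cdir, sprintf("topo_%02d.csv", i))
      utils::write.csv(s$topography[[i]]$height, p, row.names = FALSE)
      add(p, cond, "topography")
    }
    for (i in seq_along(s$wound)) {
      p <- file.path(cdir, sprintf("wound_%02d.csv", i))
      utils::write.csv(data.frame(time_h = s$wound[[i]]$times,
                                  area = s$wound[[i]]$areas), p,
                       row.names = FALSE)
      add(p, cond, "wound")
    }
    if (!is.null(s$ct)) {
      p <- file.path(cdir, "qpcr_ct.csv")
      utils::write.csv(s$ct$data, p, row.names = FALSE)
      add(p, cond, "qpcr")
    }
  }
  manifest <- list(seed = attr(suite, "seed"),
                   size_factor = attr(suite, "size_factor"),
                   files = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
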