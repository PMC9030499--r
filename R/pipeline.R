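# End-to-end analysis of a (synthetic or real) multi-condition assay suite.

#' Run every analysis stage over an assay suite
#'
#' For each condition: fits Pf from the mannitol traces and Pgly from the
#' glycerol traces (Pf fixed from the matched mannitol fit), fits the
#' peroxide influx rate constant per trace, computes calibrated GP summaries
#' over segmented membrane ROIs, runs the elasticity chain on every
#' indentation curve plus the population Gaussian peak, analyzes every
#' adhesion retraction curve, quantifies morphometry per topograph, computes
#' migration rates (percent of control), and knockdown percentages from the
#' Ct tables.
#'
#' @param suite an `assay_suite` from [gen_assay_suite()].
#' @param gp_calibration GP calibration used for the images (the generator's
#'   convention is g = 1).
#' @return list of class `suite_results`: per condition, data/lists of
#'   per-replicate estimates plus condition-level summaries.
#' @export
analyze_assay_suite <- function(suite, gp_calibration = 1) {
  out <- lapply(names(suite), function(cond) {
    s <- suite[[cond]]
    man <- osmotic_challenge("mannitol")
    gly <- osmotic_challenge("glycerol")

    pf <- vapply(s$volume_mannitol, function(tr)
      fit_water_permeability(tr, man)$p_f, numeric(1))
    pf_med <- stats::median(pf, na.rm = TRUE)
    pgly <- vapply(s$volume_glycerol, function(tr)
      fit_glycerol_permeability(tr, gly, p_f = pf_med)$p_gly, numeric(1))
    k <- vapply(s$dcf, function(tr) fit_h2o2_rate_constant(tr)$k, numeric(1))

    gp_cells <- unlist(lapply(s$laurdan, function(li) {
      gp <- compute_gp_image(li$image, gp_calibration, min_denominator = 50)
      masks <- segment_membrane_roi(li$image)
      if (length(masks) == 0L) return(numeric())
      suppressWarnings(summarize_gp(gp, masks, min_cells = 1)$per_cell_mean)
    }))

    fits <- lapply(s$indentation, function(cur)
      tryCatch(analyze_indentation(cur), error = function(e)
        list(youngs_modulus = NA_real_, penetration_depth_nm = NA_real_)))
    moduli <- vapply(fits, `[[`, numeric(1), "youngs_modulus")
    depth <- vapply(fits, `[[`, numeric(1), "penetration_depth_nm")
    pop <- suppressWarnings(population_peak(moduli))

    adh <- lapply(s$adhesion, analyze_retraction)
    adh_sum <- suppressWarnings(
      summarize_adhesion(adh, design = list(n = length(adh))))

    morpho <- do.call(rbind, lapply(s$topography, analyze_topograph))

    migr <- lapply(s$wound, closure_series)
    rates <- vapply(migr, `[[`, numeric(1), "rate")

    kd <- if (!is.null(s$ct)) {
      genes <- setdiff(unique(s$ct$data$gene), s$ct$reference_gene)
      stats::setNames(vapply(genes, function(g)
        knockdown_percent(min(relative_expression(s$ct, g, cond, "control"), 1)),
        numeric(1)), genes)
    } else NULL

    list(condition = cond,
         p_f = pf, p_gly = pgly, k_h2o2 = k,
         gp_per_cell = gp_cells,
         moduli = moduli, penetration_depth_nm = depth,
         stiffness_peak = pop$gaussian_peak,
         adhesion = adh, adhesion_summary = adh_sum,
         work_aJ = vapply(adh, `[[`, numeric(1), "work_aJ"),
         n_jumps = vapply(adh, `[[`, numeric(1), "n_jumps"),
         n_tethers = vapply(adh, `[[`, numeric(1), "n_tethers"),
         morphometry = morpho,
         migration_rates = rates,
         knockdown_percent = kd)
  })
  names(out) <- names(suite)
  # migration as percent of control, when a control condition is present
  if ("control" %in% names(out)) {
    cr <- mean(out$control$migration_rates)
    for (cond in names(out))
      out[[cond]]$migration_percent_of_control <-
        100 * mean(out[[cond]]$migration_rates) / cr
    ck <- mean(out$control$k_h2o2)
    for (cond in names(out))
      out[[cond]]$influx_percent_of_control <-
        mean(vapply(out[[cond]]$k_h2o2, normalize_influx_to_control,
                    numeric(1), k_control = ck))
  }
  structure(out, class = "suite_results")
}

#' Condition-level summary table of suite results
#'
#' @param results a `suite_results` from [analyze_assay_suite()].
#' @return data frame with one row per condition.
#' @export
summarize_suite <- function(results) {
  do.call(rbind, lapply(results, function(r) data.frame(
    condition = r$condition,
    p_f_cm_s = stats::median(r$p_f, na.rm = TRUE),
    p_gly_cm_s = stats::median(r$p_gly, na.rm = TRUE),
    k_h2o2_s = stats::median(r$k_h2o2, na.rm = TRUE),
    influx_pct_control = r$influx_percent_of_control %||% NA_real_,
    gp_mean = mean(r$gp_per_cell),
    stiffness_peak_Pa = r$stiffness_peak,
    work_aJ = mean(r$work_aJ),
    area_um2 = mean(r$morphometry$area_um2),
    volume_um3 = mean(r$morphometry$volume_um3),
    elongation = mean(r$morphometry$elongation),
    rq_nm = mean(r$morphometry$rq_nm),
    migration_pct_control = r$migration_percent_of_control %||% NA_real_,
    row.names = NULL)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
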