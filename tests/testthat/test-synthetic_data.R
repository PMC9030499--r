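test_that("generators are deterministic under a fixed seed", {
  a <- gen_volume_trace(2e-3, 0, osmotic_challenge("mannitol"), seed = 5)
  b <- gen_volume_trace(2e-3, 0, osmotic_challenge("mannitol"), seed = 5)
  expect_identical(a$value, b$value)
  ia <- gen_laurdan_image(n_cells = 2, dim = 96, seed = 5)
  ib <- gen_laurdan_image(n_cells = 2, dim = 96, seed = 5)
  expect_identical(ia$image$blue, ib$image$blue)
  ca <- gen_indentation_curve(2000, noise = 5, seed = 5)
  cb <- gen_indentation_curve(2000, noise = 5, seed = 5)
  expect_identical(ca$segments[[1]]$force_pN, cb$segments[[1]]$force_pN)
  ta <- gen_topography(seed = 5); tb <- gen_topography(seed = 5)
  expect_identical(ta$height, tb$height)
})

test_that("zero-noise generators reduce to their deterministic models", {
  man <- osmotic_challenge("mannitol")
  tr <- gen_volume_trace(2e-3, 0, man, noise = 0)
  fm <- osmotic_forward_model(osmotic_params(), man, 2e-3, 0, tr$time)
  expect_identical(tr$value, fm$value)
  d0 <- gen_dcf_trace(0, noise = 0)
  expect_true(all(d0$value == d0$value[1])) # k = 0: flat after baseline
  d <- gen_dcf_trace(0.015, noise = 0)
  expect_rel(fit_h2o2_rate_constant(d)$k, 0.015, 1e-6)
})

test_that("noise-free laurdan images invert through the GP formula", {
  li <- gen_laurdan_image(n_cells = 3, gp_membrane = 0.31, g = 1.4,
                         dim = 128, noise = "none", seed = 2)
  gp <- compute_gp_image(li$image, 1.4, min_denominator = 10)
  for (m in li$truth$rim_masks)
    expect_lt(abs(mean(gp$gp[m & gp$valid_mask]) - 0.31), 1e-6)
  empty <- gen_laurdan_image(n_cells = 0, dim = 64, noise = "none")
  expect_equal(max(empty$image$blue), 0)
})

test_that("indentation curves reach the setpoint and embed the truth", {
  cur <- gen_indentation_curve(2000, noise = 0)
  f <- get_segment(cur, "approach")$force_pN
  expect_equal(max(f), 300, tolerance = 1e-9)
  expect_rel(analyze_indentation(cur)$youngs_modulus, 2000, 1e-3)
  tilted <- gen_indentation_curve(2000, tilt = c(5, -0.4), noise = 0)
  expect_rel(analyze_indentation(tilted)$youngs_modulus, 2000, 1e-3)
})

test_that("retraction curves carry a consistent truth inventory", {
  empty <- gen_retraction_curve(noise = 0)
  res <- analyze_retraction(empty, noise_sd = 5)
  expect_equal(res$work_aJ, 0, tolerance = 1e-6)
  expect_length(res$events, 0L)
  ev <- data.frame(plateau_length_um = c(0.1, 0.4), step_force_pN = c(70, 50))
  cur <- gen_retraction_curve(ev, detachment_force = 400, z_length = 10,
                              noise = 0)
  truth <- attr(cur, "truth")
  expect_equal(truth$events$kind, c("jump", "tether"))
  got <- analyze_retraction(cur, noise_sd = 5)
  expect_equal(got$n_jumps, 1L)
  expect_equal(got$n_tethers, 1L)
  # truth work equals the independent trapezoid on the raw arrays
  seg <- get_segment(cur, "retract")
  neg <- pmax(-seg$force_pN, 0)
  expect_rel(truth$work_aJ,
             sum(diff(seg$piezo_um) * (head(neg, -1) + tail(neg, -1)) / 2),
             1e-9)
})

test_that("topography truths match their closed forms", {
  round_topo <- gen_topography(axis_ratio = 1, texture_rq_nm = 0, seed = 3)
  expect_rel(analyze_topograph(round_topo)$elongation, 1, 0.02)
  truth <- attr(round_topo, "truth")
  expect_rel(cell_volume(segment_cell(round_topo)), truth$volume_um3, 0.02)
})

test_that("presets encode the configured silencing contrasts", {
  p <- condition_presets()
  expect_named(p, c("control", "siAQP3", "siAQP5", "siAQP3_5"))
  expect_rel(p$siAQP3$k_h2o2 / p$control$k_h2o2, 0.30, 1e-9)
  expect_rel(p$siAQP3_5$k_h2o2 / p$control$k_h2o2, 0.15, 1e-9)
  expect_lt(p$siAQP3$p_gly, p$control$p_gly)
  expect_lt(p$siAQP5$gp_membrane, p$control$gp_membrane)
  expect_lt(p$siAQP5$youngs_modulus, p$control$youngs_modulus)
  expect_gt(p$siAQP5$texture_rq_nm, p$control$texture_rq_nm)
  rates <- vapply(p, `[[`, numeric(1), "migration_rate")
  expect_equal(unname(rates[-1] / rates[1]), c(0.11, 0.14, 0.08))
})

test_that("a written suite has a reproducible manifest", {
  tiny <- gen_assay_suite(seed = 9, presets = c("control", "siAQP5"),
                          size_factor = 0.01)
  tiny2 <- gen_assay_suite(seed = 9, presets = c("control", "siAQP5"),
                           size_factor = 0.01)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- write_assay_suite(tiny, d1)
  m2 <- write_assay_suite(tiny2, d2)
  md5_1 <- vapply(m1$files, `[[`, character(1), "md5")
  md5_2 <- vapply(m2$files, `[[`, character(1), "md5")
  expect_identical(md5_1, md5_2)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  # a written force curve reads back identically
  f <- vapply(m1$files, `[[`, character(1), "file")
  idx <- grep("indentation", f)[1]
  cond <- m1$files[[idx]]$condition
  back <- read_force_curve(file.path(d1, cond, f[idx]))
  orig <- tiny[[cond]]$indentation[[1]]
  expect_identical(back$segments[[1]]$force_pN,
                   orig$segments[[1]]$force_pN)
})
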