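test_that("baseline correction removes linear tilt and is idempotent", {
  z <- seq(10, 5, by = -0.05)
  tilted <- force_curve(list(list(label = "approach", piezo_um = z,
                                  force_pN = 2 + 0.1 * z)), 0.02)
  cor <- correct_baseline(tilted)
  expect_lt(max(abs(get_segment(cor, "approach")$force_pN)), 1e-10)
  cor2 <- correct_baseline(cor)
  expect_equal(get_segment(cor2, "approach")$force_pN,
               get_segment(cor, "approach")$force_pN, tolerance = 1e-10)
})

test_that("contact point is found at the onset of sustained contact", {
  cur <- gen_indentation_curve(E = 3000, contact_z = 5, noise = 0)
  # noise-free: a tight threshold localizes contact to ~one sample spacing
  z_c <- detect_contact_point(correct_baseline(cur), noise_sd = 0.1)
  expect_lt(abs(z_c - 5), 0.011)
  flat <- force_curve(list(list(label = "approach",
                                piezo_um = seq(10, 5, by = -0.05),
                                force_pN = rep(0, 101))), 0.02)
  expect_error(detect_contact_point(flat, noise_sd = 1), "no contact")
  # refined contact point under noise
  set.seed(12)
  errs <- vapply(1:20, function(i) {
    cur <- gen_indentation_curve(E = runif(1, 1000, 5000), noise = 5)
    abs(analyze_indentation(cur)$contact_point - 5)
  }, numeric(1))
  expect_lte(median(errs), 0.02) # two sample spacings
})

test_that("indentation handles the rigid and deflection-free limits", {
  k <- 0.02; z_c <- 5
  z <- seq(z_c, z_c - 0.5, by = -0.01)
  # rigid substrate: all piezo travel goes into deflection, delta = 0
  rigid <- force_curve(list(list(label = "approach", piezo_um = z,
                                 force_pN = k * (z_c - z) * 1e6)), k)
  ind <- compute_indentation(rigid, z_c)
  expect_lt(max(ind$indentation_nm), 1e-6)
  # zero force: no deflection, delta = full travel
  soft <- force_curve(list(list(label = "approach", piezo_um = z,
                                force_pN = rep(0, length(z)))), k)
  ind2 <- compute_indentation(soft, z_c)
  expect_equal(ind2$indentation_nm, (z_c - z) * 1000, tolerance = 1e-9)
  # generator's stored indentation is reproduced
  cur <- gen_indentation_curve(E = 2000, noise = 0)
  tr <- attr(cur, "truth")
  ind3 <- compute_indentation(cur, tr$z_c)
  got <- sort(ind3$indentation_nm[ind3$indentation_nm > 0])
  expect_lt(max(abs(got - sort(tr$indentation_nm))), 0.1)
})

test_that("Hertz fits recover the modulus and flag model mismatch", {
  geom <- contact_geometry()
  delta <- seq(1, 400, length.out = 80)
  f <- hertz_force(delta, 5000, geom)
  fit <- fit_hertz(delta, f, geom)
  expect_true(fit$converged)
  expect_rel(fit$youngs_modulus, 5000, 1e-3)
  # zero force: no positive modulus
  expect_false(fit_hertz(delta, rep(0, 80), geom)$converged)
  # wrong geometry leaves systematic residuals
  cone_fit <- fit_hertz(delta, f, contact_geometry("cone", half_angle = 20))
  expect_gt(cone_fit$residual_rms, fit$residual_rms)
})

test_that("full elasticity chain inverts the generator", {
  # noise-free, with tilt: baseline correction + refinement recover E to 0.1%
  cur <- gen_indentation_curve(E = 2500, tilt = c(3, 0.2), noise = 0)
  fit <- analyze_indentation(cur)
  expect_rel(fit$youngs_modulus, 2500, 1e-3)
  # tilt invariance: same curve with and without tilt agree
  cur0 <- gen_indentation_curve(E = 2500, noise = 0)
  fit0 <- analyze_indentation(cur0)
  expect_rel(fit$youngs_modulus, fit0$youngs_modulus, 1e-3)
  # noisy population: median recovery within 10%
  set.seed(31)
  errs <- vapply(1:50, function(i) {
    E <- runif(1, 800, 6000)
    f <- analyze_indentation(gen_indentation_curve(E, noise = 5))
    abs(f$youngs_modulus - E) / E
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})

test_that("penetration depth interpolates the setpoint and scales as E^(-2/3)", {
  geom <- contact_geometry()
  depth_of <- function(E) {
    delta <- seq(0, 1500, length.out = 400)
    penetration_depth_at_force(delta, hertz_force(delta, E, geom), 300)
  }
  d5 <- depth_of(5000)
  closed <- (300 / ((4 / 3) * (5000 / (1 - 0.5^2)) * sqrt(15e-9) * 1e12))^(2 / 3) * 1e9
  expect_rel(d5, closed, 0.01)
  expect_rel(depth_of(10000) / d5, 2^(-2 / 3), 0.01)
  grid <- c(1000, 2000, 3000, 4000, 5000)
  depths <- vapply(grid, depth_of, numeric(1))
  scaled <- depths * grid^(2 / 3)
  expect_lt(max(abs(scaled / scaled[1] - 1)), 0.02)
  expect_true(all(diff(depths) < 0))
  expect_error(penetration_depth_at_force(c(1, 2), c(10, 20), 300),
               "max force")
})

test_that("population peak finds the Gaussian mode and flags pathologies", {
  set.seed(44)
  pop <- population_peak(rnorm(600, 2000, 200))
  expect_lt(abs(pop$gaussian_peak - 2000), 50)
  expect_false(pop$degenerate)
  same <- suppressWarnings(population_peak(rep(1500, 40)))
  expect_true(same$degenerate)
  expect_equal(same$gaussian_peak, 1500)
  bim <- population_peak(c(rnorm(300, 1000, 80), rnorm(300, 3000, 80)))
  expect_true(bim$poor_fit)
})
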