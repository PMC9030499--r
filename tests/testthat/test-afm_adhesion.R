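test_that("flat retraction yields zero work, zero force, no events", {
  z <- seq(0, 10, by = 0.01)
  flat <- force_curve(list(list(label = "retract", piezo_um = z,
                                force_pN = rep(0, length(z)))), 0.03)
  res <- analyze_retraction(flat, noise_sd = 5)
  expect_equal(res$work_aJ, 0)
  expect_equal(res$max_detachment_force_pN, 0)
  expect_length(res$events, 0L)
  expect_error(analyze_retraction(demo_curve()[["nope"]]))
})

test_that("triangular adhesion well gives the closed-form work", {
  # dips linearly to -500 pN over 1 um and back over 1 um: W = 500 aJ
  z <- seq(0, 10, by = 0.001)
  f <- ifelse(z <= 1, -500 * z, ifelse(z <= 2, -500 * (2 - z), 0))
  cur <- force_curve(list(list(label = "retract", piezo_um = z,
                               force_pN = f)), 0.03)
  res <- analyze_retraction(cur, noise_sd = 5)
  expect_rel(res$work_aJ, 500, 1e-3)
  expect_equal(res$max_detachment_force_pN, 500)
})

test_that("work matches an independent trapezoid oracle on seeded fixtures", {
  set.seed(14)
  for (i in 1:8) {
    ev <- data.frame(plateau_length_um = runif(2, 0.05, 0.6),
                     step_force_pN = runif(2, 40, 90))
    cur <- gen_retraction_curve(ev, detachment_force = runif(1, 200, 600),
                                z_length = 12, noise = 3)
    res <- analyze_retraction(cur)
    seg <- get_segment(correct_baseline(cur, "retract", fraction = 0.2,
                                        region = "trailing"), "retract")
    neg <- pmax(-seg$force_pN, 0)
    oracle <- sum(diff(seg$piezo_um) * (head(neg, -1) + tail(neg, -1)) / 2)
    expect_rel(res$work_aJ, oracle, 0.005)
  }
})

test_that("work and detachment force are direction-convention invariant", {
  ev <- data.frame(plateau_length_um = 0.4, step_force_pN = 60)
  cur <- gen_retraction_curve(ev, detachment_force = 300, z_length = 8,
                              noise = 0)
  seg <- get_segment(cur, "retract")
  rev_cur <- force_curve(list(list(label = "retract",
                                   piezo_um = rev(seg$piezo_um),
                                   force_pN = rev(seg$force_pN))),
                         cur$spring_constant)
  a <- analyze_retraction(cur, noise_sd = 5)
  b <- analyze_retraction(rev_cur, noise_sd = 5)
  expect_equal(a$work_aJ, b$work_aJ, tolerance = 1e-9)
  expect_equal(a$max_detachment_force_pN, b$max_detachment_force_pN)
})

test_that("step detection finds discrete steps, not smooth returns or noise", {
  z <- seq(0, 10, by = 0.002)
  smooth <- -300 * exp(-z / 2)
  expect_equal(nrow(detect_steps(smooth, z, noise_sd = 5)), 0L)
  # single 80 pN step after a 0.4 um plateau (instantaneous edges)
  f <- rep(0, length(z))
  f[z >= 1 & z < 1.4] <- -200
  f[z >= 1.4 & z < 5] <- -120 # terminal release at z = 5
  steps <- detect_steps(f, z, noise_sd = 5)
  first <- steps[which.min(abs(steps$position_um - 1.4)), ]
  expect_lt(abs(first$position_um - 1.4), 0.01)
  expect_rel(first$step_force_pN, 80, 0.1)
  expect_lt(abs(first$plateau_length_um - 0.4), 0.01)
  # same step buried in 30 pN noise: 4 sigma = 120 pN, 80 pN is subthreshold
  set.seed(2)
  noisy <- f + rnorm(length(z), 0, 30)
  got <- detect_steps(noisy, z, noise_sd = 30)
  expect_false(any(abs(got$position_um - 1.4) < 0.05))
})

test_that("classification is a deterministic threshold at 0.25 um", {
  mk <- function(pl) data.frame(position_um = 1, step_force_pN = 50,
                                plateau_length_um = pl)
  expect_equal(classify_event(mk(0.40))$kind, "tether")
  expect_equal(classify_event(mk(0.10))$kind, "jump")
  expect_equal(classify_event(mk(0))$kind, "jump")
  expect_equal(classify_event(mk(0.25))$kind, "tether") # boundary: tether
  labels <- vapply(seq(0.05, 0.50, by = 0.01), function(pl)
    classify_event(mk(pl))$kind, character(1))
  expect_equal(sum(labels[-1] != labels[-length(labels)]), 1L)
})

test_that("generated event inventories are recovered and classified", {
  ev <- data.frame(plateau_length_um = c(0.10, 0.05, 0.40),
                   step_force_pN = c(80, 60, 50))
  cur <- gen_retraction_curve(ev, detachment_force = 500, z_length = 10,
                              noise = 0)
  res <- analyze_retraction(cur, noise_sd = 5)
  expect_equal(res$n_jumps, 2L)
  expect_equal(res$n_tethers, 1L)
  got <- sort(vapply(res$events, `[[`, numeric(1), "step_force"))
  expect_lt(max(abs(got - sort(ev$step_force_pN)) / sort(ev$step_force_pN)),
            0.1)
  expect_equal(attr(cur, "truth")$events$kind, c("jump", "jump", "tether"))
})

test_that("condition summaries aggregate and check design completeness", {
  ev <- data.frame(plateau_length_um = c(0.1, 0.4),
                   step_force_pN = c(70, 50))
  one <- analyze_retraction(
    gen_retraction_curve(ev, detachment_force = 400, z_length = 8,
                         noise = 0), noise_sd = 5)
  res36 <- rep(list(one), 36)
  summ <- summarize_adhesion(res36, design = list(cells = 36,
                                                  curves_per_cell = 1))
  expect_equal(summ$work_aJ_mean, one$work_aJ)
  expect_equal(summ$work_aJ_sem, 0)
  expect_true(attr(summ, "complete"))
  expect_warning(
    summarize_adhesion(res36[1:30], design = list(cells = 36,
                                                  curves_per_cell = 1)),
    "incomplete")
})
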