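# Shared helpers for the test suite.

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}

# a small, well-formed three-segment curve
demo_curve <- function() {
  force_curve(
    list(list(label = "approach", piezo_um = seq(10, 5, by = -0.5),
              force_pN = c(rep(0, 8), 50, 150, 300)),
         list(label = "pause", piezo_um = seq(5.01, 5.05, by = 0.01),
              force_pN = rep(300, 5)),
         list(label = "retract", piezo_um = seq(5.1, 10, by = 0.5),
              force_pN = c(-200, -100, -50, 0, 0, 0, 0, 0, 0, 0))),
    spring_constant = 0.02, approach_speed = 2, z_length = 5,
    metadata = list(cell = "c1", condition = "control"))
}

# true step positions of a generated retraction curve, from its event list
truth_step_positions <- function(events, well_width = 1, ramp_length = 0.1,
                                 dz = 0.004) {
  z <- well_width; pos <- numeric(nrow(events))
  for (j in seq_len(nrow(events))) {
    z <- z + ramp_length + events$plateau_length_um[j]
    pos[j] <- z
    z <- z + dz / 10
  }
  pos
}
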