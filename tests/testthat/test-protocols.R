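test_that("a zero-duration stimulus leaves the system at rest, uncommitted", {
  traj <- simulate_protocol(stimulation_protocol(c(2e5, 2e5), 0,
                                                 post_hours = 20),
                            "AND", save_dt_h = 5)
  expect_false(traj$committed)
  rest <- bcl2_steady_state(c(0, 0), "AND")
  expect_equal(unname(traj$states[nrow(traj$states), ]),
               as.numeric(rest), tolerance = 1e-4)
  expect_lt(max_pool_drift(traj), 1e-6)
})

test_that("ten hours of dual-maximal stimulation fail where eleven succeed (AND preset)", {
  tr10 <- simulate_protocol(stimulation_protocol(c(2e5, 2e5), 10), "AND",
                            save_dt_h = 0.5)
  tr11 <- simulate_protocol(stimulation_protocol(c(2e5, 2e5), 11), "AND",
                            save_dt_h = 0.5)
  expect_false(tr10$committed)
  expect_true(tr11$committed)
  # the failed run still makes a transient excursion above both the Bax
  # fold and the caspase fold level before relaxing back
  bif <- find_bifurcation()
  expect_gt(max(tr10$states[, "Bax"]), bif$Bax_bif)
  expect_gt(max(tr10$states[, "Casp"]), bif$Casp_bif)
  expect_lt(tr10$states[nrow(tr10$states), "Casp"], 1000)
})

test_that("after commitment Casp settles on the high branch while Bax resets", {
  traj <- simulate_protocol(stimulation_protocol(c(2e5, 2e5), 14), "AND",
                            save_dt_h = 2)
  expect_true(traj$committed)
  hi <- max(caspase_steady_states(0)$Casp)
  terminal <- traj$states[nrow(traj$states), ]
  expect_equal(unname(terminal["Casp"]), hi, tolerance = 0.01)
  rest <- bcl2_steady_state(c(0, 0), "AND")
  expect_equal(unname(terminal["Bax"]), rest[["Bax"]], tolerance = 0.05)
})

test_that("commitment decisions refuse ambiguity instead of guessing", {
  params <- default_parameters()
  thr <- commitment_threshold(params)
  fake <- function(casp) {
    structure(list(time_h = 0, states = matrix(c(rep(0, 10), casp), 1,
                                               dimnames = list(NULL,
                                                               species_names())),
                   params = params),
              class = "bclgate_trajectory")
  }
  expect_error(committed_to_apoptosis(fake(thr)), "indeterminate")
  expect_error(committed_to_apoptosis(fake(5e4)), "extend")
  expect_true(committed_to_apoptosis(fake(max(caspase_steady_states(0)$Casp))))
  expect_false(committed_to_apoptosis(fake(10)))
})

test_that("commitment is monotone in stimulus duration around the minimum", {
  d <- minimal_stimulation_duration(c(2e5, 2e5), "AND")
  probe <- function(dur) {
    committed_to_apoptosis(simulate_protocol(
      stimulation_protocol(c(2e5, 2e5), dur), "AND", save_dt_h = 5))
  }
  for (dur in c(0.5, 0.8) * d) expect_false(probe(dur))
  for (dur in c(1.2, 1.5, 2) * d) expect_true(probe(dur))
  expect_lte(diff(attr(d, "bracket")), 0.05)
})

test_that("minimal durations match the reference commitment times", {
  d <- minimal_stimulation_duration(c(2e5, 0), "OR")
  expect_equal(as.numeric(d), 3.0, tolerance = 0.1)
})

test_that("inputs that can never commit raise a bracket error", {
  expect_error(
    minimal_stimulation_duration(c(2e5, 0), "AND", bracket = c(0, 24)),
    "does not commit")
})

test_that("minimal durations are robust to a tenfold tighter solver tolerance", {
  d1 <- minimal_stimulation_duration(c(0, 2e5), "OR")
  d2 <- minimal_stimulation_duration(c(0, 2e5), "OR",
                                     solver = solver_settings(rtol = 1e-9))
  expect_lt(abs(as.numeric(d1) - as.numeric(d2)), 0.05 + 1e-9)
})
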