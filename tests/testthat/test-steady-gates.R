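test_that("the resting OR-preset steady state reproduces the reference abundances", {
  ss <- bcl2_steady_state(c(0, 0), "OR")
  expect_equal(ss[["cBaxBclxL"]], 2e4, tolerance = 0.05)
  expect_equal(ss[["cBclxLBadu"]], 6.67e4, tolerance = 0.05)
  expect_equal(ss[["cBadpScaffold"]], 1.333e5, tolerance = 0.05)
  expect_equal(ss[["Scaffold"]], 6.67e4, tolerance = 0.05)
  # free Bcl-xL from mass balance with phosphorylated fraction 2/3
  expect_equal(ss[["BclxL"]], 1.33e4, tolerance = 0.02)
  expect_lt(attr(ss, "residual"), 1e-6)
})

test_that("the AND preset carries a large free Bcl-xL buffer at rest", {
  ss <- bcl2_steady_state(c(0, 0), "AND")
  expect_equal(ss[["BclxL"]], 6e4, tolerance = 0.05)
})

test_that("full Akt dephosphorylation releases all Bax in the OR preset", {
  ss <- bcl2_steady_state(c(0, 2e5), "OR")
  expect_equal(ss[["Bax"]], 2e4, tolerance = 0.05)
})

test_that("steady states respect conservation and the phosphorylation closed form", {
  set.seed(3)
  for (k in 1:10) {
    params <- perturbed_parameters(200 + k, 0.05)
    pools <- pool_config(runif(1, 0.5e5, 2.5e5), runif(1, 0.5e5, 2.5e5))
    inp <- input_point(runif(1, 0, 2e5), runif(1, 0, params$Akt_tot), params)
    ss <- bcl2_steady_state(inp, pools, params)
    got <- conserved_pools(ss)
    expect_equal(unname(got),
                 c(pools$BclxL_tot, pools$Bad_tot, pools$Scaffold_tot),
                 tolerance = 1e-8)
    # at steady state the phosphorylated fraction of the Bad pool equals
    # p1*Akt_p / (q1 + p1*Akt_p) regardless of the binding equilibria
    frac <- (ss[["Bad_p"]] + ss[["cBadpScaffold"]]) / pools$Bad_tot
    expect_equal(frac, params$p1 * inp$Akt_p / (params$q1 + params$p1 *
                                                  inp$Akt_p),
                 tolerance = 1e-3)
  }
})

test_that("macro-parameters take their closed-form values", {
  m <- macro_parameters()
  expect_equal(m$m1, 2e4)
  expect_equal(m$m2, 6.8e4)
  expect_equal(m$m3, 0.3)
  expect_equal(m$m4, 30)
  expect_equal(m$m5, 30)
  expect_equal(m$m6, 2 / 3)
  expect_equal(m$m7, find_bifurcation()$Bax_bif)
  expect_lt(m$m1, m$m2)
  expect_true(m$m6 > 0 && m$m6 < 1)
  expect_lt(m$m3, m$m4 / 10) # displacement condition m3 << m4
})

test_that("algebraic corner predictions follow the stoichiometric inequality", {
  macro <- macro_parameters()
  p00 <- algebraic_corner_prediction(c(0, 0), "OR", macro)
  expect_equal(as.character(p00), "SURVIVAL")
  # margin = m1 + (1/3) Bad_tot - BclxL_tot - m7
  expect_equal(attr(p00, "margin"), 2e4 + 2e5 / 3 - 1e5 - macro$m7)
  expect_equal(as.character(algebraic_corner_prediction(c(0, 1), "OR", macro)),
               "APOPTOSIS")
  expect_equal(as.character(algebraic_corner_prediction(c(1, 0), "AND", macro)),
               "SURVIVAL")
  expect_error(algebraic_corner_prediction(c(2, 0), "OR", macro), "logic")
})

test_that("preset pool configurations classify as their nominal gates", {
  bif <- find_bifurcation()
  expected <- c(OR = "OR", AND = "AND", AND_STAR = "AND")
  for (g in names(expected)) {
    ode <- classify_gate(g, method = "ode", bifurcation = bif)
    alg <- classify_gate(g, method = "algebraic", bifurcation = bif)
    expect_equal(ode$gate_type, unname(expected[g]))
    expect_equal(alg$gate_type, unname(expected[g]))
    expect_equal(ode$truth_table$fate, alg$truth_table$fate)
  }
})

test_that("ODE and algebraic corner fates agree outside the finite-affinity band", {
  params <- default_parameters()
  bif <- find_bifurcation(params)
  macro <- macro_parameters(params)
  set.seed(5)
  corners <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  for (k in 1:6) {
    pools <- pool_config(runif(1, 0.3e5, 2.5e5), runif(1, 0.6e5, 2.5e5))
    for (cc in corners) {
      alg <- algebraic_corner_prediction(cc, pools, macro)
      if (abs(attr(alg, "margin")) > 0.1 * (pools$BclxL_tot + macro$m7)) {
        ode <- classify_fate(corner_input(cc, params), pools, params,
                             bifurcation = bif)
        expect_equal(as.character(ode), as.character(alg))
      }
    }
  }
})

test_that("free Bax rises monotonically over the input plane and isolines behave", {
  sc <- input_plane_scan("OR", grid = 9)
  expect_true(all(apply(sc$bax, 2, diff) > -0.1))
  expect_true(all(apply(sc$bax, 1, diff) > -0.1))
  expect_lt(sc$bax[1, 1], sc$bax_bif)   # resting corner survives
  expect_gt(sc$bax[9, 9], sc$bax_bif)   # dual-maximal corner commits
  iso <- apoptotic_isoline(sc)
  expect_gt(nrow(iso), 0)
  # a constant sub-threshold surface has no isoline
  flat <- sc
  flat$bax[] <- 1
  expect_equal(nrow(apoptotic_isoline(flat)), 0)
})

test_that("gate boundaries along Bad_tot bracket the AND-to-OR transition", {
  gb <- gate_boundary(pools = pool_preset("OR"), vary = "Bad_tot",
                      range = c(0.2e5, 1.6e5), step = 2500)
  # p53-only corner flips at the OR onset, Akt-only corner at the AND exit
  expect_equal(unname(gb$corner_flips["{1,0}"]), 1.1e5, tolerance = 0.05)
  expect_equal(unname(gb$corner_flips["{0,1}"]), 0.9e5, tolerance = 0.10)
  expect_equal(gb$boundaries$OR_onset, unname(gb$corner_flips["{1,0}"]))
  expect_lt(gb$boundaries$AND_last, gb$boundaries$OR_onset)
  # between AND and OR the gate passes through the Akt-intermediate band
  expect_true("AKT_INTERMEDIATE" %in% gb$table$gate_type)
  # algebraic oracle for the OR onset: Bad_tot = 3 (BclxL_tot + m7 - m2)
  macro <- macro_parameters()
  expect_equal(gb$boundaries$OR_onset,
               3 * (1e5 + macro$m7 - macro$m2), tolerance = 0.05)
})
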