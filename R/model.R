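# Right-hand side of the 11-ODE module, conservation accounting,
# and the internal integration helpers shared by all analyses.

#' Species names of the model state
#'
#' The model state has 11 components, all in molecules/cell:
#' `Bax_mRNA`, `Bax`, `BclxL`, `cBaxBclxL` (Bax:Bcl-xL complex),
#' `cBclxLBadu` (Bcl-xL:Bad_u complex), `Bad_u`, `Bad_p`,
#' `cBadpScaffold` (Bad_p:Scaffold 14-3-3 complex), `Scaffold`,
#' `Procasp`, `Casp`.
#' @return Character vector of length 11.
#' @export
species_names <- function() {
  c("Bax_mRNA", "Bax", "BclxL", "cBaxBclxL", "cBclxLBadu",
    "Bad_u", "Bad_p", "cBadpScaffold", "Scaffold", "Procasp", "Casp")
}

as_system_state <- function(state) {
  nm <- species_names()
  if (length(state) != 11) stop("state must have 11 components")
  state <- as.numeric(state)
  names(state) <- nm
  state
}

#' p53-driven Bax transcription rate
#'
#' Hill kinetics with cooperativity 2:
#' `s1 + s2 * p53^2 / (M^2 + p53^2)`. Bounded in `[s1, s1 + s2]` and
#' strictly increasing in `p53_killer`.
#'
#' @param p53_killer p53_killer level, molecules (>= 0); vectorized.
#' @param params Kinetic parameters.
#' @return Synthesis rate(s), molecules/s.
#' @examples
#' hill_synthesis_rate(0)    # s1
#' hill_synthesis_rate(1e5)  # s1 + s2/2 (half-saturation)
#' @export
hill_synthesis_rate <- function(p53_killer, params = default_parameters()) {
  params <- as_bcl2_params(params)
  if (any(!is.finite(p53_killer)) || any(p53_killer < 0)) {
    stop("p53_killer must be nonnegative")
  }
  params$s1 + params$s2 * p53_killer^2 / (params$M^2 + p53_killer^2)
}

#' Time derivatives of the 11-species state
#'
#' The mass-action right-hand side of the module. Bax mRNA is produced
#' by the Hill term and degraded (d1); Bax is translated (s4), binds
#' Bcl-xL (b1/u1) and degrades (d2), including degradation of Bax inside
#' the Bax:Bcl-xL complex which releases Bcl-xL (+d2*complex). Bad_u
#' binds Bcl-xL (b2/u2); Akt_p phosphorylates both free Bad_u and Bad_u
#' complexed with Bcl-xL (p1*Akt_p*X), and dephosphorylation (q1) acts
#' on both free Bad_p and scaffold-bound Bad_p. Bad_p binds the 14-3-3
#' scaffold (b3/u3). Pro-caspase is produced (s3) and converted by
#' `a1*Bax + a2*Casp^2`, with shared degradation d3; the quadratic
#' autocatalysis makes the caspase pair bistable.
#'
#' @param state Numeric state vector of length 11 (see [species_names()]).
#' @param input An [input_point()] or numeric pair `(p53_killer, Akt_u)`.
#' @param params Kinetic parameters.
#' @return Named numeric vector of the 11 time derivatives, molecules/s.
#' @export
derivatives <- function(state, input, params = default_parameters()) {
  params <- as_bcl2_params(params)
  input <- as_input_point(input, params)
  y <- as_system_state(state)
  # tolerate integrator undershoot up to the default absolute tolerance;
  # genuinely negative abundances are rejected, never clipped
  if (any(y < -1e-3)) stop("state must be nonnegative")
  p <- params

  hill <- hill_synthesis_rate(input$p53_killer, p)
  v_b1 <- p$b1 * y[["Bax"]] * y[["BclxL"]]
  v_u1 <- p$u1 * y[["cBaxBclxL"]]
  v_b2 <- p$b2 * y[["BclxL"]] * y[["Bad_u"]]
  v_u2 <- p$u2 * y[["cBclxLBadu"]]
  v_b3 <- p$b3 * y[["Bad_p"]] * y[["Scaffold"]]
  v_u3 <- p$u3 * y[["cBadpScaffold"]]
  v_pf <- p$p1 * input$Akt_p * y[["Bad_u"]]
  v_pc <- p$p1 * input$Akt_p * y[["cBclxLBadu"]]
  v_qf <- p$q1 * y[["Bad_p"]]
  v_qc <- p$q1 * y[["cBadpScaffold"]]
  v_act <- (p$a1 * y[["Bax"]] + p$a2 * y[["Casp"]]^2) * y[["Procasp"]]

  d <- c(
    Bax_mRNA      = hill - p$d1 * y[["Bax_mRNA"]],
    Bax           = p$s4 * y[["Bax_mRNA"]] + v_u1 - v_b1 - p$d2 * y[["Bax"]],
    BclxL         = v_u2 + v_u1 + v_pc - v_b2 - v_b1 + p$d2 * y[["cBaxBclxL"]],
    cBaxBclxL     = v_b1 - v_u1 - p$d2 * y[["cBaxBclxL"]],
    cBclxLBadu    = v_b2 - v_u2 - v_pc,
    Bad_u         = v_u2 - v_b2 - v_pf + v_qf + v_qc,
    Bad_p         = v_u3 - v_b3 + v_pf + v_pc - v_qf,
    cBadpScaffold = v_b3 - v_u3 - v_qc,
    Scaffold      = v_u3 - v_b3 + v_qc,
    Procasp       = p$s3 - v_act - p$d3 * y[["Procasp"]],
    Casp          = v_act - p$d3 * y[["Casp"]]
  )
  d
}

#' Conserved pool totals of a state
#'
#' The ODE structure conserves three pools exactly:
#' Bcl-xL (`BclxL + cBaxBclxL + cBclxLBadu`),
#' Bad (`Bad_u + Bad_p + cBclxLBadu + cBadpScaffold`) and
#' Scaffold (`Scaffold + cBadpScaffold`).
#'
#' @param state State vector of length 11 (or a trajectory row).
#' @return Named numeric vector `(BclxL_tot, Bad_tot, Scaffold_tot)`.
#' @export
conserved_pools <- function(state) {
  y <- as_system_state(state)
  c(BclxL_tot = y[["BclxL"]] + y[["cBaxBclxL"]] + y[["cBclxLBadu"]],
    Bad_tot = y[["Bad_u"]] + y[["Bad_p"]] + y[["cBclxLBadu"]] +
      y[["cBadpScaffold"]],
    Scaffold_tot = y[["Scaffold"]] + y[["cBadpScaffold"]])
}

# parameter vector for the compiled rhs: rates in .param_order, then inputs
compiled_parms <- function(params, input) {
  c(unlist(unclass(params)[.param_order]),
    p53 = input$p53_killer, aktp = input$Akt_p)
}

#' Solver settings for the stiff integrator
#'
#' The module is integrated with `deSolve::lsoda`. Caspase switching is
#' stiff near the commitment threshold, so the defaults are strict:
#' relative tolerance 1e-8 and absolute tolerance 1e-3 molecules.
#'
#' @param rtol Relative tolerance.
#' @param atol Absolute tolerance, molecules.
#' @return List of solver settings.
#' @export
solver_settings <- function(rtol = 1e-8, atol = 1e-3) {
  list(rtol = rtol, atol = atol)
}

# integrate the full 11-species system over times_s (seconds, from 0),
# constant input; returns the deSolve matrix
integrate_full <- function(y0, times_s, input, params,
                           solver = solver_settings()) {
  deSolve::lsoda(
    y = as_system_state(y0), times = times_s,
    func = "bclgate_derivs", parms = compiled_parms(params, input),
    dllname = "bclgate", initfunc = "bclgate_initmod",
    rtol = solver$rtol, atol = solver$atol, maxsteps = 50000
  )
}

# integrate only the caspase-independent 9-species Bcl-2 subsystem
integrate_bcl2 <- function(y0_9, times_s, input, params,
                           solver = solver_settings()) {
  deSolve::lsoda(
    y = y0_9, times = times_s,
    func = "bclgate_derivs9", parms = compiled_parms(params, input),
    dllname = "bclgate", initfunc = "bclgate_initmod",
    rtol = solver$rtol, atol = solver$atol, maxsteps = 50000
  )
}
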