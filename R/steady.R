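# Steady states of the caspase-independent Bcl-2 subsystem, fate
# classification, macro-parameters and the algebraic gate conditions.

# canonical resting start: all Bad phosphorylated and scaffold-bound up
# to capacity, Bcl-xL free, no Bax or Bax mRNA
canonical_start <- function(pools) {
  cbs <- min(pools$Bad_tot, pools$Scaffold_tot)
  y <- c(Bax_mRNA = 0, Bax = 0, BclxL = pools$BclxL_tot, cBaxBclxL = 0,
         cBclxLBadu = 0, Bad_u = 0, Bad_p = pools$Bad_tot - cbs,
         cBadpScaffold = cbs, Scaffold = pools$Scaffold_tot - cbs,
         Procasp = 0, Casp = 0)
  y
}

# residual of the 9 caspase-independent equations (molecules/s)
bcl2_residual <- function(y9, input, params) {
  d <- derivatives(c(y9, Procasp = 0, Casp = 0), input, params)
  max(abs(d[1:9]))
}

#' Steady state of the Bcl-2 subsystem under constant inputs
#'
#' The first nine equations of the model (everything except the caspase
#' pair) do not depend on caspase levels, and for constant inputs the
#' subsystem is monostable. Its steady state is obtained by relaxation:
#' the system is integrated from the canonical resting start (all Bad
#' phosphorylated and bound to scaffold up to capacity, Bcl-xL free, no
#' Bax) until the maximal derivative magnitude falls below `residual_tol`,
#' with a hard cap of 2000 simulated hours.
#'
#' The returned state carries the caspase pair at its steady branch for
#' the resulting free-Bax level: the low branch where the pair is
#' bistable, otherwise the unique (high) state.
#'
#' @param input An [input_point()] or numeric pair `(p53_killer, Akt_u)`.
#' @param pools A [pool_config()] or preset name.
#' @param params Kinetic parameters.
#' @param residual_tol Convergence threshold on the maximal derivative,
#'   molecules/s.
#' @param solver Solver settings from `solver_settings()`.
#' @return Object of class `bcl2_steady`: a named state vector of length
#'   11 with attributes `residual`, `converged_at_h`, `caspase_branch`,
#'   `input` and `pools`.
#' @export
bcl2_steady_state <- function(input, pools, params = default_parameters(),
                              residual_tol = 1e-6,
                              solver = solver_settings()) {
  params <- as_bcl2_params(params)
  if (is.character(pools)) pools <- pool_preset(pools)
  input <- as_input_point(input, params)
  y <- canonical_start(pools)[1:9]

  checkpoints_h <- list(c(50, 100, 200, 400), c(800, 1200, 1600, 2000))
  t_done <- 0
  res <- Inf
  conv_h <- NA_real_
  for (block in checkpoints_h) {
    times <- c(t_done, block) * 3600
    out <- integrate_bcl2(y, times, input, params, solver)
    for (k in seq_along(block)) {
      yk <- out[k + 1, 1 + seq_len(9)]
      res <- bcl2_residual(yk, input, params)
      if (res < residual_tol) {
        conv_h <- block[k]
        y <- yk
        break
      }
    }
    if (!is.na(conv_h)) break
    y <- out[nrow(out), 1 + seq_len(9)]
    t_done <- block[length(block)]
  }
  if (is.na(conv_h)) {
    stop(sprintf(
      "Bcl-2 subsystem did not reach residual %g molecules/s within 2000 h (final residual %.3g)",
      residual_tol, res))
  }

  casp <- caspase_steady_states(max(y[["Bax"]], 0), params)
  branch <- if (nrow(casp) >= 3) "low" else "unique"
  state <- as_system_state(c(y, casp$Procasp[1], casp$Casp[1]))
  structure(state, class = "bcl2_steady", residual = res,
            converged_at_h = conv_h, caspase_branch = branch,
            input = input, pools = pools)
}

#' @export
print.bcl2_steady <- function(x, ...) {
  inp <- attr(x, "input")
  cat(sprintf(
    "Bcl-2 module steady state (p53_killer = %g, Akt_u = %g; residual %.2g mlcl/s at %g h)\n",
    inp$p53_killer, inp$Akt_u, attr(x, "residual"), attr(x, "converged_at_h")))
  v <- unclass(x)
  attributes(v) <- list(names = names(v))
  print(signif(v, 5))
  invisible(x)
}

#' Classify the fate implied by a constant input
#'
#' A constant-input steady state is apoptotic iff its free-Bax level
#' reaches the caspase saddle-node `Bax_bif`: held there, the caspase
#' switch has no surviving (low) branch.
#'
#' @inheritParams bcl2_steady_state
#' @param bifurcation Optional precomputed [find_bifurcation()] result.
#' @return `"APOPTOSIS"` or `"SURVIVAL"` (character scalar with the
#'   steady state attached as attribute `steady_state`).
#' @export
classify_fate <- function(input, pools, params = default_parameters(),
                          bifurcation = NULL) {
  params <- as_bcl2_params(params)
  if (is.null(bifurcation)) bifurcation <- find_bifurcation(params)
  ss <- bcl2_steady_state(input, pools, params)
  fate <- if (ss[["Bax"]] >= bifurcation$Bax_bif) "APOPTOSIS" else "SURVIVAL"
  structure(fate, steady_state = ss)
}

#' Macro-parameters governing steady-state levels
#'
#' Seven parameter clusters fully determine the steady-state solution:
#' `m1 = s1*s4/(d1*d2)` and `m2` (same with the Hill term at
#' `p53killer_max`) are the minimal and maximal total Bax; `m3 = b1/u1`,
#' `m4 = b2/u2`, `m5 = b3/u3` are the binding affinities; `m6 =
#' p1*Akt_tot/(q1 + p1*Akt_tot)` is the maximal phosphorylated-Bad
#' fraction; `m7` is the caspase saddle-node `Bax_bif`. The condition
#' `m3 << m4` means Bcl-xL binds Bad_u preferentially, enabling
#' displacement of Bax.
#'
#' @param params Kinetic parameters.
#' @return Object of class `macro_parameters` (named list m1--m7).
#' @export
macro_parameters <- function(params = default_parameters()) {
  params <- as_bcl2_params(params)
  p <- params
  hill_max <- hill_synthesis_rate(p$p53killer_max, p)
  m <- list(
    m1 = p$s1 * p$s4 / (p$d1 * p$d2),
    m2 = hill_max * p$s4 / (p$d1 * p$d2),
    m3 = p$b1 / p$u1,
    m4 = p$b2 / p$u2,
    m5 = p$b3 / p$u3,
    m6 = p$p1 * p$Akt_tot / (p$q1 + p$p1 * p$Akt_tot),
    m7 = find_bifurcation(p)$Bax_bif
  )
  structure(m, class = "macro_parameters")
}

#' @export
print.macro_parameters <- function(x, ...) {
  cat("Macro-parameters of the steady-state solution\n")
  print(signif(unlist(unclass(x)), 5))
  invisible(x)
}

#' Algebraic corner fate prediction
#'
#' Stoichiometric shortcut to the ODE steady state: free Bax appears
#' once the pro-apoptotic demand on Bcl-xL exceeds its supply plus the
#' fold margin, i.e. apoptosis iff
#' `Bax_tot(corner) + Bad_u(corner) > BclxL_tot + m7`, where `Bax_tot`
#' is `m1` (p53 logic 0) or `m2` (logic 1) and `Bad_u` is
#' `(1 - m6) * Bad_tot` (Akt_u logic 0) or `Bad_tot` (logic 1).
#'
#' @param corner Logic pair in \{0,1\}^2: `(p53, Akt_u)`.
#' @param pools Pool configuration or preset name.
#' @param macro Macro-parameters from [macro_parameters()].
#' @return `"APOPTOSIS"` or `"SURVIVAL"`, with attribute `margin`
#'   (left side minus right side, molecules).
#' @export
algebraic_corner_prediction <- function(corner, pools, macro) {
  if (is.character(pools)) pools <- pool_preset(pools)
  if (length(corner) != 2 || !all(corner %in% c(0, 1))) {
    stop("`corner` must be a logic pair in {0,1}^2")
  }
  bax_tot <- if (corner[1] == 0) macro$m1 else macro$m2
  bad_u <- if (corner[2] == 0) (1 - macro$m6) * pools$Bad_tot else
    pools$Bad_tot
  lhs <- bax_tot + bad_u
  rhs <- pools$BclxL_tot + macro$m7
  structure(if (lhs > rhs) "APOPTOSIS" else "SURVIVAL", margin = lhs - rhs)
}
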