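# Kinetic parameters, conserved pools and input points.

# rate constants perturbed by perturbed_parameters(); capacities excluded
.rate_names <- c("s1", "s2", "s3", "s4", "M", "d1", "d2", "d3",
                 "b1", "b2", "b3", "u1", "u2", "u3",
                 "p1", "q1", "a1", "a2")
.capacity_names <- c("Akt_tot", "p53killer_max")
.param_names <- c(.rate_names, .capacity_names)

# order in which parameters are passed to the compiled right-hand side
# (followed by p53 and Akt_p); must match src/bclgate.c
.param_order <- .rate_names

#' Default kinetic parameters of the apoptotic module
#'
#' Returns the reference parameterization of the eleven-species model:
#' synthesis rates `s1` (basal Bax mRNA), `s2` (p53-regulated Bax mRNA),
#' `s3` (pro-caspase) and `s4` (Bax translation per mRNA), the Hill
#' half-saturation level `M`, first-order degradation rates `d1`--`d3`,
#' bimolecular association rates `b1`--`b3` with dissociation rates
#' `u1`--`u3`, the Akt_p-driven Bad phosphorylation rate `p1` and
#' dephosphorylation rate `q1`, caspase activation rates `a1`
#' (Bax-driven) and `a2` (autocatalytic), and the two capacities
#' `Akt_tot` and `p53killer_max`.
#'
#' Units: abundances in molecules/cell, time in seconds. `p1` is
#' bimolecular (molecules^-1 s^-1): every phosphorylation term has the
#' form `p1 * Akt_p * X`, which also makes the maximal phosphorylated-Bad
#' fraction `p1*Akt_tot/(q1 + p1*Akt_tot)` dimensionless (= 2/3 at the
#' defaults).
#'
#' @return An object of class `bcl2_params`: a named list of the 20
#'   positive parameters.
#' @examples
#' p <- default_parameters()
#' p$s1       # 1e-2 molecules/s
#' p$Akt_tot  # 2e5 molecules
#' @export
default_parameters <- function() {
  p <- list(
    s1 = 1e-2,    # basal Bax_mRNA synthesis, mlcl/s
    s2 = 3e-2,    # p53_killer-regulated Bax_mRNA synthesis, mlcl/s
    s3 = 2e1,     # pro-caspase synthesis, mlcl/s
    s4 = 2e-1,    # Bax translation per mRNA, 1/s
    M  = 1e5,     # half-saturation of p53-driven transcription, mlcl
    d1 = 1e-3,    # Bax_mRNA degradation, 1/s
    d2 = 1e-4,    # Bax degradation, 1/s
    d3 = 2e-4,    # (pro-)caspase degradation, 1/s
    b1 = 3e-5,    # Bax--Bcl-xL binding, 1/(mlcl s)
    b2 = 3e-3,    # Bcl-xL--Bad_u binding, 1/(mlcl s)
    b3 = 3e-3,    # Bad_p--Scaffold binding, 1/(mlcl s)
    u1 = 1e-4,    # Bax:Bcl-xL unbinding, 1/s
    u2 = 1e-4,    # Bcl-xL:Bad_u unbinding, 1/s
    u3 = 1e-4,    # Bad_p:Scaffold unbinding, 1/s
    p1 = 3e-10,   # Bad phosphorylation per Akt_p, 1/(mlcl s)
    q1 = 3e-5,    # Bad_p dephosphorylation, 1/s
    a1 = 2e-10,   # Bax-driven pro-caspase activation, 1/(mlcl s)
    a2 = 1e-12,   # caspase autoactivation, 1/(mlcl^2 s)
    Akt_tot = 2e5,        # constant Akt pool, mlcl
    p53killer_max = 2e5   # maximal considered p53_killer, mlcl
  )
  structure(p, class = "bcl2_params")
}

#' Coerce and validate a kinetic parameter set
#'
#' @param params A `bcl2_params` object or a named list carrying a subset
#'   of the parameter names; missing entries take the defaults.
#' @return A validated `bcl2_params` object.
#' @export
as_bcl2_params <- function(params = list()) {
  if (inherits(params, "bcl2_params")) {
    p <- unclass(params)
  } else {
    if (!is.list(params)) stop("`params` must be a list or bcl2_params object")
    unknown <- setdiff(names(params), .param_names)
    if (length(unknown) > 0) {
      stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
    }
    p <- unclass(default_parameters())
    p[names(params)] <- params
  }
  vals <- unlist(p[.param_names])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    bad <- .param_names[!is.finite(vals) | vals <= 0]
    stop("parameters must be finite and strictly positive: ",
         paste(bad, collapse = ", "))
  }
  structure(p[.param_names], class = "bcl2_params")
}

#' Randomly perturbed parameter sets for property tests
#'
#' Multiplies each rate constant by an independent log-normal factor
#' `exp(rnorm(1, 0, log_sd))`. The capacities `Akt_tot` and
#' `p53killer_max` are left fixed unless `perturb_capacities = TRUE`.
#' Deterministic for a given `seed`.
#'
#' @param seed Integer seed.
#' @param log_sd Standard deviation of the log-factors (>= 0); 0 returns
#'   the defaults unchanged.
#' @param params Base parameter set (defaults to [default_parameters()]).
#' @param perturb_capacities Also perturb the two capacity parameters?
#' @return A `bcl2_params` object.
#' @export
perturbed_parameters <- function(seed, log_sd, params = default_parameters(),
                                 perturb_capacities = FALSE) {
  stopifnot(is.numeric(log_sd), length(log_sd) == 1, log_sd >= 0)
  p <- unclass(as_bcl2_params(params))
  targets <- if (perturb_capacities) .param_names else .rate_names
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  fac <- exp(stats::rnorm(length(targets), mean = 0, sd = log_sd))
  for (i in seq_along(targets)) p[[targets[i]]] <- p[[targets[i]]] * fac[i]
  structure(p, class = "bcl2_params")
}

#' @export
print.bcl2_params <- function(x, ...) {
  cat("Kinetic parameters of the Bcl-2 apoptotic module\n")
  v <- unlist(unclass(x))
  print(signif(v, 6))
  invisible(x)
}

#' Conserved-pool configuration
#'
#' The steady-state behavior of the Bcl-2 subsystem is controlled by
#' three conserved totals: `Bad_tot`, `BclxL_tot` and `Scaffold_tot`
#' (molecules/cell). `Scaffold_tot` defaults to 2e5.
#'
#' @param Bad_tot,BclxL_tot,Scaffold_tot Nonnegative totals (molecules).
#' @return An object of class `pool_config`.
#' @seealso [pool_preset()] for the three named gate configurations.
#' @export
pool_config <- function(Bad_tot, BclxL_tot, Scaffold_tot = 2e5) {
  vals <- c(Bad_tot = Bad_tot, BclxL_tot = BclxL_tot,
            Scaffold_tot = Scaffold_tot)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("pool totals must be finite and nonnegative")
  }
  structure(as.list(vals), class = "pool_config")
}

#' Named pool presets realizing the three gate types
#'
#' `"OR"` (Bad_tot = 2e5, BclxL_tot = 1e5): either maximal input alone
#' commits the cell. `"AND"` (Bad_tot = 0.6e5, BclxL_tot = 1e5): both
#' inputs are required. `"AND_STAR"` (Bad_tot = 2e5, BclxL_tot = 2.4e5):
#' the AND phenotype reached from OR by raising pro-survival Bcl-xL
#' instead of lowering Bad. All presets use Scaffold_tot = 2e5.
#'
#' @param name One of `"OR"`, `"AND"`, `"AND_STAR"`.
#' @return A `pool_config` object.
#' @export
pool_preset <- function(name = c("OR", "AND", "AND_STAR")) {
  name <- match.arg(name)
  switch(name,
    OR       = pool_config(Bad_tot = 2e5,   BclxL_tot = 1e5),
    AND      = pool_config(Bad_tot = 0.6e5, BclxL_tot = 1e5),
    AND_STAR = pool_config(Bad_tot = 2e5,   BclxL_tot = 2.4e5)
  )
}

#' @export
print.pool_config <- function(x, ...) {
  cat(sprintf(
    "Conserved pools (mlcl): Bad_tot = %g, BclxL_tot = %g, Scaffold_tot = %g\n",
    x$Bad_tot, x$BclxL_tot, x$Scaffold_tot))
  invisible(x)
}

#' Exogenous input point
#'
#' The module is driven by two constant (or phase-wise constant) inputs:
#' `p53_killer`, the apoptosis-competent phospho-form of p53, and
#' `Akt_u`, unphosphorylated Akt (the pro-apoptotic proxy for growth
#' factor withdrawal). The total Akt pool is constant, so
#' `Akt_p = Akt_tot - Akt_u` is derived.
#'
#' @param p53_killer p53_killer level, molecules (>= 0).
#' @param Akt_u Unphosphorylated Akt, molecules in `[0, Akt_tot]`.
#' @param params Parameter set providing `Akt_tot`.
#' @return An object of class `input_point` with fields `p53_killer`,
#'   `Akt_u` and derived `Akt_p`.
#' @export
input_point <- function(p53_killer, Akt_u, params = default_parameters()) {
  params <- as_bcl2_params(params)
  if (!is.finite(p53_killer) || p53_killer < 0) {
    stop("p53_killer must be nonnegative")
  }
  if (!is.finite(Akt_u) || Akt_u < 0 || Akt_u > params$Akt_tot) {
    stop("Akt_u must lie in [0, Akt_tot]")
  }
  structure(list(p53_killer = p53_killer, Akt_u = Akt_u,
                 Akt_p = params$Akt_tot - Akt_u),
            class = "input_point")
}

#' Corner input for a Boolean logic pair
#'
#' Maps a logic pair to input levels: logic 0 is 0 molecules; logic 1 is
#' `p53killer_max` for the p53 input and `Akt_tot` for the Akt_u input.
#'
#' @param corner Length-2 vector in \{0, 1\}: `(p53 logic, Akt_u logic)`.
#'   Fractional values (e.g. `c(0.5, 0.5)`) scale the maxima.
#' @param params Parameter set providing the capacities.
#' @return An `input_point`.
#' @export
corner_input <- function(corner, params = default_parameters()) {
  params <- as_bcl2_params(params)
  if (length(corner) != 2 || any(corner < 0) || any(corner > 1)) {
    stop("`corner` must be two values in [0, 1]")
  }
  input_point(corner[1] * params$p53killer_max, corner[2] * params$Akt_tot,
              params)
}

as_input_point <- function(input, params) {
  if (inherits(input, "input_point")) return(input)
  if (is.numeric(input) && length(input) == 2) {
    return(input_point(input[1], input[2], params))
  }
  stop("`input` must be an input_point or a numeric pair (p53_killer, Akt_u)")
}

#' @export
print.input_point <- function(x, ...) {
  cat(sprintf("Input: p53_killer = %g, Akt_u = %g (Akt_p = %g) mlcl\n",
              x$p53_killer, x$Akt_u, x$Akt_p))
  invisible(x)
}
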