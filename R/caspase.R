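# The caspase switch: steady states of the pro-caspase/caspase pair at
# clamped free Bax, the saddle-node (fold) bifurcation, and the
# commitment threshold.
#
# At steady state the pair satisfies Procasp + Casp = S with S = s3/d3,
# so the problem reduces to one cubic in Casp:
#   g(C) = (a1*Bax + a2*C^2) * (S - C) - d3*C = 0,  C in [0, S].
# A steady state is stable iff g'(C) < 0 (the reduction to the invariant
# total is exact at steady state; the full 2x2 Jacobian gives the same
# classification and is used as a test oracle).

caspase_total <- function(params) params$s3 / params$d3

caspase_residual <- function(casp, bax, params) {
  S <- caspase_total(params)
  (params$a1 * bax + params$a2 * casp^2) * (S - casp) - params$d3 * casp
}

#' Steady states of the caspase subsystem at clamped free Bax
#'
#' Solves the steady-state cubic of the pro-caspase/caspase pair with
#' free Bax held constant. Below the fold there are three steady states
#' (stable low, unstable threshold, stable high); above it a single
#' stable high-caspase state. Roots closer than `1e-6 * S` are merged
#' (near-double roots at the fold).
#'
#' @param bax_clamped Clamped free-Bax level, molecules (>= 0).
#' @param params Kinetic parameters.
#' @return A data.frame with columns `Casp`, `Procasp` (`= S - Casp`) and
#'   `stability` (`"STABLE"`/`"UNSTABLE"`), rows sorted by increasing
#'   `Casp`.
#' @export
caspase_steady_states <- function(bax_clamped, params = default_parameters()) {
  params <- as_bcl2_params(params)
  if (!is.finite(bax_clamped) || bax_clamped < 0) {
    stop("bax_clamped must be nonnegative")
  }
  S <- caspase_total(params)
  # cubic coefficients, ascending powers of Casp
  co <- c(params$a1 * bax_clamped * S,
          -(params$a1 * bax_clamped + params$d3),
          params$a2 * S,
          -params$a2)
  z <- polyroot(co)
  re <- Re(z)[abs(Im(z)) < 1e-8 * max(S, abs(Re(z)))]
  re <- re[re > -1e-9 * S & re < S * (1 + 1e-9)]
  re <- pmin(pmax(re, 0), S)
  re <- sort(re)
  # merge near-double roots
  if (length(re) > 1) {
    keep <- c(TRUE, diff(re) > 1e-6 * S)
    re <- re[keep]
  }
  # polish with Newton steps on the residual
  for (i in seq_along(re)) {
    for (k in 1:3) {
      g <- caspase_residual(re[i], bax_clamped, params)
      gp <- caspase_residual_deriv(re[i], bax_clamped, params)
      if (gp != 0) re[i] <- min(max(re[i] - g / gp, 0), S)
    }
  }
  re <- sort(unique(re))
  gp <- caspase_residual_deriv(re, bax_clamped, params)
  data.frame(Casp = re, Procasp = S - re,
             stability = ifelse(gp < 0, "STABLE", "UNSTABLE"),
             stringsAsFactors = FALSE)
}

caspase_residual_deriv <- function(casp, bax, params) {
  S <- caspase_total(params)
  2 * params$a2 * casp * (S - casp) -
    (params$a1 * bax + params$a2 * casp^2) - params$d3
}

#' Locate the saddle-node bifurcation of the caspase switch
#'
#' Finds the clamped-Bax level at which the low and unstable steady
#' states coalesce. At the fold, `g(C) = 0` and `g'(C) = 0`
#' simultaneously; eliminating Bax gives the double-root condition
#' `C * (S - C)^2 = d3 * S / (2 * a2)`, solved on `(0, S/3)`, after
#' which Bax follows from the residual equation. The result is verified
#' by a bracketing root-count change just below and above the fold.
#'
#' @param params Kinetic parameters.
#' @return Object of class `bax_bifurcation` with fields `Bax_bif` and
#'   `Casp_bif` (molecules).
#' @export
find_bifurcation <- function(params = default_parameters()) {
  params <- as_bcl2_params(params)
  S <- caspase_total(params)
  K <- params$d3 * S / (2 * params$a2)
  h <- function(C) C * (S - C)^2 - K
  # on (0, S/3] the map C*(S-C)^2 is increasing with maximum 4S^3/27
  if (h(S / 3) <= 0) {
    stop("no saddle-node with positive Bax: caspase subsystem is monostable ",
         "for these parameters (autoactivation too weak)")
  }
  C <- stats::uniroot(h, c(1e-12 * S, S / 3), tol = 1e-12 * S)$root
  bax <- (params$d3 * C / (S - C) - params$a2 * C^2) / params$a1
  if (!is.finite(bax) || bax <= 0) {
    stop("no saddle-node with positive Bax found for these parameters")
  }
  n_lo <- nrow(caspase_steady_states(bax * 0.99, params))
  n_hi <- nrow(caspase_steady_states(bax * 1.01, params))
  if (!(n_lo == 3 && n_hi == 1)) {
    stop(sprintf(
      "fold verification failed: %d roots at 0.99*Bax_bif, %d at 1.01*Bax_bif",
      n_lo, n_hi))
  }
  structure(list(Bax_bif = bax, Casp_bif = C, params = params),
            class = "bax_bifurcation")
}

#' @export
print.bax_bifurcation <- function(x, ...) {
  cat(sprintf(
    "Caspase saddle-node bifurcation: Bax_bif = %.4g, Casp_bif = %.4g mlcl\n",
    x$Bax_bif, x$Casp_bif))
  invisible(x)
}

#' Caspase commitment threshold
#'
#' The unstable steady state of the caspase pair at clamped Bax = 0.
#' Once the caspase level passes this threshold, autoactivation carries
#' the system to the high (apoptotic) branch even with all free Bax
#' withdrawn; it therefore separates reversible caspase excursions from
#' irreversible commitment.
#'
#' @param params Kinetic parameters.
#' @return Threshold caspase level, molecules.
#' @export
commitment_threshold <- function(params = default_parameters()) {
  ss <- caspase_steady_states(0, params)
  if (nrow(ss) < 3) {
    stop("caspase subsystem is monostable at Bax = 0; ",
         "no commitment threshold exists")
  }
  unstable <- ss$Casp[ss$stability == "UNSTABLE"]
  if (length(unstable) != 1) stop("unexpected stability structure at Bax = 0")
  unstable
}

#' Bifurcation diagram of Casp versus clamped Bax
#'
#' @param params Kinetic parameters.
#' @param bax_grid Nonnegative clamped-Bax values.
#' @return Data.frame with columns `bax`, `casp_root`, `procasp_root`,
#'   `stability`; one row per steady state per grid point. Carries class
#'   `bifurcation_diagram` for plotting.
#' @export
bifurcation_diagram <- function(params = default_parameters(),
                                bax_grid = seq(0, 10000, length.out = 201)) {
  params <- as_bcl2_params(params)
  if (any(bax_grid < 0)) stop("bax_grid must be nonnegative")
  rows <- lapply(bax_grid, function(b) {
    ss <- caspase_steady_states(b, params)
    data.frame(bax = b, casp_root = ss$Casp, procasp_root = ss$Procasp,
               stability = ss$stability, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("bifurcation_diagram", "data.frame")
  out
}

#' @export
plot.bifurcation_diagram <- function(x, ...) {
  st <- x$stability == "STABLE"
  graphics::plot(x$bax[st], pmax(x$casp_root[st], 1), log = "y",
                 pch = 16, cex = 0.4, xlab = "clamped free Bax (mlcl)",
                 ylab = "Casp steady states (mlcl)", ...)
  graphics::points(x$bax[!st], pmax(x$casp_root[!st], 1), pch = 1, cex = 0.4,
                   col = "grey50")
  invisible(x)
}
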