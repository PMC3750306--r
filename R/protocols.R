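# Transient stimulation: piecewise-constant protocols, commitment
# decisions, and minimal committing stimulus durations.

#' Piecewise-constant stimulation protocol
#'
#' Three phases: a pre-phase at rest (inputs (0,0)), a stimulation phase
#' at `stim_input`, and a post-phase back at (0,0). The pre-phase
#' defaults to `"equilibrated"`: the simulation starts directly at the
#' computed resting steady state instead of burning in for an arbitrary
#' finite time.
#'
#' @param stim_input [input_point()] or numeric pair applied during the
#'   stimulation phase.
#' @param stim_hours Stimulation duration, hours (>= 0).
#' @param post_hours Relaxation duration after withdrawal, hours.
#' @param pre `"equilibrated"` or a nonnegative burn-in duration in
#'   hours.
#' @return Object of class `stimulation_protocol`.
#' @export
stimulation_protocol <- function(stim_input, stim_hours, post_hours = 500,
                                 pre = "equilibrated") {
  stopifnot(is.numeric(stim_hours), stim_hours >= 0,
            is.numeric(post_hours), post_hours >= 0)
  if (!(identical(pre, "equilibrated") ||
        (is.numeric(pre) && pre >= 0))) {
    stop('`pre` must be "equilibrated" or a nonnegative duration in hours')
  }
  structure(list(stim_input = stim_input, stim_hours = stim_hours,
                 post_hours = post_hours, pre = pre),
            class = "stimulation_protocol")
}

#' @export
print.stimulation_protocol <- function(x, ...) {
  pre <- if (identical(x$pre, "equilibrated")) "equilibrated start"
  else sprintf("%g h burn-in", x$pre)
  cat(sprintf("Stimulation protocol: %s; stimulus %g h; post-phase %g h\n",
              pre, x$stim_hours, x$post_hours))
  invisible(x)
}

# classify the terminal caspase level against the Bax = 0 branches:
# "high" / "low" / "near_threshold" / "undecided"
caspase_basin <- function(casp_terminal, params) {
  S <- caspase_total(params)
  ss <- caspase_steady_states(0, params)
  if (nrow(ss) < 3) stop("caspase subsystem is monostable at Bax = 0")
  thr <- ss$Casp[ss$stability == "UNSTABLE"][1]
  stable <- ss$Casp[ss$stability == "STABLE"]
  lo <- min(stable); hi <- max(stable)
  if (abs(casp_terminal - thr) < 0.01 * thr) return("near_threshold")
  # the low branch sits at/near zero, so its proximity band is 1% of the
  # caspase capacity S rather than 1% of the (zero) branch value
  if (casp_terminal > thr && abs(casp_terminal - hi) < 0.01 * hi) {
    return("high")
  }
  if (casp_terminal < thr && abs(casp_terminal - lo) < 0.01 * S) return("low")
  "undecided"
}

#' Simulate the full module under a stimulation protocol
#'
#' Integrates the 11-ODE system through the protocol phases with a
#' stiff-capable solver (lsoda, rtol 1e-8, atol 1e-3 molecules by
#' default). Input discontinuities at phase boundaries are handled by
#' restarting the integrator, never by interpolating across them. The
#' initial state is the resting Bcl-2 steady state with the caspase pair
#' on its low branch.
#'
#' If `extend = TRUE` (default) the post-phase is extended in 500-hour
#' chunks (up to `max_post_hours`) until the terminal caspase level sits
#' unambiguously in one basin of the Bax = 0 switch, after which the
#' `committed` flag is set.
#'
#' @param protocol A [stimulation_protocol()].
#' @param pools Pool configuration or preset name.
#' @param params Kinetic parameters.
#' @param solver Solver settings from `solver_settings()`.
#' @param save_dt_h Output sampling interval, hours.
#' @param extend Extend the post-phase until the basin is unambiguous?
#' @param max_post_hours Cap on the extended post-phase.
#' @return Object of class `bclgate_trajectory`: list with `time_h`,
#'   `states` (matrix, one row per stored time, 11 species columns),
#'   `protocol`, `committed`, `pools`, `params`.
#' @export
simulate_protocol <- function(protocol, pools, params = default_parameters(),
                              solver = solver_settings(), save_dt_h = 0.25,
                              extend = TRUE, max_post_hours = 4000) {
  params <- as_bcl2_params(params)
  if (is.character(pools)) pools <- pool_preset(pools)
  stopifnot(inherits(protocol, "stimulation_protocol"))
  rest_input <- input_point(0, 0, params)
  stim_input <- as_input_point(protocol$stim_input, params)

  y0 <- unclass(bcl2_steady_state(rest_input, pools, params,
                                  solver = solver))
  attributes(y0) <- list(names = names(y0))

  phase_times <- function(dur_h) {
    tt <- seq(0, dur_h, by = save_dt_h)
    if (tt[length(tt)] < dur_h) tt <- c(tt, dur_h)
    tt
  }
  run_phase <- function(y, dur_h, input) {
    if (dur_h <= 0) return(NULL)
    out <- integrate_full(y, phase_times(dur_h) * 3600, input, params, solver)
    if (attr(out, "istate")[1] < 0) {
      stop(sprintf(
        "integrator failed (istate %d) in phase of %g h; see deSolve diagnostics",
        attr(out, "istate")[1], dur_h))
    }
    out
  }

  time_h <- 0
  states <- matrix(y0, nrow = 1, dimnames = list(NULL, species_names()))
  t_offset <- 0
  append_phase <- function(out) {
    if (is.null(out)) return(invisible(NULL))
    tt <- out[-1, 1] / 3600 + t_offset
    time_h <<- c(time_h, tt)
    states <<- rbind(states, out[-1, 1 + seq_len(11), drop = FALSE])
    t_offset <<- time_h[length(time_h)]
    invisible(NULL)
  }

  if (is.numeric(protocol$pre) && protocol$pre > 0) {
    append_phase(run_phase(states[nrow(states), ], protocol$pre, rest_input))
  }
  append_phase(run_phase(states[nrow(states), ], protocol$stim_hours,
                         stim_input))
  append_phase(run_phase(states[nrow(states), ], protocol$post_hours,
                         rest_input))

  if (extend) {
    post_done <- protocol$post_hours
    repeat {
      basin <- caspase_basin(states[nrow(states), "Casp"], params)
      if (basin %in% c("high", "low")) break
      if (post_done >= max_post_hours) {
        stop(sprintf(
          "basin assignment still ambiguous after %g h of post-phase (terminal Casp = %.4g)",
          post_done, states[nrow(states), "Casp"]))
      }
      append_phase(run_phase(states[nrow(states), ], 500, rest_input))
      post_done <- post_done + 500
    }
  }

  traj <- structure(list(time_h = time_h, states = states,
                         protocol = protocol, committed = NA,
                         pools = pools, params = params),
                    class = "bclgate_trajectory")
  traj$committed <- tryCatch(committed_to_apoptosis(traj, params),
                             error = function(e) NA)
  traj
}

#' Has a trajectory committed to apoptosis?
#'
#' A trajectory is committed iff its terminal caspase level lies above
#' the commitment threshold (the Bax = 0 unstable steady state);
#' equivalently, the nearest Bax = 0 stable branch is the high one.
#' Transient caspase excursions above `Casp_bif` that relax back do not
#' commit. The terminal point must sit close to a stable branch (the
#' post-phase must be long enough); a terminal level within 1% of the
#' threshold itself is reported as indeterminate, not guessed.
#'
#' @param trajectory A [simulate_protocol()] result.
#' @param params Kinetic parameters; defaults to those of the
#'   trajectory.
#' @return `TRUE` or `FALSE`.
#' @export
committed_to_apoptosis <- function(trajectory, params = NULL) {
  stopifnot(inherits(trajectory, "bclgate_trajectory"))
  if (is.null(params)) params <- trajectory$params
  casp_t <- trajectory$states[nrow(trajectory$states), "Casp"]
  basin <- caspase_basin(casp_t, params)
  switch(basin,
    high = TRUE,
    low = FALSE,
    near_threshold = stop(sprintf(
      "indeterminate: terminal Casp (%.5g) lies within 1%% of the commitment threshold",
      casp_t)),
    stop(sprintf(
      "terminal Casp (%.5g) is not within 1%% of a Bax = 0 stable branch; extend the post-phase",
      casp_t))
  )
}

#' @export
print.bclgate_trajectory <- function(x, ...) {
  n <- nrow(x$states)
  cat(sprintf(
    "Trajectory: %d stored points over %.4g h (stimulus %g h); committed to apoptosis: %s\n",
    n, x$time_h[n], x$protocol$stim_hours,
    ifelse(is.na(x$committed), "undecided", x$committed)))
  cat(sprintf("Terminal free Bax = %.4g, Casp = %.4g mlcl\n",
              x$states[n, "Bax"], x$states[n, "Casp"]))
  invisible(x)
}

#' @export
as.data.frame.bclgate_trajectory <- function(x, ...) {
  data.frame(time_h = x$time_h, x$states, check.names = FALSE)
}

#' @export
plot.bclgate_trajectory <- function(x, species = c("Bax", "Casp"), ...) {
  species <- match.arg(species, species_names(), several.ok = TRUE)
  graphics::matplot(x$time_h, x$states[, species, drop = FALSE], type = "l",
                    lty = 1, xlab = "time (h)", ylab = "molecules/cell", ...)
  graphics::legend("topright", legend = species, lty = 1,
                   col = seq_along(species), bty = "n")
  invisible(x)
}

#' Minimal committing stimulus duration
#'
#' Bisects the stimulation-phase duration for the smallest value that
#' commits the system to apoptosis: stimulate for `D` hours from the
#' equilibrated resting state, withdraw inputs for `post_hours`, and ask
#' whether the terminal caspase level ends in the high basin.
#' Commitment is monotone in duration, so bisection applies.
#'
#' @param stim_input [input_point()] or numeric pair applied during
#'   stimulation.
#' @param pools Pool configuration or preset name.
#' @param params Kinetic parameters.
#' @param tolerance Bisection tolerance on the duration, hours.
#' @param bracket Initial duration bracket, hours; the upper end must
#'   commit and 0 must not.
#' @param post_hours Post-phase per probe, hours.
#' @param solver Solver settings.
#' @return Minimal committing duration (midpoint of the final bracket),
#'   hours, with attribute `bracket` (the final non-committing /
#'   committing pair).
#' @export
minimal_stimulation_duration <- function(stim_input, pools,
                                         params = default_parameters(),
                                         tolerance = 0.05,
                                         bracket = c(0, 48),
                                         post_hours = 500,
                                         solver = solver_settings()) {
  params <- as_bcl2_params(params)
  if (is.character(pools)) pools <- pool_preset(pools)
  stim_input <- as_input_point(stim_input, params)
  stopifnot(tolerance > 0, length(bracket) == 2, bracket[1] < bracket[2])

  probe <- function(d) {
    traj <- simulate_protocol(
      stimulation_protocol(stim_input, d, post_hours), pools, params,
      solver = solver, save_dt_h = max(1, d))
    committed_to_apoptosis(traj, params)
  }

  lo <- bracket[1]
  hi <- bracket[2]
  if (lo > 0 && probe(lo)) {
    stop(sprintf("lower bracket end (%g h) already commits", lo))
  }
  if (lo == 0) {
    # zero-duration stimulus leaves the system at rest on the low branch
    rest <- bcl2_steady_state(input_point(0, 0, params), pools, params)
    if (rest[["Casp"]] > commitment_threshold(params)) {
      stop("resting state is already committed; no minimal duration exists")
    }
  }
  if (!probe(hi)) {
    stop(sprintf(
      "upper bracket end (%g h) does not commit; this input/pool combination may never trigger apoptosis",
      hi))
  }
  while (hi - lo > tolerance) {
    mid <- (lo + hi) / 2
    if (probe(mid)) hi <- mid else lo <- mid
  }
  structure((lo + hi) / 2, bracket = c(lo, hi))
}
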