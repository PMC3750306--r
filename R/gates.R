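# Gate classification from corner truth tables, input-plane scans,
# apoptotic isolines and gate boundaries along pool-level axes.

.gate_corners <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
.corner_labels <- c("{0,0}", "{1,0}", "{0,1}", "{1,1}")

# pure map from a 4-corner truth table (logical apoptosis flags in the
# order {0,0},{1,0},{0,1},{1,1}) to the gate label
gate_type_from_truth_table <- function(apoptotic) {
  stopifnot(length(apoptotic) == 4, is.logical(apoptotic))
  key <- paste(as.integer(apoptotic), collapse = "")
  switch(key,
    "0000" = "ALWAYS_SURVIVE",
    "0001" = "AND",
    "0011" = "AKT_INTERMEDIATE",  # Akt_u alone suffices, p53 alone does not
    "0101" = "P53_ONLY",
    "0111" = "OR",
    "1111" = "CONSTITUTIVE",
    "0010" = "AKT_ONLY",
    "0100" = "P53_ONLY",
    if (apoptotic[1]) "CONSTITUTIVE" else "OR"
  )
}

#' Classify the Boolean gate type of a pool configuration
#'
#' Evaluates the survive-vs-apoptosis fate at the four corner inputs
#' \{0,0\}, \{1,0\}, \{0,1\}, \{1,1\} (logic 1 being `p53killer_max` or
#' `Akt_tot`) and maps the truth table to a gate label. `"OR"`: either
#' single maximal signal commits; `"AND"`: only both together commit.
#' The `"ode"` method relaxes the Bcl-2 subsystem at each corner and
#' compares free Bax to `Bax_bif`; the `"algebraic"` method uses the
#' macro-parameter inequalities of [algebraic_corner_prediction()].
#'
#' @param pools Pool configuration or preset name.
#' @param params Kinetic parameters.
#' @param method `"ode"` (default) or `"algebraic"`.
#' @param bifurcation Optional precomputed [find_bifurcation()] result.
#' @return Object of class `gate_classification`: list with
#'   `truth_table` (data.frame of corners and fates), `gate_type`,
#'   `method` and `pools`.
#' @export
classify_gate <- function(pools, params = default_parameters(),
                          method = c("ode", "algebraic"),
                          bifurcation = NULL) {
  method <- match.arg(method)
  params <- as_bcl2_params(params)
  if (is.character(pools)) pools <- pool_preset(pools)
  if (is.null(bifurcation)) bifurcation <- find_bifurcation(params)
  if (method == "ode") {
    fates <- vapply(.gate_corners, function(cc) {
      as.character(classify_fate(corner_input(cc, params), pools, params,
                                 bifurcation = bifurcation))
    }, character(1))
  } else {
    macro <- macro_parameters(params)
    macro$m7 <- bifurcation$Bax_bif
    fates <- vapply(.gate_corners, function(cc) {
      as.character(algebraic_corner_prediction(cc, pools, macro))
    }, character(1))
  }
  tt <- data.frame(
    corner = .corner_labels,
    p53_logic = vapply(.gate_corners, `[`, numeric(1), 1),
    akt_u_logic = vapply(.gate_corners, `[`, numeric(1), 2),
    fate = fates, stringsAsFactors = FALSE)
  structure(list(truth_table = tt,
                 gate_type = gate_type_from_truth_table(fates == "APOPTOSIS"),
                 method = method, pools = pools, params = params),
            class = "gate_classification")
}

#' @export
print.gate_classification <- function(x, ...) {
  cat(sprintf("Apoptotic logic gate: %s  (%s path)\n", x$gate_type, x$method))
  cat(sprintf("Pools: Bad_tot = %g, BclxL_tot = %g\n",
              x$pools$Bad_tot, x$pools$BclxL_tot))
  print(x$truth_table, row.names = FALSE)
  invisible(x)
}

#' Steady-state free Bax over the input plane
#'
#' Relaxes the Bcl-2 subsystem on a regular grid over
#' `(p53_killer, Akt_u)` in `[0, p53killer_max] x [0, Akt_tot]` and
#' records steady-state free Bax. Free Bax is monotone nondecreasing in
#' both inputs.
#'
#' @param pools Pool configuration or preset name.
#' @param params Kinetic parameters.
#' @param grid Points per axis (>= 2); default 81.
#' @return Object of class `input_plane_scan`: list with axis vectors
#'   `p53_killer`, `akt_u`, matrix `bax` (rows index p53, columns Akt_u),
#'   `pools` and `bax_bif`.
#' @export
input_plane_scan <- function(pools, params = default_parameters(),
                             grid = 81) {
  params <- as_bcl2_params(params)
  if (is.character(pools)) pools <- pool_preset(pools)
  stopifnot(grid >= 2)
  bif <- find_bifurcation(params)
  p53 <- seq(0, params$p53killer_max, length.out = grid)
  akt <- seq(0, params$Akt_tot, length.out = grid)
  bax <- matrix(NA_real_, grid, grid)
  for (i in seq_len(grid)) {
    for (j in seq_len(grid)) {
      ss <- bcl2_steady_state(input_point(p53[i], akt[j], params), pools,
                              params)
      bax[i, j] <- ss[["Bax"]]
    }
  }
  structure(list(p53_killer = p53, akt_u = akt, bax = bax, pools = pools,
                 bax_bif = bif$Bax_bif),
            class = "input_plane_scan")
}

#' @export
print.input_plane_scan <- function(x, ...) {
  n_apop <- sum(x$bax >= x$bax_bif)
  cat(sprintf(
    "Input-plane scan (%d x %d): free Bax in [%.3g, %.3g] mlcl; %d/%d grid points apoptotic (Bax >= %.4g)\n",
    length(x$p53_killer), length(x$akt_u), min(x$bax), max(x$bax),
    n_apop, length(x$bax), x$bax_bif))
  invisible(x)
}

#' @export
as.data.frame.input_plane_scan <- function(x, ...) {
  data.frame(p53_killer = rep(x$p53_killer, times = length(x$akt_u)),
             akt_u = rep(x$akt_u, each = length(x$p53_killer)),
             bax_ss = as.vector(x$bax))
}

#' @export
plot.input_plane_scan <- function(x, ...) {
  graphics::image(x$p53_killer, x$akt_u, x$bax,
                  xlab = "p53_killer (mlcl)", ylab = "Akt_u (mlcl)", ...)
  graphics::contour(x$p53_killer, x$akt_u, x$bax, levels = x$bax_bif,
                    add = TRUE, lwd = 2, drawlabels = FALSE)
  invisible(x)
}

#' Apoptotic isoline of an input-plane scan
#'
#' Level set `Bax = level` of the scanned free-Bax surface, obtained by
#' linear interpolation along grid edges. In an OR configuration the
#' isoline meets both axes (either signal alone can commit); in an AND
#' configuration it detaches from both.
#'
#' @param scan An [input_plane_scan()] result.
#' @param level Free-Bax level of the isoline; defaults to the scan's
#'   `bax_bif`.
#' @return Data.frame of `(p53_killer, akt_u)` points ordered along the
#'   curve; zero rows when the whole plane lies on one side.
#' @export
apoptotic_isoline <- function(scan, level = scan$bax_bif) {
  p53 <- scan$p53_killer
  akt <- scan$akt_u
  z <- scan$bax - level
  pts <- list()
  # crossings along p53 (rows vary) at fixed Akt_u
  for (j in seq_along(akt)) {
    s <- z[, j]
    k <- which(s[-length(s)] * s[-1] < 0 | s[-length(s)] == 0)
    for (i in k) {
      w <- s[i] / (s[i] - s[i + 1])
      pts[[length(pts) + 1]] <- c(p53[i] + w * (p53[i + 1] - p53[i]), akt[j])
    }
  }
  # crossings along Akt_u at fixed p53
  for (i in seq_along(p53)) {
    s <- z[i, ]
    k <- which(s[-length(s)] * s[-1] < 0 | s[-length(s)] == 0)
    for (j in k) {
      w <- s[j] / (s[j] - s[j + 1])
      pts[[length(pts) + 1]] <- c(p53[i], akt[j] + w * (akt[j + 1] - akt[j]))
    }
  }
  if (length(pts) == 0) {
    return(data.frame(p53_killer = numeric(0), akt_u = numeric(0)))
  }
  m <- do.call(rbind, pts)
  m <- m[order(m[, 1], -m[, 2]), , drop = FALSE]
  data.frame(p53_killer = m[, 1], akt_u = m[, 2])
}

#' Gate-type boundaries along a pool axis
#'
#' Scans one conserved total (`Bad_tot` or `BclxL_tot`) over a range,
#' classifying the corner truth table at each grid value, and reports
#' where each corner flips and where the gate label changes. With
#' `BclxL_tot = 1e5` and increasing `Bad_tot`, the Akt-only corner
#' \{0,1\} flips first (end of the pure AND region) and the p53-only
#' corner \{1,0\} flips second (onset of OR).
#'
#' @param params Kinetic parameters.
#' @param pools Base pool configuration or preset name; the varied field
#'   is overwritten by the scan.
#' @param vary `"Bad_tot"` or `"BclxL_tot"`.
#' @param range Length-2 scan range (molecules).
#' @param step Scan step (> 0, molecules).
#' @param corners Subset of corner indices 1..4 (order
#'   \{0,0\},\{1,0\},\{0,1\},\{1,1\}) to evaluate; gate labels are only
#'   reported when all four are scanned.
#' @return Object of class `gate_boundary`: list with the scan `table`
#'   (varied value, corner fates, gate type), `corner_flips` (first
#'   varied value at which each scanned corner's fate differs from its
#'   fate at the range start) and, for a full scan, `boundaries` (first
#'   value classified OR; last value classified AND).
#' @export
gate_boundary <- function(params = default_parameters(),
                          pools = pool_preset("OR"),
                          vary = c("Bad_tot", "BclxL_tot"),
                          range = c(0, 2e5), step = 500,
                          corners = 1:4) {
  vary <- match.arg(vary)
  params <- as_bcl2_params(params)
  if (is.character(pools)) pools <- pool_preset(pools)
  stopifnot(step > 0, length(range) == 2, range[1] < range[2])
  stopifnot(all(corners %in% 1:4))
  bif <- find_bifurcation(params)
  values <- seq(range[1], range[2], by = step)
  inputs <- lapply(.gate_corners, corner_input, params = params)

  fates <- matrix(NA_character_, length(values), 4,
                  dimnames = list(NULL, .corner_labels))
  for (v in seq_along(values)) {
    pv <- pools
    pv[[vary]] <- values[v]
    for (ci in corners) {
      fates[v, ci] <- as.character(
        classify_fate(inputs[[ci]], pv, params, bifurcation = bif))
    }
  }

  flips <- rep(NA_real_, 4)
  names(flips) <- .corner_labels
  for (ci in corners) {
    changed <- which(fates[, ci] != fates[1, ci])
    if (length(changed) > 0) flips[ci] <- values[min(changed)]
  }

  tab <- data.frame(values, fates, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(tab)[1] <- vary
  boundaries <- NULL
  if (identical(sort(corners), 1:4)) {
    gate <- apply(fates == "APOPTOSIS", 1, gate_type_from_truth_table)
    tab$gate_type <- gate
    or_vals <- values[gate == "OR"]
    and_vals <- values[gate == "AND"]
    boundaries <- list(
      OR_onset = if (length(or_vals)) min(or_vals) else NA_real_,
      AND_last = if (length(and_vals)) max(and_vals) else NA_real_)
  }
  structure(list(table = tab, corner_flips = flips, boundaries = boundaries,
                 vary = vary, step = step),
            class = "gate_boundary")
}

#' @export
print.gate_boundary <- function(x, ...) {
  cat(sprintf("Gate boundary scan along %s (step %g mlcl)\n", x$vary, x$step))
  fl <- x$corner_flips[!is.na(x$corner_flips)]
  if (length(fl)) {
    cat("First corner flips at:\n")
    for (nm in names(fl)) cat(sprintf("  %s : %g\n", nm, fl[[nm]]))
  }
  if (!is.null(x$boundaries)) {
    cat(sprintf("First OR value: %g; last AND value: %g\n",
                x$boundaries$OR_onset, x$boundaries$AND_last))
  }
  invisible(x)
}
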