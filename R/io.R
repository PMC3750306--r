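# Configuration documents and result serialization.

.pool_keys <- c("Bad_tot", "BclxL_tot", "Scaffold_tot")
.config_keys <- c("preset", "input", "solver", "seed")

#' Load a run configuration from YAML or JSON
#'
#' A configuration document may override any kinetic parameter (by its
#' symbol, `s1` ... `a2`, `Akt_tot`, `p53killer_max`), choose a pool
#' `preset` (`OR`/`AND`/`AND_STAR`) and/or set the pool totals
#' explicitly, give an `input` (`p53_killer`, `Akt_u`), `solver`
#' settings (`rtol`, `atol`) and a fixture `seed`. Absent keys take the
#' defaults; unknown keys are rejected by name. An empty document
#' resolves to the default parameters with no pool configuration (pools
#' must be chosen explicitly before pool-dependent analyses run).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Object of class `run_config`: list with `params`
#'   (`bcl2_params`), `pools` (`pool_config` or `NULL`), `input`
#'   (`input_point` or `NULL`), `solver`, `seed` and `overridden` (names
#'   of parameters the document changed).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) stop("config document must be a mapping")
  as_run_config(coerce_numeric_strings(doc))
}

# YAML 1.1 reads scalars like "1e5" (no decimal point) as strings;
# convert anything that parses as a number
coerce_numeric_strings <- function(x) {
  if (is.list(x)) return(lapply(x, coerce_numeric_strings))
  if (is.character(x) && length(x) == 1) {
    v <- suppressWarnings(as.numeric(x))
    if (!is.na(v)) return(v)
  }
  x
}

# resolve a raw config list against the defaults
as_run_config <- function(doc) {
  allowed <- c(.param_names, .pool_keys, .config_keys)
  unknown <- setdiff(names(doc), allowed)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  overridden <- intersect(names(doc), .param_names)
  params <- as_bcl2_params(doc[overridden])

  pools <- NULL
  if (!is.null(doc$preset)) pools <- pool_preset(doc$preset)
  explicit <- intersect(names(doc), .pool_keys)
  if (length(explicit) > 0) {
    base <- if (is.null(pools)) list(Bad_tot = NA, BclxL_tot = NA,
                                     Scaffold_tot = 2e5) else unclass(pools)
    base[explicit] <- doc[explicit]
    if (any(is.na(unlist(base[c("Bad_tot", "BclxL_tot")])))) {
      stop("incomplete pool configuration: give a preset or both ",
           "Bad_tot and BclxL_tot")
    }
    pools <- pool_config(base$Bad_tot, base$BclxL_tot, base$Scaffold_tot)
  }

  input <- NULL
  if (!is.null(doc$input)) {
    inp <- doc$input
    bad <- setdiff(names(inp), c("p53_killer", "Akt_u"))
    if (length(bad) > 0) stop("unknown input key(s): ",
                              paste(bad, collapse = ", "))
    input <- input_point(inp$p53_killer %||% 0, inp$Akt_u %||% 0, params)
  }

  solver <- solver_settings()
  if (!is.null(doc$solver)) {
    bad <- setdiff(names(doc$solver), c("rtol", "atol"))
    if (length(bad) > 0) stop("unknown solver key(s): ",
                              paste(bad, collapse = ", "))
    solver <- solver_settings(doc$solver$rtol %||% solver$rtol,
                              doc$solver$atol %||% solver$atol)
  }

  structure(list(params = params, pools = pools, input = input,
                 solver = solver, seed = doc$seed,
                 overridden = overridden),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  if (length(x$overridden)) {
    cat("  overridden parameters:", paste(x$overridden, collapse = ", "), "\n")
  } else cat("  parameters: all defaults\n")
  if (is.null(x$pools)) cat("  pools: none chosen\n")
  else cat(sprintf("  pools: Bad_tot = %g, BclxL_tot = %g\n",
                   x$pools$Bad_tot, x$pools$BclxL_tot))
  invisible(x)
}

# pool configuration of a run_config, with an explicit error when absent
config_pools <- function(config) {
  if (is.null(config$pools)) {
    stop("no pool configuration: the config must name a preset ",
         "(OR/AND/AND_STAR) or set Bad_tot and BclxL_tot")
  }
  config$pools
}

# fully-resolved config as a plain serializable list
config_echo <- function(params = NULL, pools = NULL, input = NULL,
                        solver = NULL) {
  out <- list()
  if (!is.null(params)) out <- c(out, as.list(unlist(unclass(params))))
  if (!is.null(pools)) out <- c(out, unclass(pools))
  if (!is.null(input)) {
    out$input <- list(p53_killer = input$p53_killer, Akt_u = input$Akt_u)
  }
  if (!is.null(solver)) out$solver <- solver
  out
}

#' Write an analysis result to CSV or JSON
#'
#' Trajectories and input-plane scans serialize to CSV (`time_h` plus
#' the 11 species columns; long-format `p53_killer`, `akt_u`, `bax_ss`).
#' Classifications, bifurcation results, boundaries and durations
#' serialize to JSON with the fully-resolved configuration echoed under
#' `"config"`, so that any JSON result can be recomputed from its own
#' echo. Numbers are written in full double precision.
#'
#' @param result A package result object (`bclgate_trajectory`,
#'   `input_plane_scan`, `gate_classification`, `bax_bifurcation`,
#'   `gate_boundary`, `bifurcation_diagram`, or a named list/number).
#' @param path Output path.
#' @param format `"auto"` (by type), `"csv"` or `"json"`.
#' @param config Optional config echo (see `config_echo()`) embedded in
#'   JSON output; defaults to what the object itself carries.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, format = c("auto", "csv", "json"),
                          config = NULL) {
  format <- match.arg(format)
  write_json <- function(x) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }

  if (inherits(result, "bclgate_trajectory")) {
    if (format == "json") {
      write_json(list(result = as.list(as.data.frame(result)),
                      committed = result$committed,
                      config = config %||% config_echo(result$params,
                                                       result$pools)))
    } else {
      utils::write.csv(as.data.frame(result), path, row.names = FALSE)
    }
  } else if (inherits(result, "input_plane_scan")) {
    if (format == "json") {
      write_json(list(result = as.list(as.data.frame(result)),
                      config = config))
    } else {
      utils::write.csv(as.data.frame(result), path, row.names = FALSE)
    }
  } else if (inherits(result, "bifurcation_diagram")) {
    if (format == "json") write_json(list(result = as.list(result)))
    else utils::write.csv(as.data.frame(unclass(result)), path,
                          row.names = FALSE)
  } else if (inherits(result, "gate_classification")) {
    write_json(list(
      gate_type = result$gate_type,
      method = result$method,
      truth_table = result$truth_table,
      config = config %||% config_echo(result$params, result$pools)))
  } else if (inherits(result, "bax_bifurcation")) {
    write_json(list(bax_bif = result$Bax_bif, casp_bif = result$Casp_bif,
                    config = config %||% config_echo(result$params)))
  } else if (inherits(result, "gate_boundary")) {
    write_json(list(
      vary = result$vary, step = result$step,
      corner_flips = as.list(result$corner_flips),
      boundaries = result$boundaries,
      config = config))
  } else {
    write_json(list(result = result, config = config))
  }
  invisible(path)
}
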