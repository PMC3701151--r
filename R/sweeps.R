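#' Specification of a one-dimensional parameter sweep
#'
#' @param parameter parameter path or linked alias; see [param_paths()].
#' @param grid ordered numeric grid of values, nonempty and sorted.
#' @param base a [circuit_params()] object or preset name.
#' @param noise a [noise_config()].
#' @param solver a [solver_config()].
#' @param spectral a [spectral_config()].
#' @param n_trials ensemble size per grid point.
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(parameter, grid, base = default_params(),
                       noise = noise_config(), solver = solver_config(),
                       spectral = spectral_config(), n_trials = 20) {
  if (is.character(base)) base <- preset(base)
  stopifnot(is.character(parameter), length(parameter) == 1L,
            is.numeric(grid), length(grid) >= 1L, !is.unsorted(grid),
            inherits(base, "circuit_params"),
            inherits(noise, "noise_config"),
            inherits(solver, "solver_config"),
            inherits(spectral, "spectral_config"), n_trials >= 1)
  get_param(base, parameter)  # errors early on unresolvable paths
  structure(list(parameter = parameter, grid = grid, base = base,
                 noise = noise, solver = solver, spectral = spectral,
                 n_trials = n_trials),
            class = "sweep_spec")
}

sweep_cache <- new.env(parent = emptyenv())

cache_key <- function(p, nc, sc, n_trials) {
  paste(params_hash(p), nc$seed, nc$mean, nc$sd, nc$dt_hold, sc$duration,
        sc$report_dt, sc$rel_tol, sc$abs_tol, sc$method, n_trials,
        sep = "|")
}

run_classified_ensemble <- function(p, nc, sc, cfg, n_trials,
                                    cache = TRUE) {
  key <- cache_key(p, nc, sc, n_trials)
  ts <- if (cache && !is.null(sweep_cache[[key]])) sweep_cache[[key]]
        else run_ensemble(p, nc, sc, n_trials = n_trials)
  if (cache) sweep_cache[[key]] <- ts
  list(ts = ts, regime = classify_regime(ts, cfg))
}

#' Run a one-dimensional parameter sweep
#'
#' For each grid value the parameter is set on the base configuration, the
#' ensemble protocol is run, and the output is classified. Ensemble means
#' are cached in the session by (parameters, seeds, solver) so repeated
#' sweeps over overlapping grids are free.
#'
#' @param spec a [sweep_spec()].
#' @param cache reuse cached ensemble runs.
#' @param verbose print one progress line per grid point.
#' @return an object of class `sweep_result`: a data frame of one row per
#'   grid value (value, regime label, metrics) with the spec attached.
#' @export
run_sweep <- function(spec, cache = TRUE, verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- vector("list", length(spec$grid))
  for (i in seq_along(spec$grid)) {
    v <- spec$grid[i]
    p <- set_param(spec$base, spec$parameter, v)
    res <- run_classified_ensemble(p, spec$noise, spec$solver,
                                   spec$spectral, spec$n_trials, cache)
    m <- res$regime$metrics
    rows[[i]] <- data.frame(parameter = spec$parameter, value = v,
                            label = res$regime$label, t(m),
                            seed = spec$noise$seed,
                            n_trials = spec$n_trials)
    if (verbose)
      message(sprintf("%s = %g -> %s", spec$parameter, v,
                      res$regime$label))
  }
  out <- do.call(rbind, rows)
  structure(out, spec = spec, class = c("sweep_result", "data.frame"))
}

#' @export
print.sweep_result <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("Parameter sweep over '%s' (%d grid points, %d trials each)\n",
              spec$parameter, length(spec$grid), spec$n_trials))
  print.data.frame(x[, c("value", "label", "sd_raw", "dom_freq_hz",
                         "prominence_db", "env_cv")], digits = 4)
  invisible(x)
}

#' Locate a regime transition on a sweep grid
#'
#' Returns the smallest grid value labelled `to_label` whose immediate
#' predecessor on the grid is labelled `from_label`, i.e. the first grid
#' point past the bifurcation; `NA` if no such adjacent transition exists.
#' With several matching transitions the first is returned and the result
#' carries attribute `multiple = TRUE`.
#'
#' @param res a [run_sweep()] result (sorted grid).
#' @param from_label,to_label regime labels; see [regime_levels()].
#' @return grid value (or `NA`), with attribute `multiple`.
#' @export
find_bifurcation <- function(res, from_label, to_label) {
  stopifnot(inherits(res, "sweep_result"),
            from_label %in% regime_levels(), to_label %in% regime_levels())
  lab <- as.character(res$label)
  hit <- which(lab[-1] == to_label & lab[-length(lab)] == from_label) + 1L
  if (length(hit) == 0L) {
    out <- NA_real_
  } else {
    out <- res$value[hit[1]]
    if (length(hit) > 1L)
      warning("multiple transitions on the grid; returning the first")
  }
  attr(out, "multiple") <- length(hit) > 1L
  out
}

blockade_pathways <- function() {
  c("ampa_ret", "ampa_t2n", "gabaa_n2t", "gabaa_n2n", "gabab_n2t")
}

#' Receptor blockade experiment
#'
#' Sets the maximum conductance of the named synaptic pathways to zero,
#' runs the ensemble protocol and classifies the output. Blocking both
#' AMPA pathways, or jointly the GABA_A and GABA_B pathways onto the TCR,
#' silences the circuit.
#'
#' @param pathways character vector from
#'   `c("ampa_ret", "ampa_t2n", "gabaa_n2t", "gabaa_n2n", "gabab_n2t")`;
#'   may be empty for an unblocked control run.
#' @param base a [circuit_params()] object or preset name.
#' @param noise,solver,spectral protocol configuration.
#' @param n_trials ensemble size.
#' @return a `regime_label` with the ensemble mean attached as
#'   attribute `"timeseries"`.
#' @export
blockade_experiment <- function(pathways, base = default_params(),
                                noise = noise_config(),
                                solver = solver_config(),
                                spectral = spectral_config(),
                                n_trials = 20) {
  if (is.character(base)) base <- preset(base)
  stopifnot(is.character(pathways) || length(pathways) == 0L,
            inherits(base, "circuit_params"))
  bad <- setdiff(pathways, blockade_pathways())
  if (length(bad))
    stop(sprintf("unknown pathway(s) %s; valid: %s",
                 paste(bad, collapse = ", "),
                 paste(blockade_pathways(), collapse = ", ")))
  p <- base
  for (pw in pathways) p <- set_param(p, paste0(pw, ".g_max"), 0)
  res <- run_classified_ensemble(p, noise, solver, spectral, n_trials)
  out <- res$regime
  attr(out, "timeseries") <- res$ts
  out
}
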