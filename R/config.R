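# Human-readable YAML configuration mirroring the parameter, noise, solver
# and spectral objects, used by the command-line interface and the shipped
# experiment files under inst/experiments/.

#' Convert circuit parameters to / from a plain list
#'
#' @param p a [circuit_params()] object.
#' @return `params_to_list` returns a nested plain list;
#'   `params_from_list` rebuilds the `circuit_params` object.
#' @export
params_to_list <- function(p) {
  stopifnot(inherits(p, "circuit_params"))
  strip <- function(x) lapply(unclass(x), identity)
  list(transmitter = lapply(p$transmitter, strip),
       ampa_ret = strip(p$ampa_ret), ampa_t2n = strip(p$ampa_t2n),
       gabaa_n2t = strip(p$gabaa_n2t), gabaa_n2n = strip(p$gabaa_n2n),
       gabab_n2t = strip(p$gabab_n2t),
       tcr = strip(p$tcr), trn = strip(p$trn),
       conn = strip(p$conn))
}

#' @rdname params_to_list
#' @param x a nested plain list as produced by `params_to_list`.
#' @export
params_from_list <- function(x) {
  lg <- function(l) ligand_gated_params(l$alpha, l$beta, l$g_max, l$V_rev)
  tp <- function(l) transmitter_params(l$T_max, l$theta_s, l$sigma_s)
  circuit_params(
    transmitter = lapply(x$transmitter, tp),
    ampa_ret = lg(x$ampa_ret), ampa_t2n = lg(x$ampa_t2n),
    gabaa_n2t = lg(x$gabaa_n2t), gabaa_n2n = lg(x$gabaa_n2n),
    gabab_n2t = gabab_params(x$gabab_n2t$alpha1, x$gabab_n2t$beta1,
                             x$gabab_n2t$alpha2, x$gabab_n2t$beta2,
                             x$gabab_n2t$K_d, x$gabab_n2t$n,
                             x$gabab_n2t$g_max, x$gabab_n2t$V_rev),
    tcr = population_params(x$tcr$kappa_m, x$tcr$g_leak, x$tcr$V_leak,
                            x$tcr$V_rest),
    trn = population_params(x$trn$kappa_m, x$trn$g_leak, x$trn$V_leak,
                            x$trn$V_rest),
    conn = connectivity_params(x$conn$C_tre, x$conn$C_tni_a,
                               x$conn$C_tni_b, x$conn$C_nte, x$conn$C_nsi))
}

#' Read / write a full run configuration as YAML
#'
#' A configuration file may hold any of the blocks `circuit` (or a
#' top-level `preset` name plus a `set` map of parameter-path overrides),
#' `noise`, `solver` and `spectral`.
#'
#' @param path YAML file path.
#' @return a list with elements `circuit` ([circuit_params()]), `noise`,
#'   `solver`, `spectral`, each `NULL` when absent from the file.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  circuit <- NULL
  if (!is.null(x$circuit)) circuit <- params_from_list(x$circuit)
  if (!is.null(x$preset)) circuit <- preset(x$preset)
  if (is.null(circuit) && (!is.null(x$set))) circuit <- default_params()
  if (!is.null(x$set)) {
    for (nm in names(x$set)) circuit <- set_param(circuit, nm, x$set[[nm]])
  }
  noise <- if (!is.null(x$noise)) do.call(noise_config, x$noise)
  solver <- if (!is.null(x$solver)) do.call(solver_config, x$solver)
  spectral <- if (!is.null(x$spectral)) {
    sp <- x$spectral
    for (nm in c("epoch", "band", "slow_band"))
      if (!is.null(sp[[nm]])) sp[[nm]] <- as.numeric(sp[[nm]])
    do.call(spectral_config, sp)
  }
  sweep <- x$sweep
  list(circuit = circuit, noise = noise, solver = solver,
       spectral = spectral, sweep = sweep)
}

#' @rdname read_config
#' @param p a [circuit_params()] object.
#' @param noise,solver optional [noise_config()] / [solver_config()] to
#'   embed.
#' @export
write_config <- function(p, path, noise = NULL, solver = NULL) {
  x <- list(circuit = params_to_list(p))
  if (!is.null(noise)) x$noise <- unclass(noise)
  if (!is.null(solver)) x$solver <- unclass(solver)
  yaml::write_yaml(x, path)
  invisible(path)
}
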