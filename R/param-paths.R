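# Dotted parameter paths ("gabaa_n2t.g_max") plus linked aliases that set
# several components at once (e.g. "g_ampa" = both AMPA conductances, the
# joint knob used in the conductance sweeps).

param_aliases <- function() {
  list(
    "ampa.alpha"  = c("ampa_ret.alpha", "ampa_t2n.alpha"),
    "ampa.beta"   = c("ampa_ret.beta", "ampa_t2n.beta"),
    "g_ampa"      = c("ampa_ret.g_max", "ampa_t2n.g_max"),
    "g_ampa_tcr"  = "ampa_ret.g_max",
    "g_ampa_trn"  = "ampa_t2n.g_max",
    "gabaa.alpha" = c("gabaa_n2t.alpha", "gabaa_n2n.alpha"),
    "gabaa.beta"  = c("gabaa_n2t.beta", "gabaa_n2n.beta"),
    "theta_s"     = c("transmitter.ret.theta_s", "transmitter.tcr.theta_s",
                      "transmitter.trn.theta_s"),
    "sigma_s"     = c("transmitter.ret.sigma_s", "transmitter.tcr.sigma_s",
                      "transmitter.trn.sigma_s")
  )
}

param_components <- function() {
  c("ampa_ret", "ampa_t2n", "gabaa_n2t", "gabaa_n2n", "gabab_n2t",
    "tcr", "trn", "conn")
}

#' Valid sweep parameter paths
#'
#' All dotted paths accepted by [set_param()] and the sweep machinery:
#' direct component fields such as `"gabaa_n2t.g_max"` or `"trn.g_leak"`,
#' transmitter fields such as `"transmitter.ret.theta_s"`, and linked
#' aliases (`"ampa.beta"` sets both AMPA pathways, `"g_ampa"` both AMPA
#' conductances, `"theta_s"`/`"sigma_s"` all release sigmoids).
#'
#' @return character vector of paths.
#' @export
param_paths <- function() {
  p <- default_params()
  direct <- unlist(lapply(param_components(), function(comp) {
    fields <- names(p[[comp]])
    fields <- fields[vapply(p[[comp]], is.numeric, logical(1))]
    paste(comp, fields, sep = ".")
  }))
  trans <- as.vector(outer(paste0("transmitter.", c("ret", "tcr", "trn")),
                           c("T_max", "theta_s", "sigma_s"), paste,
                           sep = "."))
  c(direct, trans, names(param_aliases()))
}

resolve_path <- function(path) {
  al <- param_aliases()
  if (path %in% names(al)) return(al[[path]])
  path
}

set_one <- function(p, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- p
  for (k in seq_along(parts[-length(parts)])) {
    if (is.null(node[[parts[k]]]))
      stop(sprintf("unknown parameter path '%s'; valid paths:\n  %s", path,
                   paste(param_paths(), collapse = ", ")), call. = FALSE)
    node <- node[[parts[k]]]
  }
  leaf <- parts[length(parts)]
  if (is.null(node[[leaf]]) || !is.numeric(node[[leaf]]))
    stop(sprintf("unknown parameter path '%s'; valid paths:\n  %s", path,
                 paste(param_paths(), collapse = ", ")), call. = FALSE)
  p[[parts]] <- value
  p
}

#' Set a circuit parameter by path
#'
#' @param p a [circuit_params()] object.
#' @param path a dotted path or linked alias; see [param_paths()].
#' @param value new numeric value.
#' @return the modified `circuit_params` object.
#' @export
set_param <- function(p, path, value) {
  stopifnot(inherits(p, "circuit_params"), is.character(path),
            length(path) == 1L, is.numeric(value), length(value) == 1L,
            is.finite(value))
  for (pp in resolve_path(path)) p <- set_one(p, pp, value)
  p
}

#' Read a circuit parameter by path
#'
#' For linked aliases the first component's value is returned.
#'
#' @inheritParams set_param
#' @return numeric value.
#' @export
get_param <- function(p, path) {
  stopifnot(inherits(p, "circuit_params"), is.character(path),
            length(path) == 1L)
  pp <- resolve_path(path)[1]
  parts <- strsplit(pp, ".", fixed = TRUE)[[1]]
  v <- tryCatch(p[[parts]], error = function(e) NULL)
  if (is.null(v) || !is.numeric(v))
    stop(sprintf("unknown parameter path '%s'; valid paths:\n  %s", path,
                 paste(param_paths(), collapse = ", ")), call. = FALSE)
  v
}
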