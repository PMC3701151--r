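#' Uniformly sampled time series
#'
#' Light container for model signals: a uniform time grid in ms, a value
#' vector (mV for voltage traces), an optional full-state matrix, and a
#' provenance list (seed, parameter hash, solver settings).
#'
#' @param t time grid (ms), uniformly spaced.
#' @param values signal samples, same length as `t`.
#' @param state optional matrix of full state columns aligned with `t`.
#' @param meta provenance list.
#' @return an object of class `kin_timeseries`.
#' @export
kin_timeseries <- function(t, values, state = NULL, meta = list()) {
  stopifnot(is.numeric(t), is.numeric(values), length(t) == length(values),
            length(t) >= 2L, all(is.finite(t)))
  dts <- diff(t)
  if (max(dts) - min(dts) > 1e-6 * mean(dts))
    stop("'t' must be uniformly spaced")
  if (!is.null(state))
    stopifnot(is.matrix(state), nrow(state) == length(t))
  structure(list(t = as.numeric(t), values = as.numeric(values),
                 state = state, meta = meta),
            class = "kin_timeseries")
}

#' @export
print.kin_timeseries <- function(x, ...) {
  cat(sprintf(
    "Time series: %d samples, dt = %g ms (%.3f s total), range [%.4g, %.4g]\n",
    length(x$t), ts_dt(x), diff(range(x$t)) / 1000, min(x$values),
    max(x$values)))
  if (!is.null(x$meta$seed)) cat(sprintf("  seed: %s\n",
                                         paste(x$meta$seed, collapse = ",")))
  invisible(x)
}

#' @export
summary.kin_timeseries <- function(object, ...) {
  v <- object$values
  out <- c(n = length(v), dt_ms = ts_dt(object), mean = mean(v),
           sd = stats::sd(v), min = min(v), max = max(v))
  class(out) <- "summary.kin_timeseries"
  out
}

#' @export
print.summary.kin_timeseries <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' @export
plot.kin_timeseries <- function(x, y, xlab = "time (s)",
                                ylab = "V (mV)", type = "l", ...) {
  plot(x$t / 1000, x$values, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

ts_dt <- function(ts) ts$t[2] - ts$t[1]
ts_fs <- function(ts) 1000 / ts_dt(ts)  # Hz

#' Crop a time series to a time window
#'
#' @param ts a [kin_timeseries()].
#' @param start,end window bounds (ms); samples with `start <= t <= end`.
#' @return cropped `kin_timeseries`.
#' @export
ts_crop <- function(ts, start, end) {
  stopifnot(inherits(ts, "kin_timeseries"), start < end)
  keep <- ts$t >= start - 1e-9 & ts$t <= end + 1e-9
  if (sum(keep) < 2L)
    stop("epoch lies outside the series")
  kin_timeseries(ts$t[keep], ts$values[keep],
                 state = if (!is.null(ts$state)) ts$state[keep, , drop = FALSE],
                 meta = ts$meta)
}

#' Write / read a time series as columnar text
#'
#' CSV with a `t_ms` column, the signal column, and optionally the full
#' state; provenance is embedded as `#`-prefixed header comments.
#'
#' @param ts a [kin_timeseries()].
#' @param path file path.
#' @param full_state also write the state matrix columns.
#' @return `write_timeseries` returns `path` invisibly; `read_timeseries`
#'   returns a `kin_timeseries`.
#' @export
write_timeseries <- function(ts, path, full_state = FALSE) {
  stopifnot(inherits(ts, "kin_timeseries"))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(ts$meta)) {
    val <- ts$meta[[nm]]
    if (is.atomic(val) && length(val) < 20)
      writeLines(sprintf("# %s: %s", nm, paste(val, collapse = ",")), con)
  }
  df <- data.frame(t_ms = ts$t, V_tcr_mV = ts$values)
  if (full_state && !is.null(ts$state)) df <- cbind(df, ts$state)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  state <- NULL
  if (ncol(df) > 2L) state <- as.matrix(df[, -(1:2), drop = FALSE])
  kin_timeseries(df[[1]], df[[2]], state = state,
                 meta = list(source = path))
}
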