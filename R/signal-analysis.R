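#' Spectral analysis configuration
#'
#' The published analysis chain: crop to the 100-599 s epoch, resample to
#' 250 Hz, band-pass 3.5-14 Hz with an order-10 Butterworth filter applied
#' forward-backward (zero phase), then a short-time Fourier transform with
#' a 10 s Hamming window at 50% overlap. Classifier thresholds formalize
#' the qualitative regime vocabulary and were calibrated on constructed
#' synthetic signals.
#'
#' @param epoch analysis window `c(start, end)` in ms. The default follows
#'   the full 600 s protocol; for shorter runs pass a window inside the
#'   simulated span (the transient must still be discarded).
#' @param fs_out resampling rate (Hz).
#' @param band band-pass edges (Hz).
#' @param filter_order total Butterworth band-pass order (even).
#' @param stft_window STFT window length (s).
#' @param overlap STFT window overlap fraction in (0, 1).
#' @param eps_q quiescence threshold: quiescent when the raw epoch SD is
#'   below `eps_q * |mean level|`.
#' @param p_min_db spectral peak prominence threshold (dB above the median
#'   spectrum) for calling an oscillation.
#' @param cv_split envelope coefficient-of-variation split between the
#'   limit-cycle (constant envelope) and spindling (waxing-waning) labels.
#' @param slow_band frequency range (Hz) of the slow-oscillation label,
#'   searched on the raw detrended epoch.
#' @param burst_thresh envelope excursion threshold (multiples of the
#'   median envelope) used by the burst-rate metric.
#' @return an object of class `spectral_config`.
#' @export
spectral_config <- function(epoch = c(100000, 599000), fs_out = 250,
                            band = c(3.5, 14), filter_order = 10,
                            stft_window = 10, overlap = 0.5,
                            eps_q = 1e-3, p_min_db = 10, cv_split = 0.25,
                            slow_band = c(0.005, 0.5), burst_thresh = 2) {
  stopifnot(length(epoch) == 2L, epoch[1] < epoch[2], fs_out > 0,
            length(band) == 2L, band[1] > 0, band[1] < band[2],
            band[2] < fs_out / 2, filter_order >= 2,
            filter_order %% 2 == 0, stft_window > 0, overlap > 0,
            overlap < 1, eps_q > 0, p_min_db > 0, cv_split > 0,
            length(slow_band) == 2L, slow_band[1] > 0,
            slow_band[1] < slow_band[2], burst_thresh > 0)
  structure(list(epoch = epoch, fs_out = fs_out, band = band,
                 filter_order = filter_order, stft_window = stft_window,
                 overlap = overlap, eps_q = eps_q, p_min_db = p_min_db,
                 cv_split = cv_split, slow_band = slow_band,
                 burst_thresh = burst_thresh),
            class = "spectral_config")
}

#' Epoch, resample and band-pass a model output
#'
#' Crops to the analysis epoch, decimates to `fs_out` (an anti-alias
#' Butterworth low-pass applied forward-backward, then every k-th sample),
#' and band-passes with the order-`filter_order` Butterworth design, also
#' applied forward-backward so the chain is zero-phase.
#'
#' @param ts a [kin_timeseries()] covering the epoch.
#' @param cfg a [spectral_config()].
#' @return the filtered [kin_timeseries()] at `fs_out`.
#' @export
preprocess <- function(ts, cfg = spectral_config()) {
  stopifnot(inherits(ts, "kin_timeseries"), inherits(cfg, "spectral_config"))
  if (cfg$epoch[1] < ts$t[1] - 1e-9 || cfg$epoch[2] > ts$t[length(ts$t)] + 1e-9)
    stop("epoch lies outside the series")
  cropped <- ts_crop(ts, cfg$epoch[1], cfg$epoch[2])
  dec <- decimate_ts(cropped, cfg$fs_out)
  x <- dec$values - mean(dec$values)
  bf <- butter_bandpass(cfg)
  y <- signal::filtfilt(bf, x)
  kin_timeseries(dec$t, y, meta = c(ts$meta, list(preprocessed = TRUE)))
}

butter_bandpass <- function(cfg) {
  # signal::butter(n, c(lo, hi), "pass") yields a band-pass of order 2n
  signal::butter(cfg$filter_order / 2,
                 cfg$band / (cfg$fs_out / 2), type = "pass")
}

decimate_ts <- function(ts, fs_out) {
  fs_in <- ts_fs(ts)
  k <- fs_in / fs_out
  if (abs(k - round(k)) > 1e-6)
    stop("input rate must be an integer multiple of fs_out")
  k <- round(k)
  if (k == 1L) return(ts)
  # anti-alias low-pass at 80% of the output Nyquist before subsampling
  lp <- signal::butter(8, 0.8 * fs_out / fs_in, type = "low")
  mu <- mean(ts$values)
  y <- signal::filtfilt(lp, ts$values - mu) + mu
  idx <- seq(1, length(y), by = k)
  kin_timeseries(ts$t[idx], y[idx], meta = ts$meta)
}

#' Short-time Fourier transform
#'
#' Hamming-windowed one-sided power spectrogram. Power is normalized so
#' that the sum of each column equals the energy of the corresponding
#' windowed segment (discrete Parseval identity).
#'
#' @param ts a [kin_timeseries()] (normally the output of [preprocess()]).
#' @param cfg a [spectral_config()].
#' @return an object of class `kin_spectrogram` with fields `times`
#'   (window centres, s), `freqs` (Hz) and `power` (freq x time matrix).
#' @export
stft <- function(ts, cfg = spectral_config()) {
  stopifnot(inherits(ts, "kin_timeseries"), inherits(cfg, "spectral_config"))
  fs <- ts_fs(ts)
  n <- round(cfg$stft_window * fs)
  if (length(ts$values) < n)
    stop("series shorter than one STFT window")
  hop <- max(1L, round(n * (1 - cfg$overlap)))
  w <- hamming_window(n)
  starts <- seq(1L, length(ts$values) - n + 1L, by = hop)
  nf <- n %/% 2 + 1L
  power <- matrix(0, nrow = nf, ncol = length(starts))
  for (j in seq_along(starts)) {
    seg <- ts$values[starts[j]:(starts[j] + n - 1L)] * w
    X <- stats::fft(seg)
    p2 <- Mod(X[seq_len(nf)])^2 / n
    # fold the negative frequencies onto the positive side
    dup <- if (n %% 2 == 0) 2:(nf - 1L) else 2:nf
    p2[dup] <- 2 * p2[dup]
    power[, j] <- p2
  }
  structure(list(times = (ts$t[starts] - ts$t[1] + (n - 1) / fs * 1000 / 2) / 1000,
                 freqs = (seq_len(nf) - 1L) * fs / n,
                 power = power,
                 window = n, fs = fs),
            class = "kin_spectrogram")
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

#' @export
print.kin_spectrogram <- function(x, ...) {
  cat(sprintf(
    "Spectrogram: %d freq bins (0-%.1f Hz) x %d windows (%.1f-%.1f s)\n",
    length(x$freqs), max(x$freqs), length(x$times), min(x$times),
    max(x$times)))
  invisible(x)
}

#' @export
plot.kin_spectrogram <- function(x, y, fmax = 20, ...) {
  keep <- x$freqs <= fmax
  image(x$times, x$freqs[keep], t(log10(x$power[keep, , drop = FALSE] + 1e-12)),
        xlab = "time (s)", ylab = "frequency (Hz)", ...)
  invisible(x)
}

#' Band power time course
#'
#' Per-window integrated power over a frequency band of a spectrogram.
#'
#' @param sg a `kin_spectrogram` from [stft()].
#' @param band `c(lo, hi)` in Hz; e.g. theta `c(4, 7)`, alpha `c(8, 13)`.
#' @return numeric vector, one value per STFT window.
#' @export
band_power <- function(sg, band) {
  stopifnot(inherits(sg, "kin_spectrogram"), length(band) == 2L,
            band[1] < band[2])
  keep <- sg$freqs >= band[1] & sg$freqs <= band[2]
  if (!any(keep)) stop("band contains no frequency bins")
  colSums(sg$power[keep, , drop = FALSE])
}

linear_detrend <- function(x) {
  n <- length(x)
  i <- seq_len(n) - (n + 1) / 2
  x - mean(x) - sum(i * x) / sum(i * i) * i
}

# Full-epoch periodogram peak within [fmin, fmax]: frequency of the maximum
# and its prominence in dB over the median periodogram in that range.
periodogram_peak <- function(x, fs, fmin, fmax) {
  x <- linear_detrend(x)
  n <- length(x)
  X <- stats::fft(x)
  nf <- n %/% 2 + 1L
  p <- Mod(X[seq_len(nf)])^2 / n
  f <- (seq_len(nf) - 1L) * fs / n
  keep <- f >= fmin & f <= fmax & f > 0
  if (!any(keep)) stop("no frequency bins inside [fmin, fmax]")
  pk <- p[keep]
  fk <- f[keep]
  i <- which.max(pk)
  med <- stats::median(pk)
  list(freq = fk[i],
       prominence_db = 10 * log10(pk[i] / max(med, .Machine$double.xmin)))
}

#' Dominant frequency of a signal
#'
#' Frequency of the maximum of the full-epoch periodogram (after linear
#' detrending) restricted to `[fmin, fmax]`. For sub-Hz targets the raw,
#' unfiltered epoch must be supplied: the 3.5-14 Hz analysis chain would
#' remove them. Returns `NA` when no peak rises above the prominence
#' threshold; the peak prominence (dB over the in-range median) is attached
#' as attribute `"prominence_db"` either way.
#'
#' @param ts a [kin_timeseries()].
#' @param fmin,fmax search range (Hz); the series must span at least
#'   `2/fmin` seconds (two full cycles of the slowest resolvable
#'   component).
#' @param p_min_db prominence required to report a peak.
#' @return dominant frequency (Hz) or `NA`.
#' @export
dominant_frequency <- function(ts, fmin, fmax, p_min_db = 10) {
  stopifnot(inherits(ts, "kin_timeseries"), fmin > 0, fmin < fmax)
  fs <- ts_fs(ts)
  span_s <- diff(range(ts$t)) / 1000
  if (span_s < 2 / fmin)
    stop(sprintf("series too short to resolve %g Hz (needs >= %g s)",
                 fmin, 2 / fmin))
  pk <- periodogram_peak(ts$values, fs, fmin, fmax)
  out <- if (pk$prominence_db >= p_min_db) pk$freq else NA_real_
  attr(out, "prominence_db") <- pk$prominence_db
  out
}

# Analytic-signal envelope via the frequency-domain Hilbert transform.
envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Classify the dynamical regime of a model output
#'
#' Decision rules over the post-transient epoch (thresholds from the
#' [spectral_config()]):
#' 1. *quiescent* if the raw epoch SD is below `eps_q * |mean level|`;
#' 2. *slow_oscillation* if the dominant component of the raw detrended
#'    epoch lies in `slow_band` with prominence at least `p_min_db`;
#' 3. otherwise band-pass via [preprocess()]; *point_attractor* if the
#'    in-band Welch spectrum has no peak of prominence `p_min_db` (the
#'    output merely reflects the noisy drive);
#' 4. otherwise *limit_cycle* if the analytic-envelope coefficient of
#'    variation is below `cv_split`;
#' 5. otherwise *spindling* (waxing-and-waning envelope, recurring
#'    bursts).
#'
#' @param ts a [kin_timeseries()] of the (ensemble-averaged) model output
#'   covering the configured epoch.
#' @param cfg a [spectral_config()].
#' @return an object of class `regime_label`: list with `label` and a
#'   `metrics` vector (raw SD, dominant frequency, spectral prominence,
#'   envelope CV, burst rate per minute).
#' @export
classify_regime <- function(ts, cfg = spectral_config()) {
  stopifnot(inherits(ts, "kin_timeseries"), inherits(cfg, "spectral_config"))
  raw <- ts_crop(ts, cfg$epoch[1], cfg$epoch[2])
  span_s <- diff(range(raw$t)) / 1000
  if (span_s < 2 * cfg$stft_window)
    stop("epoch must cover at least two STFT windows")
  sd_raw <- stats::sd(raw$values)
  level <- max(abs(mean(raw$values)), 1)

  metrics <- c(sd_raw = sd_raw, dom_freq_hz = NA_real_,
               prominence_db = NA_real_, env_cv = NA_real_,
               burst_rate_per_min = NA_real_)
  finish <- function(label) {
    structure(list(label = label, metrics = metrics), class = "regime_label")
  }

  if (sd_raw < cfg$eps_q * level) return(finish("quiescent"))

  # Slow oscillations are read off the raw (unfiltered) detrended epoch.
  # Two conditions: the globally dominant component must lie in the slow
  # band, and it must stand out above the slow-band median spectrum.
  slow_lo <- max(cfg$slow_band[1], 3 / span_s)
  pk_all <- periodogram_peak(raw$values, ts_fs(raw), slow_lo,
                             ts_fs(raw) / 2 * 0.99)
  if (pk_all$freq <= cfg$slow_band[2]) {
    pk_slow <- periodogram_peak(raw$values, ts_fs(raw), slow_lo,
                                cfg$slow_band[2])
    if (pk_slow$prominence_db >= cfg$p_min_db) {
      metrics["dom_freq_hz"] <- pk_slow$freq
      metrics["prominence_db"] <- pk_slow$prominence_db
      return(finish("slow_oscillation"))
    }
  }

  filt <- preprocess(ts, cfg)
  sg <- stft(filt, cfg)
  welch <- rowMeans(sg$power)
  inband <- sg$freqs >= cfg$band[1] & sg$freqs <= cfg$band[2]
  pw <- welch[inband]
  fw <- sg$freqs[inband]
  i <- which.max(pw)
  prom <- 10 * log10(pw[i] / max(stats::median(pw), .Machine$double.xmin))
  metrics["dom_freq_hz"] <- fw[i]
  metrics["prominence_db"] <- prom
  if (prom < cfg$p_min_db) return(finish("point_attractor"))

  env <- envelope(filt$values)
  # trim filter edge transients before summarizing the envelope
  ntrim <- min(length(env) %/% 10, round(ts_fs(filt)))
  env <- env[(ntrim + 1):(length(env) - ntrim)]
  cv <- stats::sd(env) / mean(env)
  metrics["env_cv"] <- cv
  thr <- cfg$burst_thresh * stats::median(env)
  above <- env > thr
  n_bursts <- sum(diff(c(FALSE, above)) == 1)
  metrics["burst_rate_per_min"] <- n_bursts / (length(env) / ts_fs(filt) / 60)
  if (cv < cfg$cv_split) return(finish("limit_cycle"))
  finish("spindling")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("Regime: %s\n", x$label))
  m <- x$metrics
  cat(sprintf("  raw SD %.4g mV | dominant %.4g Hz | prominence %.3g dB | env CV %.3g | bursts %.3g /min\n",
              m["sd_raw"], m["dom_freq_hz"], m["prominence_db"],
              m["env_cv"], m["burst_rate_per_min"]))
  invisible(x)
}

#' All regime labels
#' @return character vector of the possible labels.
#' @export
regime_levels <- function() {
  c("quiescent", "point_attractor", "limit_cycle", "spindling",
    "slow_oscillation")
}

#' Write a spectrogram as a CSV matrix
#'
#' First row holds window-centre times (s), first column frequencies (Hz).
#'
#' @param sg a `kin_spectrogram`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_spectrogram <- function(sg, path) {
  stopifnot(inherits(sg, "kin_spectrogram"))
  m <- cbind(freq_hz = sg$freqs, sg$power)
  colnames(m) <- c("freq_hz", sprintf("t_%gs", sg$times))
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}
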