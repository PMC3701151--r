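# Synthetic signals on the model's native 1 kHz grid
mk_ts <- function(f, dur_s = 60, fs = 1000, amp = 1, mod = NULL) {
  t_ms <- seq(0, dur_s * 1000 - 1, by = 1000 / fs)
  x <- amp * sin(2 * pi * f * t_ms / 1000)
  if (!is.null(mod)) x <- x * mod(t_ms / 1000)
  kin_timeseries(t_ms, x)
}
cfg60 <- spectral_config(epoch = c(0, 59999))

test_that("preprocess passes the band and removes out-of-band components", {
  ts10 <- mk_ts(10)
  out <- preprocess(ts10, cfg60)
  expect_equal(ts_dt <- out$t[2] - out$t[1], 4)  # 250 Hz
  # interior amplitude preserved within 1%
  core <- out$values[2000:12000]
  expect_gt(max(core), 0.99)
  expect_lt(max(core), 1.01)
  # 1 Hz attenuated by > 40 dB
  out1 <- preprocess(mk_ts(1), cfg60)
  expect_lt(max(abs(out1$values[2000:12000])), 10^(-40 / 20))
  # DC removed entirely by the band-pass
  dc <- kin_timeseries(seq(0, 59999), rep(5, 60000))
  outdc <- preprocess(dc, cfg60)
  expect_lt(max(abs(outdc$values[2000:12000])), 1e-8)
  expect_error(preprocess(ts10, spectral_config(epoch = c(0, 1e6))),
               "epoch")
})

test_that("the designed Butterworth band-pass meets its magnitude spec", {
  bf <- kinmass:::butter_bandpass(cfg60)
  hf <- function(f) {
    # evaluate the transfer function b(z)/a(z) at z = exp(i*2*pi*f/fs)
    z <- exp(-1i * 2 * pi * f / 250 * (seq_along(bf$b) - 1))
    Mod(sum(bf$b * z) / sum(bf$a * z))
  }
  expect_gt(hf(8), 0.95)
  expect_lt(hf(1), 10^(-40 / 20))      # stop band
  expect_lt(hf(40), 10^(-40 / 20))
  expect_lt(hf(0), 1e-6)
})

test_that("preprocess is linear", {
  set.seed(2)
  t_ms <- seq(0, 59999)
  x <- kin_timeseries(t_ms, rnorm(60000))
  y <- kin_timeseries(t_ms, sin(2 * pi * 7 * t_ms / 1000))
  a <- 2.5; b <- -1.3
  mix <- kin_timeseries(t_ms, a * x$values + b * y$values)
  lhs <- preprocess(mix, cfg60)$values
  rhs <- a * preprocess(x, cfg60)$values + b * preprocess(y, cfg60)$values
  # linearity holds to the numerical conditioning of the order-10
  # IIR cascade (double precision), not to machine epsilon
  expect_lt(max(abs(lhs - rhs)), 1e-5 * max(abs(lhs)))
})

test_that("STFT localizes stationary tones and satisfies Parseval", {
  ts10 <- preprocess(mk_ts(10), cfg60)
  sg <- stft(ts10, cfg60)
  expect_equal(dim(sg$power), c(1251, length(sg$times)))
  for (j in seq_along(sg$times))
    expect_lt(abs(sg$freqs[which.max(sg$power[, j])] - 10), 0.11)
  # two-tone: persistent ridges at both bins
  ts2 <- kin_timeseries(seq(0, 59999, by = 4),
                        sin(2 * pi * 5 * seq(0, 59999, by = 4) / 1000) +
                        sin(2 * pi * 11 * seq(0, 59999, by = 4) / 1000))
  sg2 <- stft(ts2, cfg60)
  for (j in seq_along(sg2$times)) {
    top2 <- sg2$freqs[order(sg2$power[, j], decreasing = TRUE)[1:2]]
    expect_setequal(round(sort(top2), 1), c(5, 11))
  }
  # Parseval: column power equals windowed segment energy within 1%
  w <- kinmass:::hamming_window(sg2$window)
  n <- sg2$window
  hop <- n %/% 2
  for (j in c(1, 3, 5)) {
    seg <- ts2$values[((j - 1) * hop + 1):((j - 1) * hop + n)] * w
    expect_equal(sum(sg2$power[, j]), sum(seg^2), tolerance = 0.01)
  }
  expect_error(stft(kin_timeseries(seq(0, 999, by = 4),
                                   rnorm(250)), cfg60),
               "window")
})

test_that("band power separates theta from alpha and is additive", {
  theta <- c(4, 7); alpha <- c(8, 13)
  sg10 <- stft(preprocess(mk_ts(10), cfg60), cfg60)
  expect_gt(mean(band_power(sg10, alpha)) /
            mean(band_power(sg10, theta)), 100)
  sg5 <- stft(preprocess(mk_ts(5), cfg60), cfg60)
  expect_gt(mean(band_power(sg5, theta)) /
            mean(band_power(sg5, alpha)), 100)
  # equal-amplitude two-tone splits power evenly within 10%
  t_ms <- seq(0, 59999, by = 4)
  ts2 <- kin_timeseries(t_ms, sin(2 * pi * 5 * t_ms / 1000) +
                              sin(2 * pi * 10 * t_ms / 1000))
  sg2 <- stft(ts2, cfg60)
  expect_equal(mean(band_power(sg2, theta)) /
               mean(band_power(sg2, alpha)), 1, tolerance = 0.1)
  # nonnegative and additive over disjoint bands
  bp <- band_power(sg2, c(4, 13))
  expect_true(all(bp >= 0))
  expect_equal(bp, band_power(sg2, c(4, 7.9)) + band_power(sg2, c(8, 13)),
               tolerance = 1e-12)
  expect_error(band_power(sg2, c(130, 140)), "no frequency bins")
})

test_that("dominant frequency finds slow and fast peaks and flags noise", {
  # 0.03 Hz sine over 500 s, sampled at 10 Hz
  t_ms <- seq(0, 500000 - 1, by = 100)
  slow <- kin_timeseries(t_ms, sin(2 * pi * 0.03 * t_ms / 1000))
  f <- dominant_frequency(slow, 0.005, 0.5)
  expect_lt(abs(f - 0.03), 1 / 500 + 1e-9)  # within one bin
  # white noise: no prominent peak
  set.seed(4)
  noise <- kin_timeseries(seq(0, 59999), rnorm(60000))
  fn <- dominant_frequency(noise, 1, 100, p_min_db = 15)
  expect_true(is.na(fn))
  # AM carrier detection in the alpha band
  t_s <- seq(0, 59999) / 1000
  am <- kin_timeseries(seq(0, 59999),
                       (1 + 0.8 * sin(2 * pi * 0.2 * t_s)) *
                         sin(2 * pi * 10 * t_s))
  expect_lt(abs(dominant_frequency(am, 8, 13) - 10), 0.05)
  expect_error(dominant_frequency(slow, 0.001, 0.5), "too short")
})

test_that("regime classifier fires correctly on constructed signals", {
  cfgc <- spectral_config(epoch = c(0, 99999))
  t_ms <- seq(0, 99999)
  t_s <- t_ms / 1000
  level <- -65
  # constant -> quiescent
  const <- kin_timeseries(t_ms, rep(level, length(t_ms)) +
                            1e-6 * sin(2 * pi * 3 * t_s))
  expect_equal(classify_regime(const, cfgc)$label, "quiescent")
  # pure 8 Hz sine -> limit cycle with tiny envelope CV
  sine <- kin_timeseries(t_ms, level + 2 * sin(2 * pi * 8 * t_s))
  r_lc <- classify_regime(sine, cfgc)
  expect_equal(r_lc$label, "limit_cycle")
  expect_lt(r_lc$metrics["env_cv"], 0.05)
  # 10 Hz bursts recurring at 0.05 Hz with quiet gaps -> spindling
  bursts <- kin_timeseries(t_ms, level +
    2 * pmax(sin(2 * pi * 0.05 * t_s), 0)^2 * sin(2 * pi * 10 * t_s))
  r_sp <- classify_regime(bursts, cfgc)
  expect_equal(r_sp$label, "spindling")
  expect_gt(r_sp$metrics["env_cv"], 0.25)
  expect_gt(r_sp$metrics["burst_rate_per_min"], 2)
  # 0.03 Hz slow wave (500 s epoch) -> slow oscillation
  t2 <- seq(0, 499999, by = 4)
  slow <- kin_timeseries(t2, level + 3 * sin(2 * pi * 0.03 * t2 / 1000) +
                           0.01 * rnorm(length(t2)))
  cfg_slow <- spectral_config(epoch = c(0, 499999))
  r_sl <- classify_regime(slow, cfg_slow)
  expect_equal(r_sl$label, "slow_oscillation")
  expect_lt(abs(r_sl$metrics["dom_freq_hz"] - 0.03), 0.01)
  # band-passed white noise -> point attractor (no prominent line)
  set.seed(6)
  pa <- kin_timeseries(t_ms, level + 0.5 * rnorm(length(t_ms)))
  expect_equal(classify_regime(pa, cfgc)$label, "point_attractor")
  expect_error(classify_regime(ts_crop(pa, 0, 15000),
                               spectral_config(epoch = c(0, 15000))),
               "two STFT windows")
})

test_that("classifier labels are scale- and shift-invariant for oscillations", {
  cfgc <- spectral_config(epoch = c(0, 99999))
  t_ms <- seq(0, 99999)
  t_s <- t_ms / 1000
  base <- 2 * abs(sin(2 * pi * 0.05 * t_s)) * sin(2 * pi * 10 * t_s)
  for (amp in c(0.5, 1, 20)) {
    x <- kin_timeseries(t_ms, -65 + amp * base)
    expect_equal(classify_regime(x, cfgc)$label, "spindling")
  }
  shifted <- kin_timeseries(t_ms, -65 + base[c(10001:100000, 1:10000)])
  expect_equal(classify_regime(shifted, cfgc)$label, "spindling")
})

test_that("time series round-trips through columnar text", {
  ts <- kin_timeseries(seq(0, 999), sin(seq(0, 999) / 50),
                       meta = list(seed = 7L))
  f <- tempfile(fileext = ".csv")
  write_timeseries(ts, f)
  back <- read_timeseries(f)
  expect_equal(back$t, ts$t)
  expect_equal(back$values, ts$values, tolerance = 1e-12)
  # spectrogram export has time/freq headers
  sg <- stft(preprocess(mk_ts(10), cfg60), cfg60)
  f2 <- tempfile(fileext = ".csv")
  write_spectrogram(sg, f2)
  m <- utils::read.csv(f2)
  expect_equal(m$freq_hz, sg$freqs)
  expect_equal(ncol(m), length(sg$times) + 1)
  unlink(c(f, f2))
})
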