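test_that("band-pass attenuates stop-band tones by at least 40 dB and preserves pass-band tones within 1 dB", {
  mid <- function(x) {
    n <- length(x)
    x[floor(n / 4):floor(3 * n / 4)]
  }
  rms <- function(x) sqrt(mean(x^2))
  low <- tone_recording(100, dur = 0.5)
  out <- bandpass_call(low)
  expect_lt(rms(mid(out$waveform)) / rms(mid(low$waveform)), 10^(-40 / 20))
  pass <- tone_recording(1000, dur = 0.5)
  ratio <- rms(mid(bandpass_call(pass)$waveform)) / rms(mid(pass$waveform))
  expect_gt(20 * log10(ratio), -1)
  expect_lt(20 * log10(ratio), 1)
})

test_that("band-pass of white noise matches a direct FFT-mask filtering oracle", {
  set.seed(31)
  n <- 2^15
  sr <- 44100
  x <- rnorm(n)
  y <- bandpass_call(make_recording(x / max(abs(x)), sr))$waveform
  # oracle: brick-wall FFT mask
  X <- fft(x / max(abs(x)))
  f <- (seq_len(n) - 1) / n * sr
  f <- pmin(f, sr - f)
  X[f < 200 | f > 4000] <- 0
  y0 <- Re(fft(X, inverse = TRUE)) / n
  bandpow <- function(w, lo, hi) {
    P <- Mod(fft(w))^2
    sum(P[f >= lo & f <= hi])
  }
  # in-band power agrees with the oracle away from the transition bands
  expect_equal(bandpow(y, 400, 3800), bandpow(y0, 400, 3800), tolerance = 0.05)
  # out-of-band leakage is negligible relative to the pass band
  expect_lt(bandpow(y, 0, 120) / bandpow(y, 400, 3800), 1e-3)
  expect_lt(bandpow(y, 4300, sr / 2) / bandpow(y, 400, 3800), 1e-3)
})

test_that("a low-pass above Nyquist is rejected", {
  expect_error(bandpass_call(tone_recording(1000, sr = 7000)), "Nyquist")
})

test_that("the parameter registry has 26 entries and extraction returns exactly them", {
  expect_length(spectral_param_names(), 26L)
  p <- extract_spectral_params(bandpass_call(tone_recording()))
  expect_identical(names(p), spectral_param_names())
  expect_false(anyNA(p))
})

test_that("a stationary tone yields the closed-form parameter values", {
  p <- extract_spectral_params(bandpass_call(tone_recording(1000, dur = 0.5)))
  bw <- default_binwidth()
  expect_equal(p[["duration"]], 0.5, tolerance = 1e-3)
  expect_lt(abs(p[["peakf"]] - 1000), bw)
  expect_lt(abs(p[["meandom"]] - 1000), bw)
  expect_equal(p[["dfrange"]], 0)
  expect_equal(p[["modindx"]], 0)
  expect_lt(p[["sfm"]], 0.05)
})

test_that("a linear sweep recovers its endpoints and slope within a frequency bin", {
  sr <- 44100
  f0 <- seq(500, 1500, length.out = sr)          # 1 s linear sweep
  sweep <- make_recording(0.5 * sin(2 * pi * cumsum(f0) / sr), sr, "sweep")
  p <- extract_spectral_params(bandpass_call(sweep))
  bw <- default_binwidth()
  expect_lt(abs(p[["startdom"]] - 500), 1.5 * bw)
  expect_lt(abs(p[["enddom"]] - 1500), 1.5 * bw)
  expect_gt(p[["dfslope"]], 0)
  expect_lt(abs(p[["dfslope"]] - 1000), 3 * bw)
})

test_that("in-band white noise has near-maximal flatness and spectral entropy", {
  set.seed(5)
  r <- make_recording(runif(22050, -0.9, 0.9), 44100, "wn")
  p <- extract_spectral_params(bandpass_call(r))
  expect_gt(p[["sfm"]], 0.8)
  expect_gt(p[["sp_ent"]], 0.95)
})

test_that("too-short and silent clips raise informative errors carrying the call id", {
  short <- make_recording(rnorm(500) / 10, 44100, "tiny_call")
  expect_error(extract_spectral_params(short), "tiny_call.*too short")
  silent <- make_recording(numeric(5000), 44100, "mute_call")
  expect_error(extract_spectral_params(silent), "mute_call")
  expect_error(dominant_contour(silent), "mute_call")
})

test_that("dominant contour tracks the generator's f0 trajectory", {
  tone <- bandpass_call(tone_recording(1000, dur = 0.4))
  ct <- dominant_contour(tone)
  expect_length(ct, feature_config()$contour_points)
  expect_lt(max(abs(ct - 1000)), default_binwidth())
  expect_identical(ct, dominant_contour(tone))   # determinism
  # arch-shaped call: rises then falls, maximum near the midpoint
  a <- call_archetype("archy", 800, 800, "arch", 0.5, 0,
                      tonality = 1, n_harmonics = 1)
  arch <- bandpass_call(synthesize_call(a, 3))
  ca <- dominant_contour(arch)
  peak_at <- which.max(ca)
  expect_gt(peak_at, 5)
  expect_lt(peak_at, 16)
  expect_gt(max(ca) - ca[1], 100)                # genuinely rises
  # trajectory matches the archetype's analytic contour within a bin
  tt <- seq(0, 1, length.out = length(ca))
  expected <- vocrep:::archetype_trajectory(a, tt)
  expect_lt(stats::median(abs(ca - expected)), 1.5 * default_binwidth())
})

test_that("feature table has 31 columns, is deterministic, and respects the band", {
  tab <- demo_features()
  expect_length(feature_columns(tab), 31L)
  expect_identical(feature_columns(tab)[27:31], paste0("mds", 1:5))
  expect_false(anyNA(tab))
  freq_cols <- c("meanfreq", "medianfreq", "q25freq", "q75freq", "peakf",
                 "meanpeakf", "meandom", "mindom", "maxdom", "startdom", "enddom")
  for (cn in freq_cols) {
    expect_gte(min(tab[[cn]]), 200)
    expect_lte(max(tab[[cn]]), 4000)
  }
  # identical clips give identical rows
  recs <- demo_dataset()$recordings[1:6]
  recs[[2]] <- recs[[1]]
  recs[[2]]$call_id <- "dup"
  cfg <- feature_config(mds_dims = 2L)
  t2 <- build_feature_table(recs, cfg)
  expect_equal(unlist(t2[1, feature_columns(t2)]),
               unlist(t2[2, feature_columns(t2)]), tolerance = 1e-10)
})

test_that("permuting the input order permutes rows but not values", {
  recs <- demo_dataset()$recordings[1:8]
  cfg <- feature_config(mds_dims = 3L)
  t1 <- build_feature_table(recs, cfg)
  t2 <- build_feature_table(rev(recs), cfg)
  t1 <- t1[order(t1$call_id), ]
  t2 <- t2[order(t2$call_id), ]
  expect_equal(unname(as.matrix(t1[feature_columns(t1)])),
               unname(as.matrix(t2[feature_columns(t2)])), tolerance = 1e-8)
})

test_that("extraction failures are propagated with all offending call ids", {
  recs <- demo_dataset()$recordings[1:6]
  recs[[2]] <- make_recording(rnorm(300) / 10, 44100, "bad_a")
  recs[[5]] <- make_recording(rnorm(300) / 10, 44100, "bad_b")
  expect_error(build_feature_table(recs), "2 call\\(s\\)")
  expect_error(build_feature_table(recs), "bad_a")
  expect_error(build_feature_table(recs), "bad_b")
})
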