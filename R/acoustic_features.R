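#' Feature-extraction configuration
#'
#' @param highpass,lowpass analysis band edges in Hz (default 200-4000); all
#'   frequency-valued features are computed inside this band.
#' @param window_length STFT window length in samples (Hanning window).
#' @param overlap fractional window overlap in \[0, 1).
#' @param contour_points number of equally spaced time points the
#'   dominant-frequency contour is resampled to.
#' @param mds_dims number of classical-MDS coordinates appended to the 26
#'   spectral/temporal parameters.
#' @param fir_order order of the linear-phase FIR band-pass filter.
#' @param noise_floor_db frames whose peak power falls more than this many dB
#'   below the clip's maximum are excluded from dominant-frequency tracking.
#' @return object of class `feature_config`.
#' @export
feature_config <- function(highpass = 200, lowpass = 4000,
                           window_length = 512L, overlap = 0.5,
                           contour_points = 20L, mds_dims = 5L,
                           fir_order = 2048L, noise_floor_db = -60) {
  if (highpass >= lowpass) stop("highpass must be below lowpass")
  if (contour_points < 2L) stop("contour_points must be >= 2")
  if (mds_dims < 1L) stop("mds_dims must be >= 1")
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  structure(list(highpass = highpass, lowpass = lowpass,
                 window_length = as.integer(window_length), overlap = overlap,
                 contour_points = as.integer(contour_points),
                 mds_dims = as.integer(mds_dims),
                 fir_order = as.integer(fir_order),
                 noise_floor_db = noise_floor_db),
            class = "feature_config")
}

#' Band-pass filter a call
#'
#' Applies a linear-phase FIR band-pass (Hamming-window design via
#' [signal::fir1()]), with the group delay compensated so the output is
#' time-aligned with the input. At the default order the stop band is
#' attenuated by more than 40 dB while pass-band tones are preserved within
#' 1 dB.
#'
#' @param recording a `call_recording`.
#' @param cfg a [feature_config()].
#' @return the recording with its waveform filtered.
#' @export
bandpass_call <- function(recording, cfg = feature_config()) {
  sr <- recording$sample_rate
  if (cfg$lowpass >= sr / 2)
    stop("lowpass (", cfg$lowpass, " Hz) must be below the Nyquist frequency (",
         sr / 2, " Hz)")
  b <- signal::fir1(cfg$fir_order, c(cfg$highpass, cfg$lowpass) / (sr / 2),
                    type = "pass")
  x <- recording$waveform
  half <- cfg$fir_order / 2
  y <- signal::fftfilt(b, c(x, numeric(cfg$fir_order)))
  recording$waveform <- y[(half + 1):(half + length(x))]
  recording
}

# Hanning-window short-time power spectrum restricted to the analysis band.
# Returns power (band bins x frames), band frequencies, frame-centre times.
stft_power <- function(x, sr, cfg) {
  win <- cfg$window_length
  hop <- max(1L, as.integer(round(win * (1 - cfg$overlap))))
  n <- length(x)
  if (n < 2L * win) return(NULL)                     # caller raises too-short
  starts <- seq(1L, n - win + 1L, by = hop)
  frames <- vapply(starts, function(s) x[s:(s + win - 1L)], numeric(win))
  w <- 0.5 * (1 - cos(2 * pi * seq(0, win - 1) / (win - 1)))  # Hanning
  spec <- stats::mvfft(frames * w)
  nb <- win %/% 2L + 1L
  power <- abs(spec[seq_len(nb), , drop = FALSE])^2
  freq <- (seq_len(nb) - 1) / win * sr
  keep <- freq >= cfg$highpass & freq <= cfg$lowpass
  list(power = power[keep, , drop = FALSE], freq = freq[keep],
       time = (starts - 1 + win / 2) / sr)
}

too_short_error <- function(call_id, dur, need) {
  stop(sprintf("call '%s' too short for analysis (%.3f s < %d windows)",
               if (is.na(call_id)) "<unnamed>" else call_id, dur, need),
       call. = FALSE)
}

#' Names of the 26 spectral/temporal acoustic parameters
#'
#' The registry of band-limited time- and frequency-domain parameters commonly
#' used in bioacoustic repertoire work (warbleR-style): duration; moments and
#' quartiles of the mean frequency spectrum; spectral, temporal and joint
#' entropies; spectral flatness; peak and mean peak frequency; eight
#' dominant-frequency statistics; and three energy-quartile times.
#'
#' @return character vector of length 26.
#' @export
spectral_param_names <- function() {
  c("duration", "meanfreq", "sdfreq", "medianfreq", "q25freq", "q75freq",
    "iqrfreq", "skew", "kurt", "sp_ent", "time_ent", "entropy", "sfm",
    "peakf", "meanpeakf", "meandom", "mindom", "maxdom", "dfrange",
    "startdom", "enddom", "dfslope", "modindx",
    "time_q25", "time_median", "time_q75")
}

# weighted distribution quartile over an ordered grid
grid_quantile <- function(grid, p, q) grid[which(cumsum(p) >= q)[1]]

#' Extract the 26 spectral/temporal parameters from one call
#'
#' All frequency statistics are computed on the Hanning-window mean power
#' spectrum restricted to \[highpass, lowpass\]; temporal statistics use the
#' frame energy envelope; dominant-frequency statistics use the per-frame
#' peak-frequency track over frames above the noise floor. Units: seconds for
#' durations/times, Hz for frequencies, Hz/s for `dfslope`; entropies, flatness
#' and modulation index are unitless.
#'
#' @param recording a band-passed `call_recording` (see [bandpass_call()]).
#' @param cfg a [feature_config()].
#' @return named numeric vector of length 26 (see [spectral_param_names()]).
#' @export
extract_spectral_params <- function(recording, cfg = feature_config()) {
  x <- recording$waveform
  sr <- recording$sample_rate
  duration <- length(x) / sr
  S <- stft_power(x, sr, cfg)
  if (is.null(S) || ncol(S$power) < 2L)
    too_short_error(recording$call_id, duration, 2L)
  f <- S$freq
  s <- rowMeans(S$power)
  if (sum(s) <= 0)
    stop("call '", recording$call_id, "' has no in-band energy", call. = FALSE)
  p <- s / sum(s)

  mu <- sum(p * f)
  sdv <- sqrt(sum(p * (f - mu)^2))
  skew <- if (sdv > 0) sum(p * (f - mu)^3) / sdv^3 else 0
  kurt <- if (sdv > 0) sum(p * (f - mu)^4) / sdv^4 else 0
  q25 <- grid_quantile(f, p, 0.25)
  q50 <- grid_quantile(f, p, 0.50)
  q75 <- grid_quantile(f, p, 0.75)
  nz <- p[p > 0]
  sp_ent <- -sum(nz * log(nz)) / log(length(p))

  et <- colSums(S$power)
  q <- et / sum(et)
  nzq <- q[q > 0]
  time_ent <- if (length(q) > 1) -sum(nzq * log(nzq)) / log(length(q)) else 0
  eps <- max(s) * 1e-12
  sfm <- exp(mean(log(s + eps))) / mean(s + eps)

  peakf <- f[which.max(s)]
  frame_peak <- f[max.col(t(S$power), ties.method = "first")]
  meanpeakf <- mean(frame_peak)

  dom <- dominant_track(S, cfg)
  if (length(dom$freq) < 1L)
    stop("call '", recording$call_id, "' is silent: all frames below the ",
         cfg$noise_floor_db, " dB noise floor", call. = FALSE)
  dfrange <- max(dom$freq) - min(dom$freq)
  binw <- if (length(f) > 1) f[2] - f[1] else 0
  modindx <- if (dfrange > binw) sum(abs(diff(dom$freq))) / dfrange else 0

  c(duration = duration, meanfreq = mu, sdfreq = sdv, medianfreq = q50,
    q25freq = q25, q75freq = q75, iqrfreq = q75 - q25, skew = skew,
    kurt = kurt, sp_ent = sp_ent, time_ent = time_ent,
    entropy = sp_ent * time_ent, sfm = sfm, peakf = peakf,
    meanpeakf = meanpeakf, meandom = mean(dom$freq), mindom = min(dom$freq),
    maxdom = max(dom$freq), dfrange = dfrange,
    startdom = dom$freq[1], enddom = dom$freq[length(dom$freq)],
    dfslope = (dom$freq[length(dom$freq)] - dom$freq[1]) / duration,
    modindx = modindx,
    time_q25 = grid_quantile(S$time, q, 0.25),
    time_median = grid_quantile(S$time, q, 0.50),
    time_q75 = grid_quantile(S$time, q, 0.75))
}

# per-frame peak frequencies over frames above the noise floor
dominant_track <- function(S, cfg) {
  frame_max <- apply(S$power, 2, max)
  top <- max(frame_max)
  keep <- top > 0 & 10 * log10(pmax(frame_max, top * 1e-300) / top) >= cfg$noise_floor_db
  idx <- which(keep)
  list(freq = S$freq[max.col(t(S$power[, idx, drop = FALSE]),
                             ties.method = "first")],
       time = S$time[idx])
}

#' Dominant-frequency contour of a call
#'
#' Tracks the per-frame peak frequency of the band-limited spectrogram
#' (frames below the noise floor excluded) and linearly resamples the track to
#' `cfg$contour_points` equally spaced time points, the fixed-length input to
#' the DTW distance.
#'
#' @param recording a band-passed `call_recording`.
#' @param cfg a [feature_config()].
#' @return numeric vector of length `cfg$contour_points` (Hz).
#' @export
dominant_contour <- function(recording, cfg = feature_config()) {
  S <- stft_power(recording$waveform, recording$sample_rate, cfg)
  if (is.null(S) || ncol(S$power) < 2L)
    too_short_error(recording$call_id, length(recording$waveform) / recording$sample_rate, 2L)
  dom <- dominant_track(S, cfg)
  if (length(dom$freq) == 0L)
    stop("call '", recording$call_id, "' is silent: all frames below the ",
         cfg$noise_floor_db, " dB noise floor", call. = FALSE)
  if (length(dom$freq) == 1L)
    return(rep(dom$freq, cfg$contour_points))
  tt <- seq(min(dom$time), max(dom$time), length.out = cfg$contour_points)
  stats::approx(dom$time, dom$freq, xout = tt)$y
}

#' Build the full 31-column acoustic feature table
#'
#' For every call: band-pass, extract the 26 spectral/temporal parameters and
#' the dominant-frequency contour; then compute the pairwise DTW distance
#' matrix over contours (expressed in kHz, un-normalised) and append the
#' top-`mds_dims` classical-MDS coordinates as additional per-call features.
#'
#' @param recordings list of `call_recording` objects (>= 2, and more than
#'   `cfg$mds_dims`).
#' @param cfg a [feature_config()].
#' @param keep_contours if `TRUE`, the contour matrix and DTW distance matrix
#'   are attached as attributes `"contours"` and `"dtw_distances"`.
#' @return data.frame with columns `call_id`, `original_label` and 31 named
#'   feature columns (26 parameters + `mds1..mds5` by default).
#' @export
build_feature_table <- function(recordings, cfg = feature_config(),
                                keep_contours = FALSE) {
  if (length(recordings) < 2L) stop("need at least 2 recordings")
  if (length(recordings) <= cfg$mds_dims)
    stop("need more recordings than mds_dims = ", cfg$mds_dims)
  failures <- character(0)
  rows <- vector("list", length(recordings))
  contours <- matrix(NA_real_, length(recordings), cfg$contour_points)
  for (i in seq_along(recordings)) {
    rec <- bandpass_call(recordings[[i]], cfg)
    res <- tryCatch(
      list(params = extract_spectral_params(rec, cfg),
           contour = dominant_contour(rec, cfg)),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0(recordings[[i]]$call_id, ": ",
                                     conditionMessage(res)))
    } else {
      rows[[i]] <- res$params
      contours[i, ] <- res$contour
    }
  }
  if (length(failures))
    stop("feature extraction failed for ", length(failures), " call(s):\n  ",
         paste(failures, collapse = "\n  "), call. = FALSE)
  params <- do.call(rbind, rows)
  d <- dtw_distance_matrix(contours / 1000)           # contours in kHz
  mds <- mds_embed(d, dims = cfg$mds_dims)
  out <- data.frame(
    call_id = vapply(recordings, `[[`, character(1), "call_id"),
    original_label = vapply(recordings, `[[`, character(1), "original_label"),
    params, mds, stringsAsFactors = FALSE, row.names = NULL)
  if (anyNA(out[feature_columns(out)]))
    stop("missing values after extraction; offending calls: ",
         paste(out$call_id[!stats::complete.cases(out)], collapse = ", "))
  if (keep_contours) {
    attr(out, "contours") <- contours
    attr(out, "dtw_distances") <- d
  }
  out
}

#' Names of the feature columns of a feature table
#'
#' @param table a feature table from [build_feature_table()].
#' @return character vector of feature column names (everything except
#'   `call_id` and `original_label`).
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("call_id", "original_label"))
}

#' Write / read a feature table as CSV
#'
#' @param table feature table data.frame.
#' @param path CSV path.
#' @return `path` invisibly / the feature table.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
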