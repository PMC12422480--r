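#' Define a synthetic call archetype
#'
#' An archetype is the parametric recipe for one putative call type: a
#' fundamental-frequency contour, a harmonic stack mixed with band-limited
#' noise at a given tonality, a truncated-normal duration, and optional
#' amplitude pulsing (for laughter- or pant-grunt-like calls).
#'
#' @param name call-type label.
#' @param f0_start,f0_end fundamental frequency (Hz) at call onset/offset.
#' @param contour_shape one of `"flat"`, `"rise"`, `"fall"`, `"arch"`,
#'   `"sigmoid"`. `"flat"` holds the mean of `f0_start` and `f0_end`.
#' @param duration_mean,duration_sd call duration distribution (s); draws are
#'   truncated below at 0.02 s.
#' @param tonality fraction of signal energy in the harmonic stack, in
#'   \[0, 1\]; the remainder is band-limited noise.
#' @param n_harmonics number of harmonics (1/h amplitude roll-off).
#' @param noise_band two-vector (low, high) Hz for the noise component.
#' @param pulse_rate amplitude-pulsing rate in Hz, or `NA` for unpulsed calls.
#' @param amplitude_db peak amplitude in dB re full scale (<= 0).
#' @return object of class `call_archetype`.
#' @export
call_archetype <- function(name, f0_start, f0_end,
                           contour_shape = c("flat", "rise", "fall", "arch", "sigmoid"),
                           duration_mean, duration_sd = duration_mean / 8,
                           tonality = 0.8, n_harmonics = 3L,
                           noise_band = c(200, 4000),
                           pulse_rate = NA_real_, amplitude_db = -12) {
  contour_shape <- match.arg(contour_shape)
  a <- structure(
    list(name = as.character(name), f0_start = f0_start, f0_end = f0_end,
         contour_shape = contour_shape, duration_mean = duration_mean,
         duration_sd = duration_sd, tonality = tonality,
         n_harmonics = n_harmonics, noise_band = noise_band,
         pulse_rate = pulse_rate, amplitude_db = amplitude_db),
    class = "call_archetype")
  validate_archetype(a)
  a
}

validate_archetype <- function(a) {
  bad <- function(field, why) stop("invalid archetype parameter '", field, "': ", why,
                                   call. = FALSE)
  if (!nzchar(a$name)) bad("name", "must be a nonempty label")
  if (!is.numeric(a$f0_start) || a$f0_start <= 0) bad("f0_start", "must be > 0 Hz")
  if (!is.numeric(a$f0_end) || a$f0_end <= 0) bad("f0_end", "must be > 0 Hz")
  if (!is.numeric(a$duration_mean) || a$duration_mean <= 0)
    bad("duration_mean", "must be > 0 s")
  if (a$duration_sd < 0) bad("duration_sd", "must be >= 0 s")
  if (a$tonality < 0 || a$tonality > 1) bad("tonality", "must lie in [0, 1]")
  if (a$n_harmonics < 1) bad("n_harmonics", "must be >= 1")
  if (length(a$noise_band) != 2L || a$noise_band[1] >= a$noise_band[2] ||
      a$noise_band[1] <= 0)
    bad("noise_band", "must be (low, high) with 0 < low < high")
  if (!is.na(a$pulse_rate) && a$pulse_rate <= 0) bad("pulse_rate", "must be > 0 Hz")
  if (a$amplitude_db > 0) bad("amplitude_db", "must be <= 0 dBFS")
  invisible(a)
}

#' @export
print.call_archetype <- function(x, ...) {
  cat(sprintf("<call_archetype '%s'> f0 %g->%g Hz (%s), dur %g s, tonality %g\n",
              x$name, x$f0_start, x$f0_end, x$contour_shape,
              x$duration_mean, x$tonality))
  invisible(x)
}

# f0 trajectory on a normalised time grid t in [0,1]
archetype_trajectory <- function(a, t) {
  s <- a$f0_start; e <- a$f0_end
  switch(a$contour_shape,
    flat = rep((s + e) / 2, length(t)),
    rise = s + (e - s) * t,
    fall = s + (e - s) * t,
    arch = s + (e - s) * t + 0.25 * max(s, e) * sin(pi * t),
    sigmoid = s + (e - s) / (1 + exp(-10 * (t - 0.5))))
}

# Resolve an archetype into the flat "effective parameter" list that the
# gradedness knob interpolates. The f0 trajectory is sampled on a fixed
# 64-point grid so trajectories (and hence contour shapes) blend too.
TRAJ_GRID <- seq(0, 1, length.out = 64L)

effective_params <- function(a, fallback_pulse_rate = 30) {
  list(name = a$name,
       traj = archetype_trajectory(a, TRAJ_GRID),
       duration_mean = a$duration_mean, duration_sd = a$duration_sd,
       tonality = a$tonality, n_harmonics = as.numeric(a$n_harmonics),
       noise_lo = a$noise_band[1], noise_hi = a$noise_band[2],
       pulse_rate = if (is.na(a$pulse_rate)) fallback_pulse_rate else a$pulse_rate,
       pulse_depth = if (is.na(a$pulse_rate)) 0 else 0.9,
       amplitude_db = a$amplitude_db)
}

# p_i(lambda) = (1 - lambda) p_i + lambda p_bar, applied to every effective
# parameter including the trajectory, so lambda = 1 collapses all classes.
blend_params <- function(params, lambda) {
  if (lambda == 0) return(params)
  num_fields <- setdiff(names(params[[1]]), "name")
  bar <- lapply(num_fields, function(f)
    Reduce(`+`, lapply(params, `[[`, f)) / length(params))
  names(bar) <- num_fields
  lapply(params, function(p) {
    for (f in num_fields) p[[f]] <- (1 - lambda) * p[[f]] + lambda * bar[[f]]
    p
  })
}

# run expr under a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# band-limit white noise with an FFT mask (generation only; the analysis
# band-pass in bandpass_call() is an FIR filter)
band_noise <- function(n, sr, lo, hi) {
  m <- stats::nextn(n, c(2, 3, 5))         # composite length keeps the FFT fast
  x <- stats::rnorm(m)
  X <- stats::fft(x)
  f <- (seq_len(m) - 1) / m * sr
  f <- pmin(f, sr - f)                     # two-sided frequency axis
  X[f < lo | f > hi] <- 0
  Re(stats::fft(X, inverse = TRUE))[seq_len(n)] / m
}

synthesize_from_params <- function(p, jitter_seed, sample_rate = 44100,
                                   f0_scale = 1, dur_scale = 1, snr_db = Inf) {
  with_seed(jitter_seed, {
    dur <- -1
    while (dur <= 0.02)
      dur <- stats::rnorm(1, p$duration_mean * dur_scale, p$duration_sd * dur_scale)
    n <- max(round(dur * sample_rate), round(0.02 * sample_rate) + 1L)
    tt <- seq(0, 1, length.out = n)
    f0 <- stats::approx(TRAJ_GRID, p$traj, xout = tt)$y * f0_scale
    phase <- 2 * pi * cumsum(f0) / sample_rate
    nh <- max(p$n_harmonics, 1)
    harm <- numeric(n)
    for (h in seq_len(ceiling(nh))) {
      w <- if (h <= floor(nh)) 1 else nh - floor(nh)   # fractional last harmonic
      harm <- harm + (w / h) * sin(h * phase)
    }
    noise <- band_noise(n, sample_rate, p$noise_lo, p$noise_hi)
    unit <- function(x) if (stats::sd(x) > 0) x / sqrt(mean(x^2)) else x
    x <- sqrt(p$tonality) * unit(harm) + sqrt(1 - p$tonality) * unit(noise)
    if (p$pulse_depth > 0) {
      tsec <- (seq_len(n) - 1) / sample_rate
      x <- x * ((1 - p$pulse_depth) + p$pulse_depth *
                  0.5 * (1 + cos(2 * pi * p$pulse_rate * tsec)))
    }
    if (is.finite(snr_db)) {
      bg <- band_noise(n, sample_rate, 100, min(6000, sample_rate / 2 * 0.9))
      x <- unit(x) + unit(bg) * 10^(-snr_db / 20)
    }
    nf <- min(round(0.005 * sample_rate), floor(n / 2))   # 5 ms raised-cosine fades
    if (nf > 0) {
      ramp <- 0.5 * (1 - cos(pi * seq_len(nf) / nf))
      x[seq_len(nf)] <- x[seq_len(nf)] * ramp
      x[n - nf + seq_len(nf)] <- x[n - nf + seq_len(nf)] * rev(ramp)
    }
    x <- x / max(abs(x)) * 10^(p$amplitude_db / 20)
    round(x * 32767) / 32767     # snap to the 16-bit grid: WAV round-trip exact
  })
}

#' Synthesise one call from an archetype
#'
#' Deterministic given (`archetype`, `jitter_seed`): the duration draw, noise
#' and phases all come from a private RNG stream seeded with `jitter_seed`.
#' The waveform is quantised to the 16-bit grid so in-memory samples equal a
#' WAV write/read round trip exactly.
#'
#' @param archetype a [call_archetype()].
#' @param jitter_seed integer seed for this call's randomness.
#' @param sample_rate sampling rate, Hz.
#' @param f0_scale,dur_scale multiplicative per-caller jitter on fundamental
#'   frequency and duration (1 = none).
#' @param snr_db signal-to-background-noise ratio in dB; `Inf` adds none.
#' @return object of class `call_recording`: list with `call_id`, `waveform`,
#'   `sample_rate`, `caller_id`, `community`, `date`, `original_label`.
#' @export
synthesize_call <- function(archetype, jitter_seed, sample_rate = 44100,
                            f0_scale = 1, dur_scale = 1, snr_db = Inf) {
  validate_archetype(archetype)
  p <- effective_params(archetype)
  w <- synthesize_from_params(p, jitter_seed, sample_rate, f0_scale, dur_scale, snr_db)
  new_call_recording(waveform = w, sample_rate = sample_rate,
                     original_label = archetype$name)
}

new_call_recording <- function(waveform, sample_rate, call_id = NA_character_,
                               caller_id = NA_character_, community = NA_character_,
                               date = NA_character_, original_label = NA_character_) {
  stopifnot(length(waveform) > 0, sample_rate > 0)
  structure(list(call_id = call_id, waveform = waveform,
                 sample_rate = sample_rate, caller_id = caller_id,
                 community = community, date = date,
                 original_label = original_label),
            class = "call_recording")
}

#' @export
print.call_recording <- function(x, ...) {
  cat(sprintf("<call_recording %s> %.3f s @ %d Hz, label '%s', caller %s\n",
              x$call_id, length(x$waveform) / x$sample_rate,
              as.integer(x$sample_rate), x$original_label, x$caller_id))
  invisible(x)
}

#' Specify a synthetic call dataset
#'
#' Bundles archetypes with class sizes, the gradedness knob, per-caller
#' variation and noise level. `gradedness = 0` leaves archetypes as defined;
#' `gradedness = 1` collapses every archetype's effective parameters
#' (including the f0 trajectory) onto their grand mean, making classes
#' exchangeable up to noise.
#'
#' @param archetypes list of [call_archetype()] objects.
#' @param n_per_class integer vector of class sizes, same length and order as
#'   `archetypes` (may be unbalanced).
#' @param gradedness lambda in \[0, 1\].
#' @param individual_effects sdlog of the per-caller log-normal multiplicative
#'   jitter on f0 and duration.
#' @param snr_db signal-to-background-noise ratio, dB.
#' @param n_callers number of distinct callers shared across call types.
#' @param sample_rate,bit_depth output audio format (16-bit PCM only).
#' @param seed integer master seed; identical spec + seed gives bit-identical
#'   audio and metadata.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(archetypes, n_per_class, gradedness = 0,
                           individual_effects = 0.05, snr_db = 25,
                           n_callers = 12L, sample_rate = 44100,
                           bit_depth = 16L, seed = 1L) {
  if (length(n_per_class) != length(archetypes))
    stop("n_per_class has length ", length(n_per_class),
         " but there are ", length(archetypes), " archetypes")
  lapply(archetypes, validate_archetype)
  if (gradedness < 0 || gradedness > 1) stop("gradedness must lie in [0, 1]")
  if (any(n_per_class < 1)) stop("every class needs n >= 1")
  structure(list(archetypes = archetypes,
                 n_per_class = as.integer(n_per_class),
                 gradedness = gradedness,
                 individual_effects = individual_effects,
                 snr_db = snr_db, n_callers = as.integer(n_callers),
                 sample_rate = sample_rate, bit_depth = as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a labelled synthetic call dataset
#'
#' Draws every call from its (gradedness-blended) archetype with per-caller
#' multiplicative jitter and background noise, entirely determined by
#' `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir optional directory; when given, one WAV per call plus a
#'   `metadata.csv` (columns call_id, file, caller_id, community, date,
#'   original_label) are written there.
#' @return list with `recordings` (list of `call_recording`) and `metadata`
#'   (data.frame, one row per call).
#' @export
generate_dataset <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  params <- blend_params(lapply(spec$archetypes, effective_params),
                         spec$gradedness)
  labels <- vapply(spec$archetypes, `[[`, character(1), "name")
  n_total <- sum(spec$n_per_class)
  communities <- c("Kokoalongo", "Ekalakala", "Fekako", "Luikotale")

  plan <- with_seed(spec$seed, {
    caller_f0 <- stats::rlnorm(spec$n_callers, 0, spec$individual_effects)
    caller_dur <- stats::rlnorm(spec$n_callers, 0, spec$individual_effects)
    caller_comm <- sample(communities, spec$n_callers, replace = TRUE)
    list(caller_f0 = caller_f0, caller_dur = caller_dur,
         caller_comm = caller_comm,
         caller_of = sample.int(spec$n_callers, n_total, replace = TRUE),
         jitter_seeds = sample.int(.Machine$integer.max - 1L, n_total),
         dates = format(as.Date("2021-01-01") +
                          sample.int(720L, n_total, replace = TRUE), "%Y-%m-%d"))
  })

  recordings <- vector("list", n_total)
  meta <- vector("list", n_total)
  idx <- 0L
  for (k in seq_along(params)) {
    for (j in seq_len(spec$n_per_class[k])) {
      idx <- idx + 1L
      cid <- plan$caller_of[idx]
      w <- synthesize_from_params(params[[k]], plan$jitter_seeds[idx],
                                  sample_rate = spec$sample_rate,
                                  f0_scale = plan$caller_f0[cid],
                                  dur_scale = plan$caller_dur[cid],
                                  snr_db = spec$snr_db)
      call_id <- sprintf("call_%04d", idx)
      recordings[[idx]] <- new_call_recording(
        waveform = w, sample_rate = spec$sample_rate, call_id = call_id,
        caller_id = sprintf("ID%02d", cid),
        community = plan$caller_comm[cid], date = plan$dates[idx],
        original_label = labels[k])
      meta[[idx]] <- data.frame(
        call_id = call_id, file = paste0(call_id, ".wav"),
        caller_id = sprintf("ID%02d", cid), community = plan$caller_comm[cid],
        date = plan$dates[idx], original_label = labels[k],
        stringsAsFactors = FALSE)
    }
  }
  metadata <- do.call(rbind, meta)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (r in recordings)
      write_wav(r$waveform, file.path(out_dir, paste0(r$call_id, ".wav")),
                sample_rate = spec$sample_rate)
    utils::write.csv(metadata, file.path(out_dir, "metadata.csv"),
                     row.names = FALSE)
  }
  list(recordings = recordings, metadata = metadata)
}

#' Load a call dataset from a directory of WAV files plus metadata CSV
#'
#' @param dir directory containing `metadata.csv` and the WAV files it lists.
#' @return same shape as [generate_dataset()].
#' @export
read_dataset <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) stop("no metadata.csv under ", dir)
  metadata <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  recordings <- lapply(seq_len(nrow(metadata)), function(i) {
    wav <- read_wav(file.path(dir, metadata$file[i]))
    new_call_recording(waveform = wav$waveform, sample_rate = wav$sample_rate,
                       call_id = metadata$call_id[i],
                       caller_id = metadata$caller_id[i],
                       community = metadata$community[i],
                       date = metadata$date[i],
                       original_label = metadata$original_label[i])
  })
  list(recordings = recordings, metadata = metadata)
}

#' Default archetype set: fifteen bonobo-like putative call types
#'
#' Fifteen synthetic-generator conventions named after the putative call types
#' of the wild-bonobo repertoire (tonal hoots, noisy screams and barks, pulsed
#' laughter and pant grunts, low grunts). All numbers are generator
#' conventions chosen to give graded acoustic overlap inside the 200-4000 Hz
#' analysis band; they are not field measurements. The four bark variants are
#' deliberately placed near the high hoot to emulate their known confusability.
#'
#' @return named list of 15 [call_archetype()] objects.
#' @export
bonobo_archetypes <- function() {
  a <- list(
    call_archetype("high_hoot",    600, 900,  "arch",    0.45, 0.06, 0.90, 4),
    call_archetype("scream",      1400, 2000, "rise",    0.60, 0.10, 0.45, 3,
                   noise_band = c(800, 4000)),
    call_archetype("grunt",        260, 240,  "fall",    0.22, 0.04, 0.50, 6,
                   noise_band = c(200, 1500)),
    call_archetype("peep",        1150, 1250, "rise",    0.12, 0.02, 0.95, 2),
    call_archetype("laughter",     420, 380,  "flat",    0.80, 0.15, 0.30, 4,
                   noise_band = c(200, 2500), pulse_rate = 14),
    call_archetype("low_hoot",     520, 310,  "fall",    0.55, 0.08, 0.85, 5),
    call_archetype("whistle",     2100, 2400, "arch",    0.50, 0.08, 0.98, 1),
    call_archetype("contest_hoot", 700, 1500, "sigmoid", 0.65, 0.10, 0.80, 3),
    call_archetype("pant_grunt",   320, 300,  "flat",    0.50, 0.08, 0.40, 5,
                   noise_band = c(200, 2000), pulse_rate = 8),
    call_archetype("yelp",         800, 1400, "rise",    0.15, 0.03, 0.70, 3),
    call_archetype("peep_yelp",   1000, 1350, "rise",    0.13, 0.025, 0.85, 2),
    call_archetype("scream_bark", 1100, 800,  "fall",    0.30, 0.05, 0.45, 3,
                   noise_band = c(500, 4000)),
    call_archetype("wieew_bark",   900, 650,  "sigmoid", 0.35, 0.06, 0.60, 3),
    call_archetype("bark",         750, 620,  "fall",    0.20, 0.04, 0.50, 4,
                   noise_band = c(300, 3500)),
    call_archetype("soft_bark",    680, 610,  "fall",    0.18, 0.035, 0.60, 3,
                   amplitude_db = -20))
  names(a) <- vapply(a, `[[`, character(1), "name")
  a
}

#' Class sizes of the fifteen putative call types
#'
#' Row sums of the published confusion matrix over the putative repertoire
#' (1506 calls), used as default unbalanced class sizes for SUNG-scale
#' synthetic datasets (Small, Unbalanced, Noisy, but Genuine).
#'
#' @return named integer vector of 15 class sizes.
#' @export
repertoire_class_sizes <- function() {
  cm <- published_confusion()
  stats::setNames(as.integer(rowSums(cm$counts)), cm$labels)
}
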