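#' Visualization configuration
#'
#' @param tsne_perplexity t-SNE perplexity (must satisfy
#'   `3 * perplexity < n` for n calls).
#' @param tsne_seed integer seed for the embedding.
#' @param spectro_floor_db minimum level (dB re spectrogram maximum) rendered;
#'   pixels below the floor are blank.
#' @param margin_s silent margin (s) added at both ends of spectrograms.
#' @return object of class `viz_config`.
#' @export
viz_config <- function(tsne_perplexity = 30, tsne_seed = 1L,
                       spectro_floor_db = -30, margin_s = 0.05) {
  if (tsne_perplexity <= 1) stop("tsne_perplexity must exceed 1")
  structure(list(tsne_perplexity = tsne_perplexity,
                 tsne_seed = as.integer(tsne_seed),
                 spectro_floor_db = spectro_floor_db, margin_s = margin_s),
            class = "viz_config")
}

#' t-SNE embedding of a feature table
#'
#' Features are standardised (zero mean, unit variance; zero-variance columns
#' dropped) before embedding. Deterministic under `cfg$tsne_seed`.
#'
#' @param table feature table.
#' @param cfg a [viz_config()].
#' @return n x 2 matrix of embedding coordinates (columns `tsne1`, `tsne2`).
#' @export
tsne_embed <- function(table, cfg = viz_config()) {
  if (!requireNamespace("Rtsne", quietly = TRUE))
    stop("tsne_embed requires the Rtsne package")
  feats <- feature_columns(table)
  x <- as.matrix(table[feats])
  n <- nrow(x)
  if (n < 3 * cfg$tsne_perplexity + 2)
    stop("too few calls (", n, ") for perplexity ", cfg$tsne_perplexity,
         "; try perplexity <= ", floor((n - 2) / 3))
  keep <- apply(x, 2, stats::sd) > 0
  x <- scale(x[, keep, drop = FALSE])
  emb <- with_seed(cfg$tsne_seed,
                   Rtsne::Rtsne(x, perplexity = cfg$tsne_perplexity,
                                check_duplicates = FALSE, pca = TRUE,
                                num_threads = 1L))
  coords <- emb$Y
  dimnames(coords) <- list(table$call_id, c("tsne1", "tsne2"))
  coords
}

#' Scatter plot of a t-SNE embedding coloured by call type
#'
#' @param coords n x 2 matrix from [tsne_embed()].
#' @param labels call-type label per row.
#' @param path PNG output path.
#' @return `path` invisibly.
#' @export
plot_tsne <- function(coords, labels, path) {
  labels <- factor(labels)
  grDevices::png(path, width = 900, height = 700)
  on.exit(grDevices::dev.off())
  pal <- grDevices::hcl.colors(max(nlevels(labels), 3L), "Dark 3")
  graphics::plot(coords, col = pal[as.integer(labels)], pch = 19, cex = 0.8,
                 xlab = "t-SNE 1", ylab = "t-SNE 2",
                 main = "Acoustic similarity of calls (t-SNE)")
  graphics::legend("topright", legend = levels(labels),
                   col = pal[seq_len(nlevels(labels))], pch = 19, cex = 0.8)
  invisible(path)
}

#' Render a call spectrogram with descriptive statistics
#'
#' Hanning-window spectrogram with a dB floor (pixels below it are blank) and
#' silent margins at both ends. The descriptive statistics (duration; peak,
#' dominant and mean frequency) come from [extract_spectral_params()] so the
#' figure and the feature table share a single source of truth.
#'
#' @param recording a `call_recording`.
#' @param cfg a [viz_config()].
#' @param fcfg the [feature_config()] used for the statistics.
#' @param path optional PNG path; when `NULL` nothing is drawn.
#' @return (invisibly) list with `db` (dB matrix, `NA` below the floor),
#'   `freq`, `time`, and `stats` (duration_s, peakf_hz, meandom_hz,
#'   meanfreq_hz).
#' @export
render_spectrogram <- function(recording, cfg = viz_config(),
                               fcfg = feature_config(), path = NULL) {
  sr <- recording$sample_rate
  pad <- numeric(round(cfg$margin_s * sr))
  x <- c(pad, recording$waveform, pad)
  full <- feature_config(highpass = 0.001, lowpass = sr / 2 - 1,
                         window_length = fcfg$window_length,
                         overlap = fcfg$overlap)
  S <- stft_power(x, sr, full)
  if (is.null(S)) too_short_error(recording$call_id, length(x) / sr, 2L)
  db <- 10 * log10(pmax(S$power, max(S$power) * 1e-300) / max(S$power))
  db[db < cfg$spectro_floor_db] <- NA_real_
  p <- extract_spectral_params(bandpass_call(recording, fcfg), fcfg)
  stats <- c(duration_s = unname(p["duration"]), peakf_hz = unname(p["peakf"]),
             meandom_hz = unname(p["meandom"]), meanfreq_hz = unname(p["meanfreq"]))
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 500)
    on.exit(grDevices::dev.off())
    graphics::image(S$time, S$freq, t(db),
                    col = grDevices::hcl.colors(64, "Inferno"),
                    xlab = "Time (s)", ylab = "Frequency (Hz)",
                    main = sprintf("%s (%s)", recording$call_id,
                                   recording$original_label))
  }
  invisible(list(db = db, freq = S$freq, time = S$time, stats = stats))
}

#' Per-call-type acoustic summary (mean and range)
#'
#' Mirrors the descriptive fields of a repertoire catalogue: per call type,
#' mean and range of duration, peak frequency, mean dominant frequency and
#' mean frequency.
#'
#' @param table feature table (post-mapping labels give the final repertoire).
#' @return data.frame, one row per call type.
#' @export
call_type_stats <- function(table) {
  stat_cols <- c("duration", "peakf", "meandom", "meanfreq")
  out <- lapply(split(table, table$original_label), function(g) {
    v <- lapply(stat_cols, function(cn)
      c(mean = mean(g[[cn]]), min = min(g[[cn]]), max = max(g[[cn]])))
    data.frame(call_type = g$original_label[1], n = nrow(g),
               t(stats::setNames(unlist(v),
                 paste(rep(stat_cols, each = 3), c("mean", "min", "max"),
                       sep = "_"))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
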