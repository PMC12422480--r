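# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# three well-separated archetypes spanning the analysis band
test_archetypes <- function() {
  list(call_archetype("hoot",    500, 700,  "arch", 0.40, 0.05, 0.9, 4),
       call_archetype("whistle", 2200, 2500, "arch", 0.45, 0.06, 0.98, 1),
       call_archetype("grunt",   260, 240,  "fall", 0.25, 0.04, 0.5, 6,
                      noise_band = c(200, 1500)))
}

demo_dataset <- function() {
  if (is.null(.fixtures$ds))
    .fixtures$ds <- generate_dataset(
      synthetic_spec(test_archetypes(), c(15L, 15L, 15L), seed = 7L))
  .fixtures$ds
}

demo_features <- function() {
  if (is.null(.fixtures$tab))
    .fixtures$tab <- build_feature_table(demo_dataset()$recordings)
  .fixtures$tab
}

demo_clean <- function() {
  if (is.null(.fixtures$cl))
    .fixtures$cl <- suppressWarnings(replace_outliers(demo_features()))
  .fixtures$cl
}

# bare call_recording without going through the generator
make_recording <- function(waveform, sample_rate = 44100,
                           call_id = "test_call", label = "test") {
  structure(list(call_id = call_id, waveform = waveform,
                 sample_rate = sample_rate, caller_id = NA_character_,
                 community = NA_character_, date = NA_character_,
                 original_label = label),
            class = "call_recording")
}

tone_recording <- function(freq = 1000, dur = 0.5, sr = 44100, id = "tone") {
  make_recording(0.5 * sin(2 * pi * freq * seq(0, dur, by = 1 / sr)), sr, id)
}

# fft frequency-bin width of the default analysis window
default_binwidth <- function(sr = 44100) sr / feature_config()$window_length
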