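---
title: "Resolving a vocal repertoire from call acoustics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving a vocal repertoire from call acoustics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Field repertoires of graded vocal systems — bonobos being the motivating case —
are traditionally carved up by ear and eye. `vocrep` implements the
quantitative alternative: measure every call, train a supervised classifier on
the putative call-type labels, and let the *confusion structure* of the
classifier decide which putative types are acoustically discriminable and
which should be merged. The package covers the whole chain:

1. **Acoustic features.** Each call is band-passed to 200–4000 Hz and reduced
   to 31 numbers: 26 spectral/temporal parameters plus the first five
   classical-MDS coordinates of a dynamic-time-warping (DTW) distance matrix
   over dominant-frequency contours.
2. **Feature hygiene.** Per parameter, values with |z| > 3.29 are replaced by
   the parameter's median (one pass).
3. **Classification.** A 1000-tree random forest with mtry = floor(sqrt(31)) = 5
   and per-call weights proportional to the inverse of the class's relative
   frequency; every call receives an out-of-bag (OOB) prediction. Overall
   agreement is tested against the chance level 1/k with an exact two-tailed
   binomial test.
4. **Repertoire resolution.** A call type is retained iff the diagonal of its
   confusion-matrix row is the strict row maximum (the classifier assigned a
   plurality of its calls to their own label); otherwise all its calls are
   relabelled to the modal predicted type.
5. **Reporting.** t-SNE embedding of the standardized features, per-type
   spectrograms and descriptive statistics.

Because no public recordings accompany the motivating dataset, the package
also ships a **synthetic call generator** whose outputs exercise every stage,
so the pipeline's statistical behaviour can be validated end to end at desk
scale.

# The feature set

The 26 parameters (see `spectral_param_names()`) are the warbleR-style set in
common bioacoustic use, all computed inside the analysis band:

* `duration` (s); moments of the mean power spectrum: `meanfreq`, `sdfreq`,
  `skew`, `kurt` (Hz and unitless); spectral quartiles `medianfreq`,
  `q25freq`, `q75freq`, `iqrfreq` (Hz);
* `sp_ent`, `time_ent`, `entropy` (spectral, temporal and joint Wiener-style
  entropies, each normalised to [0, 1]; the joint entropy is their product),
  `sfm` (spectral flatness);
* `peakf` (argmax of the mean spectrum), `meanpeakf` (mean of per-frame peak
  frequencies over *all* frames);
* dominant-frequency statistics over frames above the noise floor: `meandom`,
  `mindom`, `maxdom`, `dfrange`, `startdom`, `enddom`, `dfslope` (Hz/s),
  `modindx` (cumulative |change| / range; defined as 0 when the range is below
  one frequency bin);
* energy-quartile times `time_q25`, `time_median`, `time_q75` (s from onset).

Numerical conventions worth knowing:

* **Spectrogram frames**: 512-sample Hanning windows with 50 % overlap at
  44.1 kHz (86.1 Hz bins, ~5.8 ms hops). Frequency-valued features are
  therefore only resolved to one bin, and tests use one-bin tolerances.
* **Noise floor**: frames whose peak power is more than 60 dB below the clip
  maximum are excluded from dominant-frequency tracking; a clip with no frame
  above the floor is a hard error, never a silent NA.
* **Band-pass**: a linear-phase FIR (Hamming-window design, order 2048) with
  group delay compensated. At this order the stop band is ≥ 40 dB down while
  pass-band tones are preserved within 1 dB; both contracts are tested, along
  with agreement against a brick-wall FFT-mask oracle away from the
  transition bands.
* **Degenerate spectra**: a zero-variance spectrum sets skew and kurtosis to
  0 rather than NaN; flatness uses a relative epsilon.

## DTW and MDS

Dominant-frequency contours are linearly resampled to 20 points (time
normalisation; the length is a package convention). DTW uses the symmetric
step pattern with absolute-difference cost and no warping window, computed in
C++; contours enter in kHz and are deliberately **not** z-normalised, so
register differences between call types remain informative. The test suite
checks the C++ kernel exhaustively against a plain R dynamic program on all
contours of length ≤ 5 over {1, 2, 3} and against a recursive enumeration of
warping paths on tiny cases.

Classical (Torgerson) MDS double-centers the squared distance matrix and
eigendecomposes it; coordinates are eigenvectors scaled by the square root of
their eigenvalues. Two conventions make the output reproducible:

* axes are oriented so each axis's largest-magnitude coordinate is positive
  (eigenvector sign is otherwise arbitrary);
* if fewer than five positive eigenvalues exist, the deficient axes are
  zero-filled with a warning rather than silently dropped.

When the distance matrix is Euclidean with intrinsic dimension ≤ 5 the
embedding reproduces the distances to floating-point accuracy, which the
suite asserts; `stats::cmdscale` serves as an independent oracle.

# Outlier hygiene

The z-score rule is applied **globally** per parameter (not per type or
caller), in a **single pass**, with z computed once from the raw column and
the replacement value being the raw column median — the most literal reading
of the procedure it reimplements. 3.29 corresponds to the two-sided 0.001
normal tail. Two caveats that the tests document:

* The rule is not idempotent in general: replacing an extreme value shrinks
  the column SD, which can expose milder values on a second pass. On
  representative extraction output a second pass replaces no more values than
  the first, and the suite asserts exactly that; a constructed
  counterexample exists and is noted in the test.
* Under extreme class imbalance (a 10:100 two-class problem) the global rule
  can replace *genuine* values of the rare class, because they are outliers
  of the pooled column. With a dozen or more types of moderate imbalance this
  does not arise, but it is the main reason the hygiene stage is a separate,
  inspectable step (`replace_outliers()` returns a per-parameter report).

# The weighted forest and its OOB surface

Weights are `w_i = N / (k · n_class(i))` — proportional to the inverse of the
class's relative frequency, normalised to mean 1, giving a 10× rare:common
ratio at 10:100. The default applies them as **bootstrap sampling weights**
(`ranger::ranger(case.weights = ...)`), i.e. rare calls are literally
oversampled into the trees; a `weighting = "class"` switch applies them in
the splitting rule instead, and `"none"` fits an unweighted baseline.

OOB votes are aggregated from the kept in-bag counts rather than taken from
the fitted object, so the per-call majority is under explicit control: ties
are broken by the class with the larger total weight, then lexicographically.
One consequence of sampling-weight oversampling is worth stating: heavily
upweighted calls are in-bag in most trees, so their OOB predictions rest on
few trees (and a call in-bag everywhere falls back, with a warning, to the
all-tree majority). This is intrinsic to the "oversampling" reading of class
weighting, not an implementation accident.

The chance test is `stats::binom.test` (exact, two-tailed by the
minimum-likelihood method) of the confusion-matrix trace against 1/k; the
suite checks it against direct enumeration for n ≤ 12. Variable importance is
ranger's permutation importance (mean decrease in accuracy).

# The plurality rule

Retention requires the diagonal to be the *strict* row maximum. Edge cases
are resolved conservatively and recorded in the mapping's notes:

* a tie that includes the diagonal retains the type;
* a tie among off-diagonal maxima targets the lexicographically first label;
* a chain (A merged into B, B itself merged into C) is followed transitively
  to a retained type;
* a cycle among non-retained types is merged into the member with the largest
  row sum.

The suite verifies on all 19 683 3×3 count matrices with entries in {0, 1, 2}
that resolution terminates, the retained set is nonempty, and every target is
retained. Resolution is single-pass from one confusion matrix — there is no
retraining after a merge — with an optional `iterate = TRUE` fixed-point mode
that is off by default.

**A structural property users should know.** If two classes are *exactly*
exchangeable and balanced, their mutual confusion is symmetric and each row
keeps a weak plurality roughly half the time, so a merge of "perfect twins"
is a coin flip — not a defect of the rule, but a regime where no plurality
signal exists. Coherent absorption of one type into another (the behaviour
the rule is designed to detect) arises when the classes are *unbalanced*:
the larger class's greater diversity wins the overlap region even under
inverse-frequency weighting. The end-to-end twin test therefore duplicates an
archetype under two unbalanced labels (60 vs 20 calls), the realistic
field situation, and the rare twin is absorbed reliably.

# What the synthetic generator does and does not emulate

`call_archetype()` defines a call type by an f0 contour (flat / rise / fall /
arch / sigmoid between `f0_start` and `f0_end`), a 1/h harmonic stack, a
tonality (harmonic fraction of signal energy) against band-limited noise, a
truncated-normal duration (floor 0.02 s), optional amplitude pulsing, and a
peak level in dBFS. Calls are rendered at 44.1 kHz, mixed with broadband
background noise at `snr_db` (default 25 dB), given 5 ms raised-cosine fades,
and quantised to the 16-bit grid so in-memory waveforms equal their WAV
round trip bit for bit. All randomness derives from the dataset seed;
identical spec + seed gives byte-identical WAV files.

Design choices made where the design was open:

* **Gradedness** is a single knob λ: every archetype's *effective parameter
  set* — including the f0 trajectory sampled on a fixed 64-point grid and
  the pulse depth — is interpolated toward the grand mean,
  p(λ) = (1 − λ)·p + λ·p̄. Interpolating only scalar means would leave
  contour shape and pulsing as residual class signal, so λ = 1 would not
  actually make classes exchangeable; blending the trajectory makes the λ = 1
  limit exact (verified: OOB accuracy sits at chance, and accuracy is
  non-increasing in λ).
* **Per-caller variation** is a multiplicative log-normal jitter on f0 and
  duration (sdlog 0.05 by default, i.e. ~5 % individual signatures), with a
  pool of callers shared across call types — the simplest individual
  signature that still supports future caller-ID work.
* **Default archetypes**: `bonobo_archetypes()` ships fifteen conventions
  named after the putative bonobo call types (tonal hoots, noisy screams and
  barks, pulsed laughter and pant grunts, low grunts), with the four bark
  variants placed acoustically near the high hoot to emulate their known
  confusability. The numbers are generator conventions, not field
  measurements. `repertoire_class_sizes()` supplies the published unbalanced
  class sizes (29–284 calls, 1506 total) for SUNG-scale runs (Small,
  Unbalanced, Noisy, but Genuine).

The generator does **not** attempt acoustically faithful bonobo synthesis,
call combinations, chorusing/overlap, reverberation, or distance-dependent
attenuation. Passing tests therefore demonstrate that the *pipeline* behaves
correctly on data with known structure — class recovery when classes are
separable, collapse to chance when they are not, absorption of duplicated
types — and say nothing about how well any real repertoire resolves.

# Problem sizes and seeds used by the test suite

Synthetic checks run at desk scale, chosen as the smallest sizes at which the
statistical assertions are stable: 3-type demo datasets of 12–20 calls per
class for unit tests; parameter recovery with 5 well-separated archetypes ×
40 calls over 10 dataset seeds (retention of all five types and OOB accuracy
≥ 0.9 required in ≥ 9/10); unbalanced twins 60/20 over 10 seeds; permutation
nulls pooled over 10 seeds and compared with a central 99 % binomial band
around 1/k. All dataset and forest seeds are fixed in the tests, so the suite
is deterministic.

# Known limitations

* The 26-parameter registry follows the common warbleR-style definitions by
  name; other toolchains define e.g. entropies or `meanpeakf` with different
  normalisations, so absolute feature values are comparable only within this
  package.
* Dominant-frequency contours track the per-frame spectral peak, not the
  fundamental; for calls whose energy maximum moves between harmonics the
  contour can jump by an octave. DTW in kHz is robust to occasional jumps but
  the contours should not be read as pitch tracks.
* OOB error is an internal generalisation estimate; with few calls per type
  its per-class errors are noisy, and the plurality rule inherits that noise.
  The published-matrix reproduction in the tests is exact because the matrix
  is fixed; synthetic reproductions are asserted over seeds for this reason.
* t-SNE coordinates are for visual inspection only (perplexity 30 by default,
  standardized features, fixed seed); they enter no decision.
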