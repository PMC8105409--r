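---
title: "Vocal states, balanced imitation, and how finchsong measures them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vocal states, balanced imitation, and how finchsong measures them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the measurement
model, the tunable parameters and why their defaults are what they are,
what the synthetic-song generator does and does not emulate, and the
numerical choices made where the underlying literature leaves the
algorithm open.

## The measurement model

Zebra finch song imitation is usually scored at the syllable level, but
pupils recombine syllables freely — fusing several tutor syllables into
one, or splitting one into several — so syllable-type inventories are
unstable across a tutor–pupil pair even when the acoustic material is
copied accurately. `finchsong` therefore measures song at the
**sub-syllabic** level. Each recording is reduced to a dense sequence of
short-window acoustic feature vectors; each voiced window is assigned to
one of ten population-level **vocal states**; and a bird's song is
summarised by its state **abundance vector** `p = (p1..p10)`, whose
Shannon entropy (bits) is the bird's **song diversity**. Imitation is
then studied through (a) asymmetric acoustic similarity between songs
and (b) the statistical relationship between tutor and pupil abundance
vectors.

Assumptions worth keeping in mind: inputs are curated song bouts (no
calls, cage noise, or overlapping birds); the state partition is
population-level by construction, never per bird; and the amplitude
scale is uncalibrated, so voicing is defined relative to a configurable
baseline rather than in physical dB SPL.

## Feature extraction (`compute_features`)

Windows are 10 ms long and advance in 1 ms steps (`window_ms`,
`step_ms`), Hann-tapered, with a single FFT per window; spectra are
restricted to 300–8600 Hz (`band_hz`), the zebra finch song band, so
low-frequency room noise cannot dominate the spectral statistics.
Amplitude is reported on a scale where a full-scale sinusoid reads
`baseline_db` (70 dB); windows at or above `threshold_db` (50 dB) are
voiced, everything else is treated as silence and excluded from further
analysis.

Per window the track records:

* **Pitch** (Hz). Normalised autocorrelation of the windowed signal,
  searched over 300–3000 Hz (`pitch_range_hz`), taking the smallest lag
  whose peak is within 90 % of the global maximum (octave guard) and
  refining it by parabolic interpolation. The peak height acts as a
  goodness-of-pitch gate (`pitch_gate`, default 0.3): windows with low
  harmonicity fall back to the spectral mean frequency, which keeps
  pitch defined on noisy syllables. On a 10 ms window this estimator is
  accurate to well under 1 % on clean tones and harmonic stacks.
* **Wiener entropy** (natural log of the geometric/arithmetic mean ratio
  of the power spectrum; ≤ 0, with 0 a perfectly flat spectrum). The raw
  periodogram's bins are chi-squared distributed, which biases the
  geometric mean low by the Euler–Mascheroni constant even for white
  noise; the spectrum is therefore smoothed with a Daniell (moving
  average) window of `wiener_smooth_bins` = 16 bins first, after which
  white noise measures within ±0.1 of zero and tones measure strongly
  negative.
* **Frequency modulation** (degrees, 0–90) from the ratio of time- to
  frequency-direction derivatives of a lightly smoothed spectrum, with
  the time derivative taken over ±`fm_lag_ms` (5 ms); 45° corresponds to
  spectral energy drifting one frequency bin per millisecond. The
  modulation **sign** (up/down/none) comes from the sign of the
  correlation between the two derivative fields, zeroed when FM is below
  `fm_sign_min_deg` (2°) — a drifting peak's time derivative
  anti-correlates with its frequency derivative, which is far more
  stable than tracking the spectral centroid.
* **Spectral continuity** (0–1): correlation between band spectra one
  window-length apart — deliberately overlap-free, so white noise
  decorrelates to ~0 while steady tonal material stays near 1. The
  reference literature does not print its continuity algorithm; this
  definition is behavioural, not bit-compatible.

## The ten-state partition (`fit_partition`, `assign_states`)

Voiced windows pooled across the colony (at least `min_windows` =
10,000) define the partition. Three pitch boundaries are placed at the
three deepest local minima of the smoothed pooled pitch density between
its modes, giving four pitch regions (very low / low / medium / high);
windows whose pitch was measured by the low-harmonicity fallback often
fall outside 300–3000 Hz and are excluded from the *fit* (though never
from assignment). Within each region, cluster centres in the (signed FM,
Wiener entropy) plane are the top density peaks of a 2-D kernel estimate
on robustly scaled coordinates (MAD scaling; bandwidth `kde_h` = 0.25
scaled units; peaks closer than `min_peak_sep` = 0.4 are suppressed).
Region state counts are fixed at 2/3/3/2, and within a region centres
are labelled by increasing signed FM, so the outer regions hold a
down-modulated and an up-modulated state (states 1–2 lowest pitch, 9–10
highest) and the central regions put their unmodulated state in the
middle label (states 4 and 7).

Assignment is total ("without residuals"): out-of-range pitches clip to
the outer regions, every voiced window goes to the nearest centre of its
region in the region's scaled units, and exact ties take the lower
label. Partitions serialise to versioned JSON, and a hand-specified
partition in the same schema can be loaded to encode published region
boundaries directly.

Two fitting choices deserve a note. The density peaks are used *as*
centres without a k-means refinement: refinement was tried and discarded
because the heavy tails contributed by syllable-boundary windows drag
refined centres off the clusters they should represent. And MAD scaling
is deliberately robust to those same tails; under strong bimodality the
MAD overestimates the within-cluster scale by roughly the cluster
separation, which is why the default bandwidth is as small as 0.25.

## Similarity and influence (`build_null`, `similarity_score`)

Similarity between two songs is computed over 70 ms windows of the
four-feature vectors (pitch, FM, Wiener entropy, continuity), z-scored
against pooled population moments, compared frame-by-frame along aligned
windows (mean Euclidean frame distance). A window-pair distance converts
to a p-value by its rank in an **empirical null**: the distances of
randomly drawn 70 ms window pairs from songs of distinct, unrelated
birds (at least 20; `n_samples` = 10,000 by default). A distance of zero
thus gets the minimum attainable p of `1/(n+1)`.

**Similarity sections** are maximal runs of window-significant
(p < `alpha`, default 0.05) cells along diagonals of the similarity
matrix. Deciding whether a run is significant needs care on two fronts:

* adjacent windows share 69 of 70 frames, so their p-values are almost
  perfectly dependent — evidence is therefore Fisher-combined only
  across non-overlapping 70 ms blocks of the run;
* the search space is the whole (reference × target) grid, so the
  combined p is Bonferroni-corrected by the effective number of
  independent cells (`(m1/W)·(m2/W)`).

Without both corrections a single borderline window would count as a
"section" somewhere on almost every diagonal, and any song would cover
any other. Within a retained section, a reference frame counts as
covered only if its own aligned frame distance is below the null's
`alpha` quantile of frame distances; this sharpens section ends at
copied/improvised junctions, which otherwise overshoot by up to a
window length (the window straddling the junction still matches on 60 of
70 frames).

**Similarity** is the % of the reference song's voiced frames covered by
retained sections; the reference is the tutor's motif for similarity and
the pupil's song for **influence** (`influence_score` simply swaps the
arguments, so the duality is exact by construction). The score is
recomputed `repeats` = 5 times with the reference boundaries jittered by
up to ±10 ms (seeded), and the median is reported — an emulation of the
run-to-run variability of manual motif outlining, whose true source in
the reference workflow is not documented.

## Syllables and recombination

Syllables are voiced segments (gaps < 5 ms closed, segments < 15 ms
dropped) summarised by duration and mean features. Types come from
single-linkage hierarchical clustering on z-scored features cut at 1.5
z-units; the standardisation scale per feature is floored at a
measurement-noise level (2 ms, 20 Hz, 1°, 0.1, 0.02) so a bird repeating
one syllable type is not shredded into many types by amplified noise.
Labels are canonicalised (largest cluster first) so the partition is
row-order invariant. Type diversity and syntax (bigram) entropy use the
same Shannon measure; bigrams are joint (not conditional) and never span
bout boundaries.

Recombination detection aligns tutor and pupil through the similarity
sections, maps each matched tutor frame to its aligned pupil frame, and
asks where each tutor syllable's copy landed: one pupil syllable
receiving ≥ 80 % (`coverage_min`) of two or more disjoint tutor
syllables is a **merge**; one ≥ 80 %-covered tutor syllable distributed
over two or more pupil syllables (each receiving ≥ 15 %) is a
**split**. The 80 % rule operationalises the restriction to clearly and
fully imitated material; counts remain a lower bound, and no correction
is attempted for the fact that merging is easier to detect than
splitting.

## Balanced-imitation statistics

All abundance-level statistics operate on a plain pairs table (one row
per tutor–pupil pair, ten abundance columns per role).

* `detrend_abundances` centres each state's abundances on its column
  mean, separately for the tutor and pupil columns. This makes every
  state equally abundant in the population and guarantees exactly zero
  expected correlation when the pairing is shuffled. (Centring each
  role's columns on their own means — rather than on a single pooled
  mean — is what makes the output columns exactly zero-mean; it is also
  the variant whose shuffle-null is exactly centred.)
* `abundance_regression` regresses detrended pupil abundances on
  detrended tutor abundances (ten points per pair). Because ten points
  per pair and repeated tutors violate independence, the default OLS
  slope comes with an optional cluster bootstrap by tutor, and
  `method = "lmer"` fits tutor and pupil random intercepts instead. The
  mixed model is a backend hook, not the acceptance path: the tested
  contracts are parameter-recovery properties, which do not depend on a
  particular mixed-model implementation.
* `diagonal_bias` uses the 20 % abundance threshold: the observed bias
  is the fraction of above-threshold tutor states whose pupil
  counterpart lies below the diagonal; the reverse bias swaps roles; the
  statistic is their difference. The underlying work does not print how
  per-pair biases were pooled before shuffling; this package pools
  fractions over all above-threshold points (matching the way the
  headline percentages are phrased) and keeps the *pair* as the shuffle
  unit. `direction_shuffle_test` swaps each pair's direction with
  probability ½ per shuffle and reports the direct p-value with the +1
  correction, `(1 + #{shuffled ≥ observed})/(1 + n_shuffles)`, so p is
  never exactly zero. Note the statistic degenerates to ~0 with tiny
  variance when tutor and pupil are unrelated — the test is informative
  for correlated pairs, which is the regime it is used in.
* `gain_curve` bins tutor abundances into 0.1-wide bins centred at 0.1,
  0.2, … (half-open, `[c−0.05, c+0.05)`), takes the median pupil
  abundance per populated bin and divides by the bin centre. On exactly
  self-imitating colonies the gains are 1 up to bin half-width; on
  β-flattened colonies `log(gain)` falls approximately linearly in
  `log(centre)` with slope `β − 1`, which is what the
  parameter-recovery tests exploit.
* `pooled_quartile_diversity`, `reversal_table`,
  `influence_feature_ranges` and `family_cv_analysis` implement the
  pooled-song contrasts, per-tutor diversity reversal directions,
  min–max tutor feature intervals of the top/bottom influence quartiles,
  and the clutch/family coefficient-of-variance analysis. Quartiles are
  always computed with Q1 = highest, stable under ties. The Bonferroni
  utility (reporting threshold 0.01) lives in `bonferroni_adjust` and is
  applied only in reporting, never inside estimators.

## The synthetic-song generator

The generator exists to give every pipeline stage a ground truth. Ten
**archetype elements** (`state_archetypes`) are harmonic stacks with
linear fundamental trajectories placed so that the pooled pitch density
has four modes and, within each pitch region, elements separate in
(signed FM, entropy): up/down sweeps in the outer regions; down, flat
(clean sparse stack) and up (noisier) elements in the central regions.
A **song** allocates voiced time across archetypes in proportion to a
target abundance vector, chops allocations into ~80 ms elements (so
sweep slopes, hence FM, do not depend on abundance), shuffles them, and
fuses runs of elements into 2–6 amplitude-threshold syllables by zeroing
within-syllable junction gaps; motifs repeat to ~2.8 s of song.
Syllable-boundary amplitude ramps are applied only at true syllable
boundaries, so fused junctions never dip below the voicing threshold.
Each bird carries per-state jitters (fundamental ±8 %, duration ±20 %,
noise ±50 %) so different birds' versions of a state are acoustically
individuated, while a pupil's *copied* elements jitter by at most ±5 % —
copies are closer than any unrelated bird's material, which is exactly
the contrast the empirical null needs.

Tutor target diversities are drawn left-tailed (median ≈ 3.1 bits,
truncated at 2.3 bits, the range at which a song effectively uses only
five states); a target vector achieving a requested entropy is found by
a power transform of a random simplex draw with the exponent solved by
root-finding. A **pupil** copies a fidelity fraction of the tutor's
elements and fills the remaining state-duration deficit with improvised
archetype variants; its target abundance vector is the renormalised
power transform `tutor_p^β`. Improvisation thereby concentrates on
states the tutor rarely uses. At colony scale, per-pair fidelity is Beta
distributed around the colony mean with a family-level effect on the
logit scale (`family_sd` = 0.8, concentration 20 — chosen so similarity
spans roughly 20–100 % with mean ~70 % and varies substantially more
across families than within, the structure reported for real colonies),
about one pair in five is fostered, and `lineage_depth` = 2 creates
grand-pupils whose tutors are generation-1 pupils. Audio-free colonies
realise abundance vectors as multinomial draws of 2,500 windows and are
cheap enough for hundred-pair statistics; `render_audio = TRUE` is meant
for ~10-pair colonies.

What the generator does **not** emulate: real zebra finch timbre and
within-syllable spectral complexity; calls and cage noise; motif syntax
beyond simple repetition; measurement artefacts of field recordings; and
any mechanism of balancing other than the β power transform. Passing
tests on synthetic colonies therefore shows that the estimators recover
known generative structure — not that real colony recordings would yield
any particular value.

## Problem sizes and numerical details

The test suite and the analysis scripts use desk-scale sizes chosen to
exercise every code path: 12-bird corpora (~25,000 pooled windows) for
partition fitting, 20-bird corpora for null models, 10-pair rendered
colonies for the full audio pipeline, and 100–160-pair audio-free
colonies for the abundance statistics (1,000 shuffles for permutation
p-values). Degenerate inputs are errors with specific messages: clips
shorter than one window, silent recordings, unimodal pitch
distributions, abundance vectors that do not sum to one, bias thresholds
that nothing exceeds. Floating-point guards: entropy uses `0·log 0 = 0`
and clips at 0 from above; distances use a hard non-negativity clamp
before the square root; equidistant assignment ties take the lower state
label everywhere.

## Known limitations

* Pitch, FM and continuity are behavioural re-implementations, not
  bit-compatible with any proprietary analysis software; absolute
  feature values differ even though the contracts (accuracy on tones,
  monotonicity, invariances) hold.
* The empirical null inherits the corpus it is fitted on: fitting it on
  songs that share material with the scored pair inflates the null's
  small-distance tail and deflates scores. Use unrelated birds.
* Measured similarity slightly understates copy fidelity when copies
  are jittered, because frames whose jittered distance exceeds the
  frame gate drop out of coverage.
* The merge/split detector reports a biased lower bound (merging is
  intrinsically easier to detect), and no correction is applied.
* Entropy-based diversity has limited bearing on combinatorial song
  complexity; it weighs states by abundance only.
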