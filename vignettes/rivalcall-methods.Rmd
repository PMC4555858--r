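---
title: "Methods and design notes for rivalcall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for rivalcall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rivalcall)
```

`rivalcall` implements an analysis chain for rival assessment in colonies of
male northern elephant seals: dominance scoring of dyadic contests, acoustic
characterization of pulsed threat calls, classification and stability
analysis of individual vocal signatures, correlation of acoustics with
morphometrics and dominance, playback-stimulus manipulation, and scoring of
behavioural responses. This vignette records the models, the parameters
that matter, the numerical choices, and the design decisions that were
genuinely open — in enough detail that a maintainer can judge every default.

## Dominance: sequential Elo rating

Each male enters the season at a rating of 1000. For a contest between
ratings $R_A$ and $R_B$ the expected score of the first male is

$$E_a = \frac{1}{1 + 10^{(R_B - R_A)/400}},$$

and the winner gains $K(1 - E_a)$ points while the loser loses the same
amount, so the colony-wide rating sum is invariant (asserted exactly in the
tests). The contests are folded in chronological order; ties on the same
day are broken by ledger row order (a stable sort), since field ledgers
rarely carry sub-day timestamps. Undecided contests — sustained fights that
end without a clear winner — are never scored but are retained in the
descriptive tallies.

The update constant `K` is not derivable from the scoring formulas (they
are K-agnostic in the quantities this package reports, which are rating
*orders* and differences measured against the same K); the default `K =
100` is common Elo practice for short observation windows with tens of
contests per individual, and it is exposed in every interface. Males are
auto-enrolled at the initial rating on first appearance, so the ledger
alone defines the roster.

Percentage tallies in `summarize_network()` always report their denominator
explicitly. Published tally tables for this system are not internally
consistent about denominators (yearly counts versus printed totals), so the
package refuses to guess: it prints counts, percentages over all
interactions, and the denominator, and leaves re-normalization to the
reader.

## Acoustics: pulse trains and energy distribution

Calls are analysed in two domains, on the *rhythmic portion* only — the
package expects calls pre-trimmed of introductory and terminal snorts, and
defines the rhythmic portion operationally as the span from the first to
the last sample of the smoothed envelope above the detection threshold.

**Temporal.** The signal is band-limited to 0–6 kHz (zero-phase FFT mask),
the Hilbert magnitude is taken, smoothed with a 41-sample moving average,
and peak-normalized. Pulse onsets are threshold up-crossings (default 0.15
of the envelope maximum) separated by at least `min_gap` (default 50 ms).
Duration runs from the first onset to the last offset, and the pulse rate
is defined as **pulses divided by duration** — not (pulses − 1) over the
onset span. The two conventions differ materially at typical pulse counts,
so this one is stated prominently wherever rates are produced or consumed.
The 41-point smoothing window is specified in samples at the native rate
(the default recorder rate for this call type is 48 kHz); the analysis
that first used such a window did not state its reference rate, so the
window is exposed as a parameter rather than hard-coded in milliseconds.

**Spectral.** Features come from a Welch-averaged periodogram (Hann window,
4096-point segments, 50% overlap), giving an 11.7 Hz bin at 48 kHz. The
frequency of maximal energy, energy-weighted centroid, and the frequencies
below which 25/50/75% of total energy lies are read off at bin resolution
with no interpolation. The −12 dB bandwidth is the *contiguous* band around
the spectral peak within 12 dB of its maximum; the phrase admits a
non-contiguous reading, but the contiguous band is the standard bioacoustic
convention and is what this package computes. Amplitude is reported as
dB peak re 20 µPa at 1 m (impulsive calls make RMS levels misleading),
and requires a calibration constant — pascals per digital full scale —
carried in a sidecar CSV because WAV files have no calibration field.
All features except the peak level are invariant under positive gain.

Degenerate inputs are first-class: silence yields a flagged degenerate
envelope, an all-zero spectrum or a pulse-free call raises an informative
error rather than NaNs.

No fundamental-frequency or formant analysis is attempted: these calls are
trains of discrete broadband pulses, not tonal roars, and such measures are
undefined for them.

## The synthetic colony generator

The generator exists so that every downstream stage has a ground truth to
recover; its defaults are the study conditions the analyses assume.

*Contests.* Dyads are drawn uniformly; the stronger male wins with
probability $\mathrm{logit}^{-1}(s \cdot \Delta\text{strength})$. No
generative win model is prescribed by the system itself; the logistic form
was chosen because it matches the functional form the Elo observer assumes,
making latent-strength recovery a well-posed check rather than a model
mismatch experiment. Winners vocalize with probability 0.95 and losers
0.29 — the rates observed in the field for this system — 5% of contests
escalate to contact, roughly a third of those to sustained fights, and a
fifth of sustained fights end undecided.

*Calls.* A call is a train of `n_pulses` 50-ms broadband noise bursts under
raised-cosine envelopes. Each burst's magnitude spectrum follows a gamma
density truncated to the 20 Hz–5.8 kHz synthesis band; the shape and scale
are solved in closed form (via the regularized incomplete gamma) so that
the *in-band* centroid and Q25 hit the signature targets, and each pulse
receives an independent phase draw so the Welch average over the train
approaches the deterministic target spectrum. A closed measurement loop
then synthesizes, re-measures with the package's own extractor, and nudges
the burst spacing and spectral targets (spectral corrections at half gain,
which damps the over-unity response of a measured quartile to a target
shift) until the measured pulse rate is within 0.2% and the measured
centroid and Q25 within half an FFT bin. Round-trip accuracy is therefore
a property of the synthesis design, and the tests verify it rather than
assume it. Within-male variation is multiplicative lognormal jitter,
default CV 5% per parameter — a modelling choice (no within-individual
dispersions are published for these features beyond group standard
deviations) sized so that between-individual separation dominates
within-individual scatter, as the signature analyses require. Jittered
Q25 draws are clamped above the attainable minimum of the truncated-gamma
family for the drawn centroid (the spectral family cannot reach arbitrarily
low Q25/centroid ratios; the clamp keeps about a 12% margin above the
power-law boundary).

*Colonies.* Per-male signature means are drawn inside the ranges observed
for this call type (pulse rates 0.94–2.84 Hz, centroids 1574–1902 Hz,
7–21 pulses). Pulse rate and Q25 are generated from vertical height through
the observed allometries (slopes 3.11 and 1693 per metre of height), so
correlation analyses have a known truth to recover; latent strength is
drawn independently of morphology, mirroring the observed absence of a
size–dominance correlation among surviving adults.

*Responses.* Paired six-measure response vectors are Gaussian around
baseline means with a configurable mean shift for the second condition;
latencies are censored at the 90-s observation window and flagged.

What the generator does **not** emulate: spatial harem structure, female
agents, observation effort bias in which dyads get recorded, recording
noise and overlapping calls, or fine within-pulse substructure. Passing
tests therefore demonstrate that the *analysis chain* is correct and
well-calibrated under its own assumptions — not that real colonies satisfy
those assumptions.

## Individual signatures: pDFA and stability

The classifier is a pooled-covariance linear discriminant written for this
package (with a trace-scaled ridge, `1e-6 * mean(diag(S))`, applied only
when the pooled covariance is ill-conditioned, with a logged notice); an
independent LDA implementation serves as a cross-check in the test suite.
Per cross-validation iteration, ⌈2n/3⌉ calls per male train the functions
and the held-out third is classified; rounding the training size *up*
guarantees every male keeps at least one validation call. The confusion
matrix aggregates held-out classifications across iterations into
p(guessed j | emitted by i), and is row-stochastic by construction.

The permutation p-value shuffles caller identities across calls (ignoring
within-male dependence deliberately — the permutation unit is the call in
the original design) and repeats the full train/validate procedure. The
estimator is $(b+1)/(m+1)$ with ties counted as exceeding: the standard
valid permutation estimator, differing from a raw proportion by at most
$1/(m+1)$. Whether the original protocol nested its 100 cross-validation
iterations inside each of its 1000 permutations is not stated; the package
exposes `iters_per_perm` (default 1). For null calibration experiments the
observed effect should be computed under the same single-split protocol as
the permuted effects so the two are exchangeable under the null; the
calibration suite does exactly this.

Signature stability works in the two-parameter space (pulse rate, spectral
centroid) after z-scoring. Which pool defines the standardization is not
prescribed anywhere; the package defaults to the first-level calls (year 1,
or the directed context) applied to all calls, and exposes the choice.
Per-male mean within-level and between-level distances are compared by a
matched-pairs Wilcoxon test; a *non-significant* difference is the
signature-stability outcome. Males with fewer than two calls in a level are
excluded with a notice.

## Correlation tables

One OLS fit per (response, predictor) pair with the morphological measure
or Elo score as predictor and per-male *mean* features as response — the
original tables regress one point per male, and the aggregation rule being
unstated, the mean was chosen and documented. Adjusted R² is reported
(negative values are expected and meaningful for null relationships). No
multiple-testing correction is applied to the significance flag, matching
the descriptive presentation such tables traditionally use; a
Benjamini–Hochberg column is emitted alongside, clearly marked as an
addition.

## Playback stimuli

Three size-cue manipulations, each verified by round-trip through the
package's own extractor:

- `modify_pulse_rate()` rescales inter-pulse silences uniformly, carrying
  each pulse's samples verbatim; pulse count is conserved exactly.
- `modify_pulse_count()` deletes pulses from the end of the call or appends
  replicas of the final pulse at the prevailing interval (which pulse to
  copy, and from which end to delete, are unprescribed; end-anchored
  operations were chosen as the least disruptive to call onset structure).
  Because the package's rate convention is pulses/duration, changing the
  count at a fixed interval alone would shift the measured rate; the gaps
  are therefore rescaled afterwards to restore the original rate.
- `shift_q25()` applies a smooth zero-phase power-law spectral tilt,
  bisecting the exponent until the re-measured Q25 sits within about half
  an FFT bin of target (so the landing bin is the nearest one). A
  pitch-synchronous resynthesis route was deliberately rejected: these
  calls are pulsatile broadband noise with no pitch periods to synchronize
  to, making PSOLA-style methods ill-defined; a spectral-domain reshaping
  achieves the targeted quartile while leaving temporal structure within
  1%.

Series composition: natural series concatenate three different calls,
modified series two repetitions of one call (fewer repetitions limit
habituation when each male hears up to seven variants), separated by
exactly 3 s of silence and rendered at 116 dB peak re 20 µPa at 1 m. The
output's calibration constant is set so digital full scale maps to exactly
the requested level; the published Q25 targets (536 and 804 Hz) are used
as printed even though they do not match "±20% of the mean" arithmetic
(643 ± 20% would give 514/772 Hz) — the printed values are authoritative.

## Response scoring

The six measures are standardized and decomposed by PCA on the correlation
matrix; components with eigenvalue above 1 are retained and
varimax-rotated (rotation restricted to retained components, the standard
practice where the alternative is not specified). Rotation is orthogonal,
so retained variance is conserved exactly — asserted to 1e-9 in the tests.
Signs are fixed so latency measures load positively: a strong aggressive
response (short latencies, approach, calling) then yields *negative*
scores, and the distance-moved convention is negative toward the speaker.
Constant measures are dropped with a notice.

Matched-pairs comparisons use the exact signed-rank distribution up to
n = 25 when ties and zero differences permit, and the tie-corrected normal
approximation otherwise; all-zero differences return p = 1 with a notice.
The crossed playback-type × distance design on harem-holding males was
originally analysed with a linear mixed model; that model is out of scope
here, and `alpha_distance_test()` provides a deliberately assumption-light
substitute — a within-male permutation test of the monotone distance-trend
statistic — documented as a methodological substitute, not an equivalent.

## Numerical choices and problem sizes

- Spectral quantities are reported at FFT-bin resolution (11.7 Hz at
  48 kHz/4096); no interpolation anywhere.
- The synthesis closed loop caps at 10 iterations and returns its
  best-measured iterate if the tolerance is not met earlier.
- Zero-sum conservation is asserted to 1e-9; varimax variance conservation
  to 1e-9; scale invariance of the classifier to 1e-6.
- The test suites run at deliberately modest scales chosen to exercise the
  statistics without waste: the Elo recovery experiment uses 20 males and
  2000 contests; permutation-test calibration uses 200 null datasets of 8
  males × 6 calls × 5 features at 200 permutations each; the acoustic
  round-trip grid is 10 pulse rates × 10 pulse counts at 12 kHz; power
  checks use 200–300 replicates at n = 10 pairs.

## Known limitations

- The truncated-gamma spectral family is unimodal and cannot reproduce
  multi-lobed call spectra, nor very low Q25/centroid ratios at high
  centroids; colony draws are clamped inside its attainable region.
- Pulse detection assumes non-overlapping pulses longer than the smoothing
  window and cleaner recordings than field microphones deliver; no noise
  reduction beyond band-limiting is attempted.
- Elo trajectories are order-sensitive by design: permuting the ledger
  changes individual paths (never the rating sum); conclusions should rest
  on final-score orders, which the recovery tests target.
- The feature-level generator (`simulate_feature_matrix()`) shares the
  waveform synthesizer's spectral family but bypasses audio entirely; it is
  the fast path for classifier experiments, and its agreement with the
  waveform path is only as good as that shared family.
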