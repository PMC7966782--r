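---
title: "Methods: unsupervised preictal-interval identification from HRV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unsupervised preictal-interval identification from HRV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preictalHRV)
```

## The problem and the model

Seizure prediction needs preictal labels, but the preictal interval — the
stretch of altered physiology before a seizure — has no clinical
parametrisation and varies between patients and between seizures of the
same patient. This package searches for that interval *per seizure*,
unsupervised, in heart-rate-variability features of the pre-seizure ECG,
under five working assumptions:

1. seizures at least 240 min apart are independent events;
2. although 240 min are analysed, only changes within the final 120 min are
   attributed to the upcoming seizure — the earlier half anchors the
   interictal baseline;
3. candidate solutions have exactly two clusters (interictal vs preictal);
4. the *smaller* cluster represents the preictal interval, because a
   preictal state is expected to be shorter than the interictal background;
5. the interval need not abut onset — autonomic changes may end well before
   the electrographic seizure.

Each seizure yields a feature matrix over `W` highly overlapping 5-min
windows (5-s step, 98.33% overlap). Every three-feature combination (4960
for the full 32-feature set) is clustered by seven method variants; gated
two-cluster solutions compete on time continuity and duration; the winner's
smaller cluster is the seizure's preictal call, stratified by start time
into 40-min pre-onset bins.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| analysis span | 240 | min | pre-onset data analysed |
| window length / step | 300 / 5 | s | feature resolution; `W = floor((span·60 − len)/step) + 1` |
| DBSCAN `MinPts` | 6 | — | twice the 3-D feature-space dimensionality |
| DBSCAN ε | 1,2,3,4 | z-units | read on the z-scored space: on min–max-scaled 3-D data all distances are ≤ √3, which would make ε ≥ 2 vacuous |
| min smaller-cluster size | 20 | windows | 1.58 min of information at the 5-s step |
| Dunn's index gate | 0.15 | — | single-linkage separation / max diameter, on the standardized space |
| SPH | 10 | min | warning horizon; a call "precedes" it when its last window starts ≥ 10 min before onset (inclusive) |
| stratification bins | (80,120], (40,80], [0,40] | min | keyed on the cluster's *earliest* window start; starts > 120 min are unstratified |

The duration of an n-window cluster is `(n − 1)·step/60` min — the time
between first and last window starts. This convention reproduces exactly
the reported sample/duration pairs (20 → 1.58 min, 66 → 5.42, 110 → 9.08,
431 → 35.83, 970 → 80.75), which is also why the 5-s step is the only
consistent reading of the window layout.

Equal-sized clusters (undefined "smaller") are resolved toward the cluster
whose last window lies nearer onset, anchoring the candidate in time.
Bin-boundary membership and the inclusive SPH comparison are conventions
chosen here; nothing in the procedure they implement defines them.

## Feature definitions and numerical choices

Time-domain features use sample (n−1) standard deviations, in ms (ms² for
RRVar). Frequency features integrate a Lomb–Scargle periodogram evaluated
directly on the uneven (beat time, RR) pairs — no resampling, hence no
interpolation bias — rescaled so its grid integral equals the series
variance; band ratios are normalisation-independent. `LF/HF` is reported
missing, not infinite, when HF = 0.

Nonlinear measures follow the common HRV defaults, all configurable:
ApEn/SampEn with m = 2, r = 0.2·SD floored at 1 ms so near-constant windows
stay defined (a constant window has SampEn 0: perfect regularity); RQA with
embedding dimension 10, delay 1, radius set to hit a 10% recurrence rate,
diagonal/vertical line floor 2, line of identity excluded; DFA α1 over box
sizes 4–16 and α2 over 16–64 with linear detrending; Rosenstein's method
for the largest Lyapunov exponent and Grassberger–Procaccia for the
correlation dimension, both at embedding dimension 10 with a Theiler window
of 10. Each feature family carries a minimum-interval precondition (e.g. 60
valid intervals for spectra and entropies, 200 for LLE/CD); windows failing
a precondition are missing for that feature only, while windows with > 20%
edited intervals are missing for all features.

Two estimator behaviours are worth knowing. First, DFA's small-box range
(4–16) has a known upward finite-size bias on uncorrelated data: seeded
white noise averages α1 ≈ 0.55–0.58 rather than 0.5, and single replicates
can graze 0.63, so the validation suite asserts the Monte-Carlo mean of 20
replicates against the theoretical band. Second, scaling-region estimators
need test hooks matched to the test system: the logistic-map Lyapunov check
uses a shallow embedding (m = 2; the map is one-dimensional, and deep
embeddings squander the short divergence region), and the noiseless-ramp
dimension check disables the Theiler window, because on a deterministic
ramp temporal neighbours *are* the geometric neighbours the exclusion would
delete.

RQA's line censoring (minimum length 2) excludes the single-point corner
diagonals, so even a fully saturated recurrence matrix has DET and LAM
marginally below 1 (0.998 at 31 embedded points); tests compare against an
exhaustive line census rather than the idealised value.

## Clustering and gating

Feature triples are standardized column-wise (sample SD; constant columns
zeroed with a warning) after dropping windows missing any of the three
features. k-means runs 10 seeded restarts; Ward agglomerative clustering
uses `ward.D2` on Euclidean distances; the Gaussian mixture is a full-
covariance EM with 5 seeded restarts (k-means and random-responsibility
initialisations), 1e-6 relative likelihood tolerance and a label-stability
early exit; mclust, where available, serves as an independent cross-check
of the EM in the test suite, never as the implementation. DBSCAN solutions
are kept only with exactly two clusters and zero noise points. Acceptance
is `n_smaller ≥ 20 ∧ DI ≥ 0.15` (both inclusive); it is monotone in the DI
threshold by construction. Whether the procedure should cluster all 240 min
or only the final 120 is not fully determined by its description; this
implementation clusters all windows and constrains candidates by time only
at stratification, which is what makes "unstratifiable" solutions (starts
earlier than 120 min) possible and observable.

Continuity of the smaller cluster is judged, by default, within the ordered
sequence of *valid* windows: gaps caused solely by noise-masked windows do
not break continuity, since noise handling would otherwise manufacture
pseudo-discontinuities. A strict mode (consecutive raw indices) exists for
sensitivity analyses.

## The synthetic generator: what it emulates, what it does not

`generate_rri()` builds beats sequentially with
`RR(t) = mean_rr + lf_amp·sin(2π·0.1·t) + hf_amp·sin(2π·0.25·t) + noise`,
a deliberately simple additive surrogate for autonomic modulation whose
LF/HF band powers are analytically known — that is what makes the spectral
features testable. The planted preictal shift is piecewise-constant in mean
RR and/or LF amplitude, mirroring the premise that the preictal state is a
distinguishable HRV regime; it must lie inside the final 120 min.
Artifacts change beats, not time (an ectopic splits one interval into a
short+long pair, a missed beat merges two), so window alignment and
cumulative time are preserved exactly. Defaults (mean RR 0.85 s, LF/HF
amplitudes 20/15 ms, 10 ms beat noise) give a within-window RR SD of about
20 ms, a plausible resting short-term variability.

What the generator does *not* emulate: circadian and vigilance-state
drifts, respiration-coupled nonstationarity, genuine nonlinear cardiac
dynamics, or realistic ECG morphology (the synthetic ECG is a fixed QRS
template on a flat baseline, sufficient only to exercise R-peak detection).
Passing the recovery experiments therefore demonstrates that the pipeline
finds regime shifts of the planted kind under controlled noise — not that
clinical preictal intervals have such shifts.

## The planted-shift recovery experiment

The end-to-end validation simulates 20 seizures with a 10-min shift of
−80 ms in mean RR (≈ 3.9 within-window SDs) starting uniformly 20–60 min
before onset, and 20 shift-free controls, at the default gates. The
scaled-down problem size — 60-s windows at a 20-s step (718 windows per
240-min seizure) and the 8 continuous time-domain/Poincaré features (SDNN,
RMSSD, SDSD, RRMean, RRMin, RRMax, SD1, SD2; 56 triples) with k-means,
DBSCAN(ε=2) and the Gaussian mixture — keeps the experiment at desk scale
while preserving the full search structure. The discrete count features
NN50/pNN50 are excluded from this reduced set: under the generator's
Gaussian noise they are near-zero integer counts whose standardized jumps
form separable clusters unrelated to any planted change — an artefact of
the synthetic noise model, not a property of the method. The pipeline must
call an interval overlapping the planted windows at Jaccard ≥ 0.5 for
≥ 80% of shifted seizures and stay quiet on ≥ 80% of controls; with the
frozen seeds it recovers 20/20 (Jaccard ≥ 0.97) and is quiet on 20/20.

## Degenerate inputs and edge behaviour

Flatline or noise-dominated ECG yields an empty peak list with a warning
(noise is recognised by implausible rate or a detected-RR coefficient of
variation above 0.35). RRI editing rejects series with more than half the
intervals abnormal; abnormal runs longer than five intervals, or at the
series edge, are excluded rather than interpolated. Editing is idempotent
and the identity on clean series. Standardization zeroes constant columns;
clustering declines all-identical feature spaces; Dunn's index returns an
infinite sentinel when both clusters collapse to points. All stochastic
steps (generator, k-means, EM) flow from explicit seeds, with one
independent substream per seizure so cohort size never perturbs individual
seizures.

## Known limitations

The R-peak detector, the RRI editing thresholds and the nonlinear-feature
parameters are standard-practice substitutes for procedures whose exact
original settings are not public; they are configurable but not tuned to
any clinical dataset. Cohort-level clinical fractions (how many real
seizures show preictal structure) are outside what synthetic data can
establish. The exhaustive 4960-triple × 7-method scan over 2821 windows is
hours-scale per seizure in pure R; the feature/method subset flags exist
precisely so that scaled studies preserve the search semantics.
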