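---
title: "Locating the ANT target from DBS lead recordings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating the ANT target from DBS lead recordings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Deep brain stimulation of the anterior nucleus of the thalamus (ANT) is an
established therapy for drug-resistant focal epilepsy, and its benefit
depends strongly on which lead contact is stimulated: contacts outside the
anteroventral target do less good. Target identification is normally an
imaging exercise. `lfptarget` implements a complementary,
electrophysiological route: the local field potentials (LFPs) that the
implanted neurostimulator can record from its own contacts are mined for a
"signal signature" of the target, and each candidate contact pair is scored
by how strongly its LFP resembles the signature.

## Lead geometry and spatial locations

The default lead model has four ring contacts (0–3) of 1.5 mm separated by
0.5 mm gaps. Sensing is bipolar, in two channel groups: *Pass1* uses the
non-adjacent pairs 0–3, 1–3, 0–2 and *Pass2* the adjacent pairs 0–1, 1–2,
2–3. A bipolar signal is nominally localized at the midpoint of its two
contacts; the contact-to-midpoint distance *d* is 1 mm for all Pass2 pairs,
2 mm for 0–2 and 1–3, and 3 mm for 0–3. Because the Pass1 and Pass2 signals
therefore sample tissue at different distances, the two passes are treated
as data of different natures and each gets its own classifier.

Midpoints define six labelled spatial locations per hemisphere (A–E, with C
appearing once per pass because pairs 1–2 and 0–3 share a midpoint but not
*d*). Each location carries an ordinal involvement grade from imaging:
`-` (outside the target), `+`, `++`, `+++` (completely inserted). The grade
table is an input (`read_involvement()`); the packaged default describes a
bilateral implant whose deep contacts lie in the target on the right and
approach it on the left. The coordinate origin (distal edge of contact 0,
increasing proximally) is an arbitrary affine choice that cancels out of
every reported quantity; whether contact 0 is distal or proximal on a given
implant does not affect midpoints or *d*.

## Recordings, segmentation and features

Sessions hold 250 Hz bipolar channels in microvolts. The reference
acquisition protocol collects 11 survey blocks totalling 231 s per pass and
hemisphere. Analysis windows are 5 s, non-overlapping, taken from the start
of each survey block; remainders are discarded and windows never straddle
block boundaries. Note an arithmetic subtlety: 11 × 21 s cut per block
yields 44 windows, while a pooled 231-s record yields the canonical 46. The
protocol's printed segment count (46) implies pooled segmentation, so the
synthetic generator's default layout is a single continuous 231-s block,
with a split-block mode available (`layout = "split"`).

Every window is described by 17 features:

* statistical — variance, skewness, kurtosis, median;
* spectral — Welch band power in delta (1–3 Hz), theta (4–7), alpha (8–12),
  beta (13–30) and gamma (30–100 Hz);
* morphological — absolute mean, mean peak amplitude, maximum, minimum;
* multivariate — the channel's node strength in four 3-node connectivity
  graphs (max-lag cross-correlation, mean magnitude-squared coherence over
  1–100 Hz, phase locking value, phase lag index) built from the three
  simultaneously recorded channels of the same pass and hemisphere — the
  only grouping for which all channels are time-aligned.

## Numerical choices

* **Welch PSD**: 1-s Hann windows, 50% overlap. Band powers integrate the
  one-sided density over inclusive bin ranges, so a unit-amplitude sinusoid
  contributes 0.5 µV² to its band.
* **Band edges**: gamma is 30–100 Hz and alpha 8–12 Hz by default; both are
  configurable via `band_definitions()`.
* **Kurtosis** uses the non-excess convention (Gaussian → 3), matching the
  common engineering-toolbox default.
* **Phase** is estimated from the analytic signal after zero-phase
  band-limiting to 1–100 Hz. PLI is `|mean(sign(sin(Δφ)))|`, so exact
  zero-lag synchrony contributes nothing — identical channels score PLI 0
  but PLV 1.
* **Cross-correlation** weights are the maximum absolute normalized
  cross-correlation over lags up to ±1 s, computed in the frequency domain
  (it matches `stats::ccf` to numerical precision), keeping all adjacency
  weights in [0, 1] so node strengths are comparable across metrics.
* **Degenerate segments** (constant signal) would make skewness and kurtosis
  undefined; they are returned as 0 and flagged in a `degenerate` column
  rather than poisoning downstream matrices. A monotone segment has no
  interior peak, so the mean-peak feature falls back to the global maximum.
* **No line-noise filtering** is applied by default; none is assumed present in the
  recordings being emulated.

## Ranking, projection, classification

Features are ranked by the absolute pooled-variance two-sample *t* statistic
between the in-target and off-target classes; the ranking is reported
(`plot_feature_ranking()`) but no feature is dropped, because the per-pass
rankings generally disagree. All 17 features go into a PCA that keeps the
minimal number of components explaining 99% of variance. Features are
z-scored before PCA by default: they mix µV², µV and dimensionless scales,
and without standardization the variance-like features would own the
rotation. A center-only covariance PCA (`scale = FALSE`) is also
provided, matching the default of common engineering toolboxes. Loading signs are fixed by making each
vector's largest-magnitude entry positive, for reproducibility.

Classification uses a nested split: 80/20 into training/test, then the
training set 80/20 into "training set 2" and a CV set, stratified by class
(with 46 + 46 segments an unstratified 20% draw risks severe imbalance).
Three families are trained on training set 2 at standard parameters — SVM
with rbf kernel, kNN with standardized-Euclidean distance, and a
single-hidden-layer neural network of size 5 — and compared by CV accuracy
(ties broken SVM → kNN → NN). The winner's parameter grid (kernels
linear/rbf/polynomial; distances seuclidean/euclidean/correlation/spearman;
hidden sizes 1–10) is then swept on the same CV set, first-in-grid winning
ties. This deliberately reuses one CV split twice, mirroring the clinical
methodology being reproduced;
the resulting optimism affects only the selection, never the untouched test
set, on which the final refit model is scored by accuracy, sensitivity and
specificity. Implementation details the methodology leaves open are fixed
as: polynomial degree 3, SVM width at the implementation default, kNN with
k = 1 neighbour (the reference toolbox default), neural-network weights
initialized from a fixed seed. The PCA is fitted on the full labelled
dataset before splitting, a property of the methodology being reproduced; the split machinery
itself never lets the outer test set influence family or parameter choice.

## Target percentage and contact ranking

A trained pass classifier is applied to the 5-s segments of the six
locations it was not trained on (the rest of its own pass plus the opposite
pass's two training locations — the only way to score a classifier's own
training locations is with the other classifier). The *target percentage*
of a location is the fraction of its segments classified in-target, which
makes every value an exact multiple of 100/46 at the default segment count.
Locations are then ranked per hemisphere and mapped back to contact pairs;
a per-contact view (best pair containing the contact) is offered as a
secondary aggregation.

## The synthetic generator

No public recordings exist for this methodology, so the package ships a
seeded surrogate generator whose defaults mirror the documented acquisition
conditions: 250 Hz, 231 s per pass and hemisphere (pooled layout), six
bipolar channels per hemisphere. Each channel is

1. a 1/f pink-noise background (5 µV RMS),
2. alpha- and gamma-band filtered-noise oscillations whose amplitudes scale
   with the channel location's involvement grade (gamma gains 1.0 / 1.5 /
   2.1 / 2.8 across `-`/`+`/`++`/`+++`; alpha gains 1.0–1.9), and
3. a hemisphere-shared 9–11 Hz component mixed in with a per-channel phase
   lag (20 ms per channel index) and a weight growing with grade
   (0.2–0.8), giving coupled channels excess PLV/PLI.

The gamma gradient encodes the generator's central assumption — that
in-target LFPs carry more gamma (and alpha) power and stronger phase
coupling — which is the package's operationalization of the qualitative
claim the methodology rests on. Effect sizes were chosen once to give a
clearly learnable but not degenerate contrast (roughly 3:1 gamma-power
ratio between the extreme grades on top of a comparable background) and are
all exposed in `synth_config()`; setting all gains equal yields a null
generator used in the tests. What the surrogate deliberately does *not*
model: ictal events, stimulation and movement artefacts, volume-conduction
forward fields, non-stationarity across days, or monopolar-to-bipolar
derivation (bipolar channels are synthesized directly for controllability).
Passing tests on this surrogate therefore demonstrate that the pipeline
recovers structure of the assumed kind when present — not that real ANT
recordings contain it.

## Problem sizes and determinism

The test suite exercises the full default-scale conditions (231 s × 12
channels, 46 segments per class) across 20 seeds for the recovery and
monotonicity properties, and uses 30-s sessions for unit-level checks.
Everything stochastic — generation, splits, permutations, network
initialization — flows from explicit integer seeds, and identical seeds
reproduce feature tables, manifests and reports byte for byte.

## Known limitations

* The methodology scores *locations*, not stimulation outcomes; no clinical
  decision rule is implied.
* A single CV split makes family/parameter selection noisy; k-fold
  selection would be more stable but would depart from the reproduced
  procedure, so it is not the default.
* Cross-pass predictions (scoring one pass's training locations with the
  other pass's classifier) mix signals of different contact-to-midpoint
  distances and should be read with that caveat.
* With 92 segments from one session, segments are not fully independent
  samples; held-out accuracy on such data estimates within-session
  generalization only.
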