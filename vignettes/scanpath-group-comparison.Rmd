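---
title: "Comparing groups of eye-movement scanpaths: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing groups of eye-movement scanpaths: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pairwise scanpath comparison algorithms assign a similarity score to a
*pair* of eye-movement sequences, but experiments usually ask a
group-level question: do the scanpaths recorded under condition A differ
from those under condition B? Because all pairwise scores involving a
given scanpath are statistically dependent, within- vs between-group
score comparisons do not support standard inference. `gazealign`
implements a workaround: embed every scanpath as a point in the plane so
that inter-point distances reflect pairwise similarity, then compare the
two *point clouds* with a distribution-free two-sample test, and isolate
the temporal (ordering) contribution with a classifier comparison
against order-destroyed control scanpaths.

## Pipeline overview

1. **AOI assignment.** Each fixation is assigned to the nearest of 76
   AOI points: 68 facial-landmark points (grouped as face outline,
   mouth, nose, eyes, eyebrows) plus 8 exterior frame points that catch
   stray fixations. Landmark *detection* is upstream; the landmark table
   is an input. Coordinates are screen pixels, origin top-left, y
   increasing downward; all distances are Euclidean in px. Ties in the
   nearest-point search break to the lowest `point_id` — deterministic
   and documented.
2. **Temporal binning.** A fixation of duration `d` contributes its AOI
   symbol `round(d / 50 ms)` times (round-half-up, so 125 ms gives 3
   bins; the rounding convention is fixed for reproducibility).
   Fixations shorter than 25 ms contribute nothing. Trials in which
   neither eye's string contains an AOI transition are excluded, as are
   (by default) trials in which one eye's string is empty — an empty
   string cannot enter a global alignment. Eyes are processed separately
   end to end, because each eye tends to be displaced slightly towards
   its own side of the face.
3. **Substitution matrix.** For distinct same-group points the score is
   `+d_min_same / d(i, j)` — positive, inversely proportional to the
   average inter-point distance across all images, equal to +1 for the
   closest same-group pair. For cross-group points it is
   `−d(i, j) / d_max_diff` — negative, directly proportional to
   distance, equal to −1 for the most distant cross-group pair. The
   diagonal is +1. The two ±1 anchors pin down the proportionality
   constants; a variant in which the same-group branch decays linearly
   instead of reciprocally is available (`form = "linear"`) because the
   anchors alone do not dictate the functional form between them.
   Distances are averaged per pair across image layouts, not computed
   between averaged landmark positions — these differ when facial
   geometry varies across images.
4. **Alignment similarity.** Needleman–Wunsch global alignment
   (score-only dynamic program, O(|s1||s2|)) with the substitution
   matrix and a gap penalty of 0, the ScanMatch toolbox default: with
   mismatches already scored negatively, a nonzero gap penalty would
   double-penalize length differences. Scores are normalized by the
   length of the longer string (a 30- vs 40-symbol pair is divided
   by 40), so shorter scanpaths are not spuriously "more similar".
5. **Embedding.** The similarity matrix is converted to dissimilarities
   by the order-reversing map `D = max(S) − S` (zero diagonal). t-SNE
   consumes only neighbor ordering through its conditional
   distributions, so any order-reversing map is equivalent up to
   bandwidth calibration; the max-shift is the simplest choice. Each eye
   and each kind (original / permuted) is embedded in its own t-SNE run.
6. **Group test.** The two groups' embedded point clouds are compared
   per eye with the Baringhaus–Franz Cramér statistic under a
   Monte-Carlo permutation null (default 1000 replicates), with the
   add-one p-value convention so p is never exactly 0.
7. **Temporal isolation.** Each scanpath string is also randomly
   permuted, destroying order while preserving AOI visit frequencies;
   the permuted strings pass through the same similarity + embedding
   stages. Per trial this yields 4 "spatial-only" coordinates (left and
   right eye of the permuted embedding) and 4 "spatial + temporal"
   coordinates (original embedding). Two gradient-boosted tree
   classifiers predict group membership from 4 vs all 8 features; their
   accuracies are compared with Dietterich's 5×2cv paired t-test
   (df = 5). If the original coordinates add predictive value over the
   permuted ones, the groups differ *temporally*.

A benchmark pathway substitutes the Levenshtein distance for the
alignment similarity and Kruskal's non-metric MDS for t-SNE, keeping
everything else identical.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `bin_ms` | 50 | ms | temporal bin; one symbol per bin |
| `frame_margin` | 5% of bbox diagonal | px | frame-point expansion; placement of the 8 frame points (corners + edge midpoints) is the simplest equidistant-per-edge reading of a rectangular frame |
| `gap_penalty` | 0 | score | per gap symbol |
| `sub_form` | `reciprocal` | — | same-group score decay |
| `perplexity` | 30 | — | t-SNE effective neighbors; requires N > 3·perplexity |
| `tsne_iterations` | 1000 | — | gradient steps |
| `cramer_replicates` | 1000 | — | permutation null size |
| `alpha` | 0.05 | — | critical-value level |
| `cv_numerator` | `first` | — | 5×2cv t numerator (see below) |
| `nrounds`, `max_depth` | 50, 6 | — | boosting caps |
| `perm_k` | 1000 | — | label permutations |

Class priors are equalized at 0.5 by weighting each training class
inversely to its frequency — the library-agnostic equivalent of setting
prior probabilities, which keeps the 0.5 decision threshold calibrated
under imbalance.

**5×2cv numerator.** Dietterich's original statistic uses the first
fold's difference as numerator; a common variant uses the mean of all
ten differences. Both are available; `first` is the default because its
null calibration is the one established in the literature. The mean
variant is slightly liberal but more stable; which one a given published
t value used is often not recoverable, so the choice is exposed.

**Label permutations** act at the subject level, never the trial level:
trials of one subject are strongly dependent, and the grouped fold
structure must be respected under the null, otherwise the permutation
distribution is too narrow.

## Numerical choices

- t-SNE is the package's own exact implementation operating directly on
  a precomputed dissimilarity matrix: Gaussian input affinities on
  squared dissimilarities with per-point bandwidths bisected to the
  target perplexity, symmetrized and normalized; Student-t embedding
  kernels; gradient descent with momentum 0.5 (0.8 after iteration
  250), gain adaptation (lower bound 0.01), learning rate 200, early
  exaggeration 12 for the first quarter of the iterations (at most
  250). Initial coordinates are `N(0, 10^-4)` draws under the stage
  seed; the run is deterministic given the seed, and the final KL
  divergence is checked against its initial value.
- Non-metric MDS delegates to `MASS::isoMDS` from a classical-scaling
  start; zero dissimilarities between distinct items are nudged to
  `max(D)·1e-9` so duplicate scanpaths may coincide instead of
  erroring.
- The Cramér permutation null reuses one pooled inter-point distance
  matrix across replicates; only index sets are resampled.
- Degenerate 5×2cv inputs (all fold differences zero) yield t = 0,
  p = 1 rather than 0/0.
- A same-group AOI pair at exactly zero distance is an error (the
  reciprocal score is undefined); coincident points should be merged
  upstream.
- Master seed → stage seeds via the first ten draws of
  `sample.int(2^31 − 1)` under the master seed, in a fixed documented
  order, so any stage is independently reproducible.

## The synthetic-data generator

`sim_scenario()` / `simulate_study()` emulate a face-viewing study:
2000 ms exposures, fixation dwell times gamma-distributed (mean 300 ms,
shape 4 — realistic face-viewing fixation durations with SD 150 ms),
fixation positions at a uniformly chosen member point of the visited
AOI group plus 10 px Gaussian jitter, six per-image layout variants
(landmarks perturbed by 3 px) mimicking varying facial geometry, and
two eye streams offset horizontally by ±3 px with 1 px per-eye noise.
Gaze dynamics follow a first-order Markov chain over the six AOI
groups with a pronounced eyes → nose → mouth → eyes cycle.

The three scenarios differ only in group B's transition matrix:

- **null** — identical chains;
- **temporal** — group B uses the interpolation
  `(1 − e)·P_A + e·rev(P_A)`, where `rev(P_A)` is the time-reversed
  chain `rev(P)[i, j] = π_j P[j, i] / π_i`. Reversal preserves the
  stationary distribution exactly, and so does any convex combination,
  so at every effect size the groups have *identical* long-run AOI
  visit frequencies — the difference is purely one of ordering. At
  `e = 1` group A cycles eyes → nose → mouth and group B the reverse.
- **spatial** — group B's rows are reweighted towards the mouth and
  away from the eyes (column weights `1 + e` and `1 − 0.6e`), shifting
  stationary mass with the transition order otherwise matched.

What the generator does *not* emulate: saccade dynamics and the
main-sequence relationship, microsaccades, drift and tracker noise
autocorrelation, within-subject heterogeneity (all subjects of a group
share one chain), pupil data, and calibration artifacts. Passing tests
on this generator therefore demonstrate that the pipeline recovers the
*kind* of structure it targets (ordering differences with matched
spatial statistics), not that it will detect any particular effect in
real recordings.

## Problem sizes used by the test suite

Unit and property tests run on strings of length ≤ 10 and layouts of 76
points; the alignment dynamic program is verified against exhaustive
enumeration over all global alignments for strings up to length 6.
Type-I calibration of the Cramér permutation test uses 500 null
datasets of 15 + 15 bivariate normal points at 199 replicates each. The
temporal-recovery check runs 50 temporal-scenario and 50 null-scenario
replicate studies at 10 subjects per group × 20 trials (400 trials,
800 scanpath strings per study) — a deliberately compact study size
chosen so that a hundred complete pipeline replicates remain tractable
on a single core; the scenario parameters themselves are the generator
defaults. At this size the spatial + temporal classifier's advantage on
the temporal scenario is consistently positive in direction, though the
5×2cv t-test at df = 5 detects it in well under half of replicates —
see Limitations.

## Known limitations

- With a zero gap penalty, global alignment reduces to a weighted
  longest-common-subsequence score. For temporally binned strings
  (long same-symbol runs) this is only mildly sensitive to ordering
  reversals, which caps the temporal signal reaching the embedding; a
  negative gap penalty sharpens order sensitivity at the cost of
  penalizing duration differences twice.
- Dietterich's 5×2cv t-test is conservative and, at df = 5, has low
  power for accuracy differences of a few percentage points — the
  regime this pipeline operates in, since single 2-second exposures
  carry little discriminative information. Group-level differences
  that are detectable by the Cramér test on embedded clouds can
  therefore still come out non-significant in the classifier
  comparison, and larger studies raise power only slowly.
- t-SNE has no out-of-sample extension: adding scanpaths means
  re-embedding everything, so trained classifiers cannot be applied to
  new recordings.
- The embedding step is stochastic; all results are conditional on the
  documented seed policy.
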