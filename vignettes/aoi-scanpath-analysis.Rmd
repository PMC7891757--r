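---
title: "AOI scanpath analysis: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AOI scanpath analysis: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aoiscan)
```

## The problem

Operators monitoring a set of instruments — the motivating case is pilots
scanning a cockpit during a manual approach — allocate visual attention by
dwelling on areas of interest (AOIs) and transitioning between them.
Classical summaries (number of dwells, mean dwell time) ignore the *order*
of the scan. `aoiscan` implements the AOI-sequence metrics that capture that
order: first-order Markov transition matrices and their density, gaze
transition entropy, the ambient/focal coefficient K, Lempel–Ziv complexity,
and n-gram pattern mining, together with a transition-matrix–based
expertise classifier, flight-performance scoring, and a synthetic scanpath
generator used to validate every stage end to end.

## From samples to dwells and transitions

The input is a gaze sample stream: per-sample AOI ids (0 = outside any AOI)
at a nominal rate, 60 Hz by default. The preprocessing chain is:

1. **Trim** each recording to a common duration by keeping the final
   `n_frames` samples (default 14,000 at 60 Hz ≈ 233 s); the start of a
   recording is the part whose length varies with operator behaviour.
2. **Segment** maximal same-AOI runs into dwells
   (`duration = run length / rate`).
3. **Clean**: drop dwells shorter than `min_dwell` (default 0.200 s, a
   conventional lower bound for an intentional instrument check) and all
   off-AOI dwells, *then* merge adjacent same-AOI dwells. Filtering before
   merging matters — the reverse order yields different sequences — and the
   order implemented here follows the processing description the pipeline
   is modelled on (so the label run 1,1,4,4,5,5,5,6 becomes 1,4,5,6).
   Cleaning is idempotent. No gap-bridging is performed: an off-AOI run
   always splits a dwell, and the two halves merge back only after the
   off-AOI run is removed.
4. **Transitions**: consecutive dwell pairs become (from, to, amplitude)
   records. Amplitude is the distance between per-dwell mean gaze positions
   when positions are available, otherwise the centroid distance of the two
   AOIs in the world model.

The bundled world model places the ten cockpit AOIs (ATT, SPD, VS, FMA,
HDG, ND, NDz, FCU, ECAM, OTW) as rectangles on a schematic panel in
centimetres, with the five primary-flight-display regions clustered, the
navigation display and its distance read-out zone beside them, and the
out-the-window region spanning the top. No published coordinates exist for
this layout, so the rectangles encode the qualitative arrangement only;
this is sufficient because every metric except coefficient K is
geometry-free, and K depends on amplitudes only through z-scores, which are
invariant to the overall scale of the layout. The distance unit is declared
once per model and carried through opaquely.

## The metrics

**Transition matrix and density.** Counts of i→j moves in AOI order,
row-normalised to conditional probabilities p(j|i). Density is the
fraction of the m² cells with at least one transition; the denominator
deliberately includes the structurally empty diagonal (self-transitions
cannot survive cleaning), capping density at m(m−1)/m² = 0.9 for m = 10.

**Gaze transition entropy (GTE).**
H = − Σᵢ p(i) Σ_{j≠i} p(j|i) log₂ p(j|i), in bits, with 0·log 0 = 0 and
all-zero rows skipped (no smoothing is applied to unvisited sources). The
weights p(i) default to observed dwell proportions — the common empirical
choice — with a left-eigenvector mode for model-based use; the eigenvector
mode refuses reducible chains and names the unreachable AOIs rather than
returning an arbitrary vector. The maximum is log₂(m−1), attained by the
uniform chain with uniform weights.

**Coefficient K.** Each dwell duration dᵢ is paired with the amplitude
aᵢ₊₁ of the transition that follows it; κᵢ is the difference of their
z-scores and K the mean of κᵢ. K > 0 indicates focal attention (long
dwells, short transitions), K < 0 ambient attention. Two conventions were
genuinely open and are exposed as options with these defaults:

* *Standardization scope*: pooled across all recordings of a dataset
  (default). Under per-recording standardization the z-scores sum to zero,
  which forces mean K = −z(d_last)/n_pairs ≈ 0 for every recording — an
  exact identity the tests assert — so distinct group-level K values are
  only possible when recordings are standardized against a common pool.
* *SD denominator*: sample (n−1) by default, configurable to population.
  All dwells, including the final one with no following transition, enter
  μ_d and ρ_d.

A zero-variance channel raises an error rather than silently substituting
zeros, since no z-score exists in that case.

**Lempel–Ziv complexity.** The sequence is scanned once left to right; each
phrase is the shortest prefix of the remaining input not yet in the phrase
dictionary, and a final incomplete phrase counts. This incremental
dictionary parsing reproduces the canonical worked decomposition
1|0|10|01|010|0101|11 (complexity 7) for the binary string
101001010010111, which the unit tests pin. Complexity is non-decreasing
under sequence extension, and a constant sequence of length ≥ 2 has
complexity 2.

**N-grams.** Overlapping windows of length n (stride 1), so counts sum to
L − n + 1. Group-common n-grams default to the strict intersection
(present in every member); a `support` parameter relaxes this to a member
fraction, since "common to the group" is also meaningfully read as a
majority criterion. Counting is per recording; pooling across scenarios is
left to the caller. A filter retains n-grams visiting n pairwise-distinct
AOIs, which isolates the more elaborate scanning routines from
back-and-forth pairs.

## Expertise classification

Each recording's transition-probability matrix is flattened row-major into
an m² = 100-feature row. PCA (mean-centred, unscaled) reduces the features
— 35 components by default; a request beyond the feasible rank
min(rows − 1, features) is capped with a warning, so 32 recordings yield at
most 31 components. Classification uses k-nearest neighbours (10 by
default, the conventional preset for a cosine-metric KNN) under cosine
distance, majority vote, with deterministic tie-breaks: smallest summed
neighbour distance, then lowest class id. Folds are stratified and seeded;
by default the PCA is refitted inside each training fold so no information
from the held-out fold leaks into the projection (the leakage-free choice
is the defensible default where the original analysis is silent; fitting
once on the full table is available as an option and recorded in the
report metadata). Significance is assessed against the exact binomial
chance level: the smallest accuracy k/n with
P(Binomial(n, 1/c) ≥ k) < α. For n = 32 and two classes at α = 0.05 this
is 22/32 = 68.75%; note this exact computation gives a sharper level than
the ≈58% sometimes quoted from normal-approximation tables at similar n.

## Flight performance

RMSE of each 1 Hz parameter trace against its instructed target: signed
deviation for point targets (speed 130 kt, heading 143°), and for the
vertical-speed band (−800, +500) ft/min, zero inside the band and distance
to the nearest bound outside — the only reading under which an RMSE
against a range target is well defined. The band's sign convention follows
the scenario instruction (descend no faster than 800 ft/min, climb no
faster than 500 ft/min). Dual-task callouts are scored by greedy
nearest-distance matching of produced calls to expected marks (each call
satisfies at most one mark) within a configurable tolerance, 0.1 Nm by
default — half the finest mark spacing, so adjacent marks cannot both
claim one call.

## The synthetic generator

`make_profile()` fixes a population's generative parameters once:

* **Transition structure** — `expert-like` spreads mass over all ten AOIs
  with extra weight on OTW and ATT (wide cross-checking); `novice-like`
  concentrates ≥ 70% of each row's mass on the five PFD AOIs. Both are
  zero-diagonal row-stochastic matrices.
* **Dwell durations** — log-normal (positive, right-skewed, the standard
  model for dwell data), solved from target mean/SD: 1.1 ± 0.5 s
  (expert-like) vs 1.51 ± 0.65 s (novice-like), the reported group means
  the generator emulates.
* **Noise** — sub-threshold "flicker" dwells (< 200 ms, removed by
  cleaning) at 5% per dwell, and off-AOI dropout runs tuned to give ~4–5%
  of time outside AOIs, matching the few-percent outside share typical of
  cockpit recordings.
* **Flight traces** — AR(1) (φ = 0.9) noise around the instructed targets
  at 1 Hz, with larger deviation scales for the novice-like profile;
  callouts omitted with probability 0.07 (expert-like) vs 0.27
  (novice-like) at ten 0.5 Nm marks.

Recordings are rendered at 60 Hz, truncated to the frame budget, and are
bit-reproducible from (profile, n_frames, seed); cohort seeds derive from
one master seed and are listed in the manifest. The `truth` element stores
the cleaned noise-free sequence, so with noise rates at zero the pipeline
output equals the truth exactly — the end-to-end correctness check. An
optional embedded motif (a configurable n-gram spliced in at a set rate)
gives the pattern-mining module a known ground truth.

What the generator does *not* emulate: oculomotor dynamics (saccade main
sequence, smooth pursuit), higher-order sequential dependence beyond the
optional motif, scenario-dependent non-stationarity, and between-subject
parameter heterogeneity within a group. Passing recovery tests therefore
shows that the metrics detect the intended contrasts under first-order
Markov scanning with realistic dwell statistics — not that they would
behave identically on human data, whose absolute metric values (e.g. GTE
and LZC levels, which depend on sequence length and true sequential
structure) can differ substantially from the synthetic ones.

## Numerical choices and degenerate inputs

* 0·log 0 = 0 throughout the entropy computation; unvisited sources are
  skipped, not smoothed.
* Empty transition lists give all-zero matrices (density 0); cleaning that
  removes everything returns an empty sequence with a warning rather than
  an error.
* The stationary eigenvector uses the eigenvalue closest to 1 of the
  transposed probability matrix restricted to visited AOIs, after an
  explicit strong-connectivity check.
* KNN tie-breaks and fold assignment are fully deterministic given the
  seed; reports are byte-stable across reruns.
* All seeded randomness restores the caller's RNG state afterwards.

## Problem sizes used in the validation suite

The recovery suite simulates 16 + 16 recordings of 14,000 frames (the
study-scale cohort) over 20 master seeds for the group-ordering and
classifier checks, 10 seeds for the identical-profile null check, and
10⁵ transitions for transition-matrix recovery (binomial standard error
≈ 0.005 per cell, well inside the 0.02 acceptance band). Oracle-equivalence
checks run on sequences of length ≤ 8 against brute-force enumerations,
plus 1,000 random sequences for the counting invariants.

## Known limitations

* The world-model geometry is schematic; amplitude-dependent results in
  physical units require a calibrated layout for the actual panel.
* Only first-order Markov structure is modelled and mined; second-order
  chains and hidden-state models are out of scope.
* `common_ngrams` treats each recording as one sequence; concatenating
  scenarios per participant, if desired, is the caller's decision.
* The classifier is intentionally minimal (cosine KNN + PCA); it is a
  reproducible baseline, not a model-selection framework.
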