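---
title: "Episodic prototypes of lifelong face memory: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Episodic prototypes of lifelong face memory: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epmfaces)
library(dplyr)
```

## The representational question

Familiar-face recognition survives decades of appearance change. Two
classical accounts bracket the possibilities: a single *prototype* that
averages all experience with a person, and an *exemplar* store that keeps
every encounter as a separate trace and recognises through the joint
"echo" of all traces (the multiple-trace idea). `epmfaces` implements a
hybrid: experience is condensed online into a small number of **episodic
prototypes**, each covering an *episode of life* within which appearance
varies only moderately. This vignette documents the model equations, the
synthetic data the package generates, the numerical and design choices
behind each module, and what the simulations can and cannot show.

## Synthetic lifespan trajectories

`generate_trajectory()` emulates the stimulus structure such studies work
with: about 20 dated appearances of one identity spanning roughly 60 years
at about 3-year intervals. Appearance is a point in an abstract feature
space (default `d = 16`; features carry no claim of correspondence to
nameable facial attributes). Two processes move it:

* **Age-dependent drift.** A Gaussian random walk with per-year scale
  `sigma(age) = sigma0 / (1 + age / tau)`, encoding that facial change is
  strongest early in life and levels off. Steps between samples use the
  exact integral of `sigma(t)^2`, so the process is invariant to sampling
  density. Defaults `sigma0 = 0.25` per sqrt-year and `tau = 20` years give
  a within-episode spread of a few feature units over 15 years.
* **Deterministic jumps.** Sudden appearance changes (a haircut, glasses,
  an accident) at configured `(age, magnitude)` pairs, displacing the walk
  along a random unit direction. Jumps are config-driven rather than a
  random point process so every trajectory carries exact ground truth
  (`segment` column) for recovery scoring.

No published quantities exist for either scale; `sigma0`, `tau` and the
jump magnitude are free simulator parameters. The template value 12 for
jump magnitudes puts sudden changes roughly an order of magnitude above the
within-episode spread — the separability regime the episodic-prototype
account presumes. Likert similarity-rating data can be emulated from any
dissimilarity matrix by an affine map onto a 1–7 scale with Gaussian rater
noise (`simulate_ratings()`); the mapping is a modelling convenience, since
no published mapping from perceived similarity to ratings exists.

## The memory core

All retrieval quantities derive from three pieces:

* **Similarity**: cosine between probe and trace. Continuous features with
  cosine similarity replace the ternary features of classical
  multiple-trace models, whose echo is otherwise described only verbally.
* **Activation**: `A = S^3`, the sign-preserving cubic. It preserves the
  "more similar is weighted higher" contract while letting near-duplicates
  dominate; activation of dissimilar traces decays fast.
* **Recency weight**: `w = 2^-(now - t)/half_life`. Temporal weighting is a
  core commitment of the account but has no published functional form; the
  exponential half-life makes "how much more recent experience counts" a
  single interpretable parameter (years, in the templates 15).

Echo intensity is `sum(w A)` over traces; echo content the corresponding
weighted sum of trace vectors. `prototypicality()` pools all traces —
typicality judgements are modelled as global resonance — whereas
`verify()` takes the maximum per-prototype intensity, because verification
is a match against *some* representation. Both routes are exposed since
the account itself leaves the pooling ambiguous.

**Genesis rule.** Each incoming exemplar computes a *maximum delta*
(largest Euclidean distance to a prototype's centroid and members) against
every prototype; if even the smallest exceeds the threshold delta, the
exemplar founds a new prototype (the single-exposure "rapid update"), else
it joins the closest prototype whose centroid updates as an incremental
mean — so the influence of each new stimulus decreases as experience
accumulates. Assignment uses maximum delta rather than nearest-centroid so
the decision variable is exactly the one the genesis rule defines. The
threshold comparison carries a 1e-9 relative tolerance so that a threshold
set exactly to the data diameter yields exactly one prototype. Prototypes
are never merged or re-assigned: the process is forward-only and therefore
order-dependent, which is a modelling commitment (representations are
built during life, not re-fitted) and a documented limitation. The
threshold has no published value; for synthetic streams
`calibrate_threshold()` sets it to the midpoint between the largest
within-segment diameter and the smallest across-jump displacement, i.e. the
regime in which the rule is well-posed, and warns when no such threshold
exists.

**Latency linking.** Verification latency is
`base - slope * log(max(strength, 1e-6))` ms, clamped below at 200 ms (the
usual validity floor for human RTs). Only the *sign and ordering* of
latency contrasts are meaningful; the linking parameters are free, so
absolute milliseconds and published coefficient magnitudes are out of
reach by design.

**Norm-based encoding in the scenarios.** The scenario runner encodes
faces as deviations from the identity's mean appearance
(`center_to_norm()`), the norm-based coding familiar from face-space
theory. This matters because raw random-walk positions share their jump
history: late-life exemplars are strongly aligned with each other in the
cosine sense regardless of episode, which inflates cross-episode echoes.
After centering, episodes spread around the norm, the exhaustive
(whole-life) average sits near the norm itself and produces only a weak
echo, and episodic probes resonate mainly with their own episode — the
configuration in which the hybrid account's predictions are articulated.
Euclidean dissimilarities, and hence all clustering, are unaffected by the
centering.

## The clustering pipeline

`two_step()` reproduces the standard two-step analysis route: a
hierarchical Ward clustering determines cluster candidates, k-means
refines the partition from the Ward-cut means (no random restarts, keeping
the routine deterministic), and the cluster number is chosen by consensus
of two criteria computed on a classical (Torgerson) MDS embedding:

* the **elbow criterion** — suggested k maximises the second difference of
  the within-groups sum of squares, accepted as a *distinct* drop only when
  it leaves behind less than 10% of the one-cluster dispersion; smooth
  power-law profiles (no real elbow) fall back to the first k below that
  10% line;
* the **gap statistic** — `Gap(k) = mean_b log W_k(ref_b) - log W_k(data)`
  with B uniform reference draws over the data's bounding box and
  `s_k = sd_b * sqrt(1 + 1/B)`, choosing the smallest k with
  `Gap(k) >= Gap(k+1) - s_{k+1}`.

Two consensus details were forced by the geometry of lifespan data and are
this package's own design:

1. **Dominant gap jumps override the 1-SE stop.** For tight, roughly
   collinear episode clusters the data's log-dispersion shrinks at the
   same rate as the uniform reference's for k below the true number, so
   the gap curve is flat early and the textbook stopping rule can halt at
   k = 1 — and, in richer embeddings, residual within-episode structure
   can keep the gap creeping upward past the true k. A single-step
   increase of the gap curve exceeding twice its simulation error is an
   unambiguous signature of the true cluster number and takes precedence.
   When the two criteria then disagree by exactly one, the larger k wins.
2. **Adaptive embedding dimension.** Cluster statistics are computed on an
   embedding that keeps every spectral component above 5% of the leading
   eigenvalue (capped at 10). A fixed 2-D projection can collide genuinely
   separated clusters for a few percent of random high-dimensional episode
   geometries; for intrinsically planar data (such as rating-derived
   face-spaces) the adaptive choice coincides with 2-D. The reported
   2-D coordinates remain the face-space used for plotting.

The gap statistic's bounding-box reference is not rotation-equivariant:
rotating the data changes the box volume and shifts all gap values by a
constant. The chosen k, the data dispersion term, and the shape of the gap
curve are the isometry invariants, and those are what the tests assert.
Singleton clusters whose nearest neighbour lies beyond the 95th percentile
of nearest-neighbour distances are flagged as outliers
(`flag_outliers()`), mirroring the treatment of highly distinctive
exemplars.

## Prototype builders and design statistics

Image morphing of member photographs is represented throughout by
feature-vector averaging — the package's central abstraction. Episodic
prototypes are cluster centroids tagged with their age span; the exhaustive
prototype averages the whole lifespan; `loo_versions()` builds the
leave-one-out versions used as non-identical probe stimuli, and the mean of
all leave-one-out centroids equals the full centroid as an exact algebraic
identity.

The design helpers reproduce published trial arithmetic exactly:
`choose(n, 2)` pairwise displays (190 for 20 presentations, 28 for 8),
repeated-evaluation blocks (72 and 216 trials; 288 in total), and
verification sets over prototype versions with match/mismatch assignment
counterbalanced within each model's sex (an odd-count remainder is carried
across same-sex models so totals differ by at most one). The RT filter
removes, in a single pass, responses faster than 200 ms and responses more
than 2.5 SD above the participant's own raw mean — the lower bound global,
the upper bound per participant, with no iterative re-filtering. Cohen's d
uses the equal-weight pooled-SD form `(m1 - m2) / sqrt((sd1^2 + sd2^2)/2)`;
on published prototypicality summaries it reproduces the reported 0.63 and
2.23, but *not* the reported 2.60 for the youngster contrast (the formula
gives about 2.13; the variant behind the published 2.60 is unstated, and
the discrepancy is documented rather than matched). Partial eta squared is
the exact identity `F df1 / (F df1 + df2)`, and per-participant
correlations aggregate as `tanh(mean(atanh(r)))^2`.

## Scenario templates

`scenario_config()` hard-codes the classic design shape, all overridable:
four identities, 20 exemplars over 60 years, three jumps per lifetime; for
the exposure scenario two sets of eight presentations at 3-year spacing
(ages about 5–26 and 40–61) separated by an unobserved gap of more than
ten years containing one appearance jump. Seeds are explicit everywhere
and identical configs yield identical reports.

Each template asserts the qualitative pattern it exists to demonstrate:

* **study1** — the two-step clustering recovers, for every identity,
  exactly jumps + 1 age-contiguous clusters (adjusted Rand index 1 against
  ground truth).
* **study2** — prototypicality of episode prototypes regresses positively
  on episode recency under a finite half-life. The positive regression
  slope, not strict pairwise ordering, is the asserted pattern: the
  model's own cross-episode echo interference can swap adjacent mid-life
  episodes by an amount of order the interference noise while the gradient
  remains clearly positive. With an infinite half-life the check inverts:
  no strict recency ordering may remain. Exact equality across episodes is
  *not* asserted in that case — under cosine similarity with cubic
  activation the centered episode geometry leaves O(1) signed cross-talk
  that depends on the jump directions.
* **study3** — the first exemplar of the post-gap exposure set founds a
  new prototype in a single step (rapid update), and the two sets end in
  distinct prototypes.
* **study4** — leave-one-out versions of episodic prototypes yield
  stronger echoes and shorter simulated latencies than versions of the
  exhaustive prototype, with episodic strength increasing in episode
  recency (episodes pooled across models by recency rank).

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 20-exemplar trajectories
(d = 16), 50 streams for threshold bracketing, 100 seeds for jump
recovery, 20 seeds at B = 50 reference draws for gap-statistic blob
recovery (four Gaussian blobs of 15 points, SD 0.5, centers 16 apart), and
the four scenario templates at single seeds — sizes at which every Monte
Carlo margin in the checks is wide relative to its simulation error.
k-means uses 10 restarts (5 within gap references) at up to 100
iterations; within-SS profiles are made monotone by a cumulative minimum
before differencing; degenerate inputs (all-identical exemplars,
zero-variance data) are special-cased to one cluster or rejected with an
informative error.

## What passing simulations do and do not show

The generator produces clean episode structure: near-orthogonal jump
directions, stationary within-episode drift, no expression, pose,
lighting or imaging variability, no semantic knowledge, and exemplars
arriving in strict chronological order. Passing checks therefore show that
the *mechanisms* behave as claimed in their intended regime — they do not
show that human face representations work this way, nor do they reproduce
published coefficient magnitudes (latency linking and all drift/jump
scales are free parameters; only signs, orderings and exact design
arithmetic are reproduced). Order dependence of the genesis rule, the
free threshold, and the unpublished rating map are the main caveats to
carry into any interpretation.
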