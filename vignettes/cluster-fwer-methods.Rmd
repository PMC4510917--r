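---
title: "Cluster-based FWER correction for mass-univariate ERP tests: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-based FWER correction for mass-univariate ERP tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpcluster)
```

## The inference problem

A mass-univariate analysis of event-related potentials (ERPs) runs one
statistical test at every channel × time point of the epoch. With 128
channels and 201 time points that is ~26,000 two-sample Student's t tests
per contrast, so an uncorrected 5% level produces false positives
essentially always. ERP data are strongly dependent in space (volume
conduction, neighbouring electrodes) and time (autocorrelated potentials),
which makes Bonferroni-style corrections needlessly conservative and makes
*topological* corrections attractive: the unit of inference becomes a
connected region of the channel × time plane, or a per-point score that has
been enhanced by its neighbourhood support.

`erpcluster` implements the cluster/TFCE family of corrections together with
the resampling machinery that calibrates them, and a Monte-Carlo harness
that measures how well each combination controls the family-wise error rate
(FWER) — the probability of at least one false positive anywhere in the
epoch.

## Statistics on the t² map

The pointwise statistic is the classical pooled-variance two-sample t with
df = n₁ + n₂ − 2 (`two_sample_t()`). Pooled rather than Welch, because the
resampling schemes below pool or centre trials across conditions, and the
pooled t is the statistic that is exchangeable under their null. Two-sided
inference is carried on the squared map t² (`as_t2()`): clustering a
sign-free map merges adjacent positive and negative deflections, which is
the convention matching a t² cluster-mass statistic. A `sign_split` option
clusters the two polarities separately for users who prefer that reading;
it is off by default.

Given a cluster-forming threshold — the positive Student critical value
`t_crit` at a univariate two-sided p (`forming_threshold()`), applied as
t² > t_crit² — the suprathreshold points are partitioned into spatiotemporal
connected components. Two points are adjacent iff they are the same channel
at consecutive samples, or neighbouring channels (per the adjacency graph)
at the same sample; diagonal channel-and-time moves do not connect. This is
the most common convention for electrode × time clustering; it is isolated
behind one predicate in the C++ engine, so it is swappable. Each cluster c
yields three attributes:

* height(c) = max of t² over members,
* extent(c) = number of member points,
* mass(c) = sum of t² over members.

Membership is strictly greater-than; labels are assigned in
channel-major/time-minor raster order so labelling is deterministic.

## TFCE

Threshold-free cluster enhancement removes the forming threshold by
integrating over all of them:

TFCE(p) = Σ over grid levels h = h₀+dh, h₀+2dh, … ≤ value(p) of
extent_h(p)^E · h^H · dh,

where extent_h(p) is the size of the connected component containing p when
the map is thresholded at h. Defaults are E = 0.5, H = 2, dh = 0.1 on the t²
scale, h₀ = 0. Choices worth stating:

* **h₀ is fixed at 0**, not at the data minimum: t² maps are non-negative
  with minimum ≈ 0, and a data-dependent h₀ would make enhanced values
  incomparable across resampling iterations.
* **dh applies on the scale of the map given** (t² by default); the scale is
  recorded in exports.
* The top level is the largest grid level ≤ the map maximum, and the last
  partial slab enters with full weight dh — a plain Riemann sum. The O(dh)
  bias this causes is shared by observed and null maps and therefore cancels
  to first order in the max-statistic comparison.
* E = 1, H = 0 reduces TFCE to the cluster-mass statistic above h₀ — exactly
  so at the peak of a *unimodal* cluster. For a multimodal cluster the peak's
  component excludes other humps at high levels, so the peak value is a
  lower bound on the mass (e.g. the map [3, 0.5, 3] has mass 6.5 but peak
  TFCE → 4 as dh → 0). The tests assert the identity on unimodal fixtures
  and the one-sided bound in general.

The implementation sweeps levels once per map, descending, with an
incremental union-find whose roots carry per-parameter accumulators and
whose merged members record offsets; it is tested against a naive oracle
that re-clusters every level independently, to 1e-9.

## Resampling nulls and the max-statistic correction

Three engines estimate the null distribution (`resampling_plan()`,
`build_null()`):

* **permutation** — pooled trials are re-split without replacement into the
  original group sizes; exact under exchangeability;
* **percentile bootstrap** — n₁+n₂ draws with replacement from the pool,
  the first n₁ to group 1;
* **bootstrap-t** — each condition is mean-centred at every point, then its
  own trials are resampled with replacement.

For each of B iterations the t² map is recomputed and the maximum of the
chosen statistic over the whole epoch is recorded (max over clusters for
height/extent/mass, 0 when no cluster forms; max over points for TFCE). The
FWE threshold at level α is the value at sorted rank ⌈(1−α)·B⌉ of those
maxima, and observed clusters/points must *exceed* it strictly. Both choices
are deliberately conservative: together they guarantee FWER ≤ α
conditionally on the null sample, and for exchangeable data they give a
rejection probability of (B+1−⌈(1−α)B⌉)/(B+1) — e.g. 41/801 ≈ 0.0512 at
α = 0.05, B = 800, which is why realised FWERs sit a shade above α and why
small B is *liberal* (11/201 ≈ 0.0547 at B = 200). The observed statistic is
**not** appended to the null distribution; appending it is a sensitivity
variant the paper-scale studies do not use, and at moderate B the difference
is within Monte-Carlo noise.

Randomness comes from a named counter-based generator (SplitMix64) with one
substream per (seed, iteration, scheme): iteration i yields the same indices
whether iterations are drawn in order, out of order, or in parallel, and
`resample_indices()` exposes exactly the stream the engine consumes.
Permutations are Monte-Carlo draws, not exhaustive enumeration;
`exhaustive_permutations()` exists as a small-sample oracle. The bootstrap
is unconstrained by default — at n = 10 a bootstrap group can contain as few
as 2 distinct trials, which collapses the variance estimate, inflates null
t values, and is precisely why bootstrap corrections go conservative at
small n. The `min_unique` option implements the standard remedy (redraw
until each group has a minimum number of distinct trials).

Degenerate points with exactly zero pooled variance yield t = 0 when the
mean difference is 0 and are capped at ±`t_cap` (default 1e6) otherwise, so
no non-finite value ever reaches the clustering stage.

## The synthetic null generator

`generate_null_trials()` draws independent trials of spatially mixed,
AR(1)-smoothed Gaussian noise on a 2-D grid montage: lag-1 temporal
autocorrelation φ = 0.8, between-channel correlation exp(−d²/(2·1.5²)) in
grid spacings, 10 µV marginal SD, adjacency = symmetrised 4-nearest
neighbours. The defaults mirror a 128-channel, 250 Hz, −300..500 ms
recording; the simulation studies scale the geometry down (see below).
These numbers are fixed, field-realistic choices — for type-1 FWER they are
*not* load-bearing, because trials are i.i.d. and therefore exchangeable
across any condition split, which is the only property the permutation null
needs to be exact and the bootstrap nulls need to be asymptotically
correct. What the generator deliberately does **not** emulate: real ERP
component waveforms, heavy-tailed single-trial noise (a Student-t option
exists as a robustness check), slow drifts across trials (exchangeability
must hold exactly for the ground truth to be nominal), and a genuine
electrode montage (any user-supplied adjacency graph is accepted; only the
existence of a plausible neighbourhood structure matters). Passing tests on
this generator therefore demonstrate correct *error control machinery*, not
realism of the noise model.

`inject_effects()` adds rectangular or raised-cosine windowed shifts to a
trial subset; `two_effect_demo()` builds the stylised pair — one transient
+25 µV effect over 3 channels, one sustained +7 µV effect over 8 channels —
that illustrates how extent and height rank the same two effects in
opposite orders while mass and TFCE sit in between.

## The Monte-Carlo FWER harness

`run_fwer_experiment()` repeats, n_mc times: draw 2·max(n) trials from the
null pool without replacement, split them into two pseudo-conditions, run
every configured correction, and record whether any point is declared
significant. The realised FWER of a cell is the rejection proportion.
Design choices:

* **Incremental sample sizes**: the trials at size n are a prefix of those
  at the next size, mirroring the incremental design of data-driven FWER
  simulations and reducing variance between sizes.
* **Nested convergence**: FWER as a function of B reuses the first k
  iterations of one stream per replicate (`convergence_curve()`), isolating
  the effect of B; the value at the evaluation prefix equals the headline
  FWER exactly.
* **Agreement** between two schemes is exact equality of the corrected
  masks per replicate — equivalently, of their surviving-cluster sets, since
  both schemes threshold the same observed clusters. Under the null almost
  all masks are empty, so agreement is high by construction when both
  schemes control the FWER; a pointwise-overlap diagnostic is available in
  `mask_agreement()`.
* **Summaries**: `summarize_fwer()` reports mean, 20% trimmed mean
  (discarding ⌊0.2n⌋ at each end) and median with percentile-bootstrap CIs.
  Simultaneous coverage over m comparisons uses Bonferroni (per-comparison
  level 1 − (1−level)/m ≈ 99.29% for m = 7 at 95% simultaneous coverage) by
  default; a Šidák convention (level^(1/m), 99.27%) is available — the two
  are numerically almost identical and the choice is configurable rather
  than consequential.

## Problem sizes used by the shipped studies

The package's own validation studies (the test suite and
`scripts/acceptance.R`) run at desk scale: 5 synthetic datasets of 16
channels × 50 timepoints with a 700-trial pool, sample sizes
{50, 100, 300} per group (plus a 10-trial study for the small-sample
regime), 200 Monte-Carlo replicates per dataset, and B = 800 evaluated
iterations (the convergence study extends to 1000 with nested prefixes).
Pooled over datasets and sizes this yields 3000 replicates per cell family,
i.e. a binomial standard error of ≈ 0.004 on a 5% FWER and ≈ 0.002 at 1%,
which is tight enough to separate nominal control from the known
small-sample and low-B deviations while keeping the full suite inside an
ordinary interactive session.

## Known limitations

* Within-subject two-sample designs only: no paired tests, F tests,
  GLM/regression designs, or between-subject heteroscedastic settings.
* No step-down max-statistic procedures, no FDR, and no cluster p-values
  beyond survive/not-survive at a fixed α.
* Cluster-level inference semantics apply: membership of a specific point
  inside a surviving cluster is not itself guaranteed at level α (TFCE
  exists precisely to soften this).
* The epochs container is a plain-text matrix format with a JSON sidecar —
  deliberately simple and diff-able; vendor EEG formats are out of scope.
* The TFCE Riemann sum carries an O(dh) discretisation bias, shared between
  observed and null maps.
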