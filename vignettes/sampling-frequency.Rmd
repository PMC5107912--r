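---
title: "Deciding how often to sample a stream community"
author: "diatomASF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding how often to sample a stream community}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diatomASF)
```

## The problem

A single grab sample of a stream community represents its date of
collection only as long as the community has not drifted away from it.
`diatomASF` quantifies that horizon: given a (near-)daily taxon-abundance
series, it finds temporal regimes in the community, measures how fast
within-regime similarity decays with the sampling interval, and reports an
*appropriate sampling frequency* (ASF) per regime — the longest interval at
which consecutive samples still resemble each other beyond a similarity
threshold. Because catchment wetness is a strong driver of turnover in
running waters, the ASF is then put in relation to an antecedent
precipitation index (API).

All computations run on relative abundances, so the input may be densities
(cells/L) or raw counts; the unit cancels in every statistic.

## The procedure, stage by stage

### Temporal clustering (SOM + Ward)

Daily profiles are mapped onto a hexagonal Kohonen lattice. The number of
units follows the standard heuristic `5 * sqrt(n)`, realized as the
near-square grid (aspect ratio at most 1.3) whose unit count is nearest the
target — for a 348-day year that is a 10 x 9 lattice of 90 units. Training
is *batch* SOM: per epoch, samples are assigned to best-matching units and
each codebook vector becomes the Gaussian-neighbourhood-weighted mean of
the assigned samples, with the radius shrinking linearly from
`max(rows, cols)/2` to 1. Batch training plus deterministic PCA-plane
initialization makes runs bit-reproducible; `init = "random"` is available
behind a seed. Quantization error (mean sample-to-BMU distance) is recorded
at the end of every epoch and decreases monotonically on all data we
generate; topographic error and the U-matrix are exposed as diagnostics.

The codebook is then agglomerated by Ward's method on Euclidean distances.
Candidate cuts are scored by the Davies–Bouldin index *on the sample-level
assignments* (a sample inherits its BMU's cluster), so codebook units that
attract no samples cannot distort the score; cuts that orphan a cluster are
skipped. The automatic choice (index minimum) can be overridden with `k`,
which mirrors practice: the cluster count in field studies is often settled
by inspecting the U-matrix and dendrogram alongside the index.

Finally, `smoothContiguity()` replaces the manual step of reassigning
isolated dates: any maximal run of identical labels shorter than `minRun`
(default 5 days, enough to absorb isolated misassignments while preserving
genuine short regimes) is relabelled with its temporally dominant
neighbour's label — the longer adjacent run, ties to the earlier one —
iterated to a fixpoint. The rule is idempotent, and the affected dates are
reported as exemptions.

### Validation (MRPP)

`mrppTest()` uses the group-size-weighted mean within-group distance
`delta` and a seeded label-permutation null. We implement the permutation
core directly (the test suite cross-checks the observed `delta` and `A`
against `vegan::mrpp`) because we additionally expose an unweighted group
scheme and record the seed in the result object. p-values use the +1
correction, so 0.001 is the floor at 999 permutations; pairwise tables are
reported raw by default with an optional Holm adjustment. The default
distance is Euclidean on profiles — the same geometry the clustering stage
uses — with Bray–Curtis behind a flag; neither choice is claimed to
reconstruct any particular historical analysis.

### Similarity decay and the ASF

The percentage similarity index `PSI = 100 * sum_k min(P_ik, P_jk)` is tied
to the L1 metric by `100 - PSI = 50 * sum_k |P_ik - P_jk|`; the suite
asserts that identity on random profiles. `psiByInterval()` works in
*calendar days*: a pair separated by an unsampled day contributes at its
true calendar interval, never re-indexed, and both endpoints must carry the
same smoothed cluster label (pairs spanning two clusters are discarded).
Smoothed rather than raw labels feed the pairing, so the decay curves are
computed on temporally coherent groups.

`estimateASF()` applies a first-crossing convention: the ASF is the last
interval before the mean PSI first drops below the threshold, with
no-pair intervals skipped in the quantifier. Noisy curves can re-cross the
threshold; taking the first crossing is conservative and well defined. The
60% threshold is an empirical stability convention, kept as a default, not
a constant. Curves that never cross within the horizon are censored above
("> 30 days" at the default horizon); curves below the threshold at one day
are censored below ("< 1 day"). The standard error uses the pair count as
denominator although overlapping pairs are not independent — a documented
simplification, which is why tests and recovery claims are phrased on the
mean, not on formal confidence intervals.

### Hydrology (API)

`computeAPI()` implements `API_t = k(month) * API_{t-1} + P_{t-1}` with a
monthly decay schedule. The default schedule is a cosine ramp between a
winter maximum of 0.98 and a summer minimum of 0.85 — the conventional band
for the coefficient — with the minimum in July; where an
evaporation-derived schedule exists it should be passed in instead. The
variant `API_t = k * (API_{t-1} + P_{t-1})`, which also decays the latest
rain by one day, sits behind `form = "decay_rain"`. Initialization is
`apiInit = 0` with a 30-day burn-in excluded from quartile fitting, since
the recursion forgets its start at rate `k^t`. Wetness classes use the
25th/75th percentiles (linear-interpolation quantiles) of a long-term
reference when available, with the boundary conventions "at or below q1 =
low", "at or above q3 = high"; literal thresholds (e.g. 15.5 and 63.4 mm)
may be supplied to mirror a published record. In the ASF–API relation,
below-censored ASFs enter at 0.5 days (half the smallest measurable
interval), while above-censored ones are excluded rather than imputed.

## The synthetic generator: what it emulates, and what not

`generateCommunity()` produces a year of daily counts organized into
precipitation-linked regimes. Within a regime the latent profile evolves by
a *replacement model*: each day a fraction `r` of the proportion mass is
removed proportionally from all taxa and handed to the next taxon of a
regime-specific novelty pool (5 x nTaxa virtual slots, rare taxa first, so
novel mass enters taxa holding essentially no current mass). This model was
chosen over, say, a Dirichlet random walk because its similarity decay is
available in closed form: the expected PSI between days `s` apart is
exactly `100 * (1 - r)^s`, so the true ASF is
`log(threshold/100) / log(1 - r)` (`trueASF()`), and every pipeline stage
can be validated against analytic truth. The suite verifies the law to
`1e-6` on latent profiles.

Observed counts are multinomial draws of `countingDepth` valves (default
300, a typical bench counting effort) from the latent profile. Finite
counting *depresses* observed PSI below the latent value — two samples from
the same profile at depth 300 already sit near 89%, not 100% — and the
suite checks this deficit against a direct multinomial-resampling oracle
and its monotone decline with depth. Consequently ASF estimates at depth
300 are biased a few days short, a caveat that applies equally to real
300-valve counts; parameter-recovery claims (ASF within +-2 days of truth
in at least 90% of seeded runs at crossings of 5, 13 and 25 days) are made
at depth 10000 on 90-day regimes, where the deficit is small.

The default configuration mirrors a realistic study year: 113 taxa, window
2013-04-25..2014-04-30 (371 days), 23 missing dates (uniform by default, or
winter-concentrated to mimic cold-season sampler outages), five regimes
whose analytic ASFs span "> 30 days" (spring, autumn), 25 days (summer),
13 days (late winter) and "< 1 day" (winter high flow), with regime
rainfall from a Bernoulli–Gamma generator at 8 mm/day in winter down to
1.2 mm/day in the autumn low-flow.

Two features of real data are deliberately *not* emulated. First, the
replacement model is a compositional random walk: at high `r` a regime
drifts far from its starting composition, while real winter communities
remain recognizably "winter" even when day-to-day similarity is low. Regime
recovery by SOM + Ward is therefore demonstrated under drift-free regimes
(`r = 0`, depth 1000, where five regimes are recovered with pair agreement
1.0 and the Davies–Bouldin index selects k = 5), and under the full default
conditions the automatic cut may merge fast-drifting regimes — the `k`
override exists for that situation. Second, there is no mechanistic
ecology: no nutrient, light or grazing dynamics, and rainfall influences
the community only through the regime structure.

## Numerical conventions

* Profiles must sum to 1 within `1e-9`; all-zero samples are errors, never
  silently dropped.
* Ties in the map-size search go to the squarer grid, then to
  `rows >= cols`; ties between neighbour runs in contiguity smoothing go to
  the earlier run.
* MRPP permutation p uses `<=` with a `1e-12` tie tolerance, so a
  permutation reproducing the observed delta counts against significance.
* Degenerate inputs are handled explicitly: all-identical SOM training data
  yield a zero-error model with a warning; an MRPP group of one is an error
  naming the group; an ASF relation with fewer than three usable points
  returns `status = "undetermined"` rather than failing.
* Problem sizes in the test suite are chosen to keep the full run under a
  minute of CPU: 50 seeds per recovery setting, 20 seeded classification
  runs, 200 null replicates for MRPP calibration.

## Limitations

* PSI has no sampling-distribution theory here; the 60% threshold is a
  convention, and no significance is attached to a crossing.
* SE bands on PSI curves ignore pair overlap (see above).
* The API decay schedule is an input; the package does not derive it from
  evaporation data.
* ASF transfers poorly across catchments: API is catchment-specific, so
  the ASF–API relation should be refit per study area.
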