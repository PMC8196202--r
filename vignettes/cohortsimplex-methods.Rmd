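---
title: "Archetype geometry for cohort biomarker panels: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Archetype geometry for cohort biomarker panels: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the tunable parameters and why their
defaults are what they are, the numerical choices that matter, and what the
synthetic-data tests do and do not establish about real cohorts.

## 1. The model

A cohort of `n` participants measured on `d` continuous biomarkers is
z-scored into a matrix `Z`.  The working hypothesis of Pareto task
inference is that `Z`'s rows concentrate inside a `(k-1)`-simplex: each
individual is approximately a convex combination

```
z_i ≈ Σ_j w_ij · a_j ,   w_ij ≥ 0, Σ_j w_ij = 1,
```

of `k` extreme profiles `a_j` (archetypes), plus noise.  The simplex is the
geometric signature of trade-offs: no individual can be extreme in all
tasks at once, and position in the simplex encodes the compromise.  The
analysis never assigns individuals to clusters; the space is continuous.

**Fitting space.** A `k`-vertex simplex has positive volume only in
`k - 1` dimensions, so archetypes are fitted in the first `k - 1` principal
components of `Z` (a tetrahedron in 3 PCs).  This is the package default
and can be overridden by constructing a projection of any dimension `m`
with `k = m + 1`.  PCA uses the sample covariance; loading signs are fixed
by orienting each column's largest-magnitude entry positive, so results are
reproducible across platforms.

## 2. The simplex fit

### Objective

`fit_simplex()` minimizes, over the `k × (k-1)` vertex matrix `A`,

```
log V(A) + λ · (k/n) · Σ_i Σ_j max(0, −w_ij(A)) ,
```

where `w_i(A)` solves the affine system `[Aᵀ; 1] w = [x_i; 1]` and
`V(A) = |det(A₂−A₁, …, A_k−A₁)|/(k−1)!`.  The first term shrinks the
simplex; the hinge term charges points that fall outside, in barycentric
units (distance to the violated facet divided by the opposite vertex's
height), making the objective scale-invariant.

**Why the per-point normalization.**  With a raw summed hinge, any cohort
beyond a few hundred points forces *full* enclosure: the marginal penalty
of letting a single boundary point out always exceeds the volume gain.  A
fully enclosing simplex must clear the most extreme noise excursion on
every facet (roughly `3σ` for Gaussian noise at realistic `n`), and because
a simplex's vertices sit three inradii from its center, a `3σ` facet shift
triples into a vertex shift — empirically 12–30% of the edge length at 2%
noise, an order of magnitude worse than the noise itself.  Normalizing the
hinge per point (and scaling by `k`) puts the enclosure/volume balance
inside the noise band: facets settle where a controlled handful of boundary
points remain outside, and vertex recovery error drops to 2–4% of the edge
under the same conditions.  The default `λ = 10` yields an effective
per-point weight of `10k/n`: large cohorts are fitted softly, while tiny
exact configurations (e.g. points that *are* a simplex's vertices) have
`10k/n > 2` and stay in the full-enclosure regime, so noise-free geometry
is reproduced exactly.  For deliberately noise-free data at large `n`,
raise `λ` (the tests use `λ = 1000` there): with no noise band to absorb,
hard enclosure is the right regime.

### Initialization and optimization

The initial vertex set is a furthest-sum seed (greedy data points
maximizing summed distance to those already chosen, started from the point
farthest from the centroid), refined by a vertex-wise maximum-volume ascent
over data points — the volume is affine in any single vertex, so each sweep
is exact — then expanded about its centroid until every point is enclosed.
From there, Nelder–Mead runs with up to `restarts` (default 6) restarts;
even-numbered restarts nudge the incumbent by a deterministic 0.1% jitter
to escape simplex-search stagnation at hinge kinks, and the best iterate
ever seen (including the initializer) is kept.  The whole fit is a pure
function of (data, configuration): the jitter stream derives from
`config$seed`.  Precision-critical uses (e.g. verifying that the minimal
enclosing triangle of the unit square has area exactly 2) should raise
`restarts` to ~100 and drop `tol`, which reaches the optimum to ~1e-4.

An alternative `algorithm = "interior"` restricts vertices to observed data
points and maximizes volume (a pure convex-combination variant).  It is
robust and fast but biased inward by construction; it serves as a
cross-check, not the default.

### Degenerate inputs

Rank-deficient clouds (hull volume 0) and `n < k` are errors.  A singular
candidate simplex inside the optimizer returns a large objective value
rather than propagating a failed solve.

## 3. The t-ratio and the shuffle null

The significance statistic is `t = V_enclosing / V_hull`.  The fitted
simplex deliberately cuts into the noise band, so its raw volume can be
smaller than the hull's; for the statistic we expand each facet just past
the furthest point beyond it.  That facet-wise minimal expansion is
algebraically an affine dilation by `1 + S`, `S` the summed per-facet
barycentric violation, so `V_enclosing = V·(1+S)^(k-1)` and `t ≥ 1`
always.  Using enclosing volumes matters: soft-fit volumes alone would let
an unstructured (ellipsoidal) cloud score as small a ratio as a genuinely
simplex-shaped one, destroying the contrast the null comparison needs.

The null model permutes each feature column independently (every marginal
preserved, all inter-feature correlation destroyed; z-scores are unchanged
by permutation, so shuffled copies are not re-standardized).  Each of
`n_shuffles` null datasets goes through the *identical* pipeline — PCA,
fit, enclosing t-ratio — with per-shuffle sub-seeds drawn from the root
seed by a fixed counter scheme.  The p-value is the fraction of null
t-ratios at or below the observed one; zero exceedances are stored as
`p_value = 0` and printed as `< 1/n_shuffles`.  Exchangeability of the
pipeline between real and shuffled data makes the test valid regardless of
optimizer imperfections, and on unstructured Gaussian cohorts its rejection
rate at α = 0.05 stays at the nominal level (checked over 50 replicates).

**Hull volumes** are computed exactly by an in-package incremental
beneath-beyond convex hull (any dimension ≥ 2; 1-D is the range), since the
fitting spaces here are low-dimensional (`m = k - 1 ≤ 7`).

## 4. Choosing k, and archetype uncertainty

`scan_k()` runs the significance test for each candidate `k` and applies
Bonferroni over the candidate set: selected `k` is the smallest candidate
with `p < α/|candidates|`, or none.  A caveat discovered with the synthetic
generator: for a *regular* simplex cloud the PC spectrum inside the simplex
plane is flat, the retained 2-PC subspace is an arbitrary rotation, and the
projected cloud is often significantly triangle-like against its own
shuffle null — so the smallest-significant rule can legitimately return
`k - 1` on perfectly tetrahedral data.  Real biomarker panels have skewed
spectra, where this degeneracy is less acute, but the scan table (raw and
corrected p per candidate) should always be inspected rather than trusting
the single selected value.

`bootstrap_archetypes()` resamples rows with replacement, refits, maps each
refit into the reference PC frame, and matches vertices to the reference by
the minimum-total-distance assignment (exhaustive over permutations,
`k ≤ 8`).  Per-archetype means and covariances of the matched positions are
the uncertainty ellipses.

## 5. Enrichment analysis

For each archetype, all samples are ranked by Euclidean distance in model
space and cut into `B = 20` equal-count bins (sizes differ by at most one;
ties broken by row index so the binning is a stable sort).  Equal-count
rather than equal-width binning guarantees the first bin — the test group —
has a fixed sample size (`n/B ≈ 155` at the scale this analysis targets)
instead of emptying in the tails.

* Continuous traits: Welch's two-sided *t* on the first bin vs all other
  samples.  Means *and* medians of both groups are reported, but the
  inferential test is on means; the median contrast is descriptive.  A
  decay-monotonicity score (Spearman correlation of per-bin means with bin
  index) is attached as a description of the "decays with distance"
  narrative, never as a gate.
* Discrete traits: each category (including an explicit `"no response"`
  category for missing answers — non-response is itself enrichable) becomes
  an indicator; both hypergeometric tails are computed, the smaller is the
  record's p-value, the direction names the tail, and *both* tails count in
  the test family.
* Family-wise control is Bonferroni at `α / n_tests`, with `n_tests`
  counting exactly the tests performed (untestable records — zero-variance
  traits, first bins with fewer than two observations, zero-carrier
  categories — are excluded from the family and reported with `p = 1`).

`bin_sensitivity()` re-runs the table at several bin counts (default 15,
20, 25) and reports hits gained/lost relative to the middle count.  With
more bins the first bin shrinks and power drops, so the significant set
generally shrinks from 15 to 25 bins.

A planted-truth caution: a trait that decays with distance to one archetype
is genuinely *depleted* near opposing archetypes, and with realistic sample
sizes the two-sided tests will flag those depletions.  "Detected at the
target archetype" therefore means significant with direction `high` there;
significant `low` records at other archetypes are real geometry, not false
positives.

## 6. Trajectories

Later visits are standardized with the *baseline* means/sds and projected
with the *baseline* loadings — never refit — so movement reflects the
individual against a fixed frame, not model drift.  Each projected point
gets barycentric coordinates from the fitted simplex; a point is outside
when its smallest weight is below `−1e-9` (absolute, configurable via
`outside_tol` to absorb fit slack).

`flag_trajectories()` considers only participants with ≥ 3 time points (a
single aberrant visit may be a measurement error or a transient), ranks by
first-to-last Euclidean displacement in model space, and flags the top 2%
as movers, labelled toward/away per archetype by the sign of the distance
change between first and last visit.  Independently, trajectories with
≥ 2 out-of-simplex points are flagged as excursions.  All three thresholds
(3 visits, 2%, 2 points) are exposed as arguments.  Distances are computed
in PC space, where the simplex lives; displacement in the full z-space can
be obtained by projecting with an identity model if needed.

## 7. The synthetic cohort generator

The generator produces what the analysis assumes, with full ground truth:

* `make_archetype_profiles()`: a regular `(k-1)`-simplex of chosen edge
  length, embedded in `d` dimensions by a seeded random orthonormal map.
* `sample_cross_section()`: symmetric Dirichlet(α) mixture weights times
  the profiles plus isotropic Gaussian noise.  Defaults α = 0.6 (slightly
  vertex-concentrated, giving the visible corners real lab clouds show) and
  noise sd = 5% of the minimum inter-archetype distance.
* `plant_trait()`: continuous traits `effect · exp(−dist/λ) + N(0,1)` with
  default decay length half the edge; discrete traits are Bernoulli
  carriers boosted inside the nearest distance decile.
* `sample_longitudinal()`: per-participant visit series confined to the
  simplex plane — stationary jitter (`tumble`), a fixed fraction of the
  remaining distance toward an archetype per visit (`drift`, default 20%),
  or fixed steps along a direction that crosses the boundary (`escape`,
  default step 40% of the edge).  Jitter-free patterns realize their
  construction exactly, which the tests exploit.  In the flagging tests the
  planted drift's total displacement is several-fold the spread of tumbler
  displacements, matching the "top 2% mover" design point.

Every generator is a pure function of (parameters, seed) and restores the
caller's RNG state.

**What passing tests do not show.**  The generator makes no attempt to
mimic real analyte marginals (skewness, heavy tails, detection limits),
inter-omic correlation structure, compositional microbiome constraints, or
informative missingness.  Recovery and calibration results here establish
the pipeline's correctness under its own model; on real data the simplex
hypothesis itself, the noise isotropy, and the Gaussianity of marginals
are empirical questions the shuffle test only partially addresses.

## 8. Numerical conventions

* z-scoring divides by the population sd (n denominator): normalization,
  not inference, and it makes fixtures exact.
* Imputation (feature mean over observed values) precedes standardization,
  so imputed cells sit exactly at z = 0, and re-projection of a baseline
  row through `apply_standardization()` reproduces its coordinates to
  1e-12.
* The missingness filter removes participants first, then features, and
  iterates both to convergence, making the survivor set order-independent.
* Equal-count binning gives the earliest bins the remainder when `B` does
  not divide `n`.
* Sub-seeds for shuffles, bootstrap resamples and scan candidates come from
  a fixed affine counter on the root seed, keeping every draw below 2³¹.
* Problem sizes in the test suite (cohorts of 200–1200, 100–1000 shuffles,
  20-seed Monte Carlos) are chosen so each statistical check has clear
  resolution at desk scale; they are the package's own test design points.

## 9. Known limitations

* Fits for `k > 8` are unsupported (exhaustive bootstrap matching and
  hull construction are low-dimensional by design); curved (non-linear)
  Pareto fronts are out of scope.
* The minimum-volume criterion is not a likelihood: no standard errors come
  with the archetypes beyond the bootstrap ellipses.
* The smallest-significant-k rule can err low on spectrally flat clouds
  (see §4).
* Trajectory flagging ranks and thresholds; it does not model measurement
  error, regression to the mean, or visit-spacing irregularity, and no
  sensitivity/specificity claims are attached to the flags.
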