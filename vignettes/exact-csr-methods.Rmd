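---
title: "Exact CSR moments for the subset nearest-neighbor G function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact CSR moments for the subset nearest-neighbor G function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nncsr)
```

## The problem

In single-cell spatial data (multiplex immunofluorescence, spatial
transcriptomics) and in many epidemiological and ecological settings, the
points of interest — phenotyped cells, infected individuals — are a subset
of a larger observed point pattern. To decide whether those n positive
points cluster, the observed nearest-neighbor G function is compared
against a null in which the n marks are assigned uniformly at random to
the N observed locations. This *sample-specific* CSR conditions on where
points could actually be: it automatically respects tissue gaps, vessels,
and density gradients that break the stationarity assumption behind the
textbook Poisson null G(r) = 1 − exp(−λπr²).

That null is usually estimated by permutation: redraw random size-n
subsets hundreds or thousands of times and average their G curves. The
result is approximate, seed-dependent, and expensive. This package
computes the permutation limit in closed form.

## The model

For a subset S of size n drawn uniformly from the N locations, the subset
G function is

G_S(r) = (1/n) Σ_{p∈S} 1{∃ q ∈ S, q ≠ p, dist(p, q) < r},

the fraction of positive points with another positive point strictly
within r. Write n_p for the number of points (of any mark) within r of p.
Conditioning on p ∈ S, the other n − 1 members of S are a uniform draw
from the remaining N − 1 points, so the chance that S avoids all n_p
neighbors of p is the hypergeometric ratio
C(N−1−n_p, n−1) / C(N−1, n−1), and

E[G_S(r)] = (1/N) Σ_p [ 1 − C(N−1−n_p, n−1) / C(N−1, n−1) ].

The variance needs second moments of the per-point success indicators
X_p. For a pair p ≠ q, E[X_p X_q] splits into two cases:

* **direct neighbors** (dist(p, q) < r): joint selection is enough, so
  E[X_p X_q] = C(N−2, n−2) / C(N, n);
* **non-neighbors**: given both selected, each must find a neighbor among
  the other n − 2 selected points. By inclusion–exclusion over "p finds
  none" and "q finds none",
  the joint success probability is C(N−2, n−2)/C(N, n) × [1 − A − B + C],
  with A = C(N−2−n_p, n−2)/C(N−2, n−2), B the same with n_q, and
  C = C(N−2−(n_p+n_q−n_{pq}), n−2)/C(N−2, n−2), where n_{pq} counts the
  shared neighbors of p and q — points within r of both are avoided once,
  not twice.

Then E[G²] = (1/n²)(Σ_p E[X_p] + 2 Σ_{p<q} E[X_p X_q]) and
Var[G_S(r)] = E[G²] − E[G]². An algebraically identical covariance
decomposition, (1/n²) Σ_p Var[X_p] + (2/n²) Σ_{p<q} Cov[X_p, X_q], is also
implemented (`method = "covariance"`); the two forms serve as mutual
cross-checks and agree to ~1e−15 on every test fixture.

## Numerical choices

* **Log-gamma evaluation.** Every binomial-coefficient ratio is computed
  as a difference of log-gamma values and exponentiated; factorial
  quotients overflow long before N reaches realistic cell counts.
  Impossible selections (k < 0 or k > a) short-circuit to a −Inf
  log-probability, i.e. probability 0 after `exp()`. This single
  convention silently covers every boundary the derivation leaves
  implicit (too few non-neighbors, n = 1, n = N); it is a documented
  numeric contract of `log_binom()`, not an error.
* **Strict inequality.** The definition uses dist < r everywhere, and the
  package follows it in neighbor counting, the observed G, and the
  enumeration/permutation baselines alike. Common G implementations use
  ≤; the `closed` flag (`--closed-radius` on the CLI) flips the
  convention consistently through every code path for cross-tool
  comparison, and a dedicated test checks that the exact moments still
  match enumeration under either convention on a boundary-heavy pattern.
* **Cancellation clamp.** Var = E[G²] − E[G]² can come out a few ulp
  below zero where the true variance vanishes (r = 0, r beyond the
  pattern diameter, n = N). Negative values within 1e−9 are clamped to 0;
  anything more negative raises an internal-consistency error rather than
  being hidden.
* **Degenerate subsets.** n ≤ 1 makes G_S identically zero; the package
  returns zero mean and variance with a warning instead of erroring, so
  batch pipelines survive samples with a single positive cell.
* **Memory shape.** The variance needs pairwise quantities, so it is
  computed radius-by-radius with one O(N²) pass per radius: memory stays
  O(N²) however long the radius grid is. Neighbor counts use a full
  distance matrix up to 2000 points and a cell-list (grid binning) pass
  above that; the two paths are tested for exact integer agreement.
* **Cost warning.** The variance pass is quadratic per radius, and beyond
  roughly 250 points permutation becomes the more practical way to get a
  null spread; `exact_var_g()` warns (configurably) past that size. The
  mean remains cheap at any N.

## Validation strategy

The closed form has an unimpeachable oracle: for small patterns every
size-n subset can be enumerated. `brute_force_csr()` walks all C(N, n)
subsets in lexicographic order (refusing beyond a cap, default 2×10⁵) and
accumulates the per-radius mean and *population* variance of G_S — the
divide-by-count convention, since the subset distribution is enumerated,
not sampled; a two-pass accumulation avoids sum-of-squares cancellation.
On the canonical fixture — 30 uniform points, 5 positive, all 142,506
subsets — the closed-form mean matches the enumeration average to ~1e−15
at every one of 100 radii, and on a 20-point pattern (15,504 subsets) the
variance matches to the same accuracy:

```{r oracle}
pp <- generate_pattern(simulation_config(N = 30, n = 5, seed = 101))
grid <- default_radius_grid(pp)
bf <- brute_force_csr(pp, 5, grid)
bf$n_subsets
max(abs(exact_mean_g(neighbor_counts(pp, grid), 5) - bf$mean$g))
```

The permutation estimator (`permuted_csr()`, uniform subset draws without
replacement, mandatory seed, type-7 quantile envelope) converges to the
closed-form mean at the Monte-Carlo rate; with 10,000 permutations the
agreement is within 4 Monte-Carlo standard errors at every radius.

## The deviation test

There is no canonical construction for a p-value of the observed curve
deviating from CSR, so the package adopts the simplest defensible choice
and documents it as such: a
two-sided normal (Wald) test, z = (G_obs − E[G]) / sd, with pointwise
mean ± z₍α/2₎·sd confidence bands. Radii with sd = 0 are reported with an
undefined (NA) z rather than dropped, with p = 1 when the observed value
equals the degenerate mean and p = 0 otherwise, so output length always
equals grid length. P-values are pointwise (the curves are reported
pointwise); a `bonferroni` flag gives family-wise control across the grid
for users who want it. No global envelope tests are attempted.

The approximation has a real, known limitation: G over small subsets is
supported on multiples of 1/n, and near r where E[G] approaches 0 or 1
the distribution is both discrete and skewed, making the Wald test
conservative. On the package's calibration fixture (20 points, 6
positive, 2,000 random markings, mid-grid radius) the empirical size at
α = 0.05 is ≈ 0.04; across other patterns of the same size it ranges
roughly 0.01–0.05 — conservative, never anticonservative, in what we
observed. The permutation envelope remains the nonparametric alternative
when exact size matters.

## Synthetic data: what it does and does not emulate

The generators exist to validate the machinery, not to imitate tissue:

* `uniform` — iid uniform points in a rectangle. The canonical fixture is
  30 points with 5 positive in the unit square, small enough to
  enumerate exhaustively. The oracle-equality property holds for *any*
  pattern, so the fixture's role is reproducibility, not realism.
* `hole` — uniform on the window minus rectangular gaps, by rejection
  sampling (exact, no area weighting). Emulates the gross heterogeneity
  (vessels, tears, compartment boundaries) that makes the stationary
  Poisson baseline misleading.
* `clusters` — uniform parents with Gaussian offspring truncated to the
  window (rejection), `offspring_sd = 0` collapsing onto parents.

Marks are assigned by drawing a uniform size-n subset (`assign_marks()`),
which *is* the null hypothesis of sample-specific CSR. All generation is
seeded and bit-reproducible. What passing tests on these patterns shows
is that the combinatorics and numerics are right for arbitrary point
configurations; what they cannot show is anything about segmentation
error, mark misclassification, or cell-size exclusion effects in real
images — those enter upstream of this package's contract.

Default problem sizes in the test-suite and validation script (30/5 for
the mean oracle, 20/5 for the variance oracle, 10,000 permutations, 2,000
markings for test size) are the exhaustively-enumerable scales at which
the ground truth is computable exactly.

## Design choices that were genuinely open

* **Radius grid default**: 100 evenly spaced radii from 0 to a quarter of
  the shorter window side (no window: to the maximum nearest-neighbor
  distance over all points). No grid is canonical; this one spans the
  informative range for the fixtures and is always overridable
  (`--rmin/--rmax/--rcount`).
* **Subset draws, not label shuffles**: permutation draws index subsets
  uniformly without replacement — the same distribution as shuffling a
  label vector, with a simpler contract.
* **Units are opaque**: coordinates and radii must merely agree; p-values
  are invariant to common rescaling (tested).
* **2D only**: the pair-case analysis is planar; inputs with a `z` column
  are rejected outright rather than silently projected.
* **No edge correction anywhere**: the observed G is the raw subset cdf
  and the null conditions on the same locations, so border effects cancel
  from the comparison; corrected estimators (border, Kaplan–Meier,
  Hanisch) would compare a corrected observed curve against an
  uncorrected null and are deliberately out of scope. Curves from tools
  that apply corrections by default will differ visually at large r.

## Known limitations

* The exact variance is O(N²) per radius and becomes impractical somewhere
  beyond a few hundred points; the package warns rather than refuses.
* The Wald p-value is approximate and conservative for small n or extreme
  radii (see above).
* The framework requires the positives to be a subset of a larger
  observed pattern; when every point is positive (n = N) the null is
  degenerate and only the theoretical Poisson baseline remains.
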