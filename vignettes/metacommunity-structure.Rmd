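---
title: "Classifying metacommunity structure from incidence matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying metacommunity structure from incidence matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emstools)
```

## The model

A metacommunity is a set of local communities (here: sites, e.g. stream
reaches) linked by dispersal of multiple species. Its co-occurrence structure
is summarized by three *elements*, all computed on a **doubly ordered
incidence matrix**: a binary sites-by-species table whose rows and columns
have been permuted by their first-axis correspondence-analysis (CA) scores so
that a latent gradient, if present, runs along the matrix.

1. **Coherence** — the number of *embedded absences*: zeros lying strictly
   inside a species' range (between its first and last presence over the
   ordered sites), plus the analogous gaps in site ranges over the ordered
   species axis. Few embedded absences mean species occupy unbroken ranges
   along one shared gradient.
2. **Turnover** — after filling each species' range, the number of
   *replacements*: for every species pair, the product of the site counts
   where each occurs without the other, summed over pairs. High turnover
   means species substitute one another along the gradient; low turnover
   means ranges nest inside one another.
3. **Boundary clumping** — Morisita's index of the tallies of species range
   limits across the ordered site axis: `I > 1` means range edges coincide
   (discrete community blocks), `I < 1` means they are overdispersed,
   `I ≈ 1` means they fall at random.

Coherence and turnover are tested against an ensemble of null matrices;
boundary clumping is tested analytically with the dispersion chi-square
`I(X−1) + n − X` for `X` boundaries over `n` positions. The classification
flowchart then assigns one of 14 structures: `random` (coherence not
distinguishable from null), `checkerboard` (more embedded absences than
null), and — for coherent metacommunities — nested subsets with clumped /
random / hyperdispersed species loss, or Clementsian / Gleasonian / evenly
spaced gradients, each with a `quasi_` variant when the turnover element has
a direction but no significance.

```{r flowchart}
# the decision function is total over all element outcomes
classify_structure(
  coherence_p = 0.001, coherence_obs = 3188, coherence_null = 5936,
  turnover_p = 0.576, turnover_obs = 874297, turnover_null = 1089300,
  morisita_index = 7.565, morisita_p = 0.001
)
```

## Null models

Two randomization schemes are provided through `simulate_null_matrices()`:

* `fixed_fixed` (default) — curveball trades preserving *every* row and
  column sum. This conditions on site richness and species occurrence
  exactly, the most conservative choice. Chain defaults: burn-in of
  `5 * fill` trades and `fill` trades between samples, where `fill` is the
  number of presences.
* `proportional_r1` — row sums fixed, species drawn with probability
  proportional to their occurrence. Column sums then vary binomially, which
  lowers the null's embedded-absence baseline.

Every null matrix is **independently doubly ordered** before its statistic
is computed, exactly as the observed matrix is; mixing an ordered observed
value with unordered null values would conflate the gradient signal with the
ordering procedure itself. Significance is a two-sided z-test against the
ensemble mean and standard deviation.

A practical consequence of conditioning on both margins is worth knowing: a
*perfectly* nested (staircase) matrix is the unique binary matrix with its
margins, so its fixed-sum null ensemble is degenerate (`sd = 0`) and the
z-test is undefined. `ems()` raises a degenerate-null error in that case;
real data, which are never perfectly nested, do not trigger it.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_sim` | 1000 | null matrices per test; 200 is adequate for screening |
| `alpha` | 0.05 | significance level in the flowchart |
| `mode` | `"both"` | embedded absences over species and site ranges; `"columns_only"` restricts to species ranges (sensitivity check) |
| `burn_in`, `thin` | `5*fill`, `fill` | curveball chain controls, in single trades |
| `tol`, `max_iter` | `1e-10`, `10000` | reciprocal-averaging convergence |
| `df_convention` | `"table"` | Morisita chi-square df (see below) |

**Morisita degrees of freedom.** The df of the boundary-clumping chi-square
is a reporting convention, not a derivable quantity, and is encapsulated in
one place. The default `"table"` convention uses `S − 3` for `S` species,
matching the reporting convention of the stream-fish study tables this
package mirrors; `"sites"` uses the classical `units − 1`. With many more
species than sites the `"table"` convention makes the test anticonservative
near `I = 1`, which biases Gleasonian verdicts toward evenly spaced; users
interested in that distinction should use `df_convention = "sites"`.

## Numerical choices

* CA axis 1 is computed by reciprocal averaging (power iteration on the
  transition operator of the smaller dimension, four averaging cycles per
  convergence check). Site scores are standardized to weighted mean zero and
  variance one (row-sum weights) and the sign is fixed by the first site, so
  outputs are deterministic; every statistic is invariant under reflection.
* The start vector is a ramp plus an incommensurate sine: a plain ramp can
  be exactly weight-orthogonal to the dominant non-trivial axis on small
  symmetric matrices, silently locking onto a lower axis.
* Ties in ordination scores are broken by original input order (stable
  sort).
* Matrices whose second and third axes are nearly tied (checkerboard-like
  data are *built* this way) make the iteration arbitrarily slow. User-facing
  `reciprocal_averaging()` errors on non-convergence; inside `ems()` both the
  observed matrix and every null matrix fall back to the final iterate, so
  the two sides of the test are always treated identically.
* Structurally disconnected matrices (block-diagonal bipartite structure)
  are ordered with a warning: axis 1 then separates blocks degenerately. A
  perfectly compartmented (Clementsian) matrix is disconnected by
  construction, so the warning is expected there.
* Degenerate shapes: single-row/column matrices pass through
  `doubly_order()` unchanged; an all-ones matrix has no non-trivial axis and
  is an error.

## Deconstruction

`core_satellite()` splits the pool at the mean occurrence fraction, with
"greater than the mean" read strictly (ties are satellite). `guild_subsets()`
builds per-guild matrices and keeps pools with more than 15 species
(`min_species = 16`), re-cleaning each independently — which is why
sub-metacommunities generally have fewer communities than the pool. In
`run_metacommunity_analysis()` a sub-metacommunity that degenerates (e.g. a
core that collapses to a constant block on idealized synthetic data) is
reported in `$skipped` rather than aborting the run.

## The gradient tree

`fit_gradient_tree()` is a deterministic univariate CART: candidate
thresholds at midpoints between adjacent observed values, split chosen to
maximize SSE reduction, ties broken by predictor column order then lower
threshold, stopping at `max_depth` (default 5), node size `< 2 * min_leaf`
(default `min_leaf = 5`), or relative SSE reduction below `cp` (default
0.01, measured against the root SSE — the convention of the usual
recursive-partitioning implementations, against which the tree is
cross-checked in the test suite). Surrogate splits are not implemented;
sites missing a chosen split variable are dropped from that subtree with a
warning.

Note that `cp` is *not* an overfitting guard: on pure-noise predictors the
best spurious split typically reduces SSE by far more than 1% of the root
SSE, so an unpruned tree will split noise. Cross-validated pruning is out of
scope; treat fitted thresholds as descriptive unless validated.

## What the synthetic generator emulates — and what it does not

`simulate_metacommunity()` places sites uniformly on a latent gradient and
builds species ranges that encode each structural family (contiguous
compartments, independent ranges, evenly spaced ranges, common-end nested
ranges with clumped / random / hyperdispersed loss positions, mutually
exclusive pairs, Bernoulli noise). Generator conventions, chosen once for
structural fidelity at the study's scale and documented here:

* Gradient-family range widths are Beta-distributed with mean 0.3
  (concentration 10); Clementsian compartments default to 3.
* Nested families use within-range occupancy 0.3 with 4 loss clusters
  spanning 0.25–1 of the gradient. Lower occupancy keeps the matrix fill
  near realistic survey levels, which is what gives the null ensemble a
  *larger* turnover than the nested observed matrix (at high fill the
  direction inverts, because range-filled null ranges span nearly the whole
  axis).
* The checkerboard family seeds mutually exclusive species pairs on sparse
  shared site sets and then applies margin-preserving swap batches that
  increase post-ordination embedded absences. This is deliberate: the EMS
  checkerboard is *defined* as the anti-coherent tail of the fixed-margin
  class, and no property shared by the whole class (exclusivity included —
  randomly placed exclusive pairs are statistically indistinguishable from
  random under the fixed-sum null) can put a matrix in that tail.
* Environmental variables are monotone transforms of the gradient plus
  Gaussian noise, scaled into realistic ranges of the seven in-stream
  predictors (turbidity, conductivity, pH, dissolved oxygen, temperature,
  channel depth and width); noise variables are gradient-independent.

What passing recovery tests show is that the classifier identifies these
*idealized* structures at survey-like dimensions (tests use 60 sites x 100
species, null ensembles of 200, and 40-site environmental tables — sizes
chosen so the whole suite runs in minutes). Real data differ in ways the
generator does not emulate: spatial autocorrelation and dendritic network
topology, abundance-dependent detection, temporal (wet/dry season) dynamics,
and mixtures of structures across species groups. A clean recovery rate on
synthetic data is evidence the statistics and flowchart are implemented
correctly, not that any field metacommunity will be classified with the same
reliability.

## Known limitations

* Only CA axis 1 is used, as in the standard workflow; structures organized
  along a second axis are invisible.
* The quasi-structure direction (`turnover_obs` vs null mean) is read as a
  point comparison; exactly equal values are resolved toward the nested
  family.
* The fixed-sum null has no power against checkerboard-like segregation
  that leaves margins unchanged in small matrices (the 2x2 checkerboard's
  class has exactly two states, both perfectly coherent).
* Morisita's test assumes boundary tallies are approximately independent
  across positions; strongly autocorrelated gradients violate this.
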