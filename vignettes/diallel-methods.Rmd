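---
title: "Half-diallel analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Half-diallel analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diallelr)
```

This vignette is the package's account of the statistics it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-trial generator does and does not emulate, and the choices made
where the design was genuinely open.

## The design and the data model

A half diallel crosses `p` inbred parents in all unordered combinations.
Griffing's **method 4** analyses the `p(p-1)/2` F1 crosses only;
**method 2** adds the `p` selfed parents (`p(p+1)/2` entries). Entries
are evaluated in a randomized complete block design (RCBD) with `r`
blocks, possibly in several environments (location-year combinations).
A record is one observation of one entry in one block of one
environment; the pair `(a, b)` is unordered, and the package
canonicalizes `(b, a)` on input. `parent_a == parent_b` marks a self.

The package analyses **balanced** layouts only. In a balanced RCBD the
arithmetic entry mean equals the least-squares mean of the entry, so
every downstream closed-form estimator is exact; unbalanced data are
rejected with a report of the missing plots (`validate_design()`) rather
than approximated. Imputation, REML for unbalanced layouts, and
reciprocal/maternal effects (Griffing methods 1 and 3) are out of scope.

Before any analysis, `qc_normality()` reports moment-ratio skewness
`g1 = m3/m2^{3/2}` and excess kurtosis `g2 = m4/m2^2 - 3` per
trait-by-environment cell, plus sorted normal-quantile pairs for a Q-Q
display. Zero-variance cells are flagged instead of returning NaN.

## Combining-ability estimators

Write `x_ij` for the entry mean of cross `i x j`, `X_i.` for the row
total of parent `i` over its crosses, and `X..` for the total over all
crosses. Method 4 uses the closed forms

- `m = 2 X.. / (p (p-1))`
- `g_i = (p X_i. - 2 X..) / (p (p-2))`
- `s_ij = x_ij - (X_i. + X_j.)/(p-2) + 2 X.. / ((p-1)(p-2))`

under the constraints `sum_i g_i = 0` and `sum_{j != i} s_ij = 0` for
every `i`. The decomposition is saturated: `m + g_i + g_j + s_ij`
reproduces every cell exactly, which the tests verify against an
independent constrained least-squares solver on random tables.

Method 2 (with `Y_i.` the symmetric-table row total counting the self
once and `Y..` the total over distinct cells) uses
`g_i = (Y_i. + y_ii - 2 Y.. / p)/(p+2)` and the corresponding SCA form,
under `sum_i g_i = 0` and `sum_j s_ij + s_ii = 0`. These forms, and the
standard-error constants below, were verified against the constrained
least-squares covariance rather than taken on faith.

Standard errors attach when an ANOVA table supplies the error mean
square `Me` (with `r` observations behind each entry mean): for
method 4, `se(g_i) = sqrt((p-1) Me / (p (p-2) r))` and
`se(s_ij) = sqrt((p-3) Me / ((p-1) r))`; for method 2,
`se(g_i) = sqrt((p-1) Me / (p (p+2) r))`,
`se(s_ij) = sqrt((p^2+p+2) Me / ((p+1)(p+2) r))` and
`se(s_ii) = sqrt(p (p-1) Me / ((p+1)(p+2) r))`.

Rankings (`rank_effects()`) are direction-aware: rank 1 is the largest
effect for a higher-is-better trait and the smallest for a
lower-is-better one (days to ripening defaults to lower-is-better).
Ties are broken by parent order and flagged.

## Analysis of variance

The single-environment table removes blocks as a stratum and splits the
entry sum of squares into GCA and SCA using Griffing's sums of squares
computed from entry means scaled by `r` (not by refitting a saturated
regression; the regression is kept as a test oracle only). For method 4,
`SS_GCA = r [sum X_i.^2/(p-2) - 4 X..^2/(p(p-2))]` and
`SS_SCA` is the remainder of `SS_Entries`; the identity
`SS_GCA + SS_SCA = SS_Entries` is exact and tested at 1e-8.

The combined table pools balanced environments: main-effect entry, GCA
and SCA sums of squares come from the across-environment means scaled by
`r x E`, and each interaction SS is the sum of within-environment
partitions minus its main effect. Degrees of freedom at `p = 8, r = 3,
E = 6` are (5, 27, 7, 20, 135, 35, 100, 324) for Environments, Entries,
GCA, SCA, Env x Entries, Env x GCA, Env x SCA and Error.

**F-test policy.** Genotypes are treated as fixed and replicates as
random, and every F ratio — including the environment and interaction
rows — is taken against the plot-error mean square. No approximate
synthesized denominators are formed. This mirrors the table layout of
the fixed-genotype multi-environment diallel reports this package is
patterned on. p-values come from the F distribution at the table's df
with no multiplicity correction.

`parents_vs_hybrids()` implements the orthogonal contrast between the
pool of hybrid entry means and the pool of parental entry means, with
`SE = sqrt(Me (1/n_h + 1/n_p)/r)`; a significant contrast indicates
average heterosis, negative for traits where hybrids mature earlier.

`as_diallel_anova()` rebuilds a valid table from published mean squares
and the design constants, so variance components and standard errors can
be recomputed without raw plot data. `glance()` on an ANOVA also reports
`sqrt(Me/r)`, the nominal standard error of an entry mean — reported
under exactly that label because published per-environment LsM standard
errors do not always follow a recoverable formula.

## Variance components and heritability

`variance_components()` solves the expected mean squares of the
all-random model. Single environment (method 4):
`sigma2_s = (MS_SCA - Me)/r`, `sigma2_g = (MS_GCA - MS_SCA)/(r(p-2))`.
Combined, in back-solve order:
`sigma2_sE = (MS_ExSCA - Me)/r`,
`sigma2_gE = (MS_ExGCA - MS_ExSCA)/(r(p-2))`,
`sigma2_s = (MS_SCA - MS_ExSCA)/(rE)`,
`sigma2_g = (MS_GCA - MS_SCA - MS_ExGCA + MS_ExSCA)/(rE(p-2))`.

Three conventions matter and are deliberate:

- **Truncation at zero** happens after solving, and `sigma2_g` keeps the
  `MS_GCA - MS_SCA` difference even when `sigma2_s` truncates (using the
  error MS instead would change the GCA component noticeably; the
  difference form is the one that reproduces published tables).
- **Phenotypic variance** is `sigma2_P = sigma2_A + sigma2_D + sigma2_e`
  with `sigma2_A = 2 sigma2_g`, `sigma2_D = sigma2_s` and the plot error
  entering undivided by `r`. Plot-basis heritability conventions differ
  across the literature; this one matches the arithmetic of the tables
  this package reproduces.
- **Component significance** is the F ratio of the defining numerator MS
  against the next MS in the back-solve order (e.g. GCA vs SCA for
  `sigma2_g`), not the ANOVA row's test against plot error. The two can
  disagree: a GCA row can be highly significant against error while the
  GCA *variance component* — and hence a heritability built from it — is
  not reliable.

`h2_N = sigma2_A / sigma2_P` and `h2_B = (sigma2_A + sigma2_D)/sigma2_P`
satisfy `0 <= h2_N <= h2_B <= 1` with equality iff `sigma2_s = 0`. The
GCA/SCA ratio is computed from unrounded components and reported as
undefined when `sigma2_s = 0`. Environments enter the EMS as random for
component estimation even though the ANOVA F-tests treat them as fixed —
the same dual use the reports make.

Method-2 tables are passed through the same EMS template. The method-2
random model is less standard (and the published method-2 column we
checked against is internally inconsistent), so method-2 components
should be read as indicative; they are not part of the package's
reproduction surface.

## Heterosis

`MPH = 100 (F1 - MP)/MP` with `MP = (P1+P2)/2`, and
`BPH = 100 (F1 - Ph)/Ph` where the better parent `Ph` honours the trait
direction: `max(P1, P2)` for higher-is-better, `min(P1, P2)` for
lower-is-better. The direction-aware better parent is not cosmetic — for
ripening time it flips the sign pattern so that `BPH >= MPH` on
lower-is-better tables, the pattern published earliness tables show.

Standard errors are `SE_MPH = sqrt(3 Me/(2r))` and
`SE_BPH = sqrt(2 Me/r)` in trait units. Two choices were open:

- The t statistic divides the heterosis in **trait units** (`F1 - MP`,
  `F1 - Ph`) by these SEs; the SE formulas are in trait units, so
  testing on the percent scale would mix scales.
- `r` is the number of records behind each entry mean **as supplied**,
  computed from the data. For plot-level traits that is the block count;
  for fruit-level traits (many fruits per plot) the effective `r` is
  larger, and published SEs for such traits are consistent with the
  larger count, not with the block count.

Crosses whose parent lacks selfed records are kept with `NA` heterosis
and flagged rather than dropped.

## GGE biplot of the diallel table

Every genotype is used both as an entry (row) and a tester (column) of
the symmetric table including selfs. The matrix is adjusted by
subtracting each **tester (column) mean** — centering only, no column
standardization and no double centering — and decomposed by SVD, keeping
two components. Entry scores are `U D^f`, tester scores `V D^(1-f)`;
`f = 0.5` by default, a symmetric split that treats entries and testers
even-handedly and leaves entry-tester inner products invariant to `f`
(the invariance is tested). The proportion of variation per axis is
`d_k^2 / sum d^2`.

The average-tester-coordinate (ATC) axis is the unit vector toward the
mean of the tester scores; entry projections on it approximate GCA (on
simulated additive tables the rank correlation with Griffing's `g`
exceeds 0.9, and a purely additive table is rank 1 with PC1 near 100%),
and projections on the orthogonal axis approximate SCA. If the mean
tester score is numerically zero the ATC is reported as undefined
rather than guessed.

The which-won-where view takes the convex hull of the entry scores,
draws the rays from the origin perpendicular to each hull edge, and
assigns each tester to the angular sector it falls in; the sector's hull
vertex is its winning entry. For interior points of a sector this is
equivalent to maximizing the entry-tester inner product, which the tests
check by brute force. A tester falling in its own entry's sector (self
better than crossing) is flagged. Collinear entry scores are an error.
The module emits coordinates; `autoplot()` is a thin optional layer.

## Distances and the Mantel test

`dist_euclidean()` standardizes each trait to zero mean and unit
variance across parents before distancing, so kilogram-scale traits
cannot dominate degree-Brix-scale ones. `dist_mahalanobis()` computes
`D2 = d' W^{-1} d` between entry mean vectors with `W` the pooled
within-entry covariance of replicates, per environment; it is
implemented as squared Euclidean distance after whitening by `W^{-1/2}`
(the canonical-variate route) and tested against the direct quadratic
form and for invariance under nonsingular linear maps of the traits.
A singular `W` is an error suggesting trait reduction, not a silent
pseudo-inverse.

`mantel_test()` correlates the `p(p-1)/2` off-diagonal pairs and builds
the null by jointly permuting rows and columns of the second matrix,
`p = (hits + 1)/(n_perm + 1)`. The test is upper-tailed by default (the
convention of the test as usually cited for this use); a two-sided
alternative is a flag. The permutation stream is seeded for
bit-reproducibility, and an exhaustive mode enumerates all `n!`
relabelings for small matrices — the sampled p-value is tested against
that enumeration, and the test's size is checked by simulation.
Per-cross statistics (entry means, SCA, MPH, BPH) are arranged into
parent-by-parent matrices by `cross_statistic_matrix()` for these
comparisons. Genetic distances are consumed as an input matrix; how they
were produced (marker panels, clustering) is outside the package.

## The synthetic-trial generator

`simulate_diallel()` generates
`y = mu + e_l + b_lk + g_i + g_j + s_ij + gE_il + gE_jl + sE_ijl + eps`,
with selfs receiving `2 g_i + s_ii + delta_self` and the doubled GxE
deviation. Defaults emulate a melon-sized trial: `p = 8` parents in
three blocks, unit-scale GCA variance with smaller SCA and GxE
components, and fixed environment offsets (the combined ANOVA tests
everything against plot error, which is coherent with fixed
environments; a `random_env` flag marks the random interpretation for
heritability studies). A negative `delta_self` on a higher-is-better
trait depresses the selfed parents, producing the positive mid-parent
heterosis that inbreeding depression creates in real trials;
its default is 0.

One modelling decision deserves emphasis. The main-effect draws are
sum-to-zero centered, but the cross deviations (`s`, `sE`) are drawn as
**unconstrained exchangeable symmetric effects** — exactly the random
model under which the expected-mean-squares coefficients used by
`variance_components()` are derived. Projecting those draws onto the
Griffing row-sum-zero subspace instead would remove their GCA-like
component from the data and make the EMS chain underestimate
`sigma2_gE` by `sigma2_sE/(p-2)` and `sigma2_g` by `sigma2_s/(p-2)` — a
33% bias on `sigma2_gE` at this trial's parameter scale. The *reported
truth*, however, uses the identifiable Griffing parametrization: the
GCA-leak of the raw main-SCA draw is moved into `g`, so the reported
effects satisfy `sum g = 0` and row-sum-zero SCA, and the estimators
reproduce them exactly on noise-free data. With this pairing, all five
variance components are recovered without systematic bias; the
package's recovery test averages 200 simulated trials at `p = 8, r = 3,
E = 6` and requires every component's mean within 10% of truth.

What the generator does **not** emulate: epistatic (additive x
additive) effects, correlated multi-trait architecture (traits are
drawn independently), non-normal errors, unbalanced or missing plots,
and fruit-level subsampling. Passing tests therefore demonstrate
correctness of the estimators under the stated model, not robustness of
the method on messy field data.

## Numerical choices and problem sizes

Tolerances: effect constraints and saturated reconstruction at 1e-10;
sum-of-squares identities at 1e-8 (relative); distance equivalences at
1e-8 and linear-map invariance at 1e-6. Degenerate inputs are flagged,
not guessed: zero-variance QC cells, zero centered GGE matrices,
undefined ATC, undefined GCA/SCA ratio at `sigma2_s = 0`, zero
mid-parent or better-parent values in heterosis.

The test suite sizes its simulations to be decisive but quick: 100
random tables against the least-squares oracle, 200 trials for variance
component recovery, 1000 replicates for the size of the GCA F-test and
of the Mantel test (199 permutations each), 100 additive tables for
the GGE-GCA concordance, and exhaustive (4! = 24) Mantel enumeration.
The full suite runs in about two minutes on one CPU.

## Known limitations

- Balanced RCBDs only; no mixed-model fallback.
- Method-2 variance components reuse the method-4 EMS template and are
  flagged as indicative (see above).
- The GGE module analyses one environment's table at a time;
  multi-environment GGE and mega-environment analysis are out of scope.
- Heritability standard errors are not computed.
- The biplot reports sector winners and mutual-best pairs; it does not
  rank all crosses by biplot geometry alone, which is an interpretive
  rule rather than an estimator.
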