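---
title: "Family-based gene coexpression network meta-analysis with famnet"
author: "famnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based gene coexpression network meta-analysis with famnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Weighted gene coexpression network analysis summarises thousands of
expression probes into modules of correlated genes and tests each module's
eigengene — its first principal component — against traits of interest. In a
family study this runs into two difficulties. First, related individuals
share polygenic and household influences on expression, so a network built
on the pooled sample mixes within-family coexpression with between-family
heterogeneity, and eigengene–trait tests that ignore relatedness produce
spurious associations when families are few and large. Second, the obvious
repair — removing the family signal from every probe before building the
network — discards genuine genetic covariance along with the nuisance.

`famnet` implements a meta-analytic alternative: build one signed
coexpression network **per family**, test every module eigengene against the
trait inside its own family with a kinship-aware mixed model, select the
most significant module overall, match it across families by gene overlap,
combine the matched modules into common gene sets (intersection and union),
summarise the better of the two by a per-family eigengene `E_F`, and test
`E_F` jointly across all families. Two naive whole-sample baselines (raw and
decorrelated expression) and a per-probe mixed-model scan are included for
comparison.

## Mixed models and kinship

All association testing and decorrelation rests on one variance-components
engine. For individual *j* of family *i*,

> Y_ij = mu + u_ij + v_i + beta * x_ij + eps_ij

with a polygenic random effect `u ~ N(0, 2K sigma_g^2)` (K the pedigree
kinship matrix), a shared-family effect `v ~ N(0, sigma_v^2)` constant within
a family, and an i.i.d. residual. K comes from the standard tabular
recursion over a topologically ordered pedigree (founders: phi_ii = 0.5;
non-founders: phi_ii = 0.5(1 + phi_fm), phi_ij = 0.5(phi_fj + phi_mj)), so
it is block-diagonal by family and `2K` is positive semidefinite; inbred
pedigrees are handled by the same recursion even though the simulator never
creates them.

Estimation is REML. The fixed effects and the residual scale are profiled
out analytically; the restricted likelihood is maximised over the two log
variance ratios with Brent/Nelder–Mead searches (objective tolerance
`1e-8`-class, log-ratio box ±14), and — because variance components live on
a boundary — every kernel subset (both, genetic only, family only, neither)
is fitted and the best restricted likelihood wins. This makes the
non-negativity constraint exact: a component that belongs at zero is
reported as exactly zero, and with both structured kernels removed the fit
reproduces ordinary least squares to numerical precision. Both kernels are
block-diagonal by family, so every likelihood evaluation factors into small
per-family Cholesky solves; per-probe batch fits (decorrelation,
heritability) additionally share Cholesky factors across probes on a grid
of variance ratios before a short per-probe polish.

Fixed effects are tested with a Wald statistic against a standard normal
reference, the common choice in kinship mixed models. This is mildly
anti-conservative in very small samples: in our null simulations a single
family of ~50 rejects at 7–9% at nominal 5%, while at 200 samples the test
is calibrated (rejection inside the exact binomial band, p-values uniform
by Kolmogorov–Smirnov). Degrees-of-freedom corrections are deliberately out
of scope; results from single small families should be read accordingly.

Three model variants appear in the pipeline:

* **single-probe scan** — probe expression as covariate, all samples, both
  kernels;
* **within-family module test** — eigengene as covariate, one family's
  samples, genetic kernel only (a family-constant effect is confounded with
  the intercept inside one family);
* **joint eigengene test** — eigengene as covariate, all samples, both
  kernels.

### Decorrelation and heritability

The decorrelated expression used by one baseline replaces each probe by the
**conditional** residuals (response minus fixed part minus random-effect
BLUPs) of the intercept-only mixed model. Marginal residuals would retain
exactly the family covariance the step exists to remove; they are available
behind `residual_type = "marginal"`. Note that conditional residuals equal
the mean-centred input only when the variance components are estimated at
the zero boundary; with finite samples roughly half the null probes get
small positive estimates and are mildly shrunken, which is correct
behaviour, not optimiser error.

Per-probe heritability is `h2 = sigma_g^2 / (sigma_g^2 + sigma_v^2 +
sigma_e^2)` from the same intercept-only fits, and `filter_heritable()`
keeps the `ceiling(top_fraction * P)` highest, breaking ties by probe id so
the subset is reproducible. One consequence of the simulator's design worth
knowing: planted module probes trade a share of their polygenic variance
for factor variance, so they rank *low* on heritability and an aggressive
filter removes modules before networks see them.

## Network construction

* **Correlation** — biweight midcorrelation: per probe,
  `u = (x - median) / (9 * MAD)` with the unscaled median absolute
  deviation; Tukey weights `(1 - u^2)^2` for `|u| < 1` zero out points
  beyond 9 MADs; the Pearson correlation of the weighted median-centred
  vectors is returned. On clean Gaussian data it tracks Pearson within a
  few hundredths while a single gross outlier barely moves it. Zero-MAD
  probes fall back to plain Pearson rows with a warning.
* **Adjacency** — signed soft threshold `a_lk = |0.5 + 0.5 cor|^gamma`,
  default `gamma = 6` (the community default for signed networks);
  `pick_soft_threshold()` instead selects the smallest exponent from
  {2, 4, ..., 20} whose scale-free fit R² (log frequency vs log binned
  connectivity, equal-width bins, sign-corrected) reaches 0.8, falling back
  to the best-fitting exponent.
* **Topological overlap** — `TOM_lk = (sum_m a_lm a_mk + a_lk) /
  (min(k_l, k_k) + 1 - a_lk)`; clustering uses `1 - TOM` by default, with
  `1 - adjacency` behind a switch.
* **Module detection** — average-linkage hierarchical clustering followed
  by a separation-validated branch selection. Every dendrogram branch gets
  a separation score — the relative margin by which its members' mean
  dissimilarity to the rest exceeds the mean internal dissimilarity — which
  average linkage lets us compute exactly for all branches in linear time
  from the merge heights. Walking the tree bottom-up, a branch becomes a
  module candidate if it has at least `min_module_size` (default 30) probes
  and separation at least `min_separation` (default 0.05); an ancestor
  absorbs its candidates when they cover at least 80% of it and none is
  better separated by more than a 10% relative margin (or when the ancestor
  is itself at least as well separated). Tight cores therefore grow into
  whole modules, while loose super-clusters can neither swallow two
  distinct modules nor drag background probes along. Unstructured data
  admits no candidate and comes back entirely grey. In planted-module
  simulations (four 60-gene modules at within-module r = 0.6 among 260
  noise probes) this recovers the truth with adjusted Rand index above 0.95,
  returns all-grey partitions on pure noise, and is exact on noiseless
  blocks.
* **Eigengenes** — probes are standardised, the leading singular vector of
  the samples-by-genes block gives per-sample scores scaled to unit
  variance, variance explained is the leading eigenvalue share, and the
  sign is fixed by positive correlation with the module's mean standardised
  expression.

## The family meta-analysis

1. Build one network per family on the covariate-adjusted expression of
   that family's members.
2. Test every non-grey module eigengene within its family (model above);
   Bonferroni control uses the total number of module tests.
3. The smallest p across all families and modules defines the top module
   `M_F^M`; ties break by larger |beta|/se, then lexicographic module id.
4. In every other family pick the module with the largest raw gene overlap
   with `M_F^M` (ties: higher Jaccard, then smaller module, then id). Raw
   shared-gene count is the primary metric because overlap, not relative
   overlap, is what makes the downstream intersection usable.
5. Intersect and union the matched modules. Compute per-family eigengenes
   for both candidate sets and summarise each candidate by its **minimum**
   variance explained across families — a worst-case criterion: the chosen
   set must summarise every family well, not just most. The winner's
   per-family score vectors are concatenated (sign-aligned by the eigengene
   convention) into `E_F`. Per-family principal components are used rather
   than one pooled PCA because the quantity of interest is how well the set
   summarises each family separately; a pooled variant would let one large
   family dominate the loading pattern.
6. Test `E_F` jointly across all samples with the full two-kernel model.

An empty intersection (a family whose best overlap is zero) is legal: the
union set carries on alone, with a warning. Whether a union eigengene would
ever be preferred is decided by the same minimum-variance-explained rule
rather than assumed.

The naive baselines build one whole-sample network each on the raw and the
decorrelated matrix, test every module eigengene with the joint model, and
Bonferroni-correct by that network's module count. The single-probe scan
re-estimates variance components per probe by default (matching the model
as written); `reuse_null = TRUE` freezes them at the trait-only null fit
for a fast approximate scan.

## The synthetic study generator

Because the motivating data (multi-generation families with ~20k expression
probes and simulated blood-pressure traits) are access-restricted, the
package ships a generator that emulates their design and makes every stage
testable end to end:

* **Pedigrees** — five families of 65/55/45/62/49 members (276 samples) by
  default, grown over 3–4 generations by adding one individual at a time
  (a child of an existing couple, or a founder spouse opening a new
  couple), hitting each family size exactly and deterministically under the
  seed.
* **Expression** — per probe `X = lambda * sigma_tot * F +
  sqrt(1 - lambda^2) (g + v + e)` plus age and sex effects, where `g` is
  gene-dropped down the pedigree (founders `N(0, sigma_g^2)`, children
  midparent plus `N(0, sigma_g^2/2)`, so its covariance converges to
  `2K sigma_g^2`), `v` is family-constant and `e` i.i.d.; defaults
  `(sigma_g^2, sigma_v^2, sigma_e^2) = (1, 0.5, 1)`. The loading `lambda`
  is the probe–factor correlation, so within-module correlation is
  `lambda^2` (default loading 0.8). Six modules are planted by default,
  four shared across families and two family-specific.
* **Traits** — the causal trait sums the expression of 15 causal genes
  (effect 0.3 each: three in the first shared module, one in each other
  module, the rest in background probes, echoing a simulation model whose
  causal genes sit in different pathways) plus its own polygenic, family,
  covariate and noise components; the null trait has the nuisance
  components only and is independent of every probe.

What the generator does **not** emulate: genotype-level transmission and
linkage disequilibrium, probe-level technical artefacts (batch, intensity-
dependent noise), non-Gaussian expression, inbreeding, and longitudinal
structure. Passing tests therefore demonstrate correct behaviour under a
Gaussian polygenic/latent-factor world, not performance guarantees on any
particular real dataset.

## Numerical choices and degenerate inputs

* Variance ratios are searched in log space within ±14; best-subset
  comparison handles the zero boundary exactly; ratios at the search floor
  are snapped to zero.
* Probes with more than 10% missing values are dropped, the remainder
  mean-imputed (the correlation step needs complete vectors); constant
  probes decorrelate to all-zero rows, are excluded from heritability
  ranking, and are dropped from eigengene gene sets — each with a warning.
* All selection steps (top module, overlap matching, heritability cutoff)
  carry explicit deterministic tie-breaks, so a fixed seed and fixed inputs
  reproduce results byte for byte, manifest checksums included.
* Family-specific module tests require at least 10 samples per family;
  smaller families are skipped with a warning.

## Validation scale

The shipped tests validate kinship against a 200,000-drop gene-dropping
Monte Carlo oracle on twenty random pedigrees (±0.01 per entry), REML
recovery over 200 replicates of the 276-sample design (means within 15% of
truth), null calibration of all three model variants over 500 replicates at
the 200-sample scale, module recovery on 500-probe planted designs, the
full meta-pipeline on 300-probe five-family studies (core recovery, 80%
power at the planted effect size, type-I control over 300 null
replicates), and byte-level determinism of the full pipeline on a
350-probe run. The acceptance script runs the complete default scenario
(2,000 probes, 276 samples) in a few minutes.

## Known limitations

* Wald tests against the normal reference are anti-conservative for single
  families much below ~100 members.
* Module probes' heritability is structurally reduced by the latent factor,
  so heritability filtering and module detection interact; this mirrors
  real analyses in which trait-relevant genes need not be the most
  heritable ones.
* The per-family network step needs families large enough (tens of
  members) to estimate ~20k pairwise correlations; very small families add
  noise to the matching step.
* No block-wise approximation is provided; beyond ~50k probes the dense
  TOM computation dominates memory and time.
* LASSO-style selection from the union set is explicitly out of scope.
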