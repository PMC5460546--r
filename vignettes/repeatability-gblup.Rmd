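---
title: "Repeatability GBLUP for repeated-record fruit traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeatability GBLUP for repeated-record fruit traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`repgblup` implements genome-enabled prediction of repeated-record fruit
traits (fruit weight in grams, sugar content in Brix degrees, titratable
acidity in meq/100 ml) in biparental F1 progenies, the setting of perennial
fruit-tree breeding programmes where each tree is phenotyped in several
successive years. The package covers the whole analysis path — genotype QC,
imputation-accuracy benchmarking, marker-based kinship and population
structure, the repeatability GBLUP mixed model, and cross-validated
predictive ability — together with a simulator of F1 crosses that generates
data under exactly the model the pipeline fits, so every stage is testable
without access to proprietary breeding data.

# The repeatability model

The phenotypic records are modelled as

$$\mathbf{y} = \mathbf{Xb} + \mathbf{Za} + \mathbf{Wpe} + \mathbf{e}$$

where $\mathbf{b}$ holds the overall mean and the (categorical) year of
measurement, $\mathbf{a} \sim N(0, \mathbf{G}\sigma^2_a)$ are additive
genetic effects with $\mathbf{G}$ a marker-based relationship matrix,
$\mathbf{pe} \sim N(0, \mathbf{I}\sigma^2_{pe})$ are permanent-environment
effects (one per plant, shared by all of its records: ontogenetic and
micro-site effects), and $\mathbf{e} \sim N(0, \mathbf{I}\sigma^2_e)$ are
record-specific residuals (the temporary environment, i.e. climatic year
variation not captured by the year mean). $\mathbf{Z} = \mathbf{W}$ both
map records to plants; the separation of $\sigma^2_a$ from $\sigma^2_{pe}$
rests entirely on the contrast between the $\mathbf{G}$ and $\mathbf{I}$
covariance structures. When the sample is nearly unrelated
($\mathbf{G} \approx \mathbf{I}$) that split is weakly identified and the
fitting functions emit a warning.

From the variance components,

$$h^2 = \frac{\sigma^2_a}{\sigma^2_a + \sigma^2_{pe} + \sigma^2_e}, \qquad
  R = \frac{\sigma^2_a + \sigma^2_{pe}}{\sigma^2_a + \sigma^2_{pe} + \sigma^2_e},$$

so $h^2 \le R$ always, and the phenotypic variance partitions into genetic
($h^2$), permanent-environment ($R - h^2$) and temporary-environment
($1 - R$) shares. Repeatability bounds the reliability of predicting a
plant's future records from its past ones.

# Kinship

`compute_grm()` implements

$$\mathbf{G} = \frac{1}{L} \sum_{l=1}^{L}
  \frac{Z_{\cdot,l} Z_{\cdot,l}'}{4 p_l (1 - p_l)}$$

with $Z_{\cdot,l}$ the genotype column centred by $2p_l$. The $4p(1-p)$
denominator puts $\mathbf{G}$ on the *kinship* scale: the expected
self-kinship of a non-inbred individual is 1/2 (verified in the tests at
HWE: mean diagonal 0.5 within 0.02 at $n = 500$, $L = 2000$). Because
$\sigma^2_a$ in the model above is defined relative to this scale, it is
the package default; `denominator = "2pq"` gives the common GRM scale
(self-kinship 1) for interoperability.

Allele frequencies are estimated within-cross for the GBLUP kinship (each
cross is analysed separately) and pooled over all samples for the
structure views, since those are across-population summaries. This pooled
choice is a documented default, not an inference: the source analysis does
not state which frequencies fed its across-population kinship.
Structure is summarized two ways: classical (Torgerson) scaling of
$1-\mathbf{G}$ — double-centring $-\tfrac12 D \circ D$, eigendecomposition,
coordinates scaled by the square roots of the positive eigenvalues, and
variance shares computed over positive eigenvalues only (the sign-indefinite
tail of a non-Euclidean $1-\mathbf{G}$ carries no usable variance) — and a
neighbor-joining tree over crosses, built from mean between-cross
kinships with off-diagonal pairs only on the within-cross diagonal.

The NJ implementation follows Saitou–Nei with the standard Q-criterion,
deterministic smallest-index tie-breaking, and negative branch lengths
clamped to zero with a warning. On additive distances it recovers the
generating topology and branch lengths exactly, which the tests assert
against random trees with `ape` as an independent oracle; the MDS is
checked against `stats::cmdscale` the same way.

# Fitting: REML and Gibbs

`reml_fit()` maximizes the restricted likelihood of the three-component
model. The $n \times n$ covariance is never formed: with
$\mathbf{A} = \sigma^2_a \mathbf{G} + \sigma^2_{pe} \mathbf{I}$ (both random
terms share $\mathbf{Z}$), Woodbury identities reduce every solve, trace
and determinant to $q \times q$ operations ($q$ = plants), which keeps a
fit at 300 plants x 3 years well under a second. Updates are
average-information steps with a damped line search, falling back to the
EM-REML update whenever an AI step fails to increase the restricted
log-likelihood; accepted steps therefore form a non-decreasing trajectory
(asserted per iteration in the tests). Components are kept non-negative by
a floor at $10^{-8} \mathrm{var}(y)$; because the EM approach to a zero
component is harmonically slow, a component at or below
$10^{-4}\mathrm{var}(y)$ whose score is negative is pinned at the floor,
and anything at the floor is reported as 0. Convergence is declared when
successive restricted log-likelihoods differ by less than `tol` (default
1e-8, `max_iter` 500). The kinship receives a 1e-6 diagonal jitter before
factorization — a per-cross $\mathbf{G}$ on a few hundred plants and a few
thousand SNPs is routinely rank-deficient.

`gibbs_fit()` is the fallback (and standalone) sampler for designs where
REML fails on singular matrices, mirroring the pragmatic REML-first,
MCMC-on-failure policy that small crosses force in practice
(`fit_repeatability(solver = "auto")`). It uses scaled inverse chi-square
priors with `prior_df = 5` and scale $(\nu+2)/\nu \cdot \mathrm{var}(y)/3$
per component, i.e. each prior mode at a third of the phenotypic variance —
weakly informative and symmetric across components. Locations are sampled
blockwise (fixed effects, then all breeding values jointly from a
$q \times q$ system, then the diagonal permanent-environment block);
variance draws are standard scaled-inverse-chi-square conditionals. Chains
are reproducible given `seed`; posterior means are reported, with thinned
component draws and a crude lag-1 ESS in the diagnostics. REML and Gibbs
point estimates agree within 0.05 on $h^2$ at 300 plants in the acceptance
suite.

Predictions sum the estimated effects,
$\hat y = \hat\mu + \widehat{year} + \hat a + \hat{pe}$. A record in a year
unseen during training (possible when record-level CV folds orphan a year)
receives the mean of the estimated year effects, with a message.

# Cross-validation

`run_cv()` implements the 5-fold scheme repeated 100 times, yielding 500
replicates per trait-cross by default; each replicate records the
training-fit $h^2$ and $R$ and the predictive ability, the Pearson
correlation $r(\hat y, y)$ in the validation fold. Partitioning is at the
*record* level, as in the source design — a plant's other-year records stay
in training, so the permanent-environment effect leaks into the validation
prediction. This is a feature of the design, not a bug: the tests assert
that record-level CV attains predictive ability at least as high as the
grouped-by-plant variant (`group_by_plant = TRUE`) when $\sigma^2_{pe} > 0$.
Predictive ability is computed per fold (matching the 500-replicate count);
`pool_folds = TRUE` gives the per-repetition pooled variant. GEBV accuracy
is summarized as $\bar{PA} / \sqrt{\bar{h^2}}$; values above 1, possible
with noisy heritability estimates, are flagged rather than truncated.

# Genotype QC

The editing rules mirror array-genotyping practice for biparental
progenies: samples with call rate $\le 0.90$ discarded (non-strict, as
printed in the source protocol), then SNPs with call rate $\le 0.90$ or
monomorphic *in every cross* removed, then within-cross MAF $< 0.01$
filtering immediately before GBLUP (strict). Monomorphism is defined on
genotype classes — a locus with a single observed genotype — so an
AA×aa-type locus where every progeny is heterozygous counts as
non-segregating (it has allele frequency 0.5 but no within-cross contrast);
such loci are additionally reported via `all_het_loci()`. The QC report
emits the residual missing rate both before and after the sample filter,
since published summaries are ambiguous about which convention they use.

# The imputation benchmark

`run_masking_experiment()` reproduces the masking design: from a complete
matrix, masking rates of 1–30% (13-point grid), 10 fresh uniform random
masks per rate, accuracy = exact-genotype-match fraction over masked cells
only. The benchmark is imputer-agnostic: any function satisfying the
contract (complete matrix out, observed cells untouched) plugs in, and
`external_imputer()` wraps a command-line tool. Two reference imputers
ship with the package: per-locus mode imputation (ties toward the lower
code) and a deterministic k-nearest-neighbour haplotype-window imputer
(`k = 5`, `window = 20` flanking SNPs) that exploits the long identical
haplotype blocks of an F1 progeny. The haplotype-cluster algorithm of
external imputation software is deliberately out of scope — the
contribution here is the benchmark design. Mode-imputer accuracy is
invariant to SNP order; the k-NN imputer is not (it reads the map order).

# The simulator

`simulate_cross()` generates the stated world end to end: two phased
parents heterozygous at each SNP with probability
`parental_heterozygosity`; recombinant gametes under the Haldane
(no-interference) map function, implemented as a Markov chain of haplotype
switches with $r = (1 - e^{-2d/100})/2$ between adjacent SNPs; genotypes
as transmitted-allele sums; uniform random missingness; and phenotypes from
the repeatability model with breeding values drawn directly from
$N(0, \mathbf{G}\sigma^2_a)$ (not via marker effects), so the generating
model is exactly the fitted model and parameter-recovery tests are clean.
Defaults describe a single mid-sized progeny on a medium-density array:
100 plants, 3000 SNPs on 8 linkage groups of 60 cM, heterozygosity 0.4
(which makes roughly a third of loci non-segregating in the progeny, as
seen after array genotyping of real F1 crosses), 3% missing calls, 3 years,
and a fruit-weight-like trait (mean 150 g, phenotypic variance 1200 g²,
$h^2 = 0.35$, $R = 0.56$, year effects ±10 g).

Two consequences of the within-cross design matter for interpreting green
tests. First, the realized variance of simulated breeding values is
$\sigma^2_a \cdot \overline{\mathrm{diag}(\mathbf{G})}$, about
$0.3\,\sigma^2_a$ under within-cross frequencies — the model is
self-consistent (REML targets $\sigma^2_a$ on the $\mathbf{G}$ scale), but
empirical variance-ratio checks must not equate $\sigma^2_a$ with realized
genetic variance; the corresponding intraclass-correlation test therefore
isolates the permanent-environment component. Second, the simulator does
not emulate selection, genotyping error, genotype-by-year interaction,
dominance/epistasis, multi-generation pedigrees, or shared parents between
crosses; a green pipeline run establishes correctness of the machinery
under the stated model, not robustness to those realities.

# Numerical choices, in one place

* Kinship jitter 1e-6 on the diagonal before any factorization.
* REML: `tol` 1e-8 on successive restricted log-likelihoods, `max_iter`
  500, component floor $10^{-8}\mathrm{var}(y)$, boundary pinning at
  $10^{-4}\mathrm{var}(y)$ with negative score, boundary estimates reported
  as 0.
* Gibbs: 12000 iterations, 2000 burn-in, thinning 5 by default; the
  automatic fallback inside CV uses a shorter 4000/1000 chain.
* Mode-imputer ties toward the lower genotype code; k-NN vote ties fall
  back to the mode answer; neighbour ranking ties break by sample index.
* NJ Q-matrix ties break toward the smallest index pair; negative branch
  lengths clamp to 0 with a warning.
* MDS variance shares use positive eigenvalues only.
* `inject_missing()` masks exactly `round(rate * n)` cells, sampled
  without replacement.

# Known limitations

Year is modelled as a within-cross categorical effect; calendar years are
not harmonized across crosses, and no genotype-by-year interaction is
fitted. Only single-trait analyses are supported. The Gibbs ESS diagnostic
is a lag-1 approximation, adequate for variance components in these models
but not a substitute for real chain diagnostics in pathological designs.
The published per-cross estimates bundled in `published_cv_summary()`
derive from unreleased data and are reproducible only at the level of their
printed across-cross averages, which is exactly what the acceptance report
recomputes.
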