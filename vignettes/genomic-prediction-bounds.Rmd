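---
title: "Asymptotic accuracy and estimability bounds for genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asymptotic accuracy and estimability bounds for genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Genomic prediction estimates marker effects from a reference population
(RP: genotyped and phenotyped) and uses them to predict the genetic merit
of validation individuals (VP: genotyped only). Two quantities measure
success: *reliability*, the squared correlation between the true genetic
value $u$ and its prediction $\hat u$, and the *prediction $R^2$*, the
squared correlation between phenotype $y$ and $\hat u$. A long-standing
practical question is what happens as the reference population grows:
does $R^2$ plateau at a fraction of heritability for individuals
unrelated to the reference, or does it climb to the genomic heritability
$h^2_M$?

This package implements, as tested and reusable code, a simulation study
of that question for a human-like trait (heritability 0.8, resembling
height), together with two analytic devices:

1. the closed-form approximation
   $R^2 \approx h^2_M\,\frac{n_R h^2_M}{n_R h^2_M + M_e}$, where
   $M_e = 2 N_e L k / \ln(N_e L)$ is the effective number of chromosome
   segments ([`r2_eq1()`], [`effective_segments()`]), which is strictly
   increasing in $n_R$ with asymptote $h^2_M$; and
2. an *estimability* bound: writing the reference genotype matrix
   $X_R$ and a validation genotype vector $x_V = x_{V1} + x_{V2}$ with
   $x_{V1}$ the orthogonal projection of $x_V$ onto the row space of
   $X_R$, the reliability of that individual's prediction can never
   exceed $UP_i = x_{V1}'x_{V1} / x_V'x_V$, and its prediction $R^2$
   can never exceed $h^2\,UP_i$ ([`up_bound()`], [`r2_upper()`]).

The second device is the package's centrepiece. It is a property of the
*design* (who is genotyped), not of any estimator: if part of a
validation genotype vector is orthogonal to every reference genotype,
no amount of data on those individuals can recover that part's
contribution. It also explains why an earlier bound built from the
regression of marker-derived on QTL-derived relationships,
$[1-(1-b)^2]h^2$ ([`dlc_bound()`]), is not in fact an upper bound: $b$
stays essentially constant as $n_R$ grows while realized accuracy keeps
rising past the supposed ceiling.

## The simulation pipeline

**Founders.** The original study seeded its simulation with phased
whole-genome haplotypes of 85 sequenced individuals. Those data are
deliberately replaced here by a synthetic founder generator
([`synth_founders()`]) so the pipeline is self-contained; a phased-VCF
reader ([`read_phased_vcf()`]) lets real haplotypes be substituted. The
generator produces Li–Stephens-style mosaics: per-site allele
frequencies are drawn from a neutral-like density $\propto 1/f$
truncated to $[0.005, 0.5]$ (so half the sites have frequency below
0.05 — a rare-skewed spectrum like sequence data), a small panel of
"ancestral" haplotypes is drawn at those frequencies, and each of the
170 founder haplotypes copies from one ancestral haplotype at a time,
switching at Poisson points. Shared copying tracts give LD that decays
with genetic distance, without the cost of a coalescent simulation.
Defaults: 30 ancestral haplotypes and 300 switches per Morgan, so
copying tracts average ~0.33 cM. Human LD useful for tagging decays on
the 0.02–0.05 cM scale against a study marker spacing of ~0.012 cM — a
spacing-to-LD ratio of roughly 2–4; the default reproduces that ratio
at this package's coarser desk-scale marker spacing (~0.1 cM), so each
QTL is tagged by a handful of markers rather than smeared over dozens,
preserving the marker-level sparsity that separates variable-selection
methods from GBLUP. With the default map of 5 chromosomes of
0.1 Morgan these are the package-wide study conditions. What the
generator does *not* emulate: mutation-age/frequency correlations,
gene conversion, variable recombination rate, and population structure;
passing tests therefore validate the machinery and the qualitative
regimes, not human-specific quantitative values.

**Gene dropping.** [`evolve()`] breeds non-overlapping generations by
random mating (monoecious, parents drawn uniformly with replacement,
selfing allowed — the common gene-dropping default) from the founder
panel: generation 1 is formed from $2\,\times$ population-size founder
gametes, each a meiosis of one founder's two phased haplotypes. A
meiosis draws a Poisson(length in Morgans) crossover count per
chromosome with uniform positions and no interference, and flips allele
states at panel sites with probability $10^{-8}$ per site per gamete.
Individuals are stored as origin-labelled half-open segments
$[\text{start}, \text{end})$ plus accumulated flip sets, so memory
scales with crossover and mutation events, not with site count;
[`drop_sequence()`] materialises 0/1/2 genotypes only for the requested
snapshot generations (101 for the reference pool, 111 for validation —
ten generations of separation so close relatives of validation
individuals are absent from the reference).

**Scenarios and traits.** After discarding sites with MAF < 0.005
([`filter_maf()`]), marker and QTL sets are chosen by MAF
([`select_loci()`]): SHL (markers high, QTL low — the adversarial chip
design), SHR (markers high, QTL random) and SRR (both random). MAFs for
filtering and selection are computed on the generation-101 snapshot:
that is what an experimenter designing a chip would observe. QTL are
selected first and markers from the remainder, so the sets are
disjoint; the selection is fixed across replicates while QTL effects
are re-drawn. [`simulate_trait()`] draws $\alpha_j \sim N(0,1)$ and
rescales so that with unit residual variance the realized heritability
is exact on the scaling cohort. The scaling cohort is the union of the
reference-generation pool and the validation sample used in the
experiment — the analyzed cohort — so heritability is pinned where the
analysis happens; the study specified rescaling per replicate without
naming the cohort.

**Estimators.** [`fit_wgr()`] runs single-site Gibbs samplers for
BayesC($\pi$) and BayesB($\pi$) — marker effects zero with probability
$\pi$, otherwise normal with a common variance (BayesC) or
locus-specific variances whose scaled-inverse-$\chi^2$ full
conditionals give the marginal $t$ prior (BayesB) — and GBLUP as BayesC
with $\pi = 0$. $\pi$ is treated as known (0.98 for the
variable-selection methods), inclusion indicators are sampled with the
effect integrated out, and the model frequency of a marker is the
fraction of post-burn-in samples that include it. Full chains are
11,000 iterations with 1,000 burn-in and no thinning. The study's
software did not publish its hyperparameters; here
$\nu_\beta = \nu_e = 4$ and the scales put the prior mean of the
marker-explained variance at half the phenotypic variance, partitioned
over the expected $(1-\pi)p$ included loci — the common convention in
this model family, recorded in `wgr_config()`. Genomic heritability is
the posterior mean of $\sigma^2_g/(\sigma^2_g + \sigma^2_e)$ with
$\sigma^2_g$ the per-iteration empirical variance of $X\beta$ over the
training individuals. The deterministic ridge solution
([`rrblup_solve()`]) is kept alongside as an independent cross-check:
with fixed variances the $\pi=0$ sampler must reproduce it, and its
predictions must equal animal-model BLUP with $G = ZZ'/p$ at the
matched variance ratio $\lambda_G = \lambda/p$ — both are asserted in
the test suite rather than assumed.

**Relationships.** $G = ZZ'/p$ with
$z_j = (x_j - 2q_j)/\sqrt{2q_j(1-q_j)}$ and $q_j$ estimated from the
combined reference + validation cohort ([`compute_grm()`]); validation
individuals are classified by their maximum QTL-level relationship to
the reference (low group below 0.15, high at or above 0.25,
[`relationship_groups()`]). The relationship regression
$g_{M,i} = b_i\,g_{Q,i} + \epsilon_i$ is fitted through the origin,
as the model has no intercept ([`b_regression()`]).

## Numerical choices

* **Projection and rank.** `up_bound()` uses a column-pivoted QR of
  $X_R'$ — a rank-revealing orthogonal decomposition — with relative
  tolerance `max(dim) * .Machine$double.eps` on the decomposition's
  diagonal; the algebra assumes exact arithmetic, so the tolerance only
  guards against floating-point rank inflation. The generalized-inverse
  formula $X_R'(X_R X_R')^- X_R\,x_V$ is the brute-force oracle in the
  tests (agreement to $10^{-10}$).
* **Centring for the bound.** The study does not state whether
  genotypes were centred before forming $X_R$. $UP$ is not invariant to
  that choice, so it is explicit here: `estimability_report()` centres
  columns by twice the combined-cohort allele frequency (the same
  centring that underlies $G$), and `up_bound()` itself projects
  whatever coding it is given. With $n_R = p$ the centred reference
  matrix has rank $p-1$ rather than $p$, which depresses mean $UP$ by
  about $1/p$ — invisible at three printed decimals.
* **Half-open segments.** A site lying exactly on a crossover
  breakpoint belongs to the right-hand segment; a site at the terminal
  chromosome position belongs to the last segment.
* **Ties in MAF ranking** are broken by an independent uniform draw, so
  "highest-MAF" selections are exchangeable among tied loci.
* **Monomorphic loci** are errors where a single locus is standardized,
  dropped with a warning where a matrix is assembled ($G$), and carry
  prior-driven inclusion (no data signal) inside the sampler.

## Problem sizes

The package's own test and analysis runs use desk-scale renditions of
the study design, stated here once as the package's defaults for those
runs: founders always 85; trend experiments use 3,000 sites, population
2,500 over 111 generations, 500 markers / 10 QTL, reference sizes
{75, 500, 2,000}, 500 validation individuals, 3 replicates, chains of
3,000 with 500 burn-in; estimability runs use 12,000 sites, population
10,000 over 111 generations, 5,000 loci acting as both markers and QTL,
$n_R = 5{,}000$ and 2,000 validation individuals — the design point at
which the reference matrix generically reaches full column rank and
mean $UP$ hits 1.000. Tables 2–4-style absolute $R^2$ values depend on
the founder LD structure and are *not* reproduced at desk scale; what
is asserted instead are the study's qualitative signatures: $R^2$
rising in $n_R$ for every method, variable selection beating GBLUP at
intermediate $n_R$ under SHL-type designs, inclusion of QTL in the
panel never hurting, and the variance of model frequencies growing with
$n_R$.

## Presentation

The repository is organised as an analysis workflow: the numbered
scripts under `analysis/` (founder synthesis and forward simulation,
scenario construction, the prediction experiment, the estimability
analysis, the closed-form approximations) are thin narrative drivers
over the package functions and write their tables under `results/`;
every computation they perform lives in `R/` where the test suite and
`scripts/acceptance.R` exercise it. There is no shell command-line
wrapper — the functions and scripts are the interface.

## Known limitations

* The founder generator is a stand-in: its LD is exchangeable across
  chromosomes and has no long-range structure, and the mosaic model
  caps attainable pairwise r-squared at roughly the reciprocal of the
  ancestral-panel size, well below real short-range haplotype LD.
  Absolute accuracies are therefore not comparable to runs seeded with
  real haplotypes (use `read_phased_vcf()` for those); in particular
  the GBLUP ceiling in the low-relationship group at $h^2 = 0.999$ and
  $n_R = p = 5{,}000$ computes to about 0.988 here against the 0.995
  published from real-haplotype founders — the small-singular-value
  tail of the reference matrix, which sets how much residual noise an
  interpolating GBLUP amplifies, is founder-data-dependent.
* BayesB's $\pi$ is fixed, not estimated; no REML route is provided.
* The samplers are single-chain; convergence is addressed by oracle
  equivalences at fixed variances and chain-length conventions, not by
  formal diagnostics.
* `up_bound()` at $n_R = p = 5{,}000$ costs one dense pivoted QR
  (minutes on a laptop core); no sparse or randomized variant is
  provided.
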