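---
title: "Models and methods behind indicusGP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind indicusGP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

indicusGP implements whole-genome prediction of breeding values for
cattle populations genotyped with dense SNP panels, in the setting
typical of indicine (zebu) beef programs: a few hundred influential
bulls with highly accurate progeny-based EBV, deep paternal half-sib
family structure, and far more markers than animals. This vignette
explains the models, the main tunable parameters, and the design
choices that were genuinely open.

## The prediction model

All engines fit the same linear model

$$\mathbf{y} = \mathbf{1}\mu + \mathbf{Z}\mathbf{g} + \mathbf{e},
\qquad \mathbf{e} \sim N(\mathbf{0}, \mathbf{R}\sigma^2_e),$$

where $\mathbf{y}$ holds deregressed EBV (dEBV) used as
pseudo-phenotypes and $\mathbf{R}$ is diagonal with
$R_{ii} = (1-r_i^2)/r_i^2$, so records backed by more information get
proportionally smaller residual variance. The engines differ in the
prior for the genetic term:

* **GBLUP** — $\mathbf{g} \sim N(\mathbf{0}, \mathbf{G}^*\sigma^2_g)$
  with $\mathbf{G}^* = (1-w)\mathbf{G} + w\mathbf{A}$.
  $\mathbf{G} = \mathbf{M}\mathbf{M}'/\sum_i 2p_i(1-p_i)$ uses
  current allele frequencies and dosages centered by $2p_i$
  (missing calls are mean-imputed first, so they contribute zero
  after centering). $w > 0$ blends in the pedigree numerator matrix
  $\mathbf{A}$, which is equivalent to fitting a residual polygenic
  effect; $w = 0$ and $w = 0.20$ are the two standard settings
  (`engine_gblup()`). The mixed-model equations are solved densely;
  a ridge of $10^{-8}$ is added to $\mathbf{G}^*$ only when its
  smallest eigenvalue drops below $10^{-10}$, which finite marker
  counts can cause. Animals without records sit in the equations
  with no data rows and are predicted purely through
  $\mathbf{G}^*$ — that is how test-set DGV are produced, and it
  stays exact under blending. Prediction-error variances come from
  the inverse coefficient matrix, and per-animal accuracies as
  $\sqrt{1 - \mathrm{PEV}_i/(\sigma^2_g G^*_{ii})}$.
* **BayesC** — $g_{j}$ is a mixture: with probability $\pi$ a normal
  effect with one common variance $\sigma^2_a$, else exactly zero.
  Both variances carry scaled inverse chi-square priors with
  $\nu = 4$; the scale of $\sigma^2_a$ is set so its prior mean
  equals the assumed genetic variance divided by
  $\pi\sum_i 2p_i(1-p_i)$ (the expected number of included markers
  times their average information). $\pi$ is *sampled* from its beta
  posterior, but the default prior Beta($10^8$, $10^{10}$) pins it
  numerically at $\approx 0.0099$ — fixed "around 0.01" without a
  hard constant in the sampler.
* **Bayesian LASSO** — each marker has its own variance $\tau^2_j$
  with exponential prior of rate $\lambda^2/2$; $1/\tau^2_j$ has an
  inverse-Gaussian full conditional, and $\lambda^2$ a gamma full
  conditional truncated so $\lambda \in (0, 10^7)$. The prior for
  $\lambda^2$ (shape 1.1, rate $10^{-4}$) is weakly informative and
  exposed in the interface. The residual variance gets a flat prior:
  the model has no common marker variance, so the flat prior
  mentioned for one in some descriptions can only attach to
  $\sigma^2_e$.

Both samplers are single-site Gibbs in compiled code, drawing through
R's RNG so `set.seed()` makes chains bit-identical. Heterogeneous
residual weights are handled once, up front, by dividing each record's
row (and the intercept column) by $\sqrt{R_{ii}}$, which turns the
weighted model into homogeneous algebra. The production chain profile
is 100 000 iterations, 20 000 burn-in, thinning 100; the reduced
profile (5 000 / 1 000 / 10, `chain_config(reduced = TRUE)`) is used
in tests and gives posterior means adequate for DGV ranking, not for
tail quantiles.

The GBLUP/SNP-BLUP duality (identical DGV from the animal-level and
marker-level parameterizations when $\sigma^2_a =
\sigma^2_g/\sum 2p(1-p)$) is used as an internal cross-check:
`snp_blup()` is a separate ridge-regression implementation kept only
to verify `fit_gblup()` to $10^{-6}$.

## Deregression

EBV cannot be used as phenotypes directly: they contain parent-average
information that would leak across train/test boundaries and their
shrinkage differs with accuracy. `deregress()` implements the
two-component parent-average removal system: the PA reliability is
$(r^2_{sire} + r^2_{dam})/4$, effective data contributions are derived
for the PA and the individual, and the individual's own-information
proof and reliability are returned. With both parents unknown it falls
back to $\mathrm{dEBV} = \mathrm{EBV}/r^2$ with reliability $r^2$. The
residual weight is always $(1-r^2)/r^2$ on the *deregressed*
reliability; the non-marker-variance parameter of the original
derivation defaults to zero, consistent with that weight.

## Quality control

`iterate_qc()` reproduces the standard iterative panel QC: per-call
quality masking (calls kept only if the score is strictly above 0.70),
removal of *all* markers sharing a map coordinate, then repeated
rounds of marker filters (call rate > 0.98, MAF > 0.02, HWE
chi-square p > $10^{-5}$, all strict), LD pruning (windows of 100
syntenic neighbours, $r^2 > 0.995$ removes the later marker of a
pair, scanning left to right) and the sample call-rate filter
(< 0.90 removed), until a full pass removes nothing. Iteration
matters because removing a badly called sample can lift a marker back
over a threshold; the fixed rule order is part of the contract, and
order-independence is deliberately not claimed. The HWE test is a
1-df chi-square on genotype counts without continuity correction —
the convention at these sample sizes.

## Validation designs and metrics

* **Forward** (`forward_split()`): train on animals accurate
  (> 0.50) in the early snapshot, test on those that became accurate
  only by the late snapshot; training proofs always come from the
  early evaluation, which is the information-leakage guard.
* **RAND** (`random_folds()`): seeded 5-fold split of near-equal
  sizes.
* **DIST** (`kmeans_folds()`): k-means on principal-coordinate
  embeddings of $\mathbf{G}$ (components covering 90% of the
  positive spectrum; 25 restarts), each cluster one fold. k-means
  needs a vector space, so the matrix is embedded rather than
  clustered directly; fold sizes are free to vary, and on structured
  populations they vary a lot.

Metrics (`run_design()`): empirical accuracy
$\mathrm{cor}(\mathrm{DGV}, \mathrm{dEBV}) / \overline{r}_{dEBV}$ —
a proxy for the correlation with the true breeding value that may
exceed 1 and is not clamped; the inflation slope of dEBV on DGV
(> 1 = deflated, compressed DGV); and prediction MSE. The mean dEBV
accuracy is the mean of per-animal $\sqrt{\text{reliability}}$.
Cross-validation metrics are unweighted fold means with standard
errors.

## Expected accuracy

`effective_segments()` computes $M_e = 2N_eL/\ln(4N_eL)$ and
`daetwyler_accuracy()` the deterministic expectation
$\sqrt{q}\,\sqrt{Nh^2/(Nh^2 + M_e)}$ for an animal without own
phenotype or close training relatives. Two conventions were genuinely
open and are both exposed rather than silently chosen: where the
marker-capture fraction $q$ enters (default: as the $\sqrt{q}$
multiplier, an upper bound on DGV accuracy; alternatives `inside` and
`both`), and how the pseudo-phenotype heritability is formed from a
summary table (default: squared mean training accuracy; alternative:
mean reliability). With $N_e = 120$, $L = 30$ Morgans, $q = 0.8$ and
the default conventions, the 15-trait summary table shipped in
`inst/extdata/` yields a mean expected accuracy of 0.49. The SD
across traits is sensitive to the convention choice; the mean is not.

## The synthetic population generator

No individual-level data are distributable for this kind of
population, so `simulate_population()` builds one with the features
the pipeline is sensitive to:

* **Founder LD** — haplotypes are first-order Markov chains along
  each chromosome. Allele frequencies follow a latent AR(1) mapped
  through a symmetric Beta(0.7, 0.7) quantile onto (0.02, 0.98),
  which gives a mean minor allele frequency of ~0.226 and keeps
  adjacent frequencies similar so the target adjacent correlation is
  achievable. The per-pair correlation is calibrated by a one-scalar
  search against the Fréchet bounds so the realized mean adjacent
  $r^2$ lands on the target (default 0.293).
* **Pedigree** — each generation draws sires from the previous one;
  every sire founds a paternal half-sib family (mean size 4.7 by a
  shifted Poisson) whose dams are new unrelated founders recorded
  with unknown parents. Four generations by default, giving son-sire
  and grandson-grandsire pairs.
* **Recombination** — Haldane map over uniformly spaced markers, 30
  Morgans total across 10 chromosomes.
* **Subgroups** — optional two founder pools with Balding-Nichols
  frequency perturbation ($F_{ST}$ default 0.15) and within-pool
  mating, which reproduces a two-cluster genomic PCA without
  modelling the selection history that caused it.
* **Traits and proofs** — QTL sampled among polymorphic markers with
  normal effects rescaled to a target genetic variance;
  `simulate_ebv_snapshots()` makes two evaluation snapshots with
  per-animal target accuracies. EBV are scaled so
  $\mathrm{sd(EBV)} = r\,\mathrm{sd(TBV)}$ — the shrinkage property
  of a BLUP evaluation. That choice (rather than full TBV scale)
  makes deregressed proofs regress on TBV with slope 1, which the
  deregression checks rely on; its limit at $r = 0$ is everyone
  predicted at the mean.

All randomness flows from one seed. What the generator does *not*
emulate: long-range LD decay of a real drift-selection history (only
the adjacent-pair summary is matched, so there is no defined $N_e$),
genotyping-error structure in quality scores, selection on the trait,
and overlapping generations. Consequently, passing tests show the
machinery is correct and directionally faithful; they do not certify
accuracy magnitudes on real data.

## Problem sizes and numerical choices

The test suite and the acceptance script run the expectation-recovery
experiment at 500 training / 150 testing animals with 5 000 *unlinked*
markers, where the effective segment count is exactly the marker count
and the markers carry all genetic variance — the matched-parameters
form of the expectation ($M_e = 5000$, $q = 1$). Replicates are
averaged (three in tests, five in the acceptance script) because a
correlation estimated on 150 animals has a sampling SE near 0.08.
Design-comparison and architecture-sensitivity experiments use the
default four-generation population (~500–1000 animals, 2 000
markers) with reduced chains. The BayesC/BLASSO agreement check
scales $\pi$ with panel density so the expected number of included
markers matches the polygenic dimension — at the production setting
$\pi m \approx 3200$ far exceeds the training size, and a fixed 0.01
at 2 000 markers would not.

Other numerical conventions: LD $r^2$ is computed on mean-imputed
dosages (matching the centering used for $\mathbf{G}$); ties in LD
pruning break towards the lexicographically larger marker id;
$\mathbf{A}$ is computed on the full pedigree and only then
restricted, because dropping ungenotyped ancestors before recursion
corrupts relationships; pedigree-mode imputation uses the Mendelian
expectation of available parents one generation deep, falling back to
$2p$; effective sample sizes use the initial-positive-sequence
autocorrelation estimator.

## Known limitations

Dense solvers limit populations to a few thousand animals. Single
trait at a time; no multi-trait deregression or GBLUP. The Bayesian
engines do not fit a residual polygenic term, so their predictions
can be deflated on traits where GBLUP blending helps — visible in the
inflation slopes. The expectation layer offers only the
$2N_eL/\ln(4N_eL)$ segment approximation.
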