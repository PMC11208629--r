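---
title: "Threshold-model genomics for ordinal cattle fertility traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-model genomics for ordinal cattle fertility traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`liabgen` analyses ordinal reproductive classifications in beef-heifer
cohorts — Early (E), Typical (T), Start-Stop-Start (SSS),
Start-Stop-Discontinued (SSD) and Non-Cycling (NC), as scored from weekly
progesterone profiles between weaning and breeding — with a Bayesian
threshold animal model on SNP-panel genotypes. This vignette explains the
models, the numerical choices behind the samplers, the synthetic cohort
generator, and what the package's tests do and do not establish.

## The threshold animal model

An observed class is assumed to arise from a latent continuous liability
$l$ cut at ordered thresholds $t_1 < t_2 < \dots < t_{K-1}$:

$$ l = Xb + Zu + e, \qquad u \sim N(0,\, G\,\sigma_u^2), \qquad
   e \sim N(0,\, I\,\sigma_e^2), $$

where $X$ carries the intercept, birth-year indicators and a birth-date
deviation covariate (day-of-year minus the within-year mean), $Z$ maps
records to animals, and $G$ is the VanRaden genomic relationship matrix
$G = MM'/\,2\sum_j p_j(1-p_j)$ built from dosages centered at twice the
post-QC allele frequencies. Because an ordinal response carries no scale
of its own, the model is identified by fixing $\sigma_e^2 = 1$ and
$t_1 = 0$, leaving the intercept free. Heritability is reported per draw
as $h^2 = \sigma_u^2 / (\sigma_u^2 + \sigma_e^2)$ and then averaged —
never as a ratio of averages.

Four trait codings map the five classes onto ordinal levels: `AL` (all
five), `ND` (SSD and NC merged), `ETvND` (cycled vs did not; SSS
excluded) and `ET` (Early vs Typical only). Codings that exclude classes
drop those records, and observed levels are relabelled to stay
contiguous.

### Sampler design

The Gibbs sampler alternates:

1. liabilities from truncated normals on their category intervals
   (inverse-CDF in the bulk, tail-safe exponential rejection beyond
   $|z| = 3.5$);
2. fixed effects from their flat-prior multivariate normal conditional;
3. the genetic variance by a random-walk Metropolis step on
   $\log \sigma_u^2$ against the *collapsed* likelihood: in the eigenbasis
   $G = VDV'$, the rotated residuals $v_j'(l - Xb)$ are independent
   $N(0, \sigma_u^2 d_j + \sigma_e^2)$, so $\sigma_u^2$ can be updated
   with the breeding values integrated out. The naive conjugate update of
   $\sigma_u^2$ given $u$ is notoriously sticky for latent-liability
   models — the pair random-walks together — and the collapsed step
   removes that coupling. The proposal step size adapts during burn-in
   only;
4. rotated breeding values from their diagonal normal conditional given
   $\sigma_u^2$ (cost $O(n^2)$ per sweep after a one-time
   eigendecomposition; eigenvalues below $10^{-8}$ of the largest are
   dropped, which also handles numerically semidefinite $G$ without
   jitter);
5. for $K > 2$, the interior thresholds by a blocked Metropolis update
   with liabilities integrated out (Cowles-style): all interior
   thresholds are proposed from order-respecting truncated-normal random
   walks, accepted jointly against the ordinal likelihood
   $\prod_i [\Phi(t_{y_i} - \mu_i) - \Phi(t_{y_i-1} - \mu_i)]$, and the
   liabilities are refreshed under accepted thresholds. The textbook
   alternative — uniform draws between adjacent liability order
   statistics — moves $O(1/n)$ per sweep and was measured to mix far too
   slowly to be usable at cohort sizes of a few hundred.

All randomness inside the compiled samplers comes from R's RNG, so a
single `set.seed()` (or the `seed` field of `mcmc_config()`) makes every
fit exactly reproducible.

### Priors, and why the prior matters here

Fixed effects get flat priors. The genetic variance gets a scaled
inverse chi-square prior with `prior_df = 4` degrees of freedom and scale
chosen so the prior *mean* equals the genetic variance implied by
`prior_h2 = 0.5` against the unit residual — the convention of the JWAS
family of samplers. (Matching the prior *mode* instead inflates the prior
mean of $\sigma_u^2$ to 3, i.e. an implicit prior heritability of 0.75,
and was measurably worse calibrated in recovery simulations.)

Two properties of this prior deserve emphasis, because they shape every
result the model produces on cohort-sized data:

* An inverse chi-square prior has essentially no mass near zero (its
  density vanishes super-exponentially as $\sigma_u^2 \to 0$). Posterior
  heritability therefore cannot reach zero, and truly null traits are
  reported around 0.2 even for a fully observed Gaussian liability at
  $n = 500$. This is a property of the model family, not of the
  implementation.
* For ordinal data the likelihood constrains large $\sigma_u^2$ only
  weakly (the right tail is nearly flat), so the posterior mean sits
  above the posterior mode. At a few hundred animals this produces a
  systematic upward tilt of posterior-mean heritability of roughly +0.1
  at moderate truths, shrinking as relatedness information grows. The
  recovery simulations in `tests/` and `scripts/acceptance.R` quantify
  this tilt rather than hide it, and an independent MCMC implementation
  of the identical model (JAGS, sampling the marginal categorical
  likelihood with no liability augmentation) reproduces the same
  posteriors, which localises the tilt in the model-plus-prior, not the
  sampler.

Both effects argue for reading cohort-scale heritability point estimates
together with their credible sets, as the reported tables do.

## BayesB genome scan and window summaries

The GWAS model replaces $Zu$ with $\sum_j x_j \alpha_j$, where each
marker effect is zero with prior probability $\pi = 0.99$ (fixed, not
estimated) and otherwise normal with a locus-specific variance carrying a
scaled-inverse-chi-square prior; the prior scale spreads the genetic
variance from a preceding GBLUP fit over the expected $(1-\pi)$ non-null
markers. Indicator and effect are sampled jointly against adjusted
residuals; ordinal traits use the same liability augmentation and
identification as the threshold model.

Results are summarised per fixed, half-open 1-Mb window
(`floor(pos / 1e6)` per chromosome). In each retained draw, a window's
genetic value is the dosage-weighted sum of its markers' effects across
animals; its proportion of genetic variance is the across-animal variance
of that value divided by the *sum of the per-window variances* of the
draw, so proportions sum to exactly 1 whenever any genetic variance is
present. (Dividing by the variance of the total genetic value instead
leaves a sampling-covariance remainder between windows; the sum-based
denominator keeps the proportions a true partition, which is also what
the sum-to-one invariant of the window summary asserts.) WPPA — the
window posterior probability of association — is the fraction of draws in
which a window's proportion exceeds 1%, the same 1% rule used to call a
window associated from its posterior-mean proportion.

## Candidate-gene scan and pseudo-p-values

Candidate SNPs are those inside a supplied gene interval or, only when a
gene contains no genotyped SNP, within 10 kb of it. Each SNP is added to
the threshold model one at a time as a fixed 0/1/2 covariate, with the
polygenic term kept in place; the SNP also remains in $G$ (no indication
of exclusion was adopted, so proximal contamination is accepted and noted
here). The association measure is the pseudo-p-value $2\min(s, 1-s)$,
with $s$ the fraction of retained draws in which the sampled effect is
negative. With 750 retained draws the smallest resolvable non-zero value
is $2/750 \approx 0.0027$; when no draw crosses zero the raw value is 0
and is displayed as $10^{-4}$ so $-\log_{10}$ plots show it at 4. No
multiple-testing correction is applied — the scan reports its test count
so users can adjust.

The file `inst/extdata/candidate_genes_synthetic.tsv` is an *editable
template* of the candidate-gene set: the symbols are real genes from the
puberty/PCOS/hormone-secretion literature, but the intervals are
synthetic megabase-resolution placeholders, to be replaced with real
assembly coordinates before use on real data.

## Exact and Monte Carlo Fisher tests

Class-by-year (and genotype-by-class) tables are tested with Fisher's
exact test under probability-mass ordering: the p-value sums the
fixed-margins probabilities of all tables no more probable than the
observed one. 2x2 tables use the hypergeometric directly; larger tables
are enumerated exactly when at most $10^6$ tables share the margins, and
otherwise sampled with `r2dtable()` using the add-one estimate
$(1 + \#\{\text{prob} \le \text{obs}\})/(1 + n_{sim})$.

A practical note on reporting: simulated Fisher p-values are
floor-limited at $1/(B+1)$ by the add-one correction. The 6x5
class-by-year table shipped with the package is so far from independence
that *no* simulated table in $10^6$ draws is as extreme; its "p = 0.0005"
under the common default of $B = 2000$ simulations is exactly that floor,
$1/2001$, and the package's tests assert precisely this behaviour rather
than treating 0.0005 as a converged estimate.

## The synthetic cohort generator

`simulation_config()` defaults describe the cohort the models target:
532 animals over 6 birth years (2017-2022), class frequencies
$(149, 226, 55, 31, 71)/532$ (i.e. 28/42/10/6/13 percent), biallelic
autosomal SNPs with frequencies Uniform(0.05, 0.5), a polygenic liability
with residual variance 1, and thresholds placed at normal quantiles of
the cumulative class frequencies. Breeding values are built from centered
dosages and rescaled so realized $\mathrm{Var}(u)/(\mathrm{Var}(u)+1)$
equals the target heritability exactly, so "truth" in recovery tests is
not itself noisy.

The default cohort contains 30 paternal half-sib families (about 5 sires
per year over 6 years, a realistic stocking for a university physiology
herd): each animal receives one gamete from its sire's simulated genotype
and one from the base population. This matters more than it may appear:
with unrelated animals ($G \approx I$) and one ordinal record per animal,
liability-scale heritability is *not identifiable at all* — thresholds
and the intercept absorb any marginal class distribution, and the
posterior simply returns the prior. Relatedness is the information source
for every variance-component result in this package, exactly as in the
real herd with its sire families and multi-generation pedigree.

What the generator does *not* emulate: linkage disequilibrium (except an
optional block-LD mode used to exercise window logic), maternal pedigree,
selection, non-genetic trends beyond birth-year effects, and genotyping
error. Passing recovery tests on this generator therefore demonstrates
correctness of the estimation machinery under the model's own
assumptions, not robustness to the full texture of real data. Marker
counts in tests (1,000-2,000) are far below a real 85k panel; they keep
genomic relationships slightly noisier than a dense panel would, which
if anything makes the recovery tests conservative.

## Numerical choices and degenerate inputs

* Missing dosages are filled with the per-marker mean of observed calls —
  a deliberate, clearly-labelled approximation standing in for
  model-based imputation, preserving per-marker means exactly and
  adding no between-marker information.
* QC order is markers (autosome, call rate >= 0.9, MAF >= 0.01, each rule
  on the survivors of the previous one) then animals (call rate >= 0.9,
  heterozygosity <= 0.5 over non-missing calls), in one pass each;
  emptying either axis is an error, not a silent empty result.
* Panel merging matches sites by (chromosome, position); discordant
  duplicate calls become missing; swapped ref/alt at a shared site is an
  error unless `allow_flip = TRUE`.
* PCA coordinates scale eigenvectors by root-eigenvalues (negative
  numerical eigenvalues clamped to zero) with the largest-magnitude
  loading forced positive for reproducible orientation.
* Thresholds built from rounded percentage vectors that sum to slightly
  under 1 are accepted; the deficit accrues to the last class.
* Degenerate mixture settings in BayesB behave as documented: $\pi = 1$
  warns and returns the all-null model; $\pi = 0$ includes every marker
  every draw.

## Problem sizes used by the shipped checks

The test-suite and acceptance script run entirely on generated data at
sizes chosen to exercise the estimators meaningfully on one CPU:
QC/GRM/Fisher oracles at tens of animals; sampler recovery at $n = 500$
animals, 2,000 markers, chains of 20,000 (burn-in 5,000, thinning 20);
BayesB scans at $n = 500$, 1,000 markers; calibration of the null
pseudo-p over a couple of hundred short-chain refits. The default
analysis configuration (chain 100,000, burn-in 25,000, thinning 100,
retaining exactly 750 draws) is asserted on a small cohort.

## Known limitations

* The five-level AL scale treats SSD as "more" than SSS; the ordinal
  assumption is adopted as stated and not tested.
* Posterior-mean heritability on cohort-sized ordinal data carries the
  upward tilt described above; credible sets are honest, point estimates
  should be read with them.
* Mean-fill imputation ignores LD; downstream sensitivity to replacing
  model-based imputation with mean-fill on real panels is unknown and
  flagged wherever fill is used.
* Window proportions use realized across-animal variance, which absorbs
  within-window LD but attributes shared variance between correlated
  windows to neither.
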