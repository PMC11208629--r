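# liabgen

Bayesian threshold-model genomics for ordinal fertility traits in beef
cattle.

Beef heifers can be classified from weekly progesterone profiles between
weaning and breeding into five ordinal pubertal classes — Early (E),
Typical (T), Start-Stop-Start (SSS), Start-Stop-Discontinued (SSD) and
Non-Cycling (NC). `liabgen` implements the quantitative-genetic analysis
of such classifications for cohorts genotyped on SNP panels:

* **Genotype handling** — matrix-TSV and PLINK ped/map readers, merging
  of two SNP panels by genomic position (discordant duplicate calls set
  missing), marker QC (autosome, call rate ≥ 0.9, MAF ≥ 0.01), animal QC
  (call rate ≥ 0.9, heterozygosity ≤ 0.5), mean-dosage fill for missing
  calls.
* **GRM** — the VanRaden genomic relationship matrix
  `G = MM' / 2Σ p_j (1 − p_j)` from centered dosages, plus
  principal-component coordinates of relatedness.
* **Threshold animal model** — a Gibbs sampler (RcppArmadillo) for
  `y = Xb + Zu + e` observed through ordered thresholds on a latent
  liability, with `u ~ N(0, G σ²_u)`, residual variance fixed at 1 and
  `t₁ = 0` for identification; heritability
  `h² = σ²_u / (σ²_u + σ²_e)` summarized per draw with 95% credible
  sets.
* **BayesB GWAS** — whole-genome regression with π = 0.99 null-effect
  prior and locus-specific variances, summarized per 1-Mb window as the
  proportion of genetic variance and the window posterior probability of
  association (WPPA), with the 1% association rule.
* **Candidate-gene scan** — SNPs inside supplied gene intervals (or
  within 10 kb when a gene has no internal SNP) fitted one at a time as
  fixed 0/1/2 covariates, reported with posterior effect mean ± SD and
  the pseudo-p-value `2·min(s, 1−s)`.
* **Contingency tests** — exact and Monte-Carlo Fisher tests on r×c
  tables (probability-mass two-sided ordering, fixed-margins
  simulation).
* **Synthetic cohorts** — a generator emulating the target cohort (532
  animals, 6 birth years, half-sib sire families, the cohort's class
  frequencies, polygenic liability with unit residual), used by every
  test.

See the vignette (`vignettes/liability-models.Rmd`) for the models,
priors, sampler design and known limitations.

## Worked example

Simulate a cohort with liability heritability 0.4, build the GRM, fit the
threshold model to the five-level classification, and summarize:

```r
library(liabgen)

cfg <- simulation_config(n_animals = 500, n_markers = 2000,
                         liability_h2 = 0.4, seed = 11)
sim <- simulate_cohort(cfg)

p   <- allele_frequencies(sim$genotypes)
g   <- build_grm(center_genotypes(sim$genotypes, p))
des <- build_design(sim$phenotypes, trait_coding("AL"), g$animal_ids)
fit <- fit_threshold_model(des, g, mcmc_config(20000, 5000, 20, seed = 42))
summarize_heritability(fit)
#> AL: h2 = 0.38 +/- 0.10 (0.21-0.60), Vg = 0.67 +/- 0.30, n = 750 draws
```

The posterior mean (0.38) sits near the generating value (0.40) with the
truth well inside the credible set; averaged over many such cohorts the
posterior mean carries a modest upward tilt that is discussed, and
quantified by simulation, in the vignette.

The shipped cohort table reproduces its printed form and Fisher test:

```r
rep <- class_by_year_report(heifer_cohort_counts())
rep$formatted["2017", ]
#>         E         T       SSS       SSD        NC     Total
#> "29 (38)" "35 (46)"   "0 (0)"   "2 (3)" "10 (13)" "76 (14)"
fisher_exact(heifer_cohort_counts(), method = "montecarlo",
             n_sim = 2000, seed = 3)$p_value
#> [1] 0.0004997501
```

An end-to-end run (QC → GRM → heritability → GWAS → Fisher) is one call:

```r
run_pipeline(list(simulate = list(n_animals = 300, n_markers = 1000),
                  traits = list("AL", "ETvND"),
                  mcmc = list(chain_length = 20000L, burn_in = 5000L,
                              thin = 20L),
                  seed = 1, output_dir = "demo_run"))
```

which writes `qc_summary.txt`, `grm.tsv`, `grm_pca.tsv`,
`class_by_year.tsv` (+ Fisher p), `heritability.tsv` (one row per trait,
`mean ± sd (2.5%–97.5%)`), per-window GWAS TSVs and `report.yaml` with
all seeds.

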