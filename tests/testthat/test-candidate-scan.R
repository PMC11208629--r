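# Candidate SNP selection, single-SNP covariate fits, pseudo-p-values.

test_that("in-gene SNPs pre-empt the flank rule; the 10 kb boundary is sharp", {
  map <- data.frame(marker_id = c("S1", "S2", "S3", "S4"),
                    chrom = c("1", "1", "1", "2"),
                    pos = c(150L, 205L, 5200L, 150L),
                    ref = "A", alt = "C", stringsAsFactors = FALSE)
  genes <- data.frame(gene = c("G1", "G2", "G3"),
                      chrom = c("1", "1", "1"),
                      start_bp = c(100L, 300L, 20000L),
                      end_bp = c(200L, 400L, 20050L),
                      stringsAsFactors = FALSE)
  sel <- candidate_snp_set(map, genes, flank_bp = 10000L)
  # G1 holds S1 inside, so nearby S2 is not added
  expect_equal(sel$marker_id[sel$gene == "G1"], "S1")
  expect_equal(sel$zone[sel$gene == "G1"], "gene")
  # G2 has no internal SNP: flank picks S1, S2, S3 (all within 10 kb), not S4
  expect_setequal(sel$marker_id[sel$gene == "G2"], c("S1", "S2", "S3"))
  # G3's nearest marker is 14,800 bp away -> empty
  expect_false("G3" %in% sel$gene)
  expect_equal(attr(sel, "empty_genes"), "G3")
  # exactly-at-boundary flank inclusion
  sel2 <- candidate_snp_set(map, genes[2, , drop = FALSE], flank_bp = 4800L)
  expect_true("S3" %in% sel2$marker_id)
  sel3 <- candidate_snp_set(map, genes[2, , drop = FALSE], flank_bp = 4799L)
  expect_false("S3" %in% sel3$marker_id)
})

test_that("pseudo-p follows 2 min(s, 1-s) with a display floor at 1e-4", {
  expect_equal(pseudo_p(0.5)$pseudo_p, 1.0)
  expect_equal(pseudo_p(0.2)$pseudo_p, 0.4)
  z <- pseudo_p(0)
  expect_equal(z$pseudo_p, 0)
  expect_equal(z$display, 1e-4)
  expect_equal(-log10(z$display), 4)
  # symmetry
  for (s in seq(0, 1, by = 0.1)) {
    expect_equal(pseudo_p(s)$pseudo_p, pseudo_p(1 - s)$pseudo_p)
  }
  expect_error(pseudo_p(1.2))
})

test_that("a strong SNP effect is detected by the covariate fit", {
  hits <- 0L
  for (r in 1:5) {
    cfg <- simulation_config(n_animals = 300, n_markers = 400,
                             liability_h2 = 0.2, seed = 400 + r)
    sim <- simulate_cohort(cfg)
    g <- build_grm(center_genotypes(sim$genotypes,
                                    allele_frequencies(sim$genotypes)))
    # inject a SNP with a positive liability effect of 0.5 SD and re-cut
    snp <- sim$genotypes$dosages[, 1]
    liab <- sim$truth$liability + 0.5 * (snp - mean(snp))
    thr <- sim$truth$thresholds
    cls <- c("E", "T", "SSS", "SSD", "NC")[findInterval(liab, thr) + 1L]
    ph <- sim$phenotypes
    ph$class <- cls
    if (length(unique(cls)) < 2) next
    des <- build_design(ph, trait_coding("AL"), g$animal_ids)
    res <- fit_snp_covariate(des, g, snp[des$animal_ids],
                             mcmc_config(4000, 1000, 10, seed = r),
                             marker_id = "S1")
    if (res$s < 0.05 && res$pseudo_p < 0.1) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("covariate fit rejects monomorphic SNPs and reports MAF", {
  cfg <- simulation_config(n_animals = 100, n_markers = 50,
                           liability_h2 = 0.3, seed = 77)
  sim <- simulate_cohort(cfg)
  g <- build_grm(center_genotypes(sim$genotypes,
                                  allele_frequencies(sim$genotypes)))
  des <- build_design(sim$phenotypes, trait_coding("AL"), g$animal_ids)
  expect_error(fit_snp_covariate(des, g, rep(1, length(des$y))),
               "covariate constant")
  snp <- sim$genotypes$dosages[des$animal_ids, 2]
  res <- fit_snp_covariate(des, g, snp, mcmc_config(1500, 500, 10, seed = 3))
  expect_true(res$maf >= 0 && res$maf <= 0.5)
  expect_equal(res$pseudo_p, 2 * min(res$s, 1 - res$s))
})

test_that("candidate_scan tests each selected SNP and counts tests", {
  cfg <- simulation_config(n_animals = 120, n_markers = 60,
                           n_chromosomes = 2, liability_h2 = 0.3, seed = 15)
  sim <- simulate_cohort(cfg)
  g <- build_grm(center_genotypes(sim$genotypes,
                                  allele_frequencies(sim$genotypes)))
  des <- build_design(sim$phenotypes, trait_coding("AL"), g$animal_ids)
  map <- sim$genotypes$map
  genes <- data.frame(gene = c("GA", "GB"),
                      chrom = map$chrom[c(1, 30)],
                      start_bp = map$pos[c(1, 30)] - 10L,
                      end_bp = map$pos[c(1, 30)] + 10L,
                      stringsAsFactors = FALSE)
  scan <- candidate_scan(des, g, sim$genotypes, genes,
                         mcmc_config(1000, 400, 10, seed = 8))
  expect_equal(attr(scan, "n_tests"), nrow(scan))
  expect_true(all(c("gene", "marker_id", "maf", "effect_mean", "effect_sd",
                    "pseudo_p") %in% names(scan)))
  expect_true(all(scan$pseudo_p >= 0 & scan$pseudo_p <= 1))
})
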