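# BayesB regression, window summaries, association calls.

sim_binary_design <- function(sim, g) {
  build_design(sim$phenotypes, trait_coding("ETvND"), g$animal_ids)
}

test_that("degenerate mixture settings behave as declared", {
  sim <- simulate_cohort(simulation_config(n_animals = 80, n_markers = 60,
                                           liability_h2 = 0.3, seed = 12))
  filled <- sim$genotypes
  des <- build_design(sim$phenotypes, trait_coding("AL"), rownames(filled$dosages))
  expect_warning(
    f1 <- fit_bayesb(des, filled, bayesb_config(pi_null = 1, chain_length = 600,
                                                burn_in = 200, thin = 4, seed = 2)),
    "null")
  expect_true(all(f1$alpha == 0))
  f0 <- fit_bayesb(des, filled, bayesb_config(pi_null = 0, chain_length = 600,
                                              burn_in = 200, thin = 4, seed = 2))
  expect_true(all(f0$alpha != 0))
  expect_equal(unname(inclusion_probabilities(f0)), rep(1, 60))
})

test_that("windows follow the half-open megabase convention", {
  sim <- simulate_cohort(simulation_config(n_animals = 60, n_markers = 4,
                                           n_chromosomes = 1,
                                           liability_h2 = 0.3, seed = 6))
  filled <- sim$genotypes
  filled$map$pos <- c(999999L, 1000000L, 1500000L, 2000001L)
  des <- build_design(sim$phenotypes, trait_coding("AL"), rownames(filled$dosages))
  fit <- fit_bayesb(des, filled, bayesb_config(pi_null = 0.5, chain_length = 400,
                                               burn_in = 100, thin = 3, seed = 3))
  ws <- window_variance(fit)
  expect_equal(ws$window_index, c(0L, 1L, 2L))
  expect_equal(ws$n_markers, c(1L, 2L, 1L))
  expect_equal(ws$start_bp[2], 1e6)
  expect_equal(ws$end_bp[2], 2e6)
})

test_that("per-draw window proportions sum to one when variance is present", {
  sim <- simulate_cohort(simulation_config(n_animals = 100, n_markers = 80,
                                           n_chromosomes = 4,
                                           liability_h2 = 0.5, seed = 8))
  filled <- sim$genotypes
  des <- build_design(sim$phenotypes, trait_coding("AL"), rownames(filled$dosages))
  fit <- fit_bayesb(des, filled, bayesb_config(pi_null = 0.9, chain_length = 1000,
                                               burn_in = 400, thin = 4, seed = 4))
  prop <- attr(window_variance(fit), "proportions")
  sums <- rowSums(prop)
  nz <- rowSums(fit$alpha != 0) > 0
  expect_true(all(abs(sums[nz] - 1) < 1e-8))
  expect_true(all(sums[!nz] == 0))
})

test_that("a single window absorbs all variance; null draws give zero WPPA", {
  sim <- simulate_cohort(simulation_config(n_animals = 80, n_markers = 30,
                                           n_chromosomes = 1,
                                           liability_h2 = 0.5, seed = 10))
  filled <- sim$genotypes
  filled$map$pos <- seq(1000L, by = 1000L, length.out = 30)  # one window
  des <- build_design(sim$phenotypes, trait_coding("AL"), rownames(filled$dosages))
  fit <- fit_bayesb(des, filled, bayesb_config(pi_null = 0.5, chain_length = 600,
                                               burn_in = 200, thin = 4, seed = 5))
  ws <- window_variance(fit)
  expect_equal(nrow(ws), 1L)
  nz <- mean(rowSums(fit$alpha != 0) > 0)
  expect_equal(ws$wppa, nz, tolerance = 1e-12)
  # all-null draws -> zero everywhere
  expect_warning(
    f1 <- fit_bayesb(des, filled, bayesb_config(pi_null = 1, chain_length = 400,
                                                burn_in = 100, thin = 3, seed = 6)))
  ws1 <- window_variance(f1)
  expect_equal(ws1$wppa, 0)
  expect_equal(ws1$mean_prop, 0)
})

test_that("call_associated applies the 1% rule and sorts descending", {
  ws <- data.frame(chrom = c("1", "2"), window_index = c(0L, 0L),
                   start_bp = 0, end_bp = 1e6, n_markers = 5L,
                   mean_prop = c(0.005, 0.020), wppa = c(0.1, 0.6))
  class(ws) <- c("window_summary", "data.frame")
  hit <- call_associated(ws)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$chrom, "2")
  expect_equal(nrow(call_associated(ws, threshold = 1)), 0L)
  all_pos <- call_associated(ws, threshold = 0)
  expect_equal(all_pos$mean_prop, c(0.020, 0.005))
})

test_that("with pi = 0 and a continuous trait, effect ranking matches ridge", {
  set.seed(19)
  n <- 300; m <- 500
  cfg <- simulation_config(n_animals = n, n_markers = m, liability_h2 = 0.5,
                           seed = 19, n_sires = 0L)
  sim <- simulate_cohort(cfg)
  filled <- sim$genotypes
  des <- build_design(sim$phenotypes, trait_coding("AL"), rownames(filled$dosages))
  y <- sim$truth$liability
  fit <- fit_bayesb(des, filled, bayesb_config(pi_null = 0, chain_length = 3000,
                                               burn_in = 1000, thin = 10, seed = 20),
                    gaussian_response = y)
  post_mean <- colMeans(fit$alpha)
  # ridge oracle at the shrinkage implied by the locus-variance prior scale
  p <- colMeans(filled$dosages) / 2
  lam <- sum(2 * p * (1 - p)) / 0.5
  M <- scale(filled$dosages, scale = FALSE)
  ridge <- solve(crossprod(M) + diag(lam, m), crossprod(M, y - mean(y)))
  expect_gt(cor(post_mean, ridge, method = "spearman"), 0.9)
})
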