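# Bayesian threshold (liability) animal model: Gibbs sampler wrapper,
# liability sampling, and heritability summaries.

#' MCMC settings for the threshold animal model
#'
#' Defaults follow the analysis the package implements: a 100,000-iteration
#' chain, 25,000 burn-in, and thinning of 100, retaining 750 draws. The
#' genetic-variance prior is a scaled inverse chi-square with `prior_df`
#' degrees of freedom whose mean equals the genetic variance implied by a
#' heritability of `prior_h2` against the fixed residual variance of 1.
#'
#' @param chain_length Total Gibbs iterations.
#' @param burn_in Iterations discarded before retention.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param prior_h2 Prior mode for heritability (default 0.5).
#' @param prior_df Prior degrees of freedom for the genetic variance.
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(chain_length = 100000L, burn_in = 25000L,
                        thin = 100L, seed = NULL, prior_h2 = 0.5,
                        prior_df = 4) {
  stopifnot(burn_in < chain_length, thin >= 1)
  if ((chain_length - burn_in) %/% thin < 2L) {
    stop("config retains fewer than 2 draws")
  }
  stopifnot(prior_h2 > 0, prior_h2 < 1)
  structure(list(chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = seed, prior_h2 = prior_h2, prior_df = prior_df),
            class = "mcmc_config")
}

#' Draw a liability for an ordinal record
#'
#' Samples from Normal(`mean`, 1) truncated to the interval of ordinal
#' level `k`: `(t_{k-1}, t_k]` with `t_0 = -Inf` and `t_K = +Inf`. The
#' thresholds vector holds `t_1 .. t_{K-1}` (by the model's identification,
#' `t_1 = 0`); a single category means no truncation.
#'
#' @param level Ordinal level in `1..K`.
#' @param mean Mean of the untruncated normal.
#' @param thresholds Strictly increasing numeric vector of length `K - 1`
#'   (length 0 for a single category).
#' @param n Number of draws.
#' @return Numeric vector of `n` draws.
#' @export
sample_liability <- function(level, mean, thresholds, n = 1L) {
  K <- length(thresholds) + 1L
  if (length(thresholds) > 1L && any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing")
  }
  if (level < 1L || level > K) stop("level out of range 1..", K)
  lo <- if (level == 1L) -Inf else thresholds[level - 1L]
  hi <- if (level == K) Inf else thresholds[level]
  pa <- stats::pnorm(lo - mean)
  pb <- stats::pnorm(hi - mean)
  u <- stats::runif(n, pa, pb)
  u <- pmin(pmax(u, 1e-15), 1 - 1e-15)
  mean + stats::qnorm(u)
}

# Eigendecompose a GRM aligned to the design's animals, dropping near-zero
# eigenvalues so the rotated breeding-value conditional is proper.
grm_eigen_for <- function(design, grm, tol = 1e-8) {
  ids <- design$animal_ids
  missing <- setdiff(ids, grm$animal_ids)
  if (length(missing)) {
    stop("design animals absent from GRM: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  if (anyDuplicated(ids)) stop("one record per animal required")
  G <- grm$values[ids, ids, drop = FALSE]
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values))) {
    stop("GRM is not positive semidefinite")
  }
  keep <- e$values > tol * max(e$values)
  list(V = e$vectors[, keep, drop = FALSE], d = e$values[keep])
}

prior_scale_from_h2 <- function(prior_h2, prior_df) {
  # mean of scaled-inv-chi2(df, S) is df*S/(df-2); set it to h2/(1-h2),
  # the genetic variance implied by prior_h2 against residual variance 1
  (prior_df - 2) / prior_df * prior_h2 / (1 - prior_h2)
}

#' Fit the Bayesian threshold animal model
#'
#' Gibbs sampler for `y = Xb + Zu + e` where `y` is observed through
#' ordered thresholds on a latent liability: liabilities are drawn from
#' truncated normals, fixed effects from their flat-prior conditionals,
#' breeding values `u ~ N(0, G sigma_u^2)` as a block through a one-time
#' eigendecomposition of G, the genetic variance from its scaled inverse
#' chi-square conditional, and interior thresholds (K > 2) from their
#' uniform conditionals. Identification: `t_1 = 0` and residual variance
#' fixed at 1; the intercept is free.
#'
#' @param design A [build_design()] result.
#' @param grm A [build_grm()] result covering the design's animals.
#' @param config An [mcmc_config()].
#' @param extra_covariate Optional numeric vector (one per record) added to
#'   the fixed-effects design as a column named `"snp"`, e.g. a candidate
#'   SNP's 0/1/2 dosage.
#' @param gaussian_response Optional numeric vector; when supplied the
#'   liability is treated as observed (no truncation, no thresholds) and
#'   the residual variance is sampled unless `fix_sigma_e = TRUE`.
#' @param fix_sigma_e Fix the residual variance at 1 in gaussian mode.
#' @return Object of class `posterior_samples`: per retained draw the
#'   genetic variance `sigma_u`, residual variance `sigma_e` (identically 1
#'   for ordinal fits), fixed effects `b`, thresholds; plus the posterior
#'   mean breeding values `u_mean` and bookkeeping.
#' @export
fit_threshold_model <- function(design, grm, config = mcmc_config(),
                                extra_covariate = NULL,
                                gaussian_response = NULL,
                                fix_sigma_e = FALSE) {
  stopifnot(inherits(design, "trait_design"), inherits(config, "mcmc_config"))
  X <- design$X
  if (!is.null(extra_covariate)) {
    stopifnot(length(extra_covariate) == nrow(X))
    if (stats::var(extra_covariate) == 0) stop("covariate constant")
    X <- cbind(X, snp = extra_covariate)
  }
  gaussian <- !is.null(gaussian_response)
  if (!gaussian && design$K < 2L) stop("need at least 2 ordinal levels")
  eg <- grm_eigen_for(design, grm)
  scale_u <- prior_scale_from_h2(config$prior_h2, config$prior_df)
  if (!is.null(config$seed)) set.seed(config$seed)
  fit <- threshold_gibbs_cpp(
    y = as.integer(design$y), K = design$K, X = X, V = eg$V, d = eg$d,
    y_cont = if (gaussian) as.numeric(gaussian_response) else numeric(nrow(X)),
    gaussian = gaussian,
    chain = config$chain_length, burnin = config$burn_in, thin = config$thin,
    prior_df_u = config$prior_df, prior_scale_u = scale_u,
    prior_df_e = 4, prior_scale_e = 1, fix_sigma_e = !gaussian || fix_sigma_e,
    init_sigma_u = config$prior_h2 / (1 - config$prior_h2))
  b <- fit$b
  colnames(b) <- colnames(X)
  structure(list(sigma_u = as.numeric(fit$sigma_u),
                 sigma_e = as.numeric(fit$sigma_e),
                 b = b, thresholds = fit$thresholds,
                 u_mean = as.numeric(fit$u_mean),
                 animal_ids = design$animal_ids,
                 n_retained = fit$n_retained,
                 K = design$K, trait = design$trait,
                 config = config),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("posterior_samples:", x$n_retained, "retained draws, trait", x$trait,
      "- mean sigma_u^2 =", round(mean(x$sigma_u), 3), "\n")
  invisible(x)
}

#' Summarize heritability from posterior draws
#'
#' Heritability is computed per draw as `h2 = sigma_u^2 / (sigma_u^2 +
#' sigma_e^2)` and then averaged (never the ratio of averages); the 95%
#' credible set is the 2.5th and 97.5th percentiles of the per-draw values.
#' Genetic and total variances are summarized the same way.
#'
#' @param samples A `posterior_samples` object.
#' @return Object of class `heritability_estimate` with `mean`, `sd`,
#'   `credible_set_95`, `genetic_variance`, `total_variance`, `n_draws`.
#' @export
summarize_heritability <- function(samples) {
  su <- samples$sigma_u
  se <- samples$sigma_e
  if (length(su) < 2L) stop("need at least 2 retained draws")
  h2 <- su / (su + se)
  tot <- su + se
  structure(list(
    mean = mean(h2), sd = stats::sd(h2),
    credible_set_95 = stats::quantile(h2, c(0.025, 0.975), names = FALSE),
    genetic_variance = c(mean = mean(su), sd = stats::sd(su)),
    total_variance = c(mean = mean(tot), sd = stats::sd(tot)),
    n_draws = length(su), trait = samples$trait),
    class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("%s: h2 = %.2f +/- %.2f (%.2f-%.2f), Vg = %.2f +/- %.2f, n = %d draws\n",
              if (is.null(x$trait)) "trait" else x$trait,
              x$mean, x$sd, x$credible_set_95[1], x$credible_set_95[2],
              x$genetic_variance["mean"], x$genetic_variance["sd"],
              x$n_draws))
  invisible(x)
}

#' Write posterior draws / heritability summaries as TSV
#'
#' @param samples A `posterior_samples`.
#' @param path Output TSV, one row per retained draw.
#' @return Invisibly, `path`.
#' @export
write_posterior_samples <- function(samples, path) {
  df <- data.frame(draw = seq_along(samples$sigma_u),
                   sigma_u = samples$sigma_u, sigma_e = samples$sigma_e,
                   h2 = samples$sigma_u / (samples$sigma_u + samples$sigma_e),
                   samples$b, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
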