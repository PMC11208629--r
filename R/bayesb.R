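# BayesB whole-genome regression and 1-Mb window summaries with WPPA.

#' BayesB sampler settings
#'
#' `pi_null` is the prior probability that a marker has a null effect
#' (default 0.99, fixed, not estimated). The locus-variance prior is a
#' scaled inverse chi-square whose scale spreads `genetic_var_prior` (e.g.
#' the posterior genetic variance from a prior GBLUP fit) over the
#' expected `(1 - pi) * sum(2 p q)` non-null marker variance.
#'
#' @param pi_null Prior null-effect probability in `[0, 1]`.
#' @param chain_length,burn_in,thin,seed As in [mcmc_config()].
#' @param genetic_var_prior Prior total genetic variance.
#' @param prior_df Degrees of freedom of the locus-variance prior.
#' @return Object of class `bayesb_config`.
#' @export
bayesb_config <- function(pi_null = 0.99, chain_length = 100000L,
                          burn_in = 25000L, thin = 100L, seed = NULL,
                          genetic_var_prior = 1, prior_df = 4) {
  stopifnot(pi_null >= 0, pi_null <= 1, burn_in < chain_length, thin >= 1,
            genetic_var_prior > 0)
  structure(list(pi_null = pi_null, chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = seed, genetic_var_prior = genetic_var_prior,
                 prior_df = prior_df),
            class = "bayesb_config")
}

#' Fit a BayesB whole-genome regression
#'
#' Each marker effect is zero with prior probability `pi_null` and
#' otherwise normal with its own locus-specific variance; indicator and
#' effect are sampled jointly against the adjusted residuals, and locus
#' variances from scaled-inverse-chi-square conditionals. Ordinal traits
#' use the same liability augmentation, fixed residual variance 1, and
#' fixed `t_1 = 0` as the threshold animal model; fixed effects get flat
#' priors.
#'
#' @param design A [build_design()] result.
#' @param genotypes A [genotype_matrix()] with no missing entries (see
#'   [fill_missing()]) covering the design's animals.
#' @param config A [bayesb_config()].
#' @param gaussian_response Optional observed continuous response (then no
#'   liability augmentation; residual variance sampled).
#' @return Object of class `marker_effect_samples`: `alpha` (retained draws
#'   x markers, zeros for excluded markers), `b`, `map`, the centered
#'   dosage matrix `M` used, and bookkeeping.
#' @export
fit_bayesb <- function(design, genotypes, config = bayesb_config(),
                       gaussian_response = NULL) {
  stopifnot(inherits(design, "trait_design"), inherits(config, "bayesb_config"))
  if (anyNA(genotypes$dosages)) stop("genotypes contain missing entries; fill first")
  ids <- design$animal_ids
  missing <- setdiff(ids, rownames(genotypes$dosages))
  if (length(missing)) {
    stop("design animals absent from genotypes: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  D <- genotypes$dosages[ids, , drop = FALSE]
  p <- colMeans(D) / 2
  M <- sweep(D, 2L, 2 * p, "-")
  sum2pq <- sum(2 * p * (1 - p))
  if (config$pi_null >= 1) {
    warning("pi_null = 1: all marker effects are null by construction")
    frac_nonnull <- 1  # scale is irrelevant, keep it finite
  } else {
    frac_nonnull <- 1 - config$pi_null
  }
  df_a <- config$prior_df
  scale_a <- config$genetic_var_prior * (df_a - 2) / df_a /
    max(frac_nonnull * sum2pq, .Machine$double.eps)
  gaussian <- !is.null(gaussian_response)
  if (!is.null(config$seed)) set.seed(config$seed)
  fit <- bayesb_gibbs_cpp(
    y = as.integer(design$y), K = design$K, X = design$X, M = M,
    y_cont = if (gaussian) as.numeric(gaussian_response) else numeric(nrow(M)),
    gaussian = gaussian, pi_null = config$pi_null,
    chain = config$chain_length, burnin = config$burn_in, thin = config$thin,
    prior_df_a = df_a, prior_scale_a = scale_a,
    prior_df_e = 4, prior_scale_e = 1, fix_sigma_e = !gaussian)
  alpha <- fit$alpha
  colnames(alpha) <- genotypes$map$marker_id
  b <- fit$b
  colnames(b) <- colnames(design$X)
  structure(list(alpha = alpha, b = b, sigma_e = as.numeric(fit$sigma_e),
                 map = genotypes$map, M = M, animal_ids = ids,
                 n_retained = fit$n_retained, trait = design$trait,
                 config = config),
            class = "marker_effect_samples")
}

#' @export
print.marker_effect_samples <- function(x, ...) {
  cat("marker_effect_samples:", x$n_retained, "draws x", ncol(x$alpha),
      "markers; mean included per draw:",
      round(mean(rowSums(x$alpha != 0)), 1), "\n")
  invisible(x)
}

#' Posterior inclusion probabilities
#'
#' Fraction of retained draws in which each marker's effect is nonzero.
#'
#' @param samples A `marker_effect_samples`.
#' @return Named numeric vector.
#' @export
inclusion_probabilities <- function(samples) {
  colMeans(samples$alpha != 0)
}

#' Per-window genetic-variance proportions and WPPA
#'
#' Markers are binned into fixed half-open windows of `window_bp` from
#' position 0 (`floor(pos / window_bp)`) per chromosome. In each retained
#' draw a window's genetic value is the sum of its markers' dosage-times-
#' effect contributions across animals; the window's proportion is the
#' variance (across animals) of that value divided by the summed window
#' variances of the draw, so proportions sum to one whenever any genetic
#' variance is present. WPPA is the fraction of draws in which the
#' window's proportion exceeds `wppa_threshold`.
#'
#' @param samples A `marker_effect_samples` from [fit_bayesb()].
#' @param map Marker map (defaults to the one stored in `samples`).
#' @param window_bp Window size in base pairs (default 1 Mb).
#' @param wppa_threshold Proportion a window must exceed, per draw, to
#'   count toward WPPA (default 0.01, the 1% association rule).
#' @return Object of class `window_summary`: data frame with `chrom`,
#'   `window_index`, `start_bp`, `end_bp`, `n_markers`, `mean_prop`,
#'   `wppa`; the per-draw proportion matrix is kept in attribute
#'   `"proportions"`.
#' @export
window_variance <- function(samples, map = samples$map, window_bp = 1e6L,
                            wppa_threshold = 0.01) {
  stopifnot(inherits(samples, "marker_effect_samples"))
  idx <- match(colnames(samples$alpha), map$marker_id)
  if (anyNA(idx)) {
    stop("marker(s) without map entry: ",
         paste(utils::head(colnames(samples$alpha)[is.na(idx)], 5L),
               collapse = ", "))
  }
  map <- map[idx, , drop = FALSE]
  win <- paste(map$chrom, floor(map$pos / window_bp), sep = ":")
  uwin <- unique(win[order(suppressWarnings(as.numeric(map$chrom)),
                           map$chrom, map$pos)])
  n_draw <- nrow(samples$alpha)
  n_an <- nrow(samples$M)
  var_w <- matrix(0, n_draw, length(uwin), dimnames = list(NULL, uwin))
  for (w in uwin) {
    cols <- which(win == w)
    gv <- samples$M[, cols, drop = FALSE] %*%
      t(samples$alpha[, cols, drop = FALSE])          # animals x draws
    mu <- colMeans(gv)
    var_w[, w] <- (colSums(gv * gv) - n_an * mu^2) / (n_an - 1)
  }
  tot <- rowSums(var_w)
  prop <- var_w / ifelse(tot > 0, tot, NA_real_)
  prop[is.na(prop)] <- 0
  wi <- as.integer(sub(".*:", "", uwin))
  out <- data.frame(
    chrom = sub(":.*", "", uwin),
    window_index = wi,
    start_bp = wi * as.numeric(window_bp),
    end_bp = (wi + 1) * as.numeric(window_bp),
    n_markers = as.integer(table(win)[uwin]),
    mean_prop = colMeans(prop),
    wppa = colMeans(prop > wppa_threshold),
    stringsAsFactors = FALSE)
  attr(out, "proportions") <- prop
  class(out) <- c("window_summary", "data.frame")
  out
}

#' Windows called associated
#'
#' Windows whose mean proportion of genetic variance exceeds `threshold`
#' (the 1% rule by default), sorted descending; an empty result mirrors a
#' null genome scan.
#'
#' @param summary A [window_variance()] result.
#' @param threshold Mean-proportion cutoff.
#' @return Data frame of associated windows.
#' @export
call_associated <- function(summary, threshold = 0.01) {
  stopifnot(nrow(summary) > 0)
  hit <- summary[summary$mean_prop > threshold, , drop = FALSE]
  hit[order(-hit$mean_prop), , drop = FALSE]
}

#' Write a window summary as TSV
#' @param summary A `window_summary`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_window_summary <- function(summary, path) {
  data.table::fwrite(as.data.frame(summary), path, sep = "\t")
  invisible(path)
}
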