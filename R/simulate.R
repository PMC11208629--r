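# Synthetic genotype and ordinal-phenotype generator emulating the cohort
# structure the models assume: ~532 animals over 6 birth years, biallelic
# autosomal SNPs, a polygenic liability with residual variance 1, and the
# cohort's ordinal class frequencies.

#' Simulation settings
#'
#' Defaults describe the cohort the analysis targets: 532 animals over 6
#' birth years, class frequencies (E, T, SSS, SSD, NC) =
#' (149, 226, 55, 31, 71)/532 — i.e. 28/42/10/6/13 percent — allele
#' frequencies Uniform(0.05, 0.5), residual liability variance 1. Markers are in linkage equilibrium
#' unless `ld_rho > 0`, in which case consecutive blocks of
#' `ld_block_size` markers copy their block anchor's dosage with
#' probability `ld_rho` per animal (enough LD to exercise window logic).
#'
#' @param n_animals,n_markers,n_chromosomes,chromosome_length_bp Genome and
#'   cohort dimensions.
#' @param maf_range Bounds of the uniform allele-frequency distribution.
#' @param architecture `"polygenic"` (every marker a small effect) or
#'   `"sparse"` (`n_qtl` loci carrying `qtl_variance_fractions` of the
#'   genetic variance).
#' @param n_qtl,qtl_variance_fractions Sparse-architecture settings;
#'   fractions default to equal shares.
#' @param liability_h2 Target liability-scale heritability
#'   `Var(u) / (Var(u) + 1)`.
#' @param n_years Number of birth years.
#' @param year_effect_sd SD of true birth-year effects (default 0: fixed
#'   effects are null unless configured, isolating genetic recovery).
#' @param birthdate_sd SD of birth day-of-year within year (days).
#' @param birthdate_effect True liability slope per day of birth-date
#'   deviation.
#' @param class_frequencies Named or ordered vector over E, T, SSS, SSD,
#'   NC summing to 1.
#' @param n_sires Number of sires; animals are assigned to paternal
#'   half-sib families, the relatedness structure a managed herd actually
#'   has and the one that identifies liability-scale heritability (with
#'   unrelated animals and a latent scale, h2 is not estimable from
#'   single records). `0` simulates unrelated animals.
#' @param missing_rate Fraction of genotype calls masked as missing.
#' @param ld_block_size,ld_rho Optional block-LD mode (see above).
#' @param seed Integer seed.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_animals = 532L, n_markers = 2000L,
                              n_chromosomes = 29L,
                              chromosome_length_bp = 1e8,
                              maf_range = c(0.05, 0.5),
                              architecture = c("polygenic", "sparse"),
                              n_qtl = 5L, qtl_variance_fractions = NULL,
                              liability_h2 = 0.38,
                              n_years = 6L, year_effect_sd = 0,
                              n_sires = 30L,
                              birthdate_sd = 15, birthdate_effect = 0,
                              class_frequencies = c(E = 149, T = 226,
                                                    SSS = 55, SSD = 31,
                                                    NC = 71) / 532,
                              missing_rate = 0, ld_block_size = 1L,
                              ld_rho = 0, seed = NULL) {
  architecture <- match.arg(architecture)
  stopifnot(abs(sum(class_frequencies) - 1) < 1e-9,
            liability_h2 >= 0, liability_h2 < 1,
            missing_rate >= 0, missing_rate < 1)
  if (architecture == "sparse" && is.null(qtl_variance_fractions)) {
    qtl_variance_fractions <- rep(1 / n_qtl, n_qtl)
  }
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a genotype panel
#'
#' Per marker, an allele frequency is drawn from the configured uniform
#' distribution; positions are uniform over the autosomes. With
#' `n_sires > 0` (the default) each animal receives one gamete sampled
#' from a simulated sire's genotype and one from the base population, so
#' the cohort consists of paternal half-sib families whose genomic
#' relatedness carries the information the variance-component models rely
#' on; with `n_sires = 0` dosages are Binomial(2, p) independently per
#' animal. Marginal allele frequencies are `p` either way. When
#' `missing_rate > 0` the complete matrix is kept in attribute
#' `"complete_dosages"` so phenotype simulation can act on the unobserved
#' truth.
#'
#' @param config A [simulation_config()].
#' @return A [genotype_matrix()]; attribute `"freqs"` holds the generating
#'   frequencies.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_animals
  m <- config$n_markers
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  chrom <- sort(sample.int(config$n_chromosomes, m, replace = TRUE))
  pos <- integer(m)
  for (cc in unique(chrom)) {
    i <- chrom == cc
    pos[i] <- sort(sample.int(config$chromosome_length_bp, sum(i)))
  }
  if (config$n_sires > 0L) {
    sire_geno <- vapply(seq_len(m),
                        function(j) stats::rbinom(config$n_sires, 2L, p[j]),
                        numeric(config$n_sires))
    sire_of <- sample.int(config$n_sires, n, replace = TRUE)
    d <- matrix(0, n, m)
    for (j in seq_len(m)) {
      paternal <- stats::rbinom(n, 1L, sire_geno[sire_of, j] / 2)
      maternal <- stats::rbinom(n, 1L, p[j])
      d[, j] <- paternal + maternal
    }
  } else {
    sire_of <- NULL
    d <- vapply(seq_len(m), function(j) stats::rbinom(n, 2L, p[j]),
                numeric(n))
  }
  if (config$ld_rho > 0 && config$ld_block_size > 1L) {
    block <- (seq_len(m) - 1L) %/% config$ld_block_size
    for (b in unique(block)) {
      cols <- which(block == b)
      if (length(cols) < 2L) next
      anchor <- d[, cols[1L]]
      for (j in cols[-1L]) {
        copy <- stats::runif(n) < config$ld_rho
        d[copy, j] <- anchor[copy]
      }
    }
  }
  dimnames(d) <- list(sprintf("A%04d", seq_len(n)),
                      sprintf("SNP%05d", seq_len(m)))
  map <- data.frame(marker_id = colnames(d), chrom = as.character(chrom),
                    pos = pos, ref = "A", alt = "C",
                    stringsAsFactors = FALSE)
  complete <- d
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
    d[mask] <- NA_real_
  }
  g <- genotype_matrix(d, map)
  attr(g, "freqs") <- p
  attr(g, "sire") <- sire_of
  if (config$missing_rate > 0) attr(g, "complete_dosages") <- complete
  g
}

#' Thresholds matching target class frequencies
#'
#' `t_k = total_sd * qnorm(cumulative frequency through class k)` for a
#' normal liability with the given total SD; strictly increasing. Raw
#' cumulative sums are used, so frequency vectors reconstructed from
#' rounded percentages (summing slightly under 1) are accepted, the
#' deficit accruing to the last class.
#'
#' @param freqs Positive class frequencies summing to 1 (up to a small
#'   rounding deficit).
#' @param total_sd Total liability SD.
#' @return Numeric vector `t_1 .. t_{K-1}`.
#' @export
thresholds_from_frequencies <- function(freqs, total_sd = 1) {
  if (any(freqs <= 0)) stop("class frequencies must all be positive")
  s <- sum(freqs)
  if (s > 1 + 1e-9 || s < 0.95) stop("class frequencies must sum to ~1")
  cum <- cumsum(freqs)
  total_sd * stats::qnorm(cum[-length(cum)])
}

#' Simulate ordinal phenotypes from genotypes
#'
#' Runs the liability model generatively: a polygenic (or sparse) breeding
#' value from centered dosages, scaled so `Var(u)/(Var(u)+1)` equals the
#' target heritability exactly; optional birth-year and birth-date effects;
#' standard-normal residual; thresholds placed at
#' [thresholds_from_frequencies()] of the theoretical total SD to yield
#' the target class frequencies.
#'
#' @param genotypes A [simulate_genotypes()] result (or any complete
#'   genotype matrix).
#' @param config The [simulation_config()] used.
#' @return List with `phenotypes` (data frame: `animal_id`, `birth_year`,
#'   `birth_date` day-of-year, `class`) and `truth` (breeding values,
#'   marker effects, year effects, liabilities, thresholds, realized h2).
#' @export
simulate_ordinal_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  d <- attr(genotypes, "complete_dosages")
  if (is.null(d)) d <- genotypes$dosages
  if (anyNA(d)) stop("phenotype simulation needs complete genotypes")
  n <- nrow(d)
  m <- ncol(d)
  M <- sweep(d, 2L, colMeans(d), "-")
  h2 <- config$liability_h2
  var_u <- h2 / (1 - h2)
  beta <- numeric(m)
  if (h2 > 0) {
    if (config$architecture == "polygenic") {
      beta <- stats::rnorm(m)
    } else {
      qtl <- sample.int(m, config$n_qtl)
      fr <- config$qtl_variance_fractions
      sdM <- apply(M[, qtl, drop = FALSE], 2L, stats::sd)
      beta[qtl] <- sample(c(-1, 1), config$n_qtl, replace = TRUE) *
        sqrt(fr * var_u) / pmax(sdM, 1e-12)
    }
    u_raw <- as.numeric(M %*% beta)
    sc <- sqrt(var_u) / stats::sd(u_raw)
    u <- (u_raw - mean(u_raw)) * sc
    beta <- beta * sc
  } else {
    u <- numeric(n)
  }
  year <- sample.int(config$n_years, n, replace = TRUE) + 2016L
  year_eff <- stats::rnorm(config$n_years, 0, config$year_effect_sd)
  names(year_eff) <- as.character(sort(unique(2016L + seq_len(config$n_years))))
  doy <- round(stats::rnorm(n, 100, config$birthdate_sd))
  dev <- doy - stats::ave(doy, year)
  total_sd <- sqrt(var_u + 1 + config$year_effect_sd^2 +
                   (config$birthdate_effect * config$birthdate_sd)^2)
  thr <- thresholds_from_frequencies(config$class_frequencies, total_sd)
  e <- stats::rnorm(n)
  liab <- u + year_eff[as.character(year)] + config$birthdate_effect * dev + e
  labels <- names(config$class_frequencies)
  if (is.null(labels)) {
    labels <- PUBERTAL_CLASSES[seq_along(config$class_frequencies)]
  }
  cls <- labels[findInterval(liab, thr) + 1L]
  phen <- data.frame(animal_id = rownames(d), birth_year = year,
                     birth_date = doy, class = cls,
                     stringsAsFactors = FALSE)
  truth <- list(u = stats::setNames(u, rownames(d)), marker_effects = beta,
                year_effects = year_eff,
                birthdate_effect = config$birthdate_effect,
                liability = liab, thresholds = thr,
                realized_h2 = if (h2 > 0) stats::var(u) / (stats::var(u) + 1) else 0,
                target_h2 = h2)
  list(phenotypes = phen, truth = truth)
}

#' Simulate a full cohort (genotypes + phenotypes)
#'
#' Convenience wrapper chaining [simulate_genotypes()] and
#' [simulate_ordinal_phenotypes()].
#'
#' @param config A [simulation_config()].
#' @return List with `genotypes`, `phenotypes`, `truth`.
#' @export
simulate_cohort <- function(config) {
  g <- simulate_genotypes(config)
  ph <- simulate_ordinal_phenotypes(g, config)
  list(genotypes = g, phenotypes = ph$phenotypes, truth = ph$truth)
}
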