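# Candidate-gene SNP selection and single-SNP fixed-covariate scans with
# MCMC pseudo-p-values.

#' Read candidate-gene intervals
#'
#' TSV with columns `gene`, `chrom`, `start_bp`, `end_bp` (1-based,
#' inclusive).
#'
#' @param path TSV path.
#' @return Data frame of gene intervals.
#' @export
read_gene_intervals <- function(path) {
  g <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                         colClasses = list(character = c("gene", "chrom")))
  stopifnot(all(c("gene", "chrom", "start_bp", "end_bp") %in% names(g)))
  if (any(g$start_bp > g$end_bp)) stop("gene interval with start > end")
  g
}

#' Select candidate SNPs per gene
#'
#' For each gene, all markers with `start_bp <= pos <= end_bp` on the same
#' chromosome; if the gene contains no marker, markers within `flank_bp`
#' of either end are taken instead. Genes with no marker in either zone
#' are reported in the `"empty_genes"` attribute.
#'
#' @param map A marker map (e.g. `genotypes$map`).
#' @param genes Gene-interval data frame (see [read_gene_intervals()]).
#' @param flank_bp Flanking distance used only when a gene has no internal
#'   marker (default 10,000 bp).
#' @return Data frame of `(gene, marker_id, chrom, pos, zone)` pairs, zone
#'   `"gene"` or `"flank"`; attribute `"empty_genes"` lists genes with no
#'   selected marker.
#' @export
candidate_snp_set <- function(map, genes, flank_bp = 10000L) {
  rows <- list()
  empty <- character(0)
  for (i in seq_len(nrow(genes))) {
    on_chr <- map$chrom == genes$chrom[i]
    inside <- on_chr & map$pos >= genes$start_bp[i] & map$pos <= genes$end_bp[i]
    if (any(inside)) {
      sel <- which(inside); zone <- "gene"
    } else {
      near <- on_chr & map$pos >= genes$start_bp[i] - flank_bp &
        map$pos <= genes$end_bp[i] + flank_bp
      sel <- which(near); zone <- "flank"
    }
    if (length(sel)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = genes$gene[i], marker_id = map$marker_id[sel],
        chrom = map$chrom[sel], pos = map$pos[sel], zone = zone,
        stringsAsFactors = FALSE)
    } else {
      empty <- c(empty, genes$gene[i])
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), marker_id = character(0),
               chrom = character(0), pos = integer(0), zone = character(0))
  attr(out, "empty_genes") <- empty
  out
}

#' Posterior pseudo-p-value
#'
#' `2 * min(s, 1 - s)` where `s` is the fraction of retained draws with a
#' negative sampled effect — a two-sided posterior tail measure. When no
#' draw crosses zero the raw value is 0; the display value floors at
#' `1e-4` so `-log10` plots render it as 4.
#'
#' @param s Fraction of draws with effect below zero.
#' @param n_draws Number of retained draws behind `s` (bookkeeping).
#' @return List with `pseudo_p` (raw) and `display` (floored at `1e-4`).
#' @export
pseudo_p <- function(s, n_draws = NA_integer_) {
  stopifnot(s >= 0, s <= 1)
  p <- 2 * min(s, 1 - s)
  list(pseudo_p = p, display = max(p, 1e-4), n_draws = n_draws)
}

#' Test one SNP as a fixed covariate in the threshold model
#'
#' Refits the threshold animal model with the SNP's 0/1/2 dosage appended
#' to the fixed effects; the polygenic term (and the SNP's own
#' contribution to G) stays in the model. Effect summaries and the
#' pseudo-p-value are computed over the retained draws.
#'
#' @param design A [build_design()] result.
#' @param grm A [build_grm()] result.
#' @param snp_dosages Numeric vector aligned to the design's records.
#' @param config An [mcmc_config()].
#' @param marker_id Label carried into the result.
#' @return One-row data frame of class `snp_association`: `marker_id`,
#'   `trait`, `maf`, `effect_mean`, `effect_sd`, `s`, `pseudo_p`,
#'   `pseudo_p_display`.
#' @export
fit_snp_covariate <- function(design, grm, snp_dosages,
                              config = mcmc_config(), marker_id = "snp") {
  stopifnot(length(snp_dosages) == length(design$y))
  if (stats::var(snp_dosages) == 0) stop("covariate constant")
  fit <- fit_threshold_model(design, grm, config,
                             extra_covariate = snp_dosages)
  eff <- fit$b[, "snp"]
  s <- mean(eff < 0)
  pp <- pseudo_p(s, length(eff))
  p_alt <- mean(snp_dosages) / 2
  out <- data.frame(marker_id = marker_id, trait = design$trait,
                    maf = min(p_alt, 1 - p_alt),
                    effect_mean = mean(eff), effect_sd = stats::sd(eff),
                    s = s, pseudo_p = pp$pseudo_p,
                    pseudo_p_display = pp$display,
                    stringsAsFactors = FALSE)
  class(out) <- c("snp_association", "data.frame")
  out
}

#' Scan candidate-gene SNPs one at a time
#'
#' Runs [fit_snp_covariate()] for every `(gene, marker)` pair selected by
#' [candidate_snp_set()]. No multiple-testing correction is applied; the
#' number of tests is recorded so users can adjust.
#'
#' @param design A [build_design()] result.
#' @param grm A [build_grm()] result.
#' @param genotypes A filled [genotype_matrix()] holding the candidate
#'   markers.
#' @param genes Gene-interval data frame.
#' @param config An [mcmc_config()]; its seed is advanced per SNP so fits
#'   are independent yet reproducible.
#' @param flank_bp Flank rule for [candidate_snp_set()].
#' @return Data frame, one row per tested SNP (gene, marker, MAF, effect
#'   mean and sd, s, pseudo-p); attribute `"n_tests"` holds the test
#'   count, `"empty_genes"` the genes with no testable SNP.
#' @export
candidate_scan <- function(design, grm, genotypes, genes,
                           config = mcmc_config(), flank_bp = 10000L) {
  pairs <- candidate_snp_set(genotypes$map, genes, flank_bp)
  rows <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(pairs))) {
    dos <- genotypes$dosages[design$animal_ids, pairs$marker_id[i]]
    if (stats::var(dos) == 0) {
      skipped <- c(skipped, pairs$marker_id[i])
      next
    }
    cfg <- config
    if (!is.null(cfg$seed)) cfg$seed <- cfg$seed + i
    r <- fit_snp_covariate(design, grm, dos, cfg,
                           marker_id = pairs$marker_id[i])
    r$gene <- pairs$gene[i]
    r$chrom <- pairs$chrom[i]
    r$pos <- pairs$pos[i]
    rows[[length(rows) + 1L]] <- r
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame()
  attr(out, "n_tests") <- length(rows)
  attr(out, "empty_genes") <- attr(pairs, "empty_genes")
  attr(out, "monomorphic_skipped") <- skipped
  out
}
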