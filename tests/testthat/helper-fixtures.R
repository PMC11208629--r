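# Shared fixture builders; everything is generated in code.

make_map <- function(n, chrom = "1", start = 1000L, step = 1000L) {
  data.frame(marker_id = sprintf("M%03d", seq_len(n)),
             chrom = rep_len(chrom, n),
             pos = start + step * (seq_len(n) - 1L),
             ref = "A", alt = "C", stringsAsFactors = FALSE)
}

make_geno <- function(dosages, map = NULL, animal_ids = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(animal_ids)) {
    animal_ids <- rownames(dosages)
    if (is.null(animal_ids)) animal_ids <- sprintf("A%02d", seq_len(nrow(dosages)))
  }
  rownames(dosages) <- animal_ids
  if (is.null(map)) map <- make_map(ncol(dosages))
  genotype_matrix(dosages, map)
}

write_matrix_tsv <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "geno.tsv")
  writeLines(lines, path)
  path
}

# small phenotype table over two years
make_phenotypes <- function(classes, years = NULL, doy = NULL) {
  n <- length(classes)
  if (is.null(years)) years <- rep(c(2017L, 2018L), length.out = n)
  if (is.null(doy)) doy <- seq(60, 90, length.out = n)
  data.frame(animal_id = sprintf("A%02d", seq_len(n)),
             birth_year = years, birth_date = doy, class = classes,
             stringsAsFactors = FALSE)
}

# brute-force GRM: element-wise double loop over animals and markers
grm_oracle <- function(M, p) {
  denom <- 2 * sum(p * (1 - p))
  n <- nrow(M)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      s <- 0
      for (j in seq_len(ncol(M))) s <- s + M[i, j] * M[k, j]
      G[i, k] <- s / denom
    }
  }
  G
}

# enumerate all 2x2 tables with the observed margins and sum probabilities
# of tables no more probable than the observed one
fisher_2x2_oracle <- function(tab) {
  rm_ <- rowSums(tab); cm_ <- colSums(tab); N <- sum(tab)
  p_of <- function(a) {
    b <- rm_[1] - a; c <- cm_[1] - a; d <- rm_[2] - c
    if (b < 0 || c < 0 || d < 0) return(NA_real_)
    exp(sum(lfactorial(rm_)) + sum(lfactorial(cm_)) - lfactorial(N) -
          sum(lfactorial(c(a, b, c, d))))
  }
  probs <- vapply(0:min(rm_[1], cm_[1]), p_of, 0)
  probs <- probs[!is.na(probs)]
  obs <- p_of(tab[1, 1])
  sum(probs[probs <= obs * (1 + 1e-7)])
}
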