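# VanRaden genomic relationship matrix and PCA coordinates.

#' Center genotypes at twice the allele frequency
#'
#' Produces the centered incidence matrix M with `M[i, j] = dosage[i, j] -
#' 2 p_j`. When `p` is computed from the same data every column of M sums
#' to zero.
#'
#' @param g A [genotype_matrix()] with no missing entries (see
#'   [fill_missing()]).
#' @param p Alt-allele frequency vector, one per marker, in `[0, 1]`.
#' @return Object of class `centered_genotypes`: list with `values`
#'   (animals x markers) and `frequencies`.
#' @export
center_genotypes <- function(g, p) {
  d <- if (inherits(g, "genotype_matrix")) g$dosages else as.matrix(g)
  if (anyNA(d)) stop("genotypes contain missing entries; fill first")
  if (length(p) != ncol(d)) {
    stop("frequency vector length ", length(p), " != marker count ", ncol(d))
  }
  if (any(p < 0 | p > 1)) stop("frequencies must lie in [0, 1]")
  m <- sweep(d, 2L, 2 * p, "-")
  structure(list(values = m, frequencies = as.numeric(p)),
            class = "centered_genotypes")
}

#' Build the VanRaden genomic relationship matrix
#'
#' `G = M M' / (2 * sum(p_j (1 - p_j)))`. G is symmetric, positive
#' semidefinite, and has mean diagonal near 1 when the centering
#' frequencies match the data.
#'
#' @param m A `centered_genotypes` object from [center_genotypes()].
#' @return Object of class `grm`: list with `values` (animals x animals),
#'   `animal_ids`, and `denominator`.
#' @export
build_grm <- function(m) {
  stopifnot(inherits(m, "centered_genotypes"))
  p <- m$frequencies
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: zero GRM denominator")
  g <- tcrossprod(m$values) / denom
  g <- (g + t(g)) / 2
  structure(list(values = g, animal_ids = rownames(m$values),
                 denominator = denom),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", nrow(x$values), "animals, mean diagonal",
      round(mean(diag(x$values)), 3), "\n")
  invisible(x)
}

#' Principal-component coordinates of a GRM
#'
#' Eigendecomposes G and returns coordinates `v_k * sqrt(lambda_k)` for the
#' top `k` components (so `coords %*% t(coords)` approximates G), together
#' with the fraction of relationship variance each component carries.
#' Negative eigenvalues (numerical noise) are clamped to zero. Each
#' eigenvector's sign is fixed so its largest-magnitude loading is
#' positive.
#'
#' @param grm A `grm` from [build_grm()].
#' @param k Number of components.
#' @return List with `coordinates` (animals x k, columns `PC1..PCk`) and
#'   `variance_fraction` (length k).
#' @export
grm_pca <- function(grm, k = 2L) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$values)
  if (k <= 0L) stop("k must be positive")
  if (k > n) stop("k exceeds animal count")
  e <- eigen(grm$values, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  vec <- e$vectors
  for (j in seq_len(k)) {
    i_max <- which.max(abs(vec[, j]))
    if (vec[i_max, j] < 0) vec[, j] <- -vec[, j]
  }
  coords <- vec[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(lam[seq_len(k)]), k, k)
  dimnames(coords) <- list(grm$animal_ids, paste0("PC", seq_len(k)))
  list(coordinates = coords,
       variance_fraction = lam[seq_len(k)] / sum(lam))
}

#' Write / read a GRM as TSV with animal IDs
#'
#' @param grm A `grm`.
#' @param path TSV path.
#' @return `write_grm` invisibly returns `path`; `read_grm` returns a `grm`
#'   (with `denominator = NA`, which is not stored in the file).
#' @export
write_grm <- function(grm, path) {
  df <- data.frame(animal_id = grm$animal_ids, grm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("animal_id", grm$animal_ids)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1))
  ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(vals) <- list(ids, ids)
  structure(list(values = vals, animal_ids = ids, denominator = NA_real_),
            class = "grm")
}
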