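# Genotype container, file readers/writers, panel merging, QC, allele
# frequencies and mean-dosage fill.

#' Construct a genotype matrix
#'
#' Bundles an animals-by-markers dosage matrix with its marker map. Dosages
#' count copies of the alt allele (0/1/2); `NA` marks a missing call. Rows
#' are animals, columns are markers; dimnames carry the IDs.
#'
#' @param dosages Numeric matrix, animals x markers, entries in `{0,1,2,NA}`
#'   (real values are permitted after [fill_missing()]).
#' @param map Data frame with columns `marker_id`, `chrom`, `pos`, `ref`,
#'   `alt`, one row per column of `dosages`, in column order.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, map) {
  stopifnot(is.matrix(dosages))
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("marker_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(map))) {
    stop("map must have columns: ", paste(need, collapse = ", "))
  }
  map$marker_id <- as.character(map$marker_id)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  if (anyDuplicated(map$marker_id)) {
    stop("duplicate marker ID: ",
         paste(unique(map$marker_id[duplicated(map$marker_id)]), collapse = ", "))
  }
  if (any(map$pos < 1L, na.rm = TRUE)) stop("marker positions must be >= 1")
  if (ncol(dosages) != nrow(map)) {
    stop("dosage columns (", ncol(dosages), ") do not match map rows (",
         nrow(map), ")")
  }
  if (is.null(rownames(dosages))) stop("dosages must have animal IDs as rownames")
  if (anyDuplicated(rownames(dosages))) stop("duplicate animal IDs")
  colnames(dosages) <- map$marker_id
  structure(list(dosages = dosages, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "animals x", ncol(x$dosages),
      "markers;", sum(is.na(x$dosages)), "missing calls\n")
  invisible(x)
}

#' Number of animals / markers
#' @param g A `genotype_matrix`.
#' @return Integer count.
#' @export
n_animals <- function(g) nrow(g$dosages)

#' @rdname n_animals
#' @export
n_markers <- function(g) ncol(g$dosages)

#' Read genotypes from disk
#'
#' Two dialects are supported. `matrix-tsv` is a tab-separated matrix with a
#' header row of marker IDs, the first column holding animal IDs, and `NA`
#' for missing calls; a companion map TSV (`marker_id`, `chrom`, `pos`,
#' `ref`, `alt`) supplies coordinates and alleles. `plink-pedmap` reads
#' PLINK text `.ped`/`.map` pairs; the `0 0` allele pair codes a missing
#' call and, because `.map` carries no alleles, the alt allele at each locus
#' is the lexicographically larger of the two observed alleles.
#'
#' @param path Matrix TSV path, or `.ped` path (or prefix) for PLINK input.
#' @param format `"matrix-tsv"` or `"plink-pedmap"`.
#' @param map_path Map TSV path (`matrix-tsv`) or `.map` path (optional for
#'   PLINK when derivable from `path`).
#' @return A [genotype_matrix()].
#' @export
read_genotype_table <- function(path, format = c("matrix-tsv", "plink-pedmap"),
                                map_path = NULL) {
  format <- match.arg(format)
  if (format == "matrix-tsv") {
    if (is.null(map_path)) stop("matrix-tsv input needs map_path")
    read_matrix_tsv(path, map_path)
  } else {
    read_plink_pedmap(path, map_path)
  }
}

read_marker_map <- function(map_path) {
  map <- data.table::fread(map_path, sep = "\t", header = TRUE,
                           colClasses = list(character = 1), data.table = FALSE)
  names(map)[1:5] <- c("marker_id", "chrom", "pos", "ref", "alt")
  map
}

read_matrix_tsv <- function(path, map_path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty genotype file: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  marker_ids <- header[-1L]
  if (length(marker_ids) == 0L) stop("no markers in ", path)
  if (anyDuplicated(marker_ids)) {
    stop("duplicate marker ID in header: ",
         paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "))
  }
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nfield <- lengths(body)
  bad <- which(nfield != length(header))
  if (length(bad)) {
    stop("unparseable line ", bad[1L] + 1L, " in ", path, ": expected ",
         length(header), " fields, found ", nfield[bad[1L]])
  }
  animal_ids <- vapply(body, `[[`, "", 1L)
  cells <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  ok <- cells %in% c("0", "1", "2", "NA")
  if (!all(ok)) {
    first <- which(!ok)[1L]
    stop("unparseable line ", (first - 1L) %/% length(marker_ids) + 2L,
         " in ", path, ": bad genotype token '", cells[first], "'")
  }
  dos <- matrix(suppressWarnings(as.numeric(cells)),
                nrow = length(body), byrow = TRUE,
                dimnames = list(animal_ids, marker_ids))
  map <- read_marker_map(map_path)
  idx <- match(marker_ids, map$marker_id)
  if (anyNA(idx)) {
    stop("markers absent from map: ",
         paste(utils::head(marker_ids[is.na(idx)], 5L), collapse = ", "))
  }
  genotype_matrix(dos, map[idx, , drop = FALSE])
}

read_plink_pedmap <- function(path, map_path = NULL) {
  ped_path <- if (grepl("\\.ped$", path)) path else paste0(path, ".ped")
  if (is.null(map_path)) map_path <- sub("\\.ped$", ".map", ped_path)
  if (!file.exists(ped_path)) stop("file not found: ", ped_path)
  if (!file.exists(map_path)) stop("file not found: ", map_path)
  pmap <- data.table::fread(map_path, header = FALSE, data.table = FALSE,
                            colClasses = list(character = c(1, 2)))
  if (ncol(pmap) < 4L) stop("unparseable .map file: expected 4 columns")
  names(pmap)[1:4] <- c("chrom", "marker_id", "cm", "pos")
  m <- nrow(pmap)
  if (m == 0L) stop("no markers in ", map_path)
  if (anyDuplicated(pmap$marker_id)) {
    stop("duplicate marker ID: ",
         paste(unique(pmap$marker_id[duplicated(pmap$marker_id)]), collapse = ", "))
  }
  lines <- readLines(ped_path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nfield <- lengths(fields)
  bad <- which(nfield != 6L + 2L * m)
  if (length(bad)) {
    stop("unparseable line ", bad[1L], " in ", ped_path, ": expected ",
         6L + 2L * m, " fields, found ", nfield[bad[1L]])
  }
  animal_ids <- vapply(fields, `[[`, "", 2L)
  al <- matrix(unlist(lapply(fields, `[`, -(1:6)), use.names = FALSE),
               nrow = length(fields), byrow = TRUE)
  a1 <- al[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * m, by = 2L), drop = FALSE]
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA
  dos <- matrix(NA_real_, nrow(a1), m, dimnames = list(animal_ids, pmap$marker_id))
  ref <- alt <- character(m)
  for (j in seq_len(m)) {
    obs <- sort(unique(stats::na.omit(c(a1[, j], a2[, j]))))
    if (length(obs) > 2L) {
      stop("marker ", pmap$marker_id[j], " has >2 alleles: ",
           paste(obs, collapse = "/"))
    }
    ref[j] <- if (length(obs)) obs[1L] else "N"
    alt[j] <- if (length(obs) == 2L) obs[2L] else "N"
    dos[, j] <- (a1[, j] == alt[j]) + (a2[, j] == alt[j])
  }
  map <- data.frame(marker_id = pmap$marker_id, chrom = as.character(pmap$chrom),
                    pos = as.integer(pmap$pos), ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
  genotype_matrix(dos, map)
}

#' Write a genotype matrix as matrix-tsv plus map TSV
#'
#' Round-trips exactly with [read_genotype_table()]: dosages and the missing
#' pattern are preserved. Real-valued (filled) dosages cannot be written in
#' this dialect.
#'
#' @param g A [genotype_matrix()].
#' @param path Output matrix TSV path.
#' @param map_path Output map TSV path.
#' @return Invisibly, `path`.
#' @export
write_genotype_table <- function(g, path, map_path) {
  d <- g$dosages
  if (any(!is.na(d) & d != round(d))) {
    stop("matrix-tsv stores integer dosages; found real values")
  }
  cells <- matrix(as.character(as.integer(d)), nrow(d), ncol(d))
  cells[is.na(d)] <- "NA"
  lines <- c(paste(c("animal_id", g$map$marker_id), collapse = "\t"),
             vapply(seq_len(nrow(d)), function(i) {
               paste(c(rownames(d)[i], cells[i, ]), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  data.table::fwrite(g$map, map_path, sep = "\t")
  invisible(path)
}

#' Merge two SNP panels
#'
#' Animals are unioned; markers are matched by (chromosome, position), as
#' panels name the same site differently. For an animal genotyped on both
#' panels at a shared site, concordant calls are kept and discordant calls
#' are set to missing. Sites private to one panel are missing for the other
#' panel's animals. Shared sites whose ref/alt coding is swapped between
#' panels raise an error unless `allow_flip = TRUE`, in which case panel
#' `b`'s dosages at those sites are flipped (`2 - dosage`) before merging.
#'
#' @param a,b `genotype_matrix` objects on the same assembly.
#' @param allow_flip Flip swapped ref/alt sites in `b` instead of erroring.
#' @return A merged [genotype_matrix()].
#' @export
merge_panels <- function(a, b, allow_flip = FALSE) {
  key_a <- paste(a$map$chrom, a$map$pos, sep = ":")
  key_b <- paste(b$map$chrom, b$map$pos, sep = ":")
  shared <- intersect(key_a, key_b)
  ia <- match(shared, key_a)
  ib <- match(shared, key_b)
  if (length(shared)) {
    same <- a$map$ref[ia] == b$map$ref[ib] & a$map$alt[ia] == b$map$alt[ib]
    swapped <- a$map$ref[ia] == b$map$alt[ib] & a$map$alt[ia] == b$map$ref[ib]
    if (any(!same & !swapped)) {
      stop("allele conflict at shared position(s): ",
           paste(utils::head(shared[!same & !swapped], 5L), collapse = ", "))
    }
    if (any(swapped)) {
      if (!allow_flip) {
        stop("ref/alt swapped at shared position(s): ",
             paste(utils::head(shared[swapped], 5L), collapse = ", "),
             " (set allow_flip = TRUE to flip panel b)")
      }
      b$dosages[, ib[swapped]] <- 2 - b$dosages[, ib[swapped]]
    }
  }
  keys <- c(key_a, setdiff(key_b, key_a))
  map <- rbind(a$map, b$map[match(setdiff(key_b, key_a), key_b), , drop = FALSE])
  # keep panel-a marker names for shared sites; dedupe any ID collisions
  if (anyDuplicated(map$marker_id)) {
    dup <- duplicated(map$marker_id)
    map$marker_id[dup] <- paste0(map$marker_id[dup], "_b")
  }
  animals <- union(rownames(a$dosages), rownames(b$dosages))
  out <- matrix(NA_real_, length(animals), length(keys),
                dimnames = list(animals, map$marker_id))
  pos_a <- match(key_a, keys)
  out[rownames(a$dosages), pos_a] <- a$dosages
  pos_b <- match(key_b, keys)
  db <- b$dosages[, , drop = FALSE]
  cur <- out[rownames(b$dosages), pos_b, drop = FALSE]
  conflict <- !is.na(cur) & !is.na(db) & cur != db
  take_b <- is.na(cur) & !is.na(db)
  cur[take_b] <- db[take_b]
  cur[conflict] <- NA_real_
  out[rownames(b$dosages), pos_b] <- cur
  ord <- order(suppressWarnings(as.numeric(map$chrom)), map$chrom, map$pos)
  genotype_matrix(out[, ord, drop = FALSE], map[ord, , drop = FALSE])
}

qc_report <- function(axis, removed, thresholds, n_input, n_retained) {
  structure(list(axis = axis, removed_by_rule = removed,
                 thresholds = thresholds, n_input = n_input,
                 n_retained = n_retained),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC on", x$axis, "-", x$n_input, "in,", x$n_retained, "retained\n")
  for (r in names(x$removed_by_rule)) {
    cat("  removed by", r, ":", x$removed_by_rule[[r]], "\n")
  }
  invisible(x)
}

is_autosome <- function(chrom) {
  grepl("^[0-9]+$", chrom) & suppressWarnings(as.integer(chrom)) >= 1L
}

#' Marker-level quality control
#'
#' Removes markers failing, in order: (1) not mapped to an autosome,
#' (2) call rate below `min_call`, (3) minor allele frequency below
#' `min_maf`. Each rule is applied to the markers surviving the previous
#' one, so the per-rule removal counts in the report are disjoint.
#'
#' @param g A [genotype_matrix()].
#' @param min_call Minimum fraction of non-missing calls per marker.
#' @param min_maf Minimum minor allele frequency.
#' @param autosomes_only Drop non-autosomal markers first.
#' @return List with `genotypes` (filtered) and `report` (a `qc_report`).
#' @export
marker_qc <- function(g, min_call = 0.9, min_maf = 0.01, autosomes_only = TRUE) {
  stopifnot(min_call >= 0, min_call <= 1, min_maf >= 0, min_maf <= 1)
  d <- g$dosages
  keep <- rep(TRUE, ncol(d))
  removed <- c(non_autosome = 0L, call_rate = 0L, maf = 0L)
  if (autosomes_only) {
    auto <- is_autosome(g$map$chrom)
    removed["non_autosome"] <- sum(!auto)
    keep <- auto
  }
  cr <- colMeans(!is.na(d[, keep, drop = FALSE]))
  fail_cr <- cr < min_call
  removed["call_rate"] <- sum(fail_cr)
  keep[keep] <- !fail_cr
  p <- colMeans(d[, keep, drop = FALSE], na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  fail_maf <- is.na(maf) | maf < min_maf
  removed["maf"] <- sum(fail_maf)
  keep[keep] <- !fail_maf
  if (!any(keep)) stop("no markers survive QC")
  out <- genotype_matrix(d[, keep, drop = FALSE], g$map[keep, , drop = FALSE])
  rep <- qc_report("markers", as.list(removed),
                   list(min_call = min_call, min_maf = min_maf,
                        autosomes_only = autosomes_only),
                   ncol(d), sum(keep))
  list(genotypes = out, report = rep)
}

#' Animal-level quality control
#'
#' Removes animals with call rate below `min_call` or heterozygosity above
#' `max_het`. Heterozygosity is the proportion of an animal's *non-missing*
#' calls equal to 1, so low call rate does not inflate it.
#'
#' @param g A [genotype_matrix()].
#' @param min_call Minimum fraction of non-missing calls per animal.
#' @param max_het Maximum heterozygosity.
#' @return List with `genotypes` and `report`.
#' @export
sample_qc <- function(g, min_call = 0.9, max_het = 0.5) {
  stopifnot(min_call >= 0, min_call <= 1, max_het >= 0, max_het <= 1)
  d <- g$dosages
  cr <- rowMeans(!is.na(d))
  het <- rowMeans(d == 1, na.rm = TRUE)
  het[is.nan(het)] <- 0
  fail_cr <- cr < min_call
  fail_het <- !fail_cr & het > max_het
  keep <- !fail_cr & !fail_het
  if (!any(keep)) stop("no animals survive QC")
  out <- genotype_matrix(d[keep, , drop = FALSE], g$map)
  rep <- qc_report("animals",
                   list(call_rate = sum(fail_cr), heterozygosity = sum(fail_het)),
                   list(min_call = min_call, max_het = max_het),
                   nrow(d), sum(keep))
  list(genotypes = out, report = rep)
}

#' Alt-allele frequencies
#'
#' `p_j` is half the mean non-missing dosage at marker `j` — the frequency
#' of the allele the dosage counts, computed over observed calls only.
#'
#' @param g A [genotype_matrix()].
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
allele_frequencies <- function(g) {
  n_obs <- colSums(!is.na(g$dosages))
  if (any(n_obs == 0L)) {
    stop("marker(s) with no non-missing calls: ",
         paste(utils::head(g$map$marker_id[n_obs == 0L], 5L), collapse = ", "))
  }
  colMeans(g$dosages, na.rm = TRUE) / 2
}

#' Fill missing genotypes with the marker mean
#'
#' Replaces each missing call with the marker's mean observed dosage, so the
#' per-marker mean is preserved exactly. This is a deliberately simple
#' stand-in for model-based imputation; filled dosages are real-valued.
#'
#' @param g A [genotype_matrix()].
#' @return A [genotype_matrix()] with no missing entries.
#' @export
fill_missing <- function(g) {
  p2 <- allele_frequencies(g) * 2
  d <- g$dosages
  miss <- which(is.na(d), arr.ind = TRUE)
  if (nrow(miss)) d[miss] <- p2[miss[, 2L]]
  genotype_matrix(d, g$map)
}
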