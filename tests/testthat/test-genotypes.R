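# Genotype IO, panel merging, QC, allele frequencies, mean fill.

test_that("matrix-tsv reader parses dosages and missing flags", {
  dir <- withr::local_tempdir()
  writeLines(c("animal_id\tM001\tM002",
               "A01\t0\t2",
               "A02\t1\tNA",
               "A03\t2\t0"),
             file.path(dir, "g.tsv"))
  data.table::fwrite(make_map(2), file.path(dir, "map.tsv"), sep = "\t")
  g <- read_genotype_table(file.path(dir, "g.tsv"), "matrix-tsv",
                           file.path(dir, "map.tsv"))
  expect_equal(dim(g$dosages), c(3L, 2L))
  expect_equal(unname(g$dosages[, 1]), c(0, 1, 2))
  expect_true(is.na(g$dosages["A02", "M002"]))
  expect_equal(sum(is.na(g$dosages)), 1L)
})

test_that("reader rejects marker-free files, bad tokens, duplicate IDs", {
  dir <- withr::local_tempdir()
  writeLines(c("animal_id", "A01"), file.path(dir, "empty.tsv"))
  data.table::fwrite(make_map(2), file.path(dir, "map.tsv"), sep = "\t")
  expect_error(read_genotype_table(file.path(dir, "empty.tsv"), "matrix-tsv",
                                   file.path(dir, "map.tsv")),
               "no markers")
  writeLines(c("animal_id\tM001\tM002", "A01\t0\t2", "A02\t1\tX"),
             file.path(dir, "bad.tsv"))
  expect_error(read_genotype_table(file.path(dir, "bad.tsv"), "matrix-tsv",
                                   file.path(dir, "map.tsv")),
               "line 3")
  writeLines(c("animal_id\tM001\tM001", "A01\t0\t2"),
             file.path(dir, "dup.tsv"))
  expect_error(read_genotype_table(file.path(dir, "dup.tsv"), "matrix-tsv",
                                   file.path(dir, "map.tsv")),
               "duplicate marker")
})

test_that("PLINK ped/map input codes '0 0' as missing and counts alt alleles", {
  dir <- withr::local_tempdir()
  writeLines(c("1\tM001\t0\t1000", "1\tM002\t0\t2000"),
             file.path(dir, "p.map"))
  writeLines(c("F1 A01 0 0 0 -9 A A C C",
               "F1 A02 0 0 0 -9 A C 0 0",
               "F1 A03 0 0 0 -9 C C A C"),
             file.path(dir, "p.ped"))
  g <- read_genotype_table(file.path(dir, "p.ped"), "plink-pedmap")
  expect_equal(unname(g$dosages[, "M001"]), c(0, 1, 2))
  expect_true(is.na(g$dosages["A02", "M002"]))
  expect_equal(g$map$alt, c("C", "C"))
})

test_that("matrix-tsv round-trip preserves dosages and missing mask", {
  set.seed(42)
  d <- matrix(sample(c(0, 1, 2, NA), 60, replace = TRUE), 6, 10)
  rownames(d) <- sprintf("A%02d", 1:6)
  g <- make_geno(d, make_map(10))
  dir <- withr::local_tempdir()
  write_genotype_table(g, file.path(dir, "g.tsv"), file.path(dir, "m.tsv"))
  g2 <- read_genotype_table(file.path(dir, "g.tsv"), "matrix-tsv",
                            file.path(dir, "m.tsv"))
  expect_identical(g2$dosages, g$dosages)
  expect_equal(g2$map$pos, g$map$pos)
})

test_that("merge_panels keeps concordant calls, blanks discordant, unions sites", {
  map_a <- make_map(2, start = 1000L)
  map_b <- rbind(make_map(1, start = 1000L),
                 data.frame(marker_id = "B2", chrom = "1", pos = 5000L,
                            ref = "A", alt = "C"))
  map_b$marker_id <- c("B1", "B2")
  a <- make_geno(matrix(c(2, 0, 1, 1), 2, 2), map_a, c("A01", "A02"))
  b <- make_geno(matrix(c(2, 1, 0, 2), 2, 2), map_b, c("A01", "A03"))
  m <- merge_panels(a, b)
  expect_setequal(rownames(m$dosages), c("A01", "A02", "A03"))
  expect_equal(ncol(m$dosages), 3L)
  pos1 <- which(m$map$pos == 1000L)
  expect_equal(unname(m$dosages["A01", pos1]), 2)       # concordant 2/2
  expect_true(is.na(m$dosages["A03", pos1]) == FALSE)   # from panel b
  expect_equal(unname(m$dosages["A03", pos1]), 1)
  # site private to a is missing for the panel-b-only animal
  pos2 <- which(m$map$pos == 2000L)
  expect_true(is.na(m$dosages["A03", pos2]))
  # site private to b is missing for panel-a-only animal
  pos5 <- which(m$map$pos == 5000L)
  expect_true(is.na(m$dosages["A02", pos5]))
})

test_that("merge_panels blanks discordant duplicate calls and is symmetric", {
  map1 <- make_map(2)
  a <- make_geno(matrix(c(2, 1, 0, 2), 2, 2), map1, c("A01", "A02"))
  b <- make_geno(matrix(c(1, 1, 0, 2), 2, 2), map1, c("A01", "A02"))
  m <- merge_panels(a, b)
  expect_true(is.na(m$dosages["A01", 1]))   # 2 vs 1 -> missing
  expect_equal(unname(m$dosages["A02", 1]), 1)
  m2 <- merge_panels(b, a)
  expect_equal(m2$dosages[rownames(m$dosages), colnames(m$dosages)],
               m$dosages)
})

test_that("merge_panels flags swapped alleles and flips when allowed", {
  map1 <- make_map(1)
  map_sw <- make_map(1)
  map_sw$ref <- "C"; map_sw$alt <- "A"
  a <- make_geno(matrix(c(2, 0), 2, 1), map1, c("A01", "A02"))
  b <- make_geno(matrix(c(0, 2), 2, 1), map_sw, c("A01", "A02"))
  expect_error(merge_panels(a, b), "swapped")
  m <- merge_panels(a, b, allow_flip = TRUE)
  expect_equal(unname(m$dosages[, 1]), c(2, 0))  # flip makes them concordant
})

test_that("marker_qc applies autosome, call-rate and MAF rules in order", {
  map <- make_map(4)
  map$chrom <- c("1", "X", "2", "3")
  d <- rbind(c(0, 1, 2, 0),
             c(1, 1, NA, 0),
             c(2, 0, NA, 0),
             c(2, 2, NA, 0))   # M003: call rate 0.25; M004 monomorphic
  g <- make_geno(d, map)
  res <- marker_qc(g, min_call = 0.9, min_maf = 0.01)
  expect_equal(res$genotypes$map$marker_id, "M001")
  expect_equal(res$report$removed_by_rule,
               list(non_autosome = 1L, call_rate = 1L, maf = 1L))
  expect_equal(res$report$n_input - sum(unlist(res$report$removed_by_rule)),
               res$report$n_retained)
  # retained markers satisfy both thresholds
  keep <- res$genotypes$dosages
  p <- colMeans(keep, na.rm = TRUE) / 2
  expect_true(all(pmin(p, 1 - p) >= 0.01))
  expect_true(all(colMeans(!is.na(keep)) >= 0.9))
})

test_that("marker_qc retains a MAF-0.375 marker and errors when none survive", {
  g <- make_geno(cbind(c(0, 1, 2, 2)), make_map(1))
  res <- marker_qc(g)
  expect_equal(n_markers(res$genotypes), 1L)
  mono <- make_geno(cbind(c(0, 0, 0, 0)), make_map(1))
  expect_error(marker_qc(mono), "no markers survive")
})

test_that("sample_qc drops high-het and low-call animals, keeps homozygous", {
  d <- rbind(A1 = c(1, 1, 1, 1, 1, 1, 1, 1, 0, 0),  # het 0.8
             A2 = c(0, 2, 0, 2, 1, 1, 1, 0, 2, 0),  # het 0.3
             A3 = c(NA, NA, 0, 2, 0, 2, 0, 2, 0, 2),# call rate 0.8
             A4 = c(0, 0, 2, 2, 0, 2, 0, 2, 0, 2))  # het 0
  g <- make_geno(d, make_map(10))
  res <- sample_qc(g, min_call = 0.9, max_het = 0.5)
  expect_setequal(rownames(res$genotypes$dosages), c("A2", "A4"))
  expect_equal(res$report$removed_by_rule$heterozygosity, 1L)
  expect_equal(res$report$removed_by_rule$call_rate, 1L)
})

test_that("allele frequencies use observed calls only", {
  g <- make_geno(cbind(c(0, 1, 2), c(2, 2, 2), c(0, NA, 2)), make_map(3))
  p <- allele_frequencies(g)
  expect_equal(unname(p), c(0.5, 1.0, 0.5))
  g0 <- make_geno(cbind(c(NA_real_, NA_real_)), make_map(1))
  expect_error(allele_frequencies(g0), "M001")
})

test_that("fill_missing imputes marker means and preserves them exactly", {
  g <- make_geno(cbind(c(0, 2, NA), c(2, NA, NA), c(0, 1, 2)), make_map(3))
  f <- fill_missing(g)
  expect_equal(unname(f$dosages[3, 1]), 1.0)
  expect_equal(unname(f$dosages[2, 2]), 2.0)
  expect_false(anyNA(f$dosages))
  expect_equal(colMeans(f$dosages), colMeans(g$dosages, na.rm = TRUE),
               ignore_attr = TRUE)
  # identity on complete input
  g2 <- make_geno(cbind(c(0, 1), c(2, 0)), make_map(2))
  expect_identical(fill_missing(g2)$dosages, g2$dosages)
})
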