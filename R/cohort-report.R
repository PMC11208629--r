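# Classification-by-birth-year cohort reporting.

# round half away from zero, as cohort tables conventionally print
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Class-by-year cohort report
#'
#' Tabulates pubertal classifications by birth year and formats each cell
#' as `count (percent of year)`, with a year-total column holding
#' `count (percent of cohort)` and a final totals row. Percentages round
#' half up to whole numbers.
#'
#' @param counts Integer matrix, years x classes (e.g. from
#'   [build_contingency()] on per-animal records, or
#'   [heifer_cohort_counts()]).
#' @return List with `counts`, `row_totals`, `percent` (within-year),
#'   `total_percent` (class totals over the cohort), `formatted`
#'   (character matrix including the Total column and Total row), and
#'   `n_total`.
#' @export
class_by_year_report <- function(counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  rt <- rowSums(counts)
  ct <- colSums(counts)
  n <- sum(counts)
  pct <- round_half_up(100 * counts / rt)
  year_pct <- round_half_up(100 * rt / n)
  tot_pct <- round_half_up(100 * ct / n)
  fmt <- matrix(sprintf("%d (%d)", counts, pct), nrow(counts),
                dimnames = dimnames(counts))
  fmt <- cbind(fmt, Total = sprintf("%d (%d)", rt, year_pct))
  fmt <- rbind(fmt, Total = c(sprintf("%d (%d)", ct, tot_pct),
                              sprintf("%d (100)", n)))
  list(counts = counts, row_totals = rt, percent = pct,
       total_percent = tot_pct, formatted = fmt, n_total = n)
}

#' Expand a count matrix to per-record labels
#'
#' Inverse of [build_contingency()]: one `(row, col)` record per counted
#' unit, useful for feeding tabulated data through record-level APIs.
#'
#' @param counts Integer matrix with dimnames.
#' @return Data frame with columns `row` and `col`.
#' @export
counts_to_records <- function(counts) {
  counts <- as.matrix(counts)
  idx <- which(counts > 0, arr.ind = TRUE)
  data.frame(
    row = rep(rownames(counts)[idx[, 1L]], counts[idx]),
    col = rep(colnames(counts)[idx[, 2L]], counts[idx]),
    stringsAsFactors = FALSE)
}

#' Beef-heifer cohort classification counts
#'
#' The observed pubertal-classification-by-birth-year counts (2017-2022,
#' 532 heifers) of the cohort whose analysis this package implements:
#' classes Early, Typical, Start-Stop-Start, Start-Stop-Discontinued and
#' Non-Cycling. Shipped as a plain TSV under `extdata` and used as the
#' worked example for [class_by_year_report()] and [fisher_exact()].
#'
#' @return Integer matrix, 6 years x 5 classes.
#' @export
heifer_cohort_counts <- function() {
  path <- system.file("extdata", "cohort_class_by_year.tsv",
                      package = "liabgen", mustWork = TRUE)
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  tab <- as.matrix(df[, -1L])
  rownames(tab) <- as.character(df[[1L]])
  storage.mode(tab) <- "integer"
  tab
}
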