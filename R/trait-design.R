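# Ordinal trait codings and fixed-effect design construction.

PUBERTAL_CLASSES <- c("E", "T", "SSS", "SSD", "NC")

#' Trait codings for pubertal classifications
#'
#' Maps the five raw pubertal classes — Early (E), Typical (T),
#' Start-Stop-Start (SSS), Start-Stop-Discontinued (SSD), Non-Cycling (NC)
#' — to the ordinal levels of one of four analyses:
#' \describe{
#'   \item{AL}{all five levels: E=1, T=2, SSS=3, SSD=4, NC=5}
#'   \item{ND}{SSD and NC share level 4: E=1, T=2, SSS=3, SSD=4, NC=4}
#'   \item{ETvND}{cycled vs did not: E=1, T=1, SSD=2, NC=2; SSS excluded}
#'   \item{ET}{timing among cyclers: E=1, T=2; others excluded}
#' }
#' Excluded classes map to `NA` and produce no record.
#'
#' @param name One of `"AL"`, `"ND"`, `"ETvND"`, `"ET"`.
#' @return Object of class `trait_coding`: list with `name` and
#'   `class_to_level` (named integer vector over the five classes).
#' @export
trait_coding <- function(name = c("AL", "ND", "ETvND", "ET")) {
  name <- match.arg(name)
  lv <- switch(name,
    AL    = c(E = 1L, T = 2L, SSS = 3L, SSD = 4L, NC = 5L),
    ND    = c(E = 1L, T = 2L, SSS = 3L, SSD = 4L, NC = 4L),
    ETvND = c(E = 1L, T = 1L, SSS = NA_integer_, SSD = 2L, NC = 2L),
    ET    = c(E = 1L, T = 2L, SSS = NA_integer_, SSD = NA_integer_,
              NC = NA_integer_))
  structure(list(name = name, class_to_level = lv), class = "trait_coding")
}

parse_birth_doy <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  suppressWarnings({
    num <- as.numeric(x)
  })
  if (!anyNA(num)) return(num)
  d <- as.Date(x)
  if (anyNA(d)) stop("unparseable birth_date value(s): ",
                     paste(utils::head(x[is.na(d)], 3L), collapse = ", "))
  as.numeric(strftime(d, "%j"))
}

#' Build the design for a threshold-model fit
#'
#' Assembles the ordinal response and fixed-effects design for model
#' `y = Xb + Zu + e`: an intercept, birth-year indicator columns (first
#' retained year absorbed into the intercept), and a birth-date deviation
#' covariate (day-of-year minus the within-year mean day-of-year,
#' recomputed on the records the coding retains). Animals whose class the
#' coding excludes are dropped; observed ordinal levels are relabelled to
#' be contiguous from 1.
#'
#' @param phenotypes Data frame with columns `animal_id`, `birth_year`,
#'   `birth_date` (ISO date or day-of-year), `class` (E/T/SSS/SSD/NC).
#' @param coding A [trait_coding()].
#' @param animals Character vector of genotyped animal IDs the design must
#'   align to (e.g. `grm$animal_ids`); phenotype records for other animals
#'   raise an error.
#' @return Object of class `trait_design`: list with `y` (integer levels
#'   1..K), `K`, `X` (full-column-rank fixed design), `animal_ids` (one per
#'   record, subset of `animals`), `trait`, and `levels_map` (raw class per
#'   retained level).
#' @export
build_design <- function(phenotypes, coding, animals) {
  stopifnot(inherits(coding, "trait_coding"))
  ph <- as.data.frame(phenotypes, stringsAsFactors = FALSE)
  need <- c("animal_id", "birth_year", "birth_date", "class")
  if (!all(need %in% names(ph))) {
    stop("phenotypes must have columns: ", paste(need, collapse = ", "))
  }
  ph$animal_id <- as.character(ph$animal_id)
  bad_class <- setdiff(unique(ph$class), PUBERTAL_CLASSES)
  if (length(bad_class)) {
    stop("unknown class label(s): ", paste(bad_class, collapse = ", "))
  }
  missing_geno <- setdiff(ph$animal_id, animals)
  if (length(missing_geno)) {
    stop("phenotyped animals absent from genotype/GRM set: ",
         paste(utils::head(missing_geno, 5L), collapse = ", "))
  }
  lev <- coding$class_to_level[ph$class]
  keep <- !is.na(lev)
  ph <- ph[keep, , drop = FALSE]
  lev <- lev[keep]
  if (nrow(ph) == 0L) stop("no records retained under coding ", coding$name)
  # relabel to contiguous 1..K in ascending original-level order
  ulev <- sort(unique(lev))
  y <- match(lev, ulev)
  if (length(ulev) < 2L) stop("response has one level under coding ", coding$name)
  doy <- parse_birth_doy(ph$birth_date)
  year <- factor(ph$birth_year)
  dev <- doy - stats::ave(doy, year)
  if (nlevels(year) > 1L) {
    X <- stats::model.matrix(~ year + dev)
  } else {
    X <- stats::model.matrix(~ dev)
  }
  # drop any aliased columns so X has full column rank
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  lm_raw <- vapply(ulev, function(l) {
    paste(sort(unique(ph$class[lev == l])), collapse = "+")
  }, "")
  structure(list(y = as.integer(y), K = length(ulev), X = X,
                 animal_ids = ph$animal_id, trait = coding$name,
                 levels_map = lm_raw, birth_doy = doy),
            class = "trait_design")
}

#' @export
print.trait_design <- function(x, ...) {
  cat("trait_design:", x$trait, "-", length(x$y), "records,", x$K,
      "levels (", paste(x$levels_map, collapse = " < "), "),",
      ncol(x$X), "fixed-effect columns\n")
  invisible(x)
}

#' Read a phenotype table
#'
#' TSV with columns `animal_id`, `birth_year`, `birth_date` (ISO date or
#' day-of-year), `class` in E/T/SSS/SSD/NC.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_phenotypes <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                    colClasses = list(character = "animal_id"))
}
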