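# Exact and Monte Carlo Fisher tests on r x c contingency tables, with
# probability-mass (two-sided) ordering.

#' Cross-tabulate paired labels
#'
#' @param records Data frame (or list) whose first two columns give the
#'   row and column label of each record.
#' @return Integer matrix of counts with sorted, unique dimnames; class
#'   `contingency_table`.
#' @export
build_contingency <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("no records")
  r <- factor(records[[1L]])
  c <- factor(records[[2L]])
  if (nlevels(r) < 2L || nlevels(c) < 2L) {
    stop("need at least 2 distinct row and column labels")
  }
  tab <- unclass(table(r, c))
  names(dimnames(tab)) <- NULL
  structure(tab, class = c("contingency_table", class(tab)))
}

# log-probability of a table under the fixed-margins (multivariate
# hypergeometric) null
log_table_prob <- function(tab) {
  sum(lfactorial(rowSums(tab))) + sum(lfactorial(colSums(tab))) -
    lfactorial(sum(tab)) - sum(lfactorial(tab))
}

# Enumerate all tables with the given margins, calling fn(cells) on each;
# stops with a condition if more than max_tables are visited.
enumerate_tables <- function(row_margins, col_margins, fn,
                             max_tables = 1e6) {
  r <- length(row_margins)
  c <- length(col_margins)
  cells <- matrix(0L, r, c)
  count <- 0L
  rec <- function(i, j, row_left, col_left) {
    if (i == r) {
      # last row forced by column margins
      if (any(col_left < 0L)) return()
      cells[r, ] <<- col_left
      count <<- count + 1L
      if (count > max_tables) stop(structure(
        class = c("too_many_tables", "error", "condition"),
        list(message = "table count exceeds cap", call = NULL)))
      fn(cells)
      return()
    }
    if (j == c) {
      # last cell in row forced by row margin
      v <- row_left
      if (v < 0L || v > col_left[c]) return()
      cells[i, c] <<- v
      cl <- col_left
      cl[c] <- cl[c] - v
      rec(i + 1L, 1L, row_margins[i + 1L], cl)
      return()
    }
    for (v in 0:min(row_left, col_left[j])) {
      cells[i, j] <<- v
      cl <- col_left
      cl[j] <- cl[j] - v
      rec(i, j + 1L, row_left - v, cl)
    }
  }
  rec(1L, 1L, row_margins[1L], col_margins)
  count
}

#' Fisher's exact test on an r x c table
#'
#' Two-sided p-value under probability-mass ordering: the sum of
#' fixed-margins probabilities of all tables no more probable than the
#' observed one. 2 x 2 tables use the hypergeometric distribution
#' directly; larger tables are enumerated exactly when the number of
#' tables with the observed margins is at most `max_tables`, and otherwise
#' sampled with fixed margins ([stats::r2dtable()]), with the add-one
#' estimate `p = (1 + #\{simulated prob <= observed\}) / (1 + n_sim)`.
#'
#' @param tab A [build_contingency()] result or plain count matrix.
#' @param method `"auto"`, `"exact"`, or `"montecarlo"`.
#' @param n_sim Monte Carlo sample size.
#' @param seed Optional integer seed for the Monte Carlo path.
#' @param max_tables Enumeration cap for `method = "auto"`/`"exact"`.
#' @return List with `p_value`, `method` used, `se` (Monte Carlo standard
#'   error, `NA` for exact), `n_sim`.
#' @export
fisher_exact <- function(tab, method = c("auto", "exact", "montecarlo"),
                         n_sim = 1e6, seed = NULL, max_tables = 1e6) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  storage.mode(tab) <- "integer"
  if (any(tab < 0L)) stop("negative counts")
  rm_ <- rowSums(tab)
  cm_ <- colSums(tab)
  if (any(rm_ == 0L) || any(cm_ == 0L)) stop("zero margin")
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("need at least a 2 x 2 table")
  # relative tolerance guards against ties lost to floating point
  tol <- 1 + 1e-7

  if (nrow(tab) == 2L && ncol(tab) == 2L && method != "montecarlo") {
    m <- cm_[1L]; n <- cm_[2L]; k <- rm_[1L]
    support <- max(0L, k - n):min(k, m)
    probs <- stats::dhyper(support, m, n, k)
    p_obs <- stats::dhyper(tab[1L, 1L], m, n, k)
    p <- sum(probs[probs <= p_obs * tol])
    return(list(p_value = min(p, 1), method = "exact", se = NA_real_,
                n_sim = NA_real_))
  }

  if (method != "montecarlo") {
    lp_obs <- log_table_prob(tab)
    acc <- 0
    res <- tryCatch({
      enumerate_tables(rm_, cm_, function(cells) {
        lp <- log_table_prob(cells)
        if (lp <= lp_obs + log(tol)) acc <<- acc + exp(lp)
      }, max_tables = max_tables)
      TRUE
    }, too_many_tables = function(e) FALSE)
    if (res) {
      return(list(p_value = min(acc, 1), method = "exact", se = NA_real_,
                  n_sim = NA_real_))
    }
    if (method == "exact") {
      stop("more than max_tables tables share these margins; ",
           "use method = 'montecarlo'")
    }
  }

  if (!is.null(seed)) set.seed(seed)
  lp_obs <- log_table_prob(tab)
  # margin factorials are constant across simulated tables: compare cell terms
  cell_obs <- sum(lfactorial(tab))
  sims <- stats::r2dtable(n_sim, rm_, cm_)
  chunk <- 50000L
  hits <- 0
  for (start in seq(1L, n_sim, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_sim)
    cellsums <- vapply(sims[idx], function(m) sum(lfactorial(m)), 0)
    # larger cell-factorial sum means smaller table probability
    hits <- hits + sum(cellsums >= cell_obs - log(tol))
  }
  p <- (1 + hits) / (1 + n_sim)
  list(p_value = p, method = "montecarlo",
       se = sqrt(p * (1 - p) / n_sim), n_sim = n_sim)
}

#' Read a counts TSV with row labels
#'
#' First column holds row labels; remaining columns are counts with column
#' labels in the header.
#'
#' @param path TSV path.
#' @return A `contingency_table` matrix.
#' @export
read_contingency <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1))
  tab <- as.matrix(df[, -1L, drop = FALSE])
  rownames(tab) <- df[[1L]]
  storage.mode(tab) <- "integer"
  structure(tab, class = c("contingency_table", class(tab)))
}
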