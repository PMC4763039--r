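#' Pearson chi-square test of independence
#'
#' Tests independence between the rows and columns of a contingency table
#' of counts with the uncorrected Pearson statistic
#' sum((O - E)^2 / E), E = row total * column total / grand total. No
#' continuity correction is applied for any table size. All-zero rows and
#' columns are dropped first (with the drop reported and the degrees of
#' freedom computed on the retained table), since small or simulated
#' data sets can produce empty classes.
#'
#' @param table matrix (or coercible) of non-negative counts.
#' @return object of class `contingency_result`: `statistic`, `df`,
#'   `p_value` (upper tail), `dropped` (labels or indices of removed
#'   all-zero margins), `observed`, `expected`.
#' @examples
#' # band-type x condition, dormant bud stage
#' db <- cbind(high = c(444, 33, 50, 83), low = c(458, 32, 50, 62))
#' pearson_chi_square(db)   # statistic 3.22, df 3
#' @export
pearson_chi_square <- function(table) {
  m <- as.matrix(table)
  if (anyNA(m) || any(m < 0)) stop("counts must be non-negative and non-missing")
  if (is.null(rownames(m))) rownames(m) <- paste0("r", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))

  zr <- rowSums(m) == 0
  zc <- colSums(m) == 0
  dropped <- c(rownames(m)[zr], colnames(m)[zc])
  m <- m[!zr, !zc, drop = FALSE]
  if (nrow(m) < 2L) stop("degenerate table: fewer than 2 informative rows")
  if (ncol(m) < 2L) stop("degenerate table: fewer than 2 informative columns")

  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  structure(
    list(statistic = unname(res$statistic),
         df = unname(res$parameter),
         p_value = unname(res$p.value),
         dropped = dropped,
         observed = m,
         expected = res$expected),
    class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X2 = %.2f, df = %d, p = %.3f\n",
              x$statistic, x$df, x$p_value))
  if (length(x$dropped) > 0L) {
    cat("dropped all-zero margins:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Upper-tail chi-square probability
#'
#' @param statistic non-negative chi-square statistic.
#' @param df degrees of freedom (>= 1).
#' @return P(X >= statistic) for X ~ chi-square(df).
#' @export
chi_square_p_value <- function(statistic, df) {
  if (any(df < 1)) stop("df must be >= 1")
  if (any(statistic < 0)) stop("statistic must be non-negative")
  stats::pchisq(statistic, df = df, lower.tail = FALSE)
}

# Pearson statistic by the definition, independent of stats::chisq.test --
# used by the permutation oracle so analytic and Monte-Carlo routes do not
# share an implementation.
pearson_statistic <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

#' Permutation p-value for a contingency table
#'
#' Monte-Carlo p-value for the Pearson statistic under the null of
#' independence conditioned on both margins: random tables with the
#' observed row and column totals are drawn with [stats::r2dtable()]
#' (Patefield's algorithm) and the statistic recomputed by definition for
#' each. Serves as the validation oracle for the analytic chi-square
#' p-value; the two agree within Monte-Carlo error whenever the asymptotic
#' approximation is adequate.
#'
#' The estimate uses the add-one rule (b+1)/(n+1), which never returns an
#' exact zero.
#'
#' @param table matrix of non-negative counts.
#' @param n_perm number of random tables (>= 1).
#' @param seed integer seed; identical seeds give identical p-values.
#' @return permutation p-value.
#' @export
permutation_chi_square <- function(table, n_perm = 10000L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  m <- as.matrix(table)
  if (anyNA(m) || any(m < 0)) stop("counts must be non-negative and non-missing")
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L) stop("degenerate table after dropping zero margins")
  observed <- pearson_statistic(m)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  draws <- stats::r2dtable(n_perm, rowSums(m), colSums(m))
  stat <- vapply(draws, pearson_statistic, numeric(1L))
  (sum(stat >= observed - 1e-12) + 1) / (n_perm + 1)
}
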