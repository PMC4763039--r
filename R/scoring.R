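#' MSAP band types
#'
#' The four canonical MSAP band types inferred from the two isoschizomer
#' lanes at a 5'-CCGG-3' locus:
#' \describe{
#'   \item{I}{band in both lanes -- unmethylated site}
#'   \item{II}{band only in the EcoRI/HpaII lane -- hemi-methylated site
#'     (HpaII tolerates hemi-methylation; MspI is blocked by external-C
#'     methylation)}
#'   \item{III}{band only in the EcoRI/MspI lane -- fully methylated
#'     internal cytosine (MspI cuts C^5mCGG; HpaII is blocked by full
#'     methylation)}
#'   \item{IV}{band in neither lane although the fragment is observed in
#'     another sample -- hyper-methylated, or demethylated relative to the
#'     sample where it appears}
#' }
#' @return character vector `c("I","II","III","IV")`.
#' @export
band_types <- function() c("I", "II", "III", "IV")

#' Classify lane-presence bits into MSAP band types
#'
#' Vectorised classification of (hpa, msp) presence bits. The double
#' absence (0,0) is only informative when the fragment is observed
#' somewhere else in the analysis set; otherwise the locus is excluded
#' (`NA`), because a band that never appears on any gel cannot be scored.
#'
#' @param hpa,msp 0/1 presence bits for the EcoRI/HpaII and EcoRI/MspI
#'   lanes.
#' @param observed_elsewhere logical: does the locus show at least one band
#'   in any lane of any *other* sample?
#' @return character vector over `c("I","II","III","IV")` with `NA` for
#'   excluded (never-observed) loci.
#' @examples
#' classify_band_type(c(1, 1, 0, 0, 0), c(1, 0, 1, 0, 0),
#'                    observed_elsewhere = c(TRUE, TRUE, TRUE, TRUE, FALSE))
#' @export
classify_band_type <- function(hpa, msp, observed_elsewhere) {
  stopifnot(all(hpa %in% c(0, 1)), all(msp %in% c(0, 1)))
  n <- max(length(hpa), length(msp), length(observed_elsewhere))
  hpa <- rep_len(as.integer(hpa), n)
  msp <- rep_len(as.integer(msp), n)
  observed_elsewhere <- rep_len(as.logical(observed_elsewhere), n)
  out <- rep(NA_character_, n)
  out[hpa == 1L & msp == 1L] <- "I"
  out[hpa == 1L & msp == 0L] <- "II"
  out[hpa == 0L & msp == 1L] <- "III"
  absent <- hpa == 0L & msp == 0L
  out[absent & observed_elsewhere] <- "IV"
  out
}

#' Score every cell of a band matrix
#'
#' Adds a band-type call to each (locus, sample) cell of the matrix. For a
#' (0,0) cell the type-IV call requires the locus to carry at least one
#' band in some other sample; loci absent from every lane of every sample
#' are excluded (`band_type = NA`, `excluded = TRUE`) and never enter any
#' denominator.
#'
#' @param x a [band_matrix].
#' @return the cell data.frame with added columns `band_type` and
#'   `excluded`.
#' @export
score_band_matrix <- function(x) {
  stopifnot(inherits(x, "band_matrix"))
  cells <- x$cells
  own <- cells$hpa + cells$msp
  locus_total <- tapply(own, cells$locus, sum)
  elsewhere <- locus_total[cells$locus] - own > 0L
  cells$band_type <- classify_band_type(cells$hpa, cells$msp, elsewhere)
  cells$excluded <- is.na(cells$band_type)
  rownames(cells) <- NULL
  cells
}

#' Methylation summary from band-type counts
#'
#' Builds the per-sample (or pooled) summary of an MSAP assay from the four
#' band-type counts. Percentages follow the standard MSAP definitions:
#' total methylation counts types II+III+IV, full methylation counts
#' III+IV, hemi-methylation counts type II, all over the total scored
#' fragments. Full precision is carried internally; [format()] and
#' [print()] render at 1 decimal.
#'
#' @param label sample or pool identifier.
#' @param counts numeric vector of four band-type counts, in type order
#'   I, II, III, IV (names optional).
#' @return object of class `methylation_summary`: a list with `label`,
#'   `n_type` (named counts), `n_total`, `pct_total_methylation`,
#'   `pct_fully_methylated`, `pct_hemi_methylated`.
#' @examples
#' s <- methylation_summary("DBH", c(444, 33, 50, 83))
#' s$pct_total_methylation   # 27.21311...
#' print(s)                  # renders 27.2 / 21.8 / 5.4
#' @export
methylation_summary <- function(label, counts) {
  counts <- unname(counts)
  if (length(counts) != 4L || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be 4 non-negative integers (types I, II, III, IV)")
  }
  counts <- as.integer(counts)
  n_total <- sum(counts)
  if (n_total == 0L) stop("no scored fragments for '", label, "'")
  names(counts) <- band_types()
  structure(
    list(label = as.character(label),
         n_type = counts,
         n_total = n_total,
         pct_total_methylation = 100 * sum(counts[c("II", "III", "IV")]) / n_total,
         pct_fully_methylated  = 100 * sum(counts[c("III", "IV")]) / n_total,
         pct_hemi_methylated   = 100 * counts[["II"]] / n_total),
    class = "methylation_summary")
}

#' @export
print.methylation_summary <- function(x, ...) {
  cat(sprintf(
    "MSAP methylation summary [%s]: n=%d (I=%d II=%d III=%d IV=%d)\n",
    x$label, x$n_total, x$n_type[["I"]], x$n_type[["II"]],
    x$n_type[["III"]], x$n_type[["IV"]]))
  cat(sprintf("  total methylation:  %.1f%%\n", x$pct_total_methylation))
  cat(sprintf("  fully methylated:   %.1f%%\n", x$pct_fully_methylated))
  cat(sprintf("  hemi-methylated:    %.1f%%\n", x$pct_hemi_methylated))
  invisible(x)
}

#' Summarize one sample of a band matrix
#'
#' Counts band types I-IV over all non-excluded loci for the sample and
#' derives the methylation percentages.
#'
#' @param x a [band_matrix].
#' @param sample sample identifier present in `x`.
#' @return a [methylation_summary].
#' @export
summarize_sample <- function(x, sample) {
  stopifnot(inherits(x, "band_matrix"))
  if (!(sample %in% x$samples)) {
    stop("unknown sample '", sample, "'; matrix has: ",
         paste(x$samples, collapse = ", "))
  }
  scored <- score_band_matrix(x)
  scored <- scored[scored$sample == sample & !scored$excluded, , drop = FALSE]
  counts <- table(factor(scored$band_type, levels = band_types()))
  methylation_summary(sample, as.integer(counts))
}

#' Summarize every sample of a band matrix
#'
#' @param x a [band_matrix].
#' @return named list of [methylation_summary] objects, one per sample.
#' @export
summarize_samples <- function(x) {
  stopifnot(inherits(x, "band_matrix"))
  out <- lapply(x$samples, function(s) summarize_sample(x, s))
  names(out) <- x$samples
  out
}

#' Pool methylation summaries
#'
#' Sums the band-type counts of several summaries and recomputes the
#' percentages from the pooled counts (never averages percentages), e.g. to
#' aggregate the four developmental stages of one chilling condition.
#'
#' @param summaries list of [methylation_summary] objects (length >= 1).
#' @param label identifier for the pool.
#' @return a [methylation_summary]. Pooling a single summary returns it
#'   unchanged apart from the label.
#' @export
pool_summaries <- function(summaries, label) {
  if (length(summaries) == 0L) stop("cannot pool an empty list of summaries")
  stopifnot(all(vapply(summaries, inherits, TRUE, "methylation_summary")))
  counts <- Reduce(`+`, lapply(summaries, `[[`, "n_type"))
  methylation_summary(label, counts)
}

#' Methylation summaries as a data.frame
#'
#' Flattens summaries into one row per sample/pool for reporting. `digits`
#' rounds the percentage columns for rendering (default `NULL` keeps full
#' precision, as in machine-readable output).
#'
#' @param summaries list of [methylation_summary] objects.
#' @param digits optional rounding for the percentage columns.
#' @return data.frame with counts, totals, and the three percentages.
#' @export
summary_table <- function(summaries, digits = NULL) {
  if (inherits(summaries, "methylation_summary")) summaries <- list(summaries)
  rows <- lapply(summaries, function(s) {
    data.frame(label = s$label,
               n_I = s$n_type[["I"]], n_II = s$n_type[["II"]],
               n_III = s$n_type[["III"]], n_IV = s$n_type[["IV"]],
               n_total = s$n_total,
               pct_total_methylation = s$pct_total_methylation,
               pct_fully_methylated = s$pct_fully_methylated,
               pct_hemi_methylated = s$pct_hemi_methylated)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(digits)) {
    pct <- grep("^pct_", names(out))
    out[pct] <- lapply(out[pct], round, digits = digits)
  }
  out
}
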