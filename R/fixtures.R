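#' Reference band-type counts from an apple chilling/dormancy MSAP survey
#'
#' Packaged example data: per-sample MSAP band-type counts (types I-IV)
#' for four developmental stages of apple buds -- dormant bud (DB), silver
#' tip (ST), green tip (GT), initial fruit set (FS) -- under high-chill
#' (suffix H) and low-chill (suffix L) winter conditions. These are
#' count-level data; the underlying gel scorings are not available, so the
#' counts serve both as a worked example and as the arithmetic test
#' surface for scoring, pooling and association statistics.
#'
#' @return data.frame with columns `sample`, `type_I` ... `type_IV`.
#' @examples
#' counts <- apple_band_counts()
#' methylation_summary("DBH", as.numeric(counts[counts$sample == "DBH", -1]))
#' @export
apple_band_counts <- function() {
  path <- system.file("extdata", "apple_chill_band_counts.tsv",
                      package = "msapkit", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Reference comparative pattern-class counts (apple chilling survey)
#'
#' Packaged example data: per-class counts of the sixteen comparative
#' banding-pattern classes A-P (see [pattern_classes()]) for the four
#' low-vs-high-chill comparisons of the apple survey shipped with
#' [apple_band_counts()]. Comparison labels follow the
#' `treatment-vs-control` convention with the high-chill sample as
#' control.
#'
#' @return data.frame with a `class` column and one count column per
#'   comparison.
#' @export
apple_pattern_counts <- function() {
  path <- system.file("extdata", "apple_chill_pattern_counts.tsv",
                      package = "msapkit", mustWork = TRUE)
  out <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  stopifnot(identical(out$class, pattern_classes()$code))
  out
}

#' Expand band-type counts into a band matrix
#'
#' Builds a synthetic two-sample band matrix whose scored band-type counts
#' for `label` are exactly the supplied counts: one locus per counted
#' fragment with the lane bits of its type, plus an all-present anchor
#' sample so that type-IV (double-absent) loci are observed elsewhere and
#' enter the denominator. Locus identifiers are synthetic
#' (`<label>_<type>_<i>`), since the underlying gel loci are not data.
#'
#' Note that an exact multi-sample expansion is impossible whenever
#' samples have different totals: any locus observed anywhere is scored in
#' every sample (as type IV where absent), which would force all totals to
#' be equal. Per-sample expansion against an anchor is therefore the
#' canonical route from published count tables back to matrix form.
#'
#' @param counts 4 band-type counts (I, II, III, IV).
#' @param label sample identifier for the expanded sample.
#' @param anchor identifier for the all-present anchor sample.
#' @return a [band_matrix] with samples `c(label, anchor)`.
#' @examples
#' m <- counts_to_band_matrix(c(4, 3, 2, 1), "DBH")
#' summarize_sample(m, "DBH")$n_type   # 4 3 2 1
#' @export
counts_to_band_matrix <- function(counts, label, anchor = "REF") {
  counts <- as.integer(unname(counts))
  stopifnot(length(counts) == 4L, all(counts >= 0), sum(counts) > 0,
            label != anchor)
  bits <- data.frame(hpa = c(1L, 1L, 0L, 0L), msp = c(1L, 0L, 1L, 0L))
  type <- rep(seq_len(4L), counts)
  loci <- sprintf("%s_%s_%04d", label, band_types()[type],
                  unlist(lapply(counts, seq_len)))
  cells <- rbind(
    data.frame(locus = loci, sample = label,
               hpa = bits$hpa[type], msp = bits$msp[type]),
    data.frame(locus = loci, sample = anchor, hpa = 1L, msp = 1L))
  band_matrix(cells, metadata = list(expanded_from = "band-type counts"))
}

#' Expand comparative class counts into a band matrix
#'
#' Builds a synthetic band matrix for one control/treatment pair whose
#' [summarize_comparison()] class counts are exactly the supplied counts:
#' one locus per counted pair with the four lane bits of its class, plus
#' an all-present anchor sample so that class-D (all-absent) loci stay in
#' the comparison universe.
#'
#' @param class_counts named counts over the codes A-P (missing codes
#'   count 0).
#' @param control,treatment sample identifiers.
#' @param anchor identifier for the anchor sample.
#' @return a [band_matrix] with three samples.
#' @export
pattern_counts_to_band_matrix <- function(class_counts, control, treatment,
                                          anchor = "REF") {
  stopifnot(!is.null(names(class_counts)), control != treatment,
            !(anchor %in% c(control, treatment)))
  pc <- pattern_classes()
  counts <- stats::setNames(integer(16L), pc$code)
  counts[names(class_counts)] <- as.integer(class_counts)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  cls <- rep(seq_len(16L), counts)
  loci <- sprintf("%s_%04d", pc$code[cls], unlist(lapply(counts, seq_len)))
  cells <- rbind(
    data.frame(locus = loci, sample = control,
               hpa = pc$control_hpa[cls], msp = pc$control_msp[cls]),
    data.frame(locus = loci, sample = treatment,
               hpa = pc$treat_hpa[cls], msp = pc$treat_msp[cls]),
    data.frame(locus = loci, sample = anchor, hpa = 1L, msp = 1L))
  band_matrix(cells, metadata = list(expanded_from = "pattern-class counts"))
}

#' Stage-wise band-type x condition contingency tables
#'
#' Arranges per-sample band-type counts into the 4x2 (band type x
#' condition) contingency tables used to test association between
#' methylation classification and chilling condition: one table per
#' developmental stage plus a pooled table over all stages. Sample labels
#' must parse under the stage/condition convention (see
#' [parse_sample_labels()]).
#'
#' @param counts data.frame as returned by [apple_band_counts()].
#' @return named list of 4x2 matrices (rows = band types, columns =
#'   `high_chill`, `low_chill`), one per stage in `c("DB","ST","GT","FS")`
#'   order plus `"pooled"`.
#' @export
stage_condition_tables <- function(counts = apple_band_counts()) {
  labels <- parse_sample_labels(counts$sample)
  if (anyNA(labels$stage)) {
    stop("sample label(s) do not parse as <stage><H|L>: ",
         paste(counts$sample[is.na(labels$stage)], collapse = ", "))
  }
  stages <- intersect(c("DB", "ST", "GT", "FS"), unique(labels$stage))
  type_cols <- paste0("type_", band_types())
  one <- function(rows) {
    m <- t(as.matrix(counts[rows, type_cols]))
    dimnames(m) <- list(band_type = band_types(),
                        condition = labels$condition[rows])
    m[, c(which(labels$condition[rows] == "high_chill"),
          which(labels$condition[rows] == "low_chill")), drop = FALSE]
  }
  tabs <- lapply(stages, function(st) one(which(labels$stage == st)))
  names(tabs) <- stages
  pooled <- Reduce(`+`, tabs)
  dimnames(pooled) <- list(band_type = band_types(),
                           condition = c("high_chill", "low_chill"))
  c(tabs, list(pooled = pooled))
}
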