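#' The sixteen comparative MSAP banding-pattern classes
#'
#' In a paired control/treatment comparison each locus shows one of
#' 2^4 = 16 possible banding patterns across the four lanes
#' (control MspI, control HpaII, treatment MspI, treatment HpaII). The
#' classes are labelled A-P and partitioned into three event groups:
#' A-D mean no change (treatment pattern equals control pattern), E-J are
#' demethylation events (bands gained in the treatment relative to control,
#' i.e. sites that became cuttable), K-P are methylation events (bands
#' lost).
#'
#' Bit order within each sample is (MspI, HpaII), matching the conventional
#' presentation; all interfaces in this package keep that order to avoid
#' silent transposition.
#'
#' @return data.frame with one row per class: `code`, `control_msp`,
#'   `control_hpa`, `treat_msp`, `treat_hpa`, `group`.
#' @examples
#' pc <- pattern_classes()
#' table(pc$group)   # no_change 4, demethylation 6, methylation 6
#' @export
pattern_classes <- function() {
  # bits: control_msp, control_hpa, treat_msp, treat_hpa
  def <- list(
    A = c(1, 1, 1, 1), B = c(0, 1, 0, 1), C = c(1, 0, 1, 0), D = c(0, 0, 0, 0),
    E = c(0, 1, 1, 1), F = c(1, 0, 1, 1), G = c(0, 0, 1, 1), H = c(1, 0, 0, 1),
    I = c(0, 0, 0, 1), J = c(0, 0, 1, 0),
    K = c(1, 1, 0, 1), L = c(1, 1, 1, 0), M = c(0, 1, 1, 0), N = c(1, 1, 0, 0),
    O = c(0, 1, 0, 0), P = c(1, 0, 0, 0))
  m <- do.call(rbind, def)
  group <- rep(c("no_change", "demethylation", "methylation"), c(4L, 6L, 6L))
  data.frame(code = names(def),
             control_msp = m[, 1L], control_hpa = m[, 2L],
             treat_msp = m[, 3L], treat_hpa = m[, 4L],
             group = group)
}

#' Event groups of the comparative classes
#' @return character vector `c("no_change","demethylation","methylation")`.
#' @export
pattern_groups <- function() c("no_change", "demethylation", "methylation")

#' Classify a control/treatment banding-pattern pair
#'
#' Total, vectorised lookup: every bit 4-tuple (control_msp, control_hpa,
#' treat_msp, treat_hpa) maps to exactly one of the sixteen classes A-P.
#' The all-absent tuple maps to class D; whether such a locus belongs in a
#' comparison at all is decided by [summarize_comparison()]'s universe
#' rule, not here.
#'
#' @param control_msp,control_hpa,treat_msp,treat_hpa 0/1 presence bits.
#' @return character vector of class codes.
#' @examples
#' classify_pair(1, 1, 1, 1)  # "A" (no change)
#' classify_pair(0, 0, 1, 1)  # "G" (demethylation)
#' classify_pair(1, 1, 0, 1)  # "K" (methylation)
#' @export
classify_pair <- function(control_msp, control_hpa, treat_msp, treat_hpa) {
  bits <- cbind(control_msp, control_hpa, treat_msp, treat_hpa)
  if (anyNA(bits) || !all(bits %in% c(0, 1))) {
    stop("presence bits must all be 0 or 1")
  }
  idx <- bits[, 1L] * 8L + bits[, 2L] * 4L + bits[, 3L] * 2L + bits[, 4L] + 1L
  pc <- pattern_classes()
  code_by_idx <- character(16L)
  code_by_idx[pc$control_msp * 8L + pc$control_hpa * 4L +
                pc$treat_msp * 2L + pc$treat_hpa + 1L] <- pc$code
  code_by_idx[idx]
}

#' Event group of a class code
#' @param code character vector of class codes A-P.
#' @return character vector of groups.
#' @export
pattern_group_of <- function(code) {
  pc <- pattern_classes()
  g <- pc$group[match(code, pc$code)]
  if (anyNA(g)) stop("unknown pattern class: ",
                     paste(unique(code[is.na(g)]), collapse = ", "))
  g
}

#' Comparison summary from per-class counts
#'
#' Low-level constructor used both by [summarize_comparison()] and when
#' per-class counts are supplied directly (e.g. published count tables).
#'
#' @param control_sample,treatment_sample identifiers (reporting only).
#' @param class_counts named integer vector over the codes A-P (missing
#'   codes count 0).
#' @return object of class `comparison_summary` with `n_class`, `n_group`,
#'   `n_total` and `pct_group` (full precision).
#' @export
comparison_summary <- function(control_sample, treatment_sample,
                               class_counts) {
  pc <- pattern_classes()
  counts <- stats::setNames(integer(16L), pc$code)
  if (is.null(names(class_counts))) {
    stop("class_counts must be named with class codes A-P")
  }
  unknown <- setdiff(names(class_counts), pc$code)
  if (length(unknown) > 0L) {
    stop("unknown class code(s): ", paste(unknown, collapse = ", "))
  }
  counts[names(class_counts)] <- as.integer(class_counts)
  if (any(counts < 0)) stop("class counts must be non-negative")
  n_total <- sum(counts)
  if (n_total == 0L) stop("comparison has no classified loci")
  n_group <- vapply(pattern_groups(), function(g) {
    sum(counts[pc$code[pc$group == g]])
  }, integer(1L))
  structure(
    list(control_sample = as.character(control_sample),
         treatment_sample = as.character(treatment_sample),
         n_class = counts,
         n_group = n_group,
         n_total = n_total,
         pct_group = 100 * n_group / n_total),
    class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat(sprintf("MSAP comparison %s-vs-%s: n=%d loci\n",
              x$treatment_sample, x$control_sample, x$n_total))
  for (g in pattern_groups()) {
    cat(sprintf("  %-14s %5d  (%.1f%%)\n", g, x$n_group[[g]],
                x$pct_group[[g]]))
  }
  invisible(x)
}

#' Classify and tally a control/treatment comparison from a band matrix
#'
#' Classifies every locus in the comparison universe into the classes A-P
#' and tallies classes, event groups, and group percentages (denominator =
#' total classified loci).
#'
#' The comparison universe contains every locus with at least one band in
#' either member of the pair, plus loci absent from both members but
#' observed in some other sample of the matrix (these score class D, the
#' all-absent no-change pattern -- mirroring the type-IV convention of
#' single-sample scoring). Loci observed nowhere are excluded.
#'
#' @param x a [band_matrix] containing both samples.
#' @param control,treatment distinct sample identifiers.
#' @return a [comparison_summary].
#' @export
summarize_comparison <- function(x, control, treatment) {
  stopifnot(inherits(x, "band_matrix"))
  if (identical(control, treatment)) {
    stop("control and treatment samples must differ (got '", control, "')")
  }
  for (s in c(control, treatment)) {
    if (!(s %in% x$samples)) stop("unknown sample '", s, "'")
  }
  cells <- x$cells
  ctl <- cells[cells$sample == control, , drop = FALSE]
  trt <- cells[cells$sample == treatment, , drop = FALSE]
  ctl <- ctl[match(x$loci, ctl$locus), , drop = FALSE]
  trt <- trt[match(x$loci, trt$locus), , drop = FALSE]
  in_pair <- (ctl$hpa + ctl$msp + trt$hpa + trt$msp) > 0L
  locus_total <- tapply(cells$hpa + cells$msp, cells$locus, sum)
  observed_anywhere <- locus_total[x$loci] > 0L
  universe <- in_pair | observed_anywhere
  codes <- classify_pair(ctl$msp[universe], ctl$hpa[universe],
                         trt$msp[universe], trt$hpa[universe])
  counts <- table(factor(codes, levels = pattern_classes()$code))
  comparison_summary(control, treatment,
                     stats::setNames(as.integer(counts), names(counts)))
}

#' Event-count contingency table across comparisons
#'
#' Assembles the group totals of several comparisons into a contingency
#' table (rows = event groups, columns = comparisons in input order) for
#' chi-square testing of whether event composition differs between
#' comparisons.
#'
#' @param summaries list of [comparison_summary] objects (length >= 2).
#' @param include_no_change also include the no-change row (default
#'   `FALSE`: the test usually contrasts demethylation vs methylation
#'   events).
#' @return integer matrix with dimnames. If any retained row is all zero
#'   the matrix carries attribute `degenerate = TRUE` and a warning is
#'   raised, so callers can catch the degeneracy before testing.
#' @export
event_counts_table <- function(summaries, include_no_change = FALSE) {
  if (length(summaries) < 2L) stop("need at least two comparisons")
  stopifnot(all(vapply(summaries, inherits, TRUE, "comparison_summary")))
  groups <- if (include_no_change) pattern_groups() else
    c("demethylation", "methylation")
  m <- vapply(summaries, function(s) s$n_group[groups],
              numeric(length(groups)))
  m <- matrix(as.integer(m), nrow = length(groups),
              dimnames = list(
                group = groups,
                comparison = vapply(summaries, function(s) {
                  paste0(s$treatment_sample, "-vs-", s$control_sample)
                }, "")))
  zero_rows <- rowSums(m) == 0L
  if (any(zero_rows)) {
    warning("degenerate event table: no '",
            paste(groups[zero_rows], collapse = "', '"),
            "' events in any comparison")
    attr(m, "degenerate") <- TRUE
  }
  m
}
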