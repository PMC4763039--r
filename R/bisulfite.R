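#' Cytosine sequence contexts
#'
#' Plant DNA methylation is classified by the two bases downstream of the
#' cytosine on the same strand: CG, CHG and CHH, where H is A, C or T.
#' Cytosines too close to the sequence end, or whose context window
#' contains an N, are `undetermined` and excluded from methylation
#' percentages (with counts reported).
#'
#' @return character vector `c("CG","CHG","CHH","undetermined")`.
#' @export
cytosine_contexts <- function() c("CG", "CHG", "CHH", "undetermined")

as_base_vector <- function(seq, what) {
  if (inherits(seq, "XString") || inherits(seq, "XStringSet")) {
    seq <- as.character(seq)
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  bases <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  bad <- which(!(bases %in% c("A", "C", "G", "T", "N")))
  if (length(bad) > 0L) {
    stop(what, " has character '", bases[bad[1L]],
         "' outside {A,C,G,T,N} at position ", bad[1L] - 1L, " (0-based)")
  }
  bases
}

#' Classify the sequence context of every reference cytosine
#'
#' Top-strand analysis: for each C at 0-based position i, the context is CG
#' if base i+1 is G; CHG if base i+1 is in {A,C,T} and base i+2 is G; CHH
#' if bases i+1 and i+2 are both in {A,C,T}; undetermined when the needed
#' downstream bases run off the sequence end or an N intervenes.
#'
#' @param reference sequence over {A,C,G,T,N}: a character scalar or a
#'   Biostrings `DNAString`/1-element `DNAStringSet`.
#' @return data.frame with columns `position` (0-based) and `context`.
#' @examples
#' classify_cytosine_contexts("CCGG")   # position 0 CHG, position 1 CG
#' classify_cytosine_contexts("ACTTC")  # position 1 CHH, position 4 undetermined
#' @export
classify_cytosine_contexts <- function(reference) {
  bases <- as_base_vector(reference, "reference")
  n <- length(bases)
  pos <- which(bases == "C")
  h <- c("A", "C", "T")
  context <- vapply(pos, function(i) {
    b1 <- if (i + 1L <= n) bases[i + 1L] else NA_character_
    b2 <- if (i + 2L <= n) bases[i + 2L] else NA_character_
    if (is.na(b1)) return("undetermined")
    if (b1 == "G") return("CG")
    if (!(b1 %in% h)) return("undetermined")  # b1 == "N"
    if (is.na(b2)) return("undetermined")
    if (b2 == "G") return("CHG")
    if (b2 %in% h) return("CHH")
    "undetermined"                            # b2 == "N"
  }, "")
  data.frame(position = pos - 1L,
             context = factor(context, levels = cytosine_contexts()))
}

#' Call per-cytosine methylation from a bisulfite-converted clone
#'
#' Bisulfite treatment converts unmethylated cytosines to uracil (read as
#' T after PCR) and leaves methylated cytosines unchanged. Comparing a
#' clone sequence of bisulfite-converted DNA against the unconverted
#' reference therefore calls each reference C: clone C = methylated,
#' clone T = unmethylated, any other clone base = ambiguous (sequencing or
#' cloning artefact).
#'
#' Sequences must be pre-aligned and of equal length (gap-free): clones are
#' PCR amplicons of fixed loci, so no indel alignment is performed.
#'
#' @param reference unconverted reference sequence.
#' @param clone bisulfite-converted clone sequence of equal length.
#' @return data.frame with columns `position` (0-based), `context`,
#'   `state` (`methylated`/`unmethylated`/`ambiguous`).
#' @examples
#' call_methylation("ACGA", "ACGA")  # position 1, CG, methylated
#' call_methylation("ACGA", "ATGA")  # position 1, CG, unmethylated
#' @export
call_methylation <- function(reference, clone) {
  ref <- as_base_vector(reference, "reference")
  cl <- as_base_vector(clone, "clone")
  if (length(ref) != length(cl)) {
    stop("length mismatch: reference has ", length(ref),
         " bases, clone has ", length(cl))
  }
  ctx <- classify_cytosine_contexts(reference)
  clone_base <- cl[ctx$position + 1L]
  state <- ifelse(clone_base == "C", "methylated",
                  ifelse(clone_base == "T", "unmethylated", "ambiguous"))
  ctx$state <- factor(state,
                      levels = c("methylated", "unmethylated", "ambiguous"))
  ctx
}

#' Methylation percentage per context
#'
#' Computes 100 * (methylated cytosines) / (countable cytosines), overall
#' and per context. Countable cytosines exclude undetermined contexts and
#' ambiguous calls; both exclusions are reported. When calls from several
#' clones of the same locus are supplied, each clone-position occurrence
#' counts once.
#'
#' @param calls data.frame of cytosine calls, as from [call_methylation()]
#'   (possibly rbind-ed over clones).
#' @param by_context also report per-context strata (default `TRUE`).
#' @return object of class `bisulfite_summary`: a data.frame with columns
#'   `context` (including `"overall"`), `n_methylated`, `n_total`, `pct`,
#'   plus attributes `n_ambiguous` and `n_undetermined`.
#' @examples
#' ref <- "ACGACGTTCAA"
#' pct <- methylation_percentage(call_methylation(ref, "ACGATGTTTAA"))
#' @export
methylation_percentage <- function(calls, by_context = TRUE) {
  stopifnot(is.data.frame(calls),
            all(c("context", "state") %in% names(calls)))
  n_undetermined <- sum(calls$context == "undetermined")
  n_ambiguous <- sum(calls$state == "ambiguous" &
                       calls$context != "undetermined")
  countable <- calls$context != "undetermined" & calls$state != "ambiguous"
  kept <- calls[countable, , drop = FALSE]
  if (nrow(kept) == 0L) {
    stop("no countable cytosines (all undetermined or ambiguous)")
  }
  strata <- if (by_context) c("overall", c("CG", "CHG", "CHH")) else "overall"
  rows <- lapply(strata, function(s) {
    sub <- if (s == "overall") kept else kept[kept$context == s, , drop = FALSE]
    data.frame(context = s,
               n_methylated = sum(sub$state == "methylated"),
               n_total = nrow(sub),
               pct = if (nrow(sub) > 0L)
                 100 * sum(sub$state == "methylated") / nrow(sub) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, n_ambiguous = n_ambiguous, n_undetermined = n_undetermined,
            class = c("bisulfite_summary", "data.frame"))
}

#' @export
print.bisulfite_summary <- function(x, ...) {
  cat("Bisulfite methylation summary (excluded: ",
      attr(x, "n_ambiguous"), " ambiguous, ",
      attr(x, "n_undetermined"), " undetermined)\n", sep = "")
  df <- as.data.frame(x)
  df$pct <- sprintf("%.2f", df$pct)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Call methylation for clone FASTA files against a reference FASTA
#'
#' Reads one reference record and one or more clone records (Biostrings
#' FASTA I/O) and calls methylation for every clone. Clone record IDs carry
#' their provenance as `locus|sample|clone`; IDs without the pipes are kept
#' verbatim with `NA` sample/clone fields.
#'
#' @param ref_path FASTA with exactly one unconverted reference record.
#' @param clones_path FASTA with >= 1 bisulfite-converted clone records of
#'   the same length as the reference.
#' @return data.frame of per-cytosine calls with columns `locus`, `sample`,
#'   `clone`, `position`, `context`, `state`.
#' @export
bisulfite_calls_from_fasta <- function(ref_path, clones_path) {
  refs <- Biostrings::readDNAStringSet(ref_path)
  if (length(refs) != 1L) {
    stop("reference FASTA must contain exactly one record, found ",
         length(refs))
  }
  clones <- Biostrings::readDNAStringSet(clones_path)
  if (length(clones) == 0L) stop("clone FASTA contains no records")
  ref_seq <- as.character(refs[[1L]])
  ids <- names(clones)
  parts <- strsplit(ids, "|", fixed = TRUE)
  out <- lapply(seq_along(clones), function(i) {
    calls <- call_methylation(ref_seq, as.character(clones[[i]]))
    p <- parts[[i]]
    calls$locus <- if (length(p) >= 1L) p[1L] else ids[i]
    calls$sample <- if (length(p) >= 2L) p[2L] else NA_character_
    calls$clone <- if (length(p) >= 3L) p[3L] else NA_character_
    calls
  })
  out <- do.call(rbind, out)
  out[c("locus", "sample", "clone", "position", "context", "state")]
}
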