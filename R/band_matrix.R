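#' Band-observation matrix for an MSAP assay
#'
#' A `band_matrix` holds the central observation table of an MSAP
#' (methylation-sensitive amplified polymorphism) experiment: for every
#' locus and every sample, one presence bit per enzyme lane -- `hpa` for the
#' EcoRI/HpaII digest and `msp` for the EcoRI/MspI digest. A bit of 1 means
#' the fragment band was scored as present in that lane.
#'
#' Every (locus, sample) pair must carry exactly one observation. A missing
#' cell is an error, never an implicit absence: the double-absence pattern
#' (0,0) is itself a scored datum (MSAP band type IV) and must be recorded
#' explicitly.
#'
#' @param cells data.frame with columns `locus`, `sample`, `hpa`, `msp`.
#'   `hpa` and `msp` must be 0/1. Every locus x sample combination must
#'   appear exactly once.
#' @param metadata named list of free-form run metadata (primer combination,
#'   condition labels, simulation seed, ...).
#'
#' @return An object of class `band_matrix`: a list with elements `cells`
#'   (the validated observation data.frame), `loci`, `samples` (ordered
#'   unique identifiers) and `metadata`.
#' @examples
#' cells <- expand.grid(locus = c("L1", "L2"), sample = c("S1", "S2"),
#'                      stringsAsFactors = FALSE)
#' cells$hpa <- 1L; cells$msp <- 1L
#' band_matrix(cells)
#' @export
band_matrix <- function(cells, metadata = list()) {
  stopifnot(is.data.frame(cells))
  required <- c("locus", "sample", "hpa", "msp")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0L) {
    stop("cells is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  cells <- cells[required]
  cells$locus <- as.character(cells$locus)
  cells$sample <- as.character(cells$sample)
  for (col in c("hpa", "msp")) {
    v <- cells[[col]]
    if (!is.numeric(v) || anyNA(v) || !all(v %in% c(0, 1))) {
      bad <- which(is.na(v) | !(v %in% c(0, 1)))[1L]
      stop("column '", col, "' has a value outside {0,1} at row ", bad)
    }
    cells[[col]] <- as.integer(v)
  }
  x <- new_band_matrix(cells, metadata)
  findings <- validate_band_matrix(x, check_unobservable = FALSE)
  if (nrow(findings) > 0L) {
    stop("invalid band matrix:\n",
         paste(utils::capture.output(print(findings)), collapse = "\n"))
  }
  x
}

# low-level constructor, no validation (used by readers before checking)
new_band_matrix <- function(cells, metadata = list()) {
  structure(
    list(cells = cells,
         loci = unique(cells$locus),
         samples = unique(cells$sample),
         metadata = metadata),
    class = "band_matrix")
}

#' @export
print.band_matrix <- function(x, ...) {
  cat("MSAP band matrix: ", length(x$loci), " loci x ",
      length(x$samples), " samples\n", sep = "")
  cat("samples:", paste(x$samples, collapse = ", "), "\n")
  present <- sum(x$cells$hpa) + sum(x$cells$msp)
  cat("bands present: ", present, " of ", 2L * nrow(x$cells),
      " lane cells\n", sep = "")
  if (length(x$metadata) > 0L) {
    cat("metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Validate a band matrix without modifying it
#'
#' Checks the `band_matrix` invariants and returns findings as data rather
#' than raising errors, so callers can inspect all problems at once. Never
#' repairs anything.
#'
#' Findings emitted:
#' \describe{
#'   \item{`duplicate cell`}{a (locus, sample) pair observed more than once}
#'   \item{`missing cell`}{a (locus, sample) pair with no observation}
#'   \item{`unobservable locus`}{a locus absent (0,0) from every lane of
#'     every sample; such loci carry no information and are excluded from
#'     all scoring denominators}
#' }
#'
#' @param x a `band_matrix` (or an unchecked structure from a reader).
#' @param check_unobservable also flag loci never observed in any lane of
#'   any sample (default `TRUE`).
#' @return data.frame with columns `finding`, `locus`, `sample` (empty when
#'   all invariants hold).
#' @export
validate_band_matrix <- function(x, check_unobservable = TRUE) {
  stopifnot(inherits(x, "band_matrix"))
  cells <- x$cells
  findings <- list()

  key <- paste(cells$locus, cells$sample, sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0L) {
    parts <- strsplit(dup, "\r", fixed = TRUE)
    findings[[length(findings) + 1L]] <- data.frame(
      finding = "duplicate cell",
      locus = vapply(parts, `[`, "", 1L),
      sample = vapply(parts, `[`, "", 2L))
  }

  expected <- expand.grid(locus = x$loci, sample = x$samples,
                          stringsAsFactors = FALSE)
  expected_key <- paste(expected$locus, expected$sample, sep = "\r")
  miss <- expected[!(expected_key %in% key), , drop = FALSE]
  if (nrow(miss) > 0L) {
    findings[[length(findings) + 1L]] <- data.frame(
      finding = "missing cell", locus = miss$locus, sample = miss$sample)
  }

  if (check_unobservable) {
    band_per_locus <- tapply(cells$hpa + cells$msp, cells$locus, sum)
    unobs <- names(band_per_locus)[band_per_locus == 0L]
    if (length(unobs) > 0L) {
      findings[[length(findings) + 1L]] <- data.frame(
        finding = "unobservable locus", locus = unobs, sample = NA_character_)
    }
  }

  if (length(findings) == 0L) {
    return(data.frame(finding = character(), locus = character(),
                      sample = character()))
  }
  out <- do.call(rbind, findings)
  rownames(out) <- NULL
  out
}

#' Read a band matrix from tab-separated text
#'
#' The canonical ("long") dialect has the header
#' `locus_id<TAB>sample_id<TAB>hpaii<TAB>mspi` followed by one row per
#' (locus, sample) cell with 0/1 lane bits. A "wide" dialect -- one row per
#' locus, two columns `<sample>_hpaii` / `<sample>_mspi` per sample -- is
#' accepted on read for convenience but never written.
#'
#' @param path file path (or connection readable by [readLines()]).
#' @param dialect `"long"` (default) or `"wide"`.
#' @param metadata metadata list stored on the returned matrix.
#' @return a validated [band_matrix].
#' @export
read_band_matrix <- function(path, dialect = c("long", "wide"),
                             metadata = list()) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty band matrix file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (dialect == "long") {
    parse_long_band_matrix(fields, metadata)
  } else {
    parse_wide_band_matrix(fields, metadata)
  }
}

parse_long_band_matrix <- function(fields, metadata) {
  header <- fields[[1L]]
  expected_header <- c("locus_id", "sample_id", "hpaii", "mspi")
  if (!identical(header, expected_header)) {
    stop("expected header '", paste(expected_header, collapse = "\t"),
         "', got '", paste(header, collapse = "\t"), "'")
  }
  body <- fields[-1L]
  if (length(body) == 0L) {
    cells <- data.frame(locus = character(), sample = character(),
                        hpa = integer(), msp = integer())
    return(band_matrix(cells, metadata))
  }
  widths <- lengths(body)
  if (any(widths != 4L)) {
    bad <- which(widths != 4L)[1L]
    stop("ragged row at line ", bad + 1L, ": expected 4 fields, got ",
         widths[bad])
  }
  m <- do.call(rbind, body)
  for (col in 3:4) {
    ok <- m[, col] %in% c("0", "1")
    if (!all(ok)) {
      bad <- which(!ok)[1L]
      stop("value outside {0,1} at line ", bad + 1L, ": '", m[bad, col], "'")
    }
  }
  key <- paste(m[, 1L], m[, 2L], sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    pair <- strsplit(d, "\r", fixed = TRUE)[[1L]]
    stop("duplicate (locus, sample) row: (", pair[1L], ", ", pair[2L], ")")
  }
  cells <- data.frame(locus = m[, 1L], sample = m[, 2L],
                      hpa = as.integer(m[, 3L]), msp = as.integer(m[, 4L]))
  band_matrix(cells, metadata)
}

parse_wide_band_matrix <- function(fields, metadata) {
  header <- fields[[1L]]
  if (header[1L] != "locus_id" || length(header) < 3L ||
      (length(header) - 1L) %% 2L != 0L) {
    stop("wide dialect needs header 'locus_id' followed by ",
         "<sample>_hpaii/<sample>_mspi column pairs")
  }
  lane_cols <- header[-1L]
  hpa_cols <- grepl("_hpaii$", lane_cols)
  msp_cols <- grepl("_mspi$", lane_cols)
  if (!all(hpa_cols | msp_cols)) {
    stop("wide-dialect column '", lane_cols[which(!(hpa_cols | msp_cols))[1L]],
         "' does not end in _hpaii or _mspi")
  }
  samples_h <- sub("_hpaii$", "", lane_cols[hpa_cols])
  samples_m <- sub("_mspi$", "", lane_cols[msp_cols])
  if (!setequal(samples_h, samples_m)) {
    stop("wide dialect: hpaii and mspi columns name different samples")
  }
  body <- fields[-1L]
  widths <- lengths(body)
  if (any(widths != length(header))) {
    bad <- which(widths != length(header))[1L]
    stop("ragged row at line ", bad + 1L, ": expected ", length(header),
         " fields, got ", widths[bad])
  }
  m <- do.call(rbind, body)
  vals <- m[, -1L, drop = FALSE]
  ok <- vals %in% c("0", "1")
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop("value outside {0,1} in wide matrix body: '", vals[bad], "'")
  }
  loci <- m[, 1L]
  cells <- do.call(rbind, lapply(samples_h, function(s) {
    data.frame(locus = loci, sample = s,
               hpa = as.integer(m[, which(header == paste0(s, "_hpaii"))]),
               msp = as.integer(m[, which(header == paste0(s, "_mspi"))]))
  }))
  band_matrix(cells, metadata)
}

#' Write a band matrix in the canonical long dialect
#'
#' Emits UTF-8, LF-terminated, tab-separated text: the long-dialect header
#' then one row per cell sorted by (locus, sample). `read_band_matrix()`
#' round-trips this output exactly.
#'
#' @param x a [band_matrix].
#' @param path output file path.
#' @export
write_band_matrix <- function(x, path) {
  stopifnot(inherits(x, "band_matrix"))
  cells <- x$cells
  ord <- order(cells$locus, cells$sample, method = "radix")
  cells <- cells[ord, , drop = FALSE]
  lines <- c("locus_id\tsample_id\thpaii\tmspi",
             sprintf("%s\t%s\t%d\t%d", cells$locus, cells$sample,
                     cells$hpa, cells$msp))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(x)
}

#' Parse stage/condition sample labels
#'
#' Sample identifiers follow the convention `<stage><condition>` with stage
#' one of DB (dormant bud), ST (silver tip), GT (green tip), FS (initial
#' fruit set) and condition suffix H (high chill) or L (low chill), e.g.
#' `DBH`, `FSL`. Identifiers are free strings at the I/O layer; this parser
#' is applied only when a pipeline stage needs the design factors.
#'
#' @param samples character vector of sample identifiers.
#' @return data.frame with columns `sample`, `stage`, `condition`
#'   (`"high_chill"`/`"low_chill"`); `NA` for identifiers that do not follow
#'   the convention.
#' @examples
#' parse_sample_labels(c("DBH", "FSL", "control7"))
#' @export
parse_sample_labels <- function(samples) {
  samples <- as.character(samples)
  m <- regmatches(samples, regexec("^(DB|ST|GT|FS)(H|L)$", samples))
  stage <- vapply(m, function(g) if (length(g)) g[2L] else NA_character_, "")
  suffix <- vapply(m, function(g) if (length(g)) g[3L] else NA_character_, "")
  condition <- ifelse(is.na(suffix), NA_character_,
                      ifelse(suffix == "H", "high_chill", "low_chill"))
  data.frame(sample = samples, stage = stage, condition = condition)
}
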