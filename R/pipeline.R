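#' Run the full MSAP analysis pipeline from one configuration
#'
#' Orchestrates scoring, comparative pattern classification, association
#' tests and (optionally) bisulfite calling, then writes TSV tables and a
#' machine-readable JSON report with a provenance block (input paths and
#' MD5 checksums, configuration, seed, package version) from which every
#' reported number is recomputable.
#'
#' The configuration is a YAML file (or an equivalent named list) with
#' these keys, all paths relative to the config file's directory:
#' \describe{
#'   \item{`bands`}{path to a band-matrix TSV (long dialect). Enables
#'     per-sample scoring and, with `comparisons`, pattern analysis.}
#'   \item{`band_counts`}{path to a per-sample band-type count TSV
#'     (columns `sample`, `type_I`..`type_IV`), for count-level data such
#'     as published tables. Enables summaries, condition pooling and
#'     stage-wise chi-square tests when the sample labels parse.}
#'   \item{`pattern_counts`}{path to a per-class comparative count TSV
#'     (column `class` then one column per comparison). Enables comparison
#'     summaries and the event-count chi-square test.}
#'   \item{`comparisons`}{list of `{control, treatment}` pairs to classify
#'     from `bands`.}
#'   \item{`bisulfite`}{list with `ref` and `clones` FASTA paths.}
#'   \item{`seed`}{integer recorded in provenance and used for any
#'     randomized step.}
#' }
#' At least one of `bands`, `band_counts`, `pattern_counts` or `bisulfite`
#' must be present. Unknown samples in a comparison pair abort the run
#' before any output is written.
#'
#' Percentages are written at full precision in the JSON report; the TSV
#' tables round percentages to 1 decimal, chi-square statistics to 2 and
#' p-values to 3, the conventional reporting precision for MSAP tables.
#'
#' @param config path to a YAML configuration file, or a named list (then
#'   `base_dir` resolves relative paths).
#' @param out_dir output directory, created if needed (default: value of
#'   `out_dir` in the config, else a `msap_report` directory next to the
#'   config).
#' @param base_dir directory for resolving relative paths when `config` is
#'   a list (default: current directory).
#' @return an `analysis_report` list (invisibly): elements `summaries`,
#'   `summary_table`, `chisq`, `comparisons`, `event_table`,
#'   `bisulfite`, `provenance`, `files`.
#' @export
run_pipeline <- function(config, out_dir = NULL, base_dir = ".") {
  if (is.character(config) && length(config) == 1L) {
    config_path <- normalizePath(config, mustWork = TRUE)
    base_dir <- dirname(config_path)
    cfg <- yaml::read_yaml(config_path)
  } else if (is.list(config)) {
    config_path <- NA_character_
    cfg <- config
  } else {
    stop("config must be a YAML path or a named list")
  }
  known <- c("bands", "band_counts", "pattern_counts", "comparisons",
             "bisulfite", "seed", "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!any(c("bands", "band_counts", "pattern_counts", "bisulfite") %in%
           names(cfg))) {
    stop("config names no inputs (need bands, band_counts, ",
         "pattern_counts or bisulfite)")
  }
  if (is.null(out_dir)) {
    out_dir <- cfg$out_dir %||% file.path(base_dir, "msap_report")
  }
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) normalizePath(p) else
      normalizePath(file.path(base_dir, p), mustWork = TRUE)
  }
  seed <- as.integer(cfg$seed %||% 1L)

  inputs <- list()
  report <- list()

  # ---- load and validate everything before writing any output ----
  bands <- NULL
  if (!is.null(cfg$bands)) {
    inputs$bands <- resolve(cfg$bands)
    bands <- read_band_matrix(inputs$bands)
  }
  comparisons <- cfg$comparisons
  if (!is.null(comparisons)) {
    if (is.null(bands)) stop("'comparisons' requires 'bands'")
    for (cmp in comparisons) {
      for (s in c(cmp$control, cmp$treatment)) {
        if (!(s %in% bands$samples)) {
          stop("comparison names unknown sample '", s, "'")
        }
      }
    }
  }
  band_counts <- NULL
  if (!is.null(cfg$band_counts)) {
    inputs$band_counts <- resolve(cfg$band_counts)
    band_counts <- utils::read.delim(inputs$band_counts,
                                     stringsAsFactors = FALSE)
    needed <- c("sample", paste0("type_", band_types()))
    if (!all(needed %in% names(band_counts))) {
      stop("band_counts needs columns: ", paste(needed, collapse = ", "))
    }
  }
  pattern_counts <- NULL
  if (!is.null(cfg$pattern_counts)) {
    inputs$pattern_counts <- resolve(cfg$pattern_counts)
    pattern_counts <- utils::read.delim(inputs$pattern_counts,
                                        stringsAsFactors = FALSE,
                                        check.names = FALSE)
    if (names(pattern_counts)[1L] != "class" || ncol(pattern_counts) < 2L) {
      stop("pattern_counts needs a 'class' column plus comparison columns")
    }
  }
  if (!is.null(cfg$bisulfite)) {
    inputs$bisulfite_ref <- resolve(cfg$bisulfite$ref)
    inputs$bisulfite_clones <- resolve(cfg$bisulfite$clones)
  }

  # ---- per-sample summaries (from matrix and/or counts) ----
  summaries <- list()
  if (!is.null(bands)) summaries <- summarize_samples(bands)
  if (!is.null(band_counts)) {
    for (i in seq_len(nrow(band_counts))) {
      s <- band_counts$sample[i]
      summaries[[s]] <- methylation_summary(
        s, as.numeric(band_counts[i, paste0("type_", band_types())]))
    }
  }
  chisq_rows <- list()
  if (length(summaries) > 0L) {
    labels <- parse_sample_labels(names(summaries))
    for (cond in c("high_chill", "low_chill")) {
      members <- labels$sample[!is.na(labels$condition) &
                                 labels$condition == cond]
      if (length(members) > 0L) {
        summaries[[cond]] <- pool_summaries(summaries[members], cond)
      }
    }
    # stage-wise and pooled band-type x condition association tests
    if (!is.null(band_counts) &&
        !anyNA(parse_sample_labels(band_counts$sample)$stage)) {
      tabs <- stage_condition_tables(band_counts)
      chisq_rows <- lapply(names(tabs), function(nm) {
        r <- pearson_chi_square(tabs[[nm]])
        data.frame(table = nm, statistic = r$statistic, df = r$df,
                   p_value = r$p_value)
      })
    }
  }
  report$summaries <- summaries
  report$summary_table <- if (length(summaries) > 0L)
    summary_table(summaries) else NULL
  report$chisq <- if (length(chisq_rows) > 0L) {
    out <- do.call(rbind, chisq_rows); rownames(out) <- NULL; out
  } else NULL

  # ---- comparative patterns ----
  comp_summaries <- list()
  if (!is.null(comparisons)) {
    for (cmp in comparisons) {
      cs <- summarize_comparison(bands, cmp$control, cmp$treatment)
      comp_summaries[[paste0(cs$treatment_sample, "-vs-",
                             cs$control_sample)]] <- cs
    }
  }
  if (!is.null(pattern_counts)) {
    for (col in names(pattern_counts)[-1L]) {
      pair <- strsplit(col, "-vs-", fixed = TRUE)[[1L]]
      ctl <- if (length(pair) == 2L) pair[2L] else "control"
      trt <- if (length(pair) == 2L) pair[1L] else col
      comp_summaries[[col]] <- comparison_summary(
        ctl, trt, stats::setNames(pattern_counts[[col]],
                                  pattern_counts$class))
    }
  }
  report$comparisons <- comp_summaries
  report$event_table <- NULL
  if (length(comp_summaries) >= 2L) {
    ev <- event_counts_table(comp_summaries)
    report$event_table <- ev
    if (!isTRUE(attr(ev, "degenerate"))) {
      r <- pearson_chi_square(ev)
      report$event_chisq <- data.frame(table = "events", statistic = r$statistic,
                                       df = r$df, p_value = r$p_value)
    }
  }

  # ---- bisulfite ----
  report$bisulfite <- NULL
  if (!is.null(cfg$bisulfite)) {
    calls <- bisulfite_calls_from_fasta(inputs$bisulfite_ref,
                                        inputs$bisulfite_clones)
    per_sample <- lapply(split(calls, calls$sample), function(d) {
      s <- methylation_percentage(d)
      cbind(sample = d$sample[1L], as.data.frame(s),
            n_clones = length(unique(d$clone)))
    })
    bs <- do.call(rbind, per_sample)
    rownames(bs) <- NULL
    report$bisulfite <- bs
  }

  # ---- provenance and output ----
  checksums <- vapply(inputs, function(p) unname(tools::md5sum(p)), "")
  report$provenance <- list(
    config = config_path,
    inputs = inputs,
    md5 = as.list(checksums),
    seed = seed,
    package_version = as.character(utils::packageVersion("msapkit")))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  write_tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, path)
  }
  if (!is.null(report$summary_table)) {
    rendered <- summary_table(summaries, digits = 1L)
    write_tsv(rendered, "summary.tsv")
  }
  if (!is.null(report$chisq)) {
    ch <- report$chisq
    ch$statistic <- round(ch$statistic, 2L)
    ch$p_value <- round(ch$p_value, 3L)
    write_tsv(ch, "chisq.tsv")
  }
  if (length(comp_summaries) > 0L) {
    comp_df <- do.call(rbind, lapply(names(comp_summaries), function(nm) {
      cs <- comp_summaries[[nm]]
      data.frame(comparison = nm,
                 group = c(rep(pattern_groups(),
                               times = c(4L, 6L, 6L)), pattern_groups()),
                 class = c(pattern_classes()$code, rep(NA_character_, 3L)),
                 count = c(unname(cs$n_class), unname(cs$n_group)),
                 pct = c(rep(NA_real_, 16L), round(unname(cs$pct_group), 1L)))
    }))
    write_tsv(comp_df, "comparisons.tsv")
  }
  if (!is.null(report$bisulfite)) {
    bs <- report$bisulfite
    bs$pct <- round(bs$pct, 2L)
    write_tsv(bs, "bisulfite.tsv")
  }
  json_report <- list(
    summary = report$summary_table,
    chisq = report$chisq,
    comparisons = lapply(comp_summaries, function(cs) {
      list(control = cs$control_sample, treatment = cs$treatment_sample,
           n_class = as.list(cs$n_class), n_group = as.list(cs$n_group),
           n_total = cs$n_total, pct_group = as.list(cs$pct_group))
    }),
    event_chisq = report$event_chisq,
    bisulfite = report$bisulfite,
    provenance = report$provenance)
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(json_report, report_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  files <- c(files, report_path)
  report$files <- files

  message("msapkit pipeline: wrote ", length(files), " file(s) to ", out_dir)
  invisible(structure(report, class = "analysis_report"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.analysis_report <- function(x, ...) {
  cat("MSAP analysis report\n")
  if (!is.null(x$summary_table)) {
    cat("  samples/pools summarized:", nrow(x$summary_table), "\n")
  }
  if (!is.null(x$chisq)) cat("  chi-square tests:", nrow(x$chisq), "\n")
  if (length(x$comparisons) > 0L) {
    cat("  comparisons:", paste(names(x$comparisons), collapse = ", "), "\n")
  }
  if (!is.null(x$bisulfite)) {
    cat("  bisulfite samples:", length(unique(x$bisulfite$sample)), "\n")
  }
  cat("  outputs:\n")
  for (f in x$files) cat("    ", f, "\n", sep = "")
  invisible(x)
}
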