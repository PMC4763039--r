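#' Methylation states of a 5'-CCGG-3' site
#'
#' The simulator's ground-truth alphabet for one restriction site:
#' \describe{
#'   \item{U}{unmethylated on both strands}
#'   \item{HM_ext}{hemi-methylated, external cytosine on one strand}
#'   \item{HM_int}{hemi-methylated, internal cytosine on one strand}
#'   \item{FM_int}{internal cytosine methylated on both strands}
#'   \item{X}{external (or both) cytosines methylated on both strands}
#' }
#' HM_int produces the same digestion pattern as U (both enzymes cut), so
#' MSAP cannot distinguish them; it exists so tests can demonstrate that
#' blind spot and defaults to probability 0 in configurations.
#'
#' @return character vector of the five state codes.
#' @export
methylation_states <- function() c("U", "HM_ext", "HM_int", "FM_int", "X")

#' Isoschizomer digestion pattern of a methylation state
#'
#' Encodes the differential methylation sensitivity of the HpaII/MspI
#' isoschizomer pair at CCGG. HpaII cuts unmethylated and hemi-methylated
#' sites but is blocked by full (double-strand) methylation. MspI cuts when
#' the internal cytosine is methylated (hemi or full, C^5mCGG) but is
#' blocked by external-cytosine methylation (^5mCCGG). A band is present in
#' a lane iff the enzyme cuts.
#'
#' State to (hpa, msp): U -> (1,1); HM_ext -> (1,0); HM_int -> (1,1);
#' FM_int -> (0,1); X -> (0,0).
#'
#' @param state character vector over [methylation_states()].
#' @return data.frame with 0/1 columns `hpa` and `msp`.
#' @examples
#' digestion_pattern(methylation_states())
#' @export
digestion_pattern <- function(state) {
  truth <- data.frame(
    state = methylation_states(),
    hpa = c(1L, 1L, 1L, 0L, 0L),
    msp = c(1L, 0L, 1L, 1L, 0L))
  i <- match(state, truth$state)
  if (anyNA(i)) {
    stop("unknown methylation state: ",
         paste(unique(state[is.na(i)]), collapse = ", "))
  }
  data.frame(hpa = truth$hpa[i], msp = truth$msp[i])
}

#' Configuration for MSAP simulation
#'
#' Defaults reflect the study conditions the package targets: the state
#' probabilities default to the high-chill dormant-bud methylation profile
#' (scored fractions 444/610 unmethylated, 33/610 external-hemi, 50/610
#' internal-full, 83/610 hyper-methylated, HM_int 0 because the assay
#' cannot resolve it) and `band_noise` defaults to 0, as no empirical
#' scoring-error rate is available to calibrate it.
#'
#' @param n_loci number of simulated loci.
#' @param samples character vector of sample identifiers.
#' @param state_probs probability vector over the five
#'   [methylation_states()] (recycled to every sample), or a matrix with
#'   one row per sample. Each row must sum to 1 within 1e-9.
#' @param band_noise probability of flipping each emitted presence bit,
#'   independently per lane (symmetric presence/absence error).
#' @param seed integer master seed; per-sample substreams are derived from
#'   it so adding samples never perturbs existing draws.
#' @return list of class `msap_sim_config`.
#' @export
msap_sim_config <- function(n_loci = 610L,
                            samples = "S1",
                            state_probs = c(U = 444, HM_ext = 33, HM_int = 0,
                                            FM_int = 50, X = 83) / 610,
                            band_noise = 0,
                            seed = 1L) {
  stopifnot(n_loci >= 1L, length(samples) >= 1L, !anyDuplicated(samples))
  if (is.null(dim(state_probs))) {
    state_probs <- matrix(state_probs, nrow = length(samples),
                          ncol = length(state_probs), byrow = TRUE)
  }
  if (ncol(state_probs) != 5L || nrow(state_probs) != length(samples)) {
    stop("state_probs must have 5 state columns and one row per sample")
  }
  colnames(state_probs) <- methylation_states()
  rownames(state_probs) <- samples
  if (any(state_probs < 0) || any(state_probs > 1)) {
    stop("state probabilities must lie in [0,1]")
  }
  if (any(abs(rowSums(state_probs) - 1) > 1e-9)) {
    stop("each state_probs row must sum to 1 (within 1e-9)")
  }
  if (band_noise < 0 || band_noise > 1) stop("band_noise must lie in [0,1]")
  structure(
    list(n_loci = as.integer(n_loci), samples = as.character(samples),
         state_probs = state_probs, band_noise = band_noise,
         seed = as.integer(seed)),
    class = "msap_sim_config")
}

# Deterministic per-(seed, index) substream seed, kept inside 32-bit range.
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483647)
}

with_preserved_rng <- function(expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  expr
}

#' Simulate an MSAP band matrix with known ground truth
#'
#' For every locus and sample, draws a methylation state from the sample's
#' state probabilities, emits the deterministic digestion pattern of that
#' state, then flips each presence bit independently with probability
#' `band_noise`. Fully reproducible from the config seed; each sample uses
#' its own derived substream, so extending the sample list leaves earlier
#' samples' draws unchanged.
#'
#' @param config an [msap_sim_config].
#' @return list with `bands` (a [band_matrix]; metadata records the seed
#'   and noise) and `truth` (data.frame `locus`, `sample`, `state`).
#' @examples
#' sim <- simulate_msap(msap_sim_config(n_loci = 50, seed = 7))
#' summarize_sample(sim$bands, "S1")
#' @export
simulate_msap <- function(config) {
  stopifnot(inherits(config, "msap_sim_config"))
  loci <- sprintf("L%05d", seq_len(config$n_loci))
  states <- methylation_states()
  with_preserved_rng({
    per_sample <- lapply(seq_along(config$samples), function(j) {
      set.seed(substream_seed(config$seed, j))
      s <- config$samples[j]
      st <- sample(states, config$n_loci, replace = TRUE,
                   prob = config$state_probs[s, ])
      bits <- digestion_pattern(st)
      if (config$band_noise > 0) {
        flip_h <- stats::runif(config$n_loci) < config$band_noise
        flip_m <- stats::runif(config$n_loci) < config$band_noise
        bits$hpa <- ifelse(flip_h, 1L - bits$hpa, bits$hpa)
        bits$msp <- ifelse(flip_m, 1L - bits$msp, bits$msp)
      }
      list(cells = data.frame(locus = loci, sample = s,
                              hpa = bits$hpa, msp = bits$msp),
           truth = data.frame(locus = loci, sample = s, state = st))
    })
    cells <- do.call(rbind, lapply(per_sample, `[[`, "cells"))
    truth <- do.call(rbind, lapply(per_sample, `[[`, "truth"))
    list(bands = band_matrix(cells,
                             metadata = list(seed = config$seed,
                                             band_noise = config$band_noise,
                                             generator = "simulate_msap")),
         truth = truth)
  })
}

#' Configuration for bisulfite-conversion simulation
#'
#' Defaults describe a typical cloned MSAP amplicon: 300 bp (the study's
#' fragments run 62-307 bp), GC content 0.45, per-context methylation
#' probabilities of 0.8 (CG), 0.3 (CHG) and 0.05 (CHH) -- the usual plant
#' gene-body ordering CG > CHG > CHH -- and complete bisulfite conversion
#' (efficiency 1.0), since conversion efficiency is a nuisance parameter
#' exposed for study rather than estimated.
#'
#' @param locus_length reference length in bases.
#' @param gc GC content of the random reference, in \[0,1\].
#' @param context_probs named probabilities of methylation for a cytosine
#'   in each classifiable context (`CG`, `CHG`, `CHH`).
#' @param conversion probability that an unmethylated C is converted (read
#'   as T) in a clone; methylated Cs are never converted.
#' @param n_clones clones emitted per sample.
#' @param samples sample identifiers.
#' @param locus locus identifier used in FASTA record names.
#' @param seed integer master seed.
#' @return list of class `bisulfite_sim_config`.
#' @export
bisulfite_sim_config <- function(locus_length = 300L,
                                 gc = 0.45,
                                 context_probs = c(CG = 0.8, CHG = 0.3,
                                                   CHH = 0.05),
                                 conversion = 1.0,
                                 n_clones = 1L,
                                 samples = "S1",
                                 locus = "locus1",
                                 seed = 1L) {
  stopifnot(locus_length >= 3L, gc >= 0, gc <= 1, n_clones >= 1L,
            length(samples) >= 1L, !anyDuplicated(samples))
  if (!all(c("CG", "CHG", "CHH") %in% names(context_probs))) {
    stop("context_probs must name CG, CHG and CHH")
  }
  if (any(context_probs < 0 | context_probs > 1) ||
      conversion < 0 || conversion > 1) {
    stop("probabilities must lie in [0,1]")
  }
  structure(
    list(locus_length = as.integer(locus_length), gc = gc,
         context_probs = context_probs[c("CG", "CHG", "CHH")],
         conversion = conversion, n_clones = as.integer(n_clones),
         samples = as.character(samples), locus = as.character(locus),
         seed = as.integer(seed)),
    class = "bisulfite_sim_config")
}

#' Simulate a reference locus and bisulfite-converted clones
#'
#' Generates a random reference of the configured length and GC content,
#' assigns each classifiable cytosine (CG/CHG/CHH context) a methylated
#' flag with its context's probability, then emits clones: a methylated C
#' always reads C; an unmethylated C reads T with probability equal to the
#' conversion efficiency (else it reads C, mimicking incomplete
#' conversion). Cytosines with undetermined context are treated as
#' unmethylated. Reproducible from the seed; clones of different samples
#' use derived substreams.
#'
#' @param config a [bisulfite_sim_config].
#' @return list with `reference` (1-record `DNAStringSet` named by locus),
#'   `clones` (`DNAStringSet`, records named `locus|sample|cloneN`) and
#'   `truth` (data.frame `position` 0-based, `context`, `methylated` for
#'   every classifiable-context cytosine).
#' @export
simulate_bisulfite <- function(config) {
  stopifnot(inherits(config, "bisulfite_sim_config"))
  with_preserved_rng({
    set.seed(substream_seed(config$seed, 0L))
    p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
           G = config$gc / 2, T = (1 - config$gc) / 2)
    ref_bases <- sample(names(p), config$locus_length, replace = TRUE,
                        prob = p)
    reference <- paste(ref_bases, collapse = "")
    ctx <- classify_cytosine_contexts(reference)
    classifiable <- ctx[ctx$context != "undetermined", , drop = FALSE]
    meth <- stats::runif(nrow(classifiable)) <
      config$context_probs[as.character(classifiable$context)]
    truth <- data.frame(position = classifiable$position,
                        context = classifiable$context,
                        methylated = meth)
    meth_pos <- truth$position[truth$methylated] + 1L
    unmeth_pos <- setdiff(which(ref_bases == "C"), meth_pos)

    clone_seqs <- character(0)
    clone_ids <- character(0)
    for (j in seq_along(config$samples)) {
      set.seed(substream_seed(config$seed, j))
      for (k in seq_len(config$n_clones)) {
        cl <- ref_bases
        converted <- stats::runif(length(unmeth_pos)) < config$conversion
        cl[unmeth_pos[converted]] <- "T"
        clone_seqs <- c(clone_seqs, paste(cl, collapse = ""))
        clone_ids <- c(clone_ids, paste(config$locus, config$samples[j],
                                        paste0("clone", k), sep = "|"))
      }
    }
    ref_set <- Biostrings::DNAStringSet(stats::setNames(reference,
                                                        config$locus))
    clone_set <- Biostrings::DNAStringSet(stats::setNames(clone_seqs,
                                                          clone_ids))
    list(reference = ref_set, clones = clone_set, truth = truth)
  })
}

#' Write a simulated bisulfite data set as FASTA
#'
#' @param sim result of [simulate_bisulfite()].
#' @param ref_path,clones_path output FASTA paths.
#' @export
write_bisulfite_fasta <- function(sim, ref_path, clones_path) {
  Biostrings::writeXStringSet(sim$reference, ref_path)
  Biostrings::writeXStringSet(sim$clones, clones_path)
  invisible(sim)
}
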