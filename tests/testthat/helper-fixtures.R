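# Shared helpers: random matrices for property tests and the packaged
# count tables in convenient shapes.

random_band_matrix <- function(n_loci = 40, samples = c("S1", "S2"),
                               seed = 1) {
  cfg <- msap_sim_config(
    n_loci = n_loci, samples = samples,
    state_probs = c(U = 0.5, HM_ext = 0.15, HM_int = 0, FM_int = 0.2,
                    X = 0.15),
    band_noise = 0, seed = seed)
  simulate_msap(cfg)$bands
}

band_counts_list <- function() {
  counts <- apple_band_counts()
  out <- lapply(seq_len(nrow(counts)), function(i) {
    as.numeric(counts[i, paste0("type_", band_types())])
  })
  names(out) <- counts$sample
  out
}

sample_summaries <- function() {
  cl <- band_counts_list()
  mapply(methylation_summary, names(cl), cl, SIMPLIFY = FALSE)
}

pattern_counts_list <- function() {
  pat <- apple_pattern_counts()
  out <- lapply(names(pat)[-1], function(col) {
    stats::setNames(pat[[col]], pat$class)
  })
  names(out) <- names(pat)[-1]
  out
}
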