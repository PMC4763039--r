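test_that("digestion patterns encode the isoschizomer sensitivity rules", {
  d <- digestion_pattern(methylation_states())
  expect_equal(d$hpa, c(1L, 1L, 1L, 0L, 0L))
  expect_equal(d$msp, c(1L, 0L, 1L, 1L, 0L))
  # downstream scoring: U -> I, HM_ext -> II, FM_int -> III, X -> IV;
  # HM_int is the assay's blind spot (scores I, like U)
  types <- classify_band_type(d$hpa, d$msp, TRUE)
  expect_equal(types, c("I", "II", "I", "III", "IV"))
  expect_error(digestion_pattern("half"), "unknown methylation state")
})

test_that("simulation is reproducible and sample substreams are stable", {
  cfg <- msap_sim_config(n_loci = 80, samples = c("A", "B"), seed = 5)
  s1 <- simulate_msap(cfg)
  s2 <- simulate_msap(cfg)
  expect_identical(s1$bands$cells, s2$bands$cells)
  expect_identical(s1$truth, s2$truth)
  # adding a sample does not perturb draws of existing samples
  cfg3 <- msap_sim_config(n_loci = 80, samples = c("A", "B", "C"), seed = 5)
  s3 <- simulate_msap(cfg3)
  expect_identical(s3$truth[s3$truth$sample %in% c("A", "B"), ], s1$truth)
})

test_that("invalid simulation configs are rejected", {
  expect_error(msap_sim_config(state_probs = c(.5, .5, 0, 0, .1)),
               "sum to 1")
  expect_error(msap_sim_config(state_probs = c(1.2, -.2, 0, 0, 0)),
               "\\[0,1\\]")
  expect_error(msap_sim_config(band_noise = 1.5), "band_noise")
  expect_error(bisulfite_sim_config(conversion = -0.1), "\\[0,1\\]")
  expect_error(bisulfite_sim_config(context_probs = c(CG = 1)), "CHG")
})

test_that("a degenerate unmethylated simulation scores 0% methylation", {
  cfg <- msap_sim_config(n_loci = 50,
                         state_probs = c(1, 0, 0, 0, 0), seed = 2)
  sim <- simulate_msap(cfg)
  expect_true(all(sim$bands$cells$hpa == 1L & sim$bands$cells$msp == 1L))
  s <- summarize_sample(sim$bands, "S1")
  expect_equal(s$pct_total_methylation, 0)
})

test_that("noise-free scoring recovers the simulated truth cell by cell", {
  # first sample all-unmethylated so every locus is observed somewhere
  probs <- rbind(c(1, 0, 0, 0, 0),
                 c(.727, .054, 0, .082, .137),
                 c(.6, .1, 0, .15, .15))
  cfg <- msap_sim_config(n_loci = 800, samples = c("REF", "S1", "S2"),
                         state_probs = probs, band_noise = 0, seed = 17)
  sim <- simulate_msap(cfg)
  scored <- score_band_matrix(sim$bands)
  merged <- merge(scored, sim$truth, by = c("locus", "sample"))
  map <- c(U = "I", HM_ext = "II", HM_int = "I", FM_int = "III", X = "IV")
  expect_false(any(merged$excluded))
  expect_equal(merged$band_type, unname(map[merged$state]))
  # per-sample counts equal truth state counts exactly
  for (s in c("S1", "S2")) {
    truth_counts <- table(factor(unname(map[sim$truth$state[
      sim$truth$sample == s]]), levels = band_types()))
    expect_equal(unname(summarize_sample(sim$bands, s)$n_type),
                 as.integer(truth_counts))
  }
})

test_that("band noise misclassifies at the analytic bit-flip rate", {
  p <- 0.1
  probs <- rbind(c(1, 0, 0, 0, 0), c(.727, .054, 0, .082, .137))
  cfg <- msap_sim_config(n_loci = 10000, samples = c("REF", "S1"),
                         state_probs = probs, band_noise = p, seed = 23)
  sim <- simulate_msap(cfg)
  scored <- score_band_matrix(sim$bands)
  merged <- merge(scored[scored$sample == "S1" & !scored$excluded, ],
                  sim$truth[sim$truth$sample == "S1", ],
                  by = c("locus", "sample"))
  map <- c(U = "I", HM_ext = "II", HM_int = "I", FM_int = "III", X = "IV")
  mis_rate <- mean(merged$band_type != unname(map[merged$state]))
  expected <- 1 - (1 - p)^2   # any lane flip changes the scored type
  se <- sqrt(expected * (1 - expected) / nrow(merged))
  expect_lt(abs(mis_rate - expected), 4 * se)
})

test_that("simulated type proportions approach the dormant-bud profile", {
  # default state_probs encode the high-chill dormant-bud fractions
  cfg <- msap_sim_config(n_loci = 610, samples = c("REF", "DBH"),
                         state_probs = rbind(c(1, 0, 0, 0, 0),
                                             c(444, 33, 0, 50, 83) / 610),
                         seed = 29)
  sim <- simulate_msap(cfg)
  s <- summarize_sample(sim$bands, "DBH")
  target <- c(444, 33, 50, 83) / 610
  for (i in 1:4) {
    se <- sqrt(target[i] * (1 - target[i]) / 610)
    expect_lt(abs(s$n_type[[i]] / s$n_total - target[i]), 4 * se)
  }
})

test_that("injected transition rates surface as comparison group rates", {
  # control unmethylated everywhere; treatment moves 10% of loci into
  # methylated states, so the methylation-event group rate must be ~10%
  probs <- rbind(c(1, 0, 0, 0, 0),
                 c(.9, .05, 0, .03, .02))
  cfg <- msap_sim_config(n_loci = 5000, samples = c("CTL", "TRT"),
                         state_probs = probs, seed = 37)
  sim <- simulate_msap(cfg)
  cs <- summarize_comparison(sim$bands, "CTL", "TRT")
  p_meth <- cs$pct_group[["methylation"]] / 100
  se <- sqrt(0.1 * 0.9 / 5000)
  expect_lt(abs(p_meth - 0.1), 4 * se)
  expect_equal(cs$pct_group[["demethylation"]], 0)
})
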