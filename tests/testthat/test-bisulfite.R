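test_that("cytosine contexts follow the CG/CHG/CHH definitions", {
  ccgg <- classify_cytosine_contexts("CCGG")
  expect_equal(ccgg$position, c(0L, 1L))
  expect_equal(as.character(ccgg$context), c("CHG", "CG"))

  acttc <- classify_cytosine_contexts("ACTTC")
  expect_equal(acttc$position, c(1L, 4L))
  expect_equal(as.character(acttc$context), c("CHH", "undetermined"))

  acgt <- classify_cytosine_contexts("ACGT")
  expect_equal(acgt$position, 1L)
  expect_equal(as.character(acgt$context), "CG")

  # N in the context window -> undetermined; CG needs only one base
  expect_equal(as.character(classify_cytosine_contexts("CNG")$context),
               "undetermined")
  expect_equal(as.character(classify_cytosine_contexts("CANA")$context[1]),
               "undetermined")
  expect_equal(as.character(classify_cytosine_contexts("CG")$context), "CG")

  expect_error(classify_cytosine_contexts("ACXG"), "position 2")
})

test_that("context counts partition the reference cytosines", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(3:80, 1)
    seq <- paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
                        prob = c(.24, .24, .24, .24, .04)), collapse = "")
    ctx <- classify_cytosine_contexts(seq)
    n_c <- sum(strsplit(seq, "")[[1]] == "C")
    expect_equal(nrow(ctx), n_c)
    expect_equal(sum(table(ctx$context)), n_c)
  }
})

test_that("bisulfite comparison calls methylated/unmethylated/ambiguous", {
  expect_equal(as.character(call_methylation("ACGA", "ACGA")$state),
               "methylated")
  expect_equal(as.character(call_methylation("ACGA", "ATGA")$state),
               "unmethylated")
  expect_equal(as.character(call_methylation("ACGA", "AGGA")$state),
               "ambiguous")
  expect_error(call_methylation("ACGA", "ACG"), "length mismatch")
})

test_that("methylation percentage implements methylated/total x 100", {
  calls <- data.frame(
    position = 0:34,
    context = factor(rep("CG", 35), levels = cytosine_contexts()),
    state = factor(c(rep("methylated", 3), rep("unmethylated", 32)),
                   levels = c("methylated", "unmethylated", "ambiguous")))
  s <- methylation_percentage(calls)
  expect_equal(round(s$pct[s$context == "overall"], 2), 8.57)

  calls$state[2:3] <- "unmethylated"   # 1 of 35
  s1 <- methylation_percentage(calls)
  expect_lt(abs(s1$pct[s1$context == "overall"] - 2.85), 0.01)

  calls$state[1] <- "unmethylated"     # 0 methylated
  s0 <- methylation_percentage(calls)
  expect_equal(s0$pct[s0$context == "overall"], 0)

  # undetermined contexts and ambiguous calls leave numerator AND denominator
  calls$context[1:5] <- "undetermined"
  calls$state[6] <- "ambiguous"
  s2 <- methylation_percentage(calls)
  expect_equal(s2$n_total[s2$context == "overall"], 29)
  expect_equal(attr(s2, "n_undetermined"), 5)
  expect_equal(attr(s2, "n_ambiguous"), 1)

  calls$context <- "undetermined"
  expect_error(methylation_percentage(calls), "no countable cytosines")
})

test_that("fully converted and unconverted clones bound the percentage", {
  cfg <- bisulfite_sim_config(locus_length = 400, conversion = 1,
                              context_probs = c(CG = 0, CHG = 0, CHH = 0),
                              seed = 8)
  sim <- simulate_bisulfite(cfg)
  ref <- as.character(sim$reference[[1]])
  calls <- call_methylation(ref, as.character(sim$clones[[1]]))
  s <- methylation_percentage(calls)
  expect_equal(s$pct[s$context == "overall"], 0)

  # a completely unconverted clone is the reference itself -> 100%
  s100 <- methylation_percentage(call_methylation(ref, ref))
  expect_equal(s100$pct[s100$context == "overall"], 100)
})

test_that("FASTA round trip carries locus|sample|clone provenance", {
  cfg <- bisulfite_sim_config(locus_length = 200, n_clones = 2,
                              samples = c("DBH", "DBL"), seed = 4)
  sim <- simulate_bisulfite(cfg)
  ref_fa <- withr::local_tempfile(fileext = ".fa")
  clones_fa <- withr::local_tempfile(fileext = ".fa")
  write_bisulfite_fasta(sim, ref_fa, clones_fa)
  calls <- bisulfite_calls_from_fasta(ref_fa, clones_fa)
  expect_setequal(unique(calls$sample), c("DBH", "DBL"))
  expect_setequal(unique(calls$clone), c("clone1", "clone2"))
  expect_equal(unique(calls$locus), "locus1")
  # against a fully-converted data set with nonzero context probabilities,
  # truth methylated positions are exactly the clone-C calls
  truth_m <- sort(sim$truth$position[sim$truth$methylated])
  called_m <- sort(unique(calls$position[calls$state == "methylated"]))
  expect_equal(called_m, truth_m)
})

test_that("per-context recovery approaches the injected probabilities", {
  probs <- c(CG = 0.8, CHG = 0.3, CHH = 0.05)
  cfg <- bisulfite_sim_config(locus_length = 2000, context_probs = probs,
                              conversion = 1, n_clones = 200, seed = 31)
  sim <- simulate_bisulfite(cfg)
  ref <- as.character(sim$reference[[1]])
  calls <- do.call(rbind, lapply(seq_along(sim$clones), function(i) {
    call_methylation(ref, as.character(sim$clones[[i]]))
  }))
  s <- methylation_percentage(calls)
  for (ctx in names(probs)) {
    est <- s$pct[s$context == ctx] / 100
    n_sites <- sum(sim$truth$context == ctx)
    se <- sqrt(probs[[ctx]] * (1 - probs[[ctx]]) / n_sites)
    expect_lt(abs(est - probs[[ctx]]), 3 * se)
  }
  # truth covers exactly the classifiable-context cytosines
  ctx_ref <- classify_cytosine_contexts(ref)
  expect_equal(sim$truth$position,
               ctx_ref$position[ctx_ref$context != "undetermined"])
})
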