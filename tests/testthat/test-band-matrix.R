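test_that("long-dialect TSV round-trips through write and read", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus_id\tsample_id\thpaii\tmspi",
               "L1\tS1\t1\t1", "L2\tS1\t1\t1"), f)
  m <- read_band_matrix(f)
  expect_s3_class(m, "band_matrix")
  expect_equal(sort(m$loci), c("L1", "L2"))
  expect_equal(m$samples, "S1")
  expect_true(all(m$cells$hpa == 1L & m$cells$msp == 1L))

  # write-read identity on randomly generated matrices, several seeds
  for (seed in 1:4) {
    m <- random_band_matrix(n_loci = 25, samples = c("A", "B", "C"),
                            seed = seed)
    out <- withr::local_tempfile(fileext = ".tsv")
    write_band_matrix(m, out)
    m2 <- read_band_matrix(out)
    ord <- function(d) d[order(d$locus, d$sample), c("locus", "sample",
                                                     "hpa", "msp")]
    expect_equal(unname(as.matrix(ord(m2$cells))),
                 unname(as.matrix(ord(m$cells))))
    # read-write identity: a second round trip is byte-identical
    out2 <- withr::local_tempfile(fileext = ".tsv")
    write_band_matrix(m2, out2)
    expect_identical(readLines(out2), readLines(out))
  }
})

test_that("malformed band-matrix files fail with precise errors", {
  write_lines <- function(...) {
    f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
    writeLines(c(...), f)
    f
  }
  expect_error(
    read_band_matrix(write_lines("locus_id\tsample_id\thpaii\tmspi",
                                 "L1\tS1\t2\t0")),
    "outside \\{0,1\\}.*line 2")
  expect_error(
    read_band_matrix(write_lines("locus_id\tsample_id\thpaii\tmspi",
                                 "L1\tS1\t1\t0", "L1\tS1\t0\t0")),
    "duplicate \\(locus, sample\\) row: \\(L1, S1\\)")
  expect_error(
    read_band_matrix(write_lines("locus_id\tsample_id\thpaii\tmspi",
                                 "L1\tS1\t1")),
    "ragged row at line 2")
  expect_error(
    read_band_matrix(write_lines("locus\tsample\thpa\tmsp", "L1\tS1\t1\t1")),
    "expected header")
})

test_that("writing an empty matrix yields a header-only file", {
  m <- band_matrix(data.frame(locus = character(), sample = character(),
                              hpa = integer(), msp = integer()))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_band_matrix(m, f)
  expect_identical(readLines(f), "locus_id\tsample_id\thpaii\tmspi")
})

test_that("wide dialect is accepted on read and agrees with long form", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus_id\tS1_hpaii\tS1_mspi\tS2_hpaii\tS2_mspi",
               "L1\t1\t1\t0\t1",
               "L2\t1\t0\t0\t0"), f)
  m <- read_band_matrix(f, dialect = "wide")
  expect_setequal(m$samples, c("S1", "S2"))
  cell <- function(l, s) m$cells[m$cells$locus == l & m$cells$sample == s, ]
  expect_equal(cell("L1", "S2")[, c("hpa", "msp")],
               data.frame(hpa = 0L, msp = 1L), ignore_attr = TRUE)
  expect_equal(cell("L2", "S2")[, c("hpa", "msp")],
               data.frame(hpa = 0L, msp = 0L), ignore_attr = TRUE)
})

test_that("validation reports findings as data and never mutates", {
  # no X state, so every locus leaves a band in at least one lane
  m <- simulate_msap(msap_sim_config(
    n_loci = 40, samples = c("S1", "S2"),
    state_probs = c(.6, .2, 0, .2, 0), seed = 9))$bands
  before <- m$cells
  expect_equal(nrow(validate_band_matrix(m)), 0L)
  expect_identical(m$cells, before)

  # a locus absent from every lane of every sample is flagged, not repaired
  cells <- expand.grid(locus = c("L1", "L2"), sample = c("S1", "S2"),
                       stringsAsFactors = FALSE)
  cells$hpa <- ifelse(cells$locus == "L1", 1L, 0L)
  cells$msp <- 0L
  m2 <- band_matrix(cells)
  f <- validate_band_matrix(m2)
  expect_equal(f$finding, "unobservable locus")
  expect_equal(f$locus, "L2")

  # a missing cell is an error at construction (absence is data, type IV)
  expect_error(band_matrix(cells[-1, ]), "invalid band matrix")
})

test_that("sample labels parse stage and condition by suffix convention", {
  lab <- parse_sample_labels(c("DBH", "DBL", "STH", "FSL", "GTX", "ref"))
  expect_equal(lab$stage[1:4], c("DB", "DB", "ST", "FS"))
  expect_equal(lab$condition[1:4],
               c("high_chill", "low_chill", "high_chill", "low_chill"))
  expect_true(all(is.na(lab$stage[5:6])))
})
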