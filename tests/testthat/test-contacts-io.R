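test_that("long-format contact lists read back identically", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t100\tchr1\t20000100\t1",
               "chr1\t500\tchr2\t900\t2",
               "chr2\t100\tchr2\t600000\t3"), path)
  rec <- read_contacts(path, "long_tsv")
  expect_equal(nrow(rec), 3)
  expect_equal(sum(rec$count), 6)
  expect_equal(rec$chrom2, c("chr1", "chr2", "chr2"))
})

test_that("malformed lines and negative counts are rejected with context", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t100\tchr1\t20000100\t1", "chr1\t100\tchr1"), path)
  expect_error(read_contacts(path, "long_tsv"), "line 2")
  writeLines(c("chr1\t100\tchr1\t20000100\t-1"), path)
  expect_error(read_contacts(path, "long_tsv"), "negative")
})

test_that("pre-binned matrices parse feature IDs round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature\ts1\ts2",
               "chr1:0-10000000|chr1:10000000-20000000\t5\t1",
               "chr1:0-10000000|chr2:0-10000000\t2\t0"), path)
  V <- read_contacts(path, "prebinned_matrix")
  expect_s3_class(V, "bulk_matrix")
  expect_equal(V$resolution, 1e7)
  expect_equal(V$features$cls, c("intra", "inter"))
  expect_equal(V$features$startB[1], 1e7)
  expect_equal(unname(V$values[, "s1"]), c(5, 2))
})

test_that("Matrix Market triplet input with sidecars is accepted", {
  d <- withr::local_tempdir()
  m <- Matrix::Matrix(matrix(c(0, 3, 2, 0), 2, 2), sparse = TRUE)
  Matrix::writeMM(m, file.path(d, "v.mtx"))
  writeLines(c("chr1:0-1000|chr1:1000-2000", "chr1:0-1000|chr2:0-1000"),
             file.path(d, "features.txt"))
  writeLines(c("a", "b"), file.path(d, "samples.txt"))
  V <- read_contacts(file.path(d, "v.mtx"), "prebinned_matrix",
                     features = file.path(d, "features.txt"),
                     samples = file.path(d, "samples.txt"))
  expect_equal(dim(V), c(2L, 2L))
  expect_equal(V$values["chr1:0-1000|chr2:0-1000", "a"], 3)
})

test_that("self-ligation filter removes short cis contacts only, strictly below the cutoff", {
  rec <- make_records(
    chrom1 = c("chr1", "chr1", "chr1", "chr2"),
    pos1 = c(1000, 1000, 1000, 1),
    chrom2 = c("chr1", "chr1", "chr2", "chr1"),
    pos2 = c(15999, 16000, 1500, 2))
  out <- filter_reads(rec, min_cis_distance = 15000)
  # 14,999 bp apart: removed; exactly 15,000: kept; trans pairs untouched
  expect_equal(nrow(out), 3)
  expect_false(any(out$chrom1 == out$chrom2 & abs(out$pos1 - out$pos2) < 15000))
  expect_true(all(c("chr2", "chr1") %in% out$chrom1))
  # idempotence
  expect_equal(filter_reads(out, 15000), out)
})

test_that("deduplication collapses symmetric duplicates to single records", {
  rec <- make_records(
    chrom1 = c("chr1", "chr2", "chr1"),
    pos1 = c(100, 5e6, 100),
    chrom2 = c("chr2", "chr1", "chr2"),
    pos2 = c(5e6, 100, 5e6))
  out <- filter_reads(rec, 0, dedupe = TRUE)
  expect_equal(nrow(out), 1)
  expect_equal(out$count, 1)
})

test_that("binning uses floor arithmetic and canonical anchor order", {
  rec <- make_records("chr1", 25000001, "chr1", 1, 1)
  b <- bin_contacts(rec, 1e7)
  expect_equal(b$startB, 2e7) # floor(25,000,001 / 10Mb) * 10Mb
  expect_equal(b$startA, 0)

  # symmetric records accumulate into one canonical bin-pair
  rec2 <- make_records(c("chr1", "chr2"), c(5e6, 5e6),
                       c("chr2", "chr1"), c(5e6, 5e6))
  b2 <- bin_contacts(rec2, 1e7)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$count, 2)
  expect_equal(b2$chromA, "chr1")

  # binning already-binned coordinates is a fixed point
  b3 <- bin_contacts(make_records(b2$chromA, b2$startA, b2$chromB, b2$startB,
                                  b2$count), 1e7)
  expect_equal(b3[, c("chromA", "startA", "chromB", "startB")],
               b2[, c("chromA", "startA", "chromB", "startB")])

  expect_equal(nrow(bin_contacts(rec2, 1e7, mode = "intra")), 0)
  expect_error(bin_contacts(rec2, 1e7, chromosomes = "chr1"), "chr2")
})

test_that("assembly takes the union of features with deterministic order", {
  m1 <- bin_contacts(make_records("chr1", 1, "chr1", 2e7, 4), 1e7)
  m2 <- bin_contacts(make_records("chr2", 1, "chr2", 1, 7), 1e7)
  V <- assemble_matrix(list(a = m1, b = m2))
  expect_equal(dim(V), c(2L, 2L))
  expect_equal(sum(V$values == 0), 2)
  expect_equal(V$values[1, "a"], 4)

  # identical maps give identical columns; 3 samples x union of 5 features
  V2 <- assemble_matrix(list(x = m1, y = m1))
  expect_equal(V2$values[, "x"], V2$values[, "y"])

  # permuting sample order permutes columns only
  Vab <- assemble_matrix(list(a = m1, b = m2))
  Vba <- assemble_matrix(list(b = m2, a = m1))
  expect_equal(Vab$values[, c("a", "b")], Vba$values[, c("a", "b")])
  expect_equal(Vab$features, Vba$features)

  attr(m2, "resolution") <- 5e6
  expect_error(assemble_matrix(list(m1, m2)), "mixed resolutions")
})

test_that("CPM normalization scales columns to one million and preserves ratios", {
  V <- make_toy_bulk(matrix(c(1, 1, 2, 0, 0,
                              2, 2, 4, 8, 0,
                              1, 0, 0, 0, 0), 5, 3,
                            dimnames = list(NULL, paste0("s", 1:3))))
  out <- cpm_normalize(V)
  expect_equal(unname(colSums(out$values)), rep(1e6, 3), tolerance = 1e-9)
  expect_equal(unname(out$values[1:3, "s1"]), c(250000, 250000, 500000))
  # within-column ratios preserved exactly
  expect_equal(out$values[3, "s2"] / out$values[1, "s2"],
               V$values[3, "s2"] / V$values[1, "s2"])
  # idempotent on an already-CPM column
  expect_equal(cpm_normalize(out)$values, out$values, tolerance = 1e-12)
  # explicit totals keep the divisor fixed under later subsetting
  sub <- subset_cls(V, "intra")
  manual <- cpm_normalize(sub, totals = colSums(V$values))
  expect_equal(manual$values, cpm_normalize(V)$values[V$features$cls == "intra", ])

  V$values[, 3] <- 0
  expect_error(cpm_normalize(V), "s3")
})

test_that("all-zero features are dropped with bookkeeping intact", {
  vals <- matrix(1, 5, 2, dimnames = list(NULL, c("a", "b")))
  vals[3, ] <- 0
  V <- make_toy_bulk(vals)
  expect_message(out <- drop_zero_features(V), "1 all-zero")
  expect_equal(nrow(out$values), 4)
  expect_equal(nrow(out$features), 4)
  # identity when nothing to drop
  expect_equal(drop_zero_features(out)$values, out$values)
  # everything zero
  V0 <- make_toy_bulk(matrix(0, 5, 2))
  expect_warning(out0 <- drop_zero_features(V0), "all features")
  expect_equal(nrow(out0$values), 0)
})
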