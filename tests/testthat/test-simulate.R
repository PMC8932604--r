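test_that("synthetic profiles are proper distributions over a shared universe", {
  pr <- synth_profiles(n_types = 3, n_chroms = 2, bins_per_chrom = 10, seed = 1)
  expect_equal(unname(colSums(pr$probs)), rep(1, 3), tolerance = 1e-12)
  expect_true(all(pr$probs >= 0))
  # universe size: 2 * C(10+1, 2) intra + 10*10 inter
  expect_equal(nrow(pr$features), 2 * 55 + 100)
  # marker sets disjoint across types
  expect_equal(anyDuplicated(unlist(pr$markers)), 0)
  # deterministic given seed
  pr2 <- synth_profiles(n_types = 3, n_chroms = 2, bins_per_chrom = 10, seed = 1)
  expect_identical(pr$probs, pr2$probs)
})

test_that("zero marker boost leaves all cell types identical", {
  pr <- synth_profiles(n_types = 3, n_chroms = 2, bins_per_chrom = 8,
                       marker_boost = 0, marker_background = 1, seed = 2)
  expect_equal(pr$probs[, 1], pr$probs[, 2], tolerance = 1e-14)
  expect_equal(pr$probs[, 1], pr$probs[, 3], tolerance = 1e-14)
})

test_that("cis decay and trans floor shape the baseline probabilities", {
  pr <- synth_profiles(n_types = 2, n_chroms = 2, bins_per_chrom = 12,
                       decay_exponent = 1.5, cis_fraction = 0.6,
                       marker_boost = 0, marker_background = 1, seed = 3)
  f <- pr$features
  intra <- f$cls == "intra"
  expect_equal(sum(pr$probs[intra, 1]), 0.6, tolerance = 1e-12)
  # monotone decay with distance on one chromosome
  chr1 <- which(f$chromA == "chr1" & f$chromB == "chr1" & f$startA == 0)
  d <- f$startB[chr1]
  expect_true(all(diff(pr$probs[chr1, 1][order(d)]) < 0))
  # inter floor uniform
  expect_equal(stats::sd(pr$probs[!intra, 1]), 0)
})

test_that("sampled cells record their true depth and are seed-stable", {
  pr <- synth_profiles(n_types = 2, n_chroms = 1, bins_per_chrom = 8,
                       marker_count = 4, seed = 5)
  cells <- sample_cells(pr, n_cells_per_type = 10, depth_meanlog = log(2000),
                        depth_sdlog = 0.3, seed = 9)
  expect_equal(unname(Matrix::colSums(cells$counts)), cells$cells$depth)
  expect_equal(nrow(cells$cells), 20)
  cells2 <- sample_cells(pr, n_cells_per_type = 10, depth_meanlog = log(2000),
                         depth_sdlog = 0.3, seed = 9)
  expect_identical(as.matrix(cells$counts), as.matrix(cells2$counts))
})

test_that("mean counts match depth times probability at large cell numbers", {
  pr <- synth_profiles(n_types = 2, n_chroms = 1, bins_per_chrom = 6,
                       marker_count = 3, seed = 11)
  n_cells <- 500
  cells <- sample_cells(pr, n_cells_per_type = c(n_cells, 1),
                        depth_meanlog = log(3000), depth_sdlog = 0,
                        cell_decay_sd = 0, seed = 13)
  t1 <- cells$cells$cell_type == colnames(pr$probs)[1]
  mean_depth <- mean(cells$cells$depth[t1])
  obs <- Matrix::rowMeans(cells$counts[, t1])
  expected <- mean_depth * pr$probs[, 1]
  se <- sqrt(mean_depth * pr$probs[, 1] / n_cells)
  expect_true(all(abs(obs - expected) <= 3 * se + 1e-9))
})

test_that("cell filters apply the printed boundary rules", {
  pr <- synth_profiles(n_types = 2, n_chroms = 2, bins_per_chrom = 6,
                       marker_count = 3, seed = 21)
  cells <- sample_cells(pr, n_cells_per_type = 30, depth_meanlog = log(4000),
                        depth_sdlog = 0.4, seed = 22)
  # hand-set depths/ratios to probe the boundaries
  cells$cells$depth[1:4] <- c(999, 1000, 5000, 5000)
  cells$cells$cis_trans[1:4] <- c(5, 5, 0.99, 1.0)
  out <- filter_cells(cells, min_reads = 1000, min_cis_trans = 1,
                      q_low = 0, q_high = 1)
  kept <- out$cells$cell_id
  expect_false(cells$cells$cell_id[1] %in% kept) # 999 reads: removed
  expect_false(cells$cells$cell_id[3] %in% kept) # cis:trans 0.99: removed
  expect_true(cells$cells$cell_id[4] %in% kept)  # cis:trans 1.0: retained
  # a 1000-read cell passes the count rule (may still fail quantiles)
  out2 <- filter_cells(cells, min_reads = 1000, min_cis_trans = 0,
                       q_low = 0, q_high = 1)
  expect_true(cells$cells$cell_id[2] %in% out2$cells$cell_id)

  # strict quantile bounds: cells at or outside the quantiles are removed
  out3 <- filter_cells(cells, min_reads = 0, min_cis_trans = 0)
  expect_true(all(out3$cells$depth > stats::quantile(cells$cells$depth, 0.2)))
  expect_true(all(out3$cells$depth < stats::quantile(cells$cells$depth, 0.9)))

  expect_error(filter_cells(cells, min_reads = 1e9), "relax")
})

test_that("downsampling equalizes depths exactly and respects zero support", {
  pr <- synth_profiles(n_types = 2, n_chroms = 1, bins_per_chrom = 8,
                       marker_count = 4, seed = 31)
  cells <- sample_cells(pr, n_cells_per_type = 15, depth_meanlog = log(3000),
                        depth_sdlog = 0.5, seed = 32)
  before <- as.matrix(cells$counts)
  m <- min(cells$cells$depth)
  down <- downsample_cells(cells, seed = 33)
  expect_true(all(down$cells$depth == m))
  expect_equal(diff(range(down$cells$depth)), 0)
  after <- as.matrix(down$counts)
  # multinomial thinning cannot create contacts where a cell had none
  expect_true(all(after[before == 0] == 0))
})

test_that("mixture designs are valid and the presets have the stated shape", {
  d3 <- design_three_type()
  expect_equal(dim(d3$proportions), c(3L, 12L))
  expect_equal(unname(colSums(d3$proportions)), rep(1, 12))
  expect_equal(sum(apply(d3$proportions, 2, function(x) sum(x == 1) == 1)), 3)

  d6 <- design_six_type()
  expect_equal(dim(d6$proportions), c(6L, 18L))
  expect_equal(unname(colSums(d6$proportions)), rep(1, 18), tolerance = 1e-12)
  expect_true(all(d6$proportions["Neuron", ] >= 0.4 - 1e-9))
  expect_true(all(d6$proportions["Neuron", ] <= 0.8 + 1e-9))

  expect_error(mixture_design(matrix(c(0.5, 0.4), 2, 1)), "sum to 1")
  expect_error(mixture_design(matrix(c(-0.2, 1.2), 2, 1)), "non-negative")
})

test_that("largest-remainder apportionment hits the total with sub-1/N error", {
  set.seed(41)
  for (r in 1:30) {
    k <- sample(2:6, 1)
    w <- runif(k)
    w <- w / sum(w)
    N <- sample(10:80, 1)
    n <- hicdecon:::largest_remainder(w, N)
    expect_equal(sum(n), N)
    expect_true(all(abs(n / N - w) < 1 / N))
  }
})

test_that("mixtures honor the design: pure columns, unit truth sums, CPM scale", {
  pr <- synth_profiles(n_types = 3, n_chroms = 2, bins_per_chrom = 8,
                       marker_count = 5, seed = 51)
  cells <- sample_cells(pr, n_cells_per_type = 20, depth_meanlog = log(3000),
                        depth_sdlog = 0.2, seed = 52)
  design <- mixture_design(cbind(c(1, 0, 0), c(0.5, 0.25, 0.25)))
  mix <- make_mixtures(cells, design, seed = 53)
  expect_equal(unname(colSums(mix$truth)), c(1, 1))
  expect_equal(mix$truth[, 1], c(type1 = 1, type2 = 0, type3 = 0))
  expect_equal(unname(colSums(mix$bulk$values)), rep(1e6, 2), tolerance = 1e-6)
  expect_true(all(mix$counts >= 0))
  # realized truth within 1/N of the design (N = 20 cells per sample here)
  expect_true(all(abs(mix$truth[, 2] - design$proportions[, 2]) < 1 / 20))

  bad <- mixture_design(matrix(c(0.4, 0.3, 0.3), 3, 1))
  tiny <- hicdecon:::subset_cells(cells, c(1, 21, 41)) # one cell per type
  expect_error(make_mixtures(tiny, bad, seed = 1), "smaller than")
})

test_that("a full simulated study is reproducible end to end", {
  s1 <- small_study(seed = 4)
  s2 <- small_study(seed = 4)
  expect_identical(s1$bulk$values, s2$bulk$values)
  expect_identical(s1$truth, s2$truth)
  expect_equal(unname(colSums(s1$truth)), rep(1, 12))
  expect_true(all(s1$bulk$values >= 0))
})

test_that("studies can be written to disk and read back through contacts_io", {
  d <- withr::local_tempdir()
  study <- small_study(seed = 6)
  write_mixture_study(study, d)
  expect_true(file.exists(file.path(d, "truth.tsv")))
  expect_true(file.exists(file.path(d, "manifest.json")))
  rec <- read_contacts(file.path(d, "pure1.contacts.tsv"), "long_tsv")
  b <- bin_contacts(rec, study$bulk$resolution)
  expect_equal(sum(b$count), sum(study$counts[, "pure1"]))
})
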