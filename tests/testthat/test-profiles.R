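test_that("cluster-specific bin-pairs follow the inclusive row-normalized cutoff", {
  W <- rbind(one_hot = c(0, 0, 4),
             uniform6 = rep(1, 3), # 1/3 each, above 0.3
             mixed = c(0.5, 0.3, 0.2))
  sets <- cluster_specific_binpairs(W, threshold = 0.3)
  expect_equal(sets[[3]], c("one_hot", "uniform6"))
  expect_true("mixed" %in% sets[[1]])
  expect_true("mixed" %in% sets[[2]]) # 0.3 is inclusive
  expect_false("mixed" %in% sets[[3]])

  # a uniform row over k = 6 clusters (1/6 < 0.3) belongs nowhere
  W6 <- matrix(1, 1, 6, dimnames = list("u", NULL))
  expect_true(all(lengths(cluster_specific_binpairs(W6, 0.3)) == 0))

  # row normalization preserves each row's argmax; sets shrink as the
  # threshold rises
  set.seed(2)
  W2 <- matrix(runif(60, 0.1, 1), 20, 3)
  norm <- attr(cluster_specific_binpairs(W2, 0.3), "normalized")
  expect_equal(apply(norm, 1, which.max), apply(W2, 1, which.max))
  lo <- cluster_specific_binpairs(W2, 0.3)
  hi <- cluster_specific_binpairs(W2, 0.5)
  for (j in 1:3) expect_true(all(hi[[j]] %in% lo[[j]]))

  expect_error(cluster_specific_binpairs(rbind(c(0, 0, 0))), "positive")
})

test_that("bin-pair IDs expand to deduplicated anchor bins", {
  ids <- c("chr1:0-10|chr1:10-20", "chr1:10-20|chr2:0-10")
  bins <- binpair_bins(ids)
  expect_equal(nrow(bins), 3) # chr1:0, chr1:10 (shared), chr2:0
  expect_setequal(paste(bins$chrom, bins$start), c("chr1 0", "chr1 10", "chr2 0"))
})

test_that("enrichment chi-squared reproduces the continuity-corrected closed form", {
  # universe of 20 bins: 10 in the cluster, annotation covering exactly those
  universe <- data.frame(chrom = "chr1", start = (0:19) * 100, end = (1:20) * 100)
  cluster <- universe[1:10, ]
  annotation <- universe[1:10, ]
  res <- enrichment_test(cluster, annotation, universe)
  # 2x2 table ((10,0),(0,10)): Yates-corrected statistic 16.2
  expect_equal(res$statistic, 16.2, tolerance = 1e-9)
  expect_lt(res$p.value, 0.01)

  # sparse tables are flagged unreliable
  u2 <- data.frame(chrom = "chr1", start = (0:9) * 100, end = (1:10) * 100)
  expect_warning(res2 <- enrichment_test(u2[1, ], u2[1, ], u2), "unreliable")
  expect_false(res2$reliable)
})

test_that("annotation overlap counts any shared base pair", {
  universe <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                         start = c(0, 1000, 0), end = c(1000, 2000, 1000))
  ann <- data.frame(chrom = "chr1", start = 999, end = 1001) # touches bins 1+2
  cluster <- universe[1:2, ]
  res <- suppressWarnings(enrichment_test(cluster, ann, universe))
  expect_equal(unname(res$table[1, 1]), 2) # both cluster bins overlap
  expect_equal(unname(res$table[2, 1]), 0) # chr2 bin does not
})

test_that("cell-type-specific genes require a strict margin over other types", {
  expr <- rbind(g1 = c(5, 1, 1, 1),
                g2 = c(2, 2, 2, 2),
                g3 = c(2, 1, 1, 1))
  colnames(expr) <- c("A", "B", "C", "D")
  sets <- celltype_specific_genes(expr, margin = 1)
  expect_equal(sets$A, "g1") # 5 - 1 = 4 > 1
  # flat profile nowhere; difference exactly 1 is not > 1
  expect_false(any(vapply(sets, function(s) "g2" %in% s, TRUE)))
  expect_false(any(vapply(sets, function(s) "g3" %in% s, TRUE)))
})

test_that("TSS flank overlap uses half-open boundary arithmetic", {
  bins <- data.frame(chrom = "chr1", start = 10000, end = 20000)
  tss <- data.frame(chrom = "chr1",
                    start = c(20000, 22001, 22000, 8001, 7999),
                    name = c("at_boundary", "just_outside", "at_flank_edge",
                             "within_upstream", "outside_upstream"))
  genes <- genes_in_binpairs(bins, tss, flank = 2000)
  expect_true("at_boundary" %in% genes)      # touching counts
  expect_false("just_outside" %in% genes)    # 2001 bp past the bin end
  expect_false("at_flank_edge" %in% genes)   # half-open window
  expect_true("within_upstream" %in% genes)
  expect_false("outside_upstream" %in% genes)
  expect_equal(genes_in_binpairs(bins[0, ], tss), character(0))
})

test_that("expression shifts toward the assigned type are detected one-sidedly", {
  set.seed(14)
  n <- 50
  genes <- paste0("g", seq_len(n))
  expr <- cbind(A = rnorm(n, 2), B = rnorm(n), C = rnorm(n))
  rownames(expr) <- genes
  p <- expression_shift_test(expr, genes, "A")
  expect_true(all(p < 0.05))
  expect_named(p, c("B", "C"))

  expect_error(expression_shift_test(expr, genes[1:2], "A"), "at least 3")
  expect_error(expression_shift_test(expr, genes, "Z"), "unknown")
})

test_that("cluster annotation table covers every cluster-annotation pair", {
  study <- small_study(seed = 3)
  fit <- hicdecon(study$bulk, k = 3, restarts = 3, max_iter = 300, seed = 8)
  res <- study$bulk$resolution
  ann <- list(
    typeA = data.frame(chrom = "chr1", start = 0, end = 5 * res),
    typeB = data.frame(chrom = "chr2", start = 0, end = 5 * res))
  tab <- annotate_clusters(fit, ann)
  expect_equal(nrow(tab), 3 * 2)
  expect_true(all(tab$p.value >= 0 | is.na(tab$p.value)))
  expect_true(all(tab$cluster %in% paste0("cluster", 1:3) |
                    tab$cluster %in% as.character(1:3)))
})
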