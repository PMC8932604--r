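# Builders for small in-code fixtures shared across test files.

make_records <- function(chrom1, pos1, chrom2, pos2, count = 1) {
  data.frame(chrom1 = chrom1, pos1 = pos1, chrom2 = chrom2, pos2 = pos2,
             count = count, stringsAsFactors = FALSE)
}

# tiny two-chromosome bulk matrix with known features
make_toy_bulk <- function(values = NULL) {
  feats <- data.frame(
    chromA = c("chr1", "chr1", "chr1", "chr2", "chr1"),
    startA = c(0, 0, 1e7, 0, 0),
    chromB = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    startB = c(0, 1e7, 1e7, 1e7, 0),
    stringsAsFactors = FALSE)
  if (is.null(values))
    values <- matrix(seq_len(15), 5, 3,
                     dimnames = list(NULL, paste0("s", 1:3)))
  bulk_matrix(values, feats, resolution = 1e7)
}

# exhaustive permutation matrix for small k (oracle for assignment tests)
all_perms <- function(k) {
  if (k == 1) return(matrix(1L))
  sub <- all_perms(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# brute-force minimum assignment cost by enumeration
brute_assignment <- function(cost) {
  k <- nrow(cost)
  pm <- all_perms(k)
  vals <- apply(pm, 1, function(p) sum(cost[cbind(p, seq_len(k))]))
  list(cost = min(vals), perm = pm[which.min(vals), ])
}

# small, fast synthetic study for pipeline-level unit tests
small_study <- function(seed = 3) {
  simulate_mixture_study("three_type", seed = seed,
                         n_cells_per_type = 25,
                         depth_meanlog = log(20000))
}
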