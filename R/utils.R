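# Internal helpers shared across modules.

# Deterministic 32-bit substream seed derived from a master seed and a stage
# index, so that independent pipeline stages (step-1 NMF, step-2 NMF,
# per-chromosome fits) never share a random stream.  Result is in [1, 2^31-2].
derive_seed <- function(master, stage) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- (as.double(master) %% m) * 48271 + (as.double(stage) + 1) * 69621
  as.integer((x %% (m - 1)) + 1)
}

# Natural chromosome ordering: chr1 < chr2 < ... < chr22 < chrX < chrY < chrM,
# unknown names after, alphabetically.  Accepts names with or without a "chr"
# prefix.
chrom_rank <- function(chroms) {
  base <- sub("^chr", "", as.character(chroms))
  num <- suppressWarnings(as.numeric(base))
  rank <- ifelse(!is.na(num), num,
    ifelse(base == "X", 1e3,
      ifelse(base == "Y", 1e3 + 1,
        ifelse(base %in% c("M", "MT"), 1e3 + 2, NA_real_))))
  unknown <- is.na(rank)
  if (any(unknown)) {
    lev <- sort(unique(base[unknown]))
    rank[unknown] <- 2e3 + match(base[unknown], lev)
  }
  rank
}

# Largest-remainder apportionment of `total` items to non-negative weights
# that sum to 1; guarantees sum(result) == total and |result/total - w| < 1/total.
largest_remainder <- function(weights, total) {
  stopifnot(all(weights >= 0), total >= 0)
  raw <- weights * total
  base <- floor(raw)
  short <- total - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
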