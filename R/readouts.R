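#' Normalized insulation score along one chromosome
#'
#' For each bin boundary, the raw insulation signal is the mean contact count
#' in the w x w square of bin-pairs spanning the boundary (w = window /
#' resolution bins upstream times w bins downstream, the focal bin excluded).
#' Scores are normalized per chromosome as log2(raw / mean(raw)), so a bin at
#' an insulating boundary (depleted cross-boundary contacts) scores below 0.
#' Bins within one window of either chromosome end have no complete square
#' and are returned as NA.
#'
#' The score is invariant under global scaling of the contact matrix: the
#' normalization ratio cancels any sequencing-depth factor.
#'
#' @param M square symmetric intrachromosomal contact matrix for one
#'   chromosome (bins in coordinate order).
#' @param resolution bin width in bp (default 100 kb).
#' @param window sliding-window width in bp (default 1.2 Mb); must be an
#'   integer multiple of `resolution`.
#' @return numeric vector of normalized scores, one per bin, NA at ends.
#' @export
insulation_score <- function(M, resolution = 1e5, window = 1.2e6) {
  M <- as.matrix(M)
  if (nrow(M) == 0 || sum(M) == 0) stop("empty chromosome contact matrix")
  if (nrow(M) != ncol(M)) stop("contact matrix must be square")
  w <- window / resolution
  if (w != round(w)) stop("window must be an integer multiple of resolution")
  w <- as.integer(w)
  n <- nrow(M)
  if (n < 2 * w + 1) {
    warning("chromosome shorter than twice the window; all scores missing")
    return(rep(NA_real_, n))
  }
  raw <- rep(NA_real_, n)
  for (i in (w + 1):(n - w)) {
    raw[i] <- mean(M[(i - w):(i - 1), (i + 1):(i + w)])
  }
  mu <- mean(raw, na.rm = TRUE)
  if (mu <= 0) stop("chromosome-wide mean insulation signal is zero")
  log2(raw / mu)
}

#' A/B compartment score (first principal component) for one chromosome
#'
#' Standard compartment calling on a single-chromosome contact matrix:
#' divide by the expected contact count at each genomic separation (the
#' per-diagonal mean over non-empty bins), take the Pearson correlation
#' matrix of the observed/expected matrix, and return the first principal
#' component score of each bin.  Bins with zero marginal counts are excluded
#' and returned as NA.  The sign of the component is arbitrary; apply
#' [abs_transform()] before using scores as a non-negative deconvolution
#' input.
#'
#' @param M square symmetric intrachromosomal contact matrix.
#' @param min_bins minimum number of non-empty bins required (compartment
#'   calls on fewer bins are not meaningful; 10+ recommended).
#' @return numeric vector of PC1 scores, one per bin, NA for excluded bins.
#' @export
compartment_pc <- function(M, min_bins = 4) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("contact matrix must be square")
  keep <- rowSums(M) > 0
  if (sum(keep) < min_bins)
    stop("fewer than ", min_bins, " non-empty bins")
  Mk <- M[keep, keep, drop = FALSE]
  nk <- nrow(Mk)
  d <- abs(outer(seq_len(nk), seq_len(nk), "-"))
  expected <- tapply(Mk, d, mean)
  E <- matrix(expected[as.character(d)], nk, nk)
  OE <- ifelse(E > 0, Mk / E, 0)
  if (all(apply(OE, 2, stats::sd) == 0))
    stop("degenerate observed/expected matrix: no contact variation")
  C <- suppressWarnings(stats::cor(OE))
  if (any(!is.finite(C)))
    stop("degenerate correlation matrix (constant observed/expected columns)")
  pc <- stats::prcomp(C, center = TRUE, scale. = FALSE)$x[, 1]
  out <- rep(NA_real_, nrow(M))
  out[keep] <- pc
  out
}

#' Absolute-value transform of a signed track
#'
#' Insulation scores and compartment PCs are signed; the factorization input
#' must be non-negative, so signed tracks are folded by elementwise absolute
#' value.  Missing values stay missing.
#'
#' @param x numeric vector or matrix.
#' @return |x| with NAs preserved.
#' @export
abs_transform <- function(x) abs(x)

#' Assemble per-sample track scores into a non-negative feature matrix
#'
#' Stacks per-sample score vectors (e.g. insulation or compartment scores,
#' one value per 1-D genomic bin) into a bins x samples matrix, drops bins
#' missing in any sample, and applies the absolute-value transform.
#'
#' @param scores named list of equal-length numeric vectors, one per sample.
#' @return non-negative matrix with one row per retained bin.
#' @export
assemble_tracks <- function(scores) {
  m <- do.call(cbind, scores)
  keep <- stats::complete.cases(m)
  abs_transform(m[keep, , drop = FALSE])
}

#' Write a per-bin track as bedGraph
#'
#' @param chrom chromosome name (recycled).
#' @param starts 0-based bin starts.
#' @param resolution bin width in bp.
#' @param values per-bin scores (NA bins skipped).
#' @param path output path.
#' @export
write_bedgraph <- function(chrom, starts, resolution, values, path) {
  keep <- !is.na(values)
  df <- data.frame(chrom = chrom, start = starts[keep],
                   end = starts[keep] + resolution, value = values[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
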