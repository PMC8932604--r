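#' Entropy-based feature score of a profile row
#'
#' For a bin-pair with fitted profile values w over k cell types, let
#' p_j = w_j / sum(w).  The feature score is
#' \deqn{FS = 1 + \frac{1}{\log_2 k} \sum_j p_j \log_2 p_j,}
#' i.e. one minus the normalized Shannon entropy of the profile: 1 for a
#' bin-pair loaded on a single cell type, 0 for a perfectly uniform one.
#'
#' @param w numeric vector of k >= 2 non-negative values with positive sum,
#'   or a matrix whose rows are scored.
#' @return feature score(s) in \[0, 1\].
#' @export
feature_score <- function(w) {
  if (is.matrix(w)) return(apply(w, 1, feature_score))
  if (length(w) < 2) stop("feature score requires k >= 2 cell types")
  s <- sum(w)
  if (s <= 0) stop("feature score undefined for an all-zero profile row")
  p <- w / s
  plogp <- ifelse(p > 0, p * log2(p), 0)
  1 + sum(plogp) / log2(length(w))
}

#' Across-cell-type standard deviation of a profile row
#'
#' Sample standard deviation of a bin-pair's fitted profile values across the
#' k cell types (divisor k - 1).
#'
#' @param w numeric vector of k >= 2 values, or a matrix whose rows are scored.
#' @return non-negative standard deviation(s).
#' @export
across_cell_type_sd <- function(w) {
  if (is.matrix(w)) return(apply(w, 1, stats::sd))
  if (length(w) < 2) stop("across-cell-type SD requires k >= 2")
  stats::sd(w)
}

#' Fano factor of a feature across samples
#'
#' Variance-to-mean ratio of a bin-pair's observed values across the bulk
#' samples.  Undefined (NA with a warning) when the mean is not positive.
#'
#' @param v numeric vector of observed values across samples, or a matrix
#'   whose rows are scored.
#' @return Fano factor(s).
#' @export
fano_factor <- function(v) {
  if (is.matrix(v)) return(apply(v, 1, fano_factor))
  m <- mean(v)
  if (m <= 0) {
    warning("Fano factor undefined for non-positive mean; returning NA")
    return(NA_real_)
  }
  stats::var(v) / m
}

#' Informative intrachromosomal bin-pairs from feature scores
#'
#' Selects bin-pairs whose feature score exceeds the median plus three raw
#' median absolute deviations: FS > median(FS) + 3 * median(|FS - median(FS)|).
#' The deviation estimate is the raw median of absolute deviations with no
#' consistency scaling, and the inequality is strict, so with half the scores
#' tied at the median nothing at or below the median is ever selected.
#'
#' @param fs numeric vector of feature scores over the intrachromosomal set.
#' @return logical selection mask.
#' @export
select_intra <- function(fs) {
  stopifnot(length(fs) >= 1)
  m <- stats::median(fs)
  s <- stats::median(abs(fs - m))
  fs > m + 3 * s
}

#' Informative interchromosomal bin-pairs from across-cell-type SDs
#'
#' Selects bin-pairs whose across-cell-type SD exceeds the mean plus three
#' sample standard deviations of the SD distribution (strict inequality).
#'
#' @param sd_vals numeric vector of across-cell-type SDs over the
#'   interchromosomal set (length >= 2).
#' @return logical selection mask.
#' @export
select_inter <- function(sd_vals) {
  stopifnot(length(sd_vals) >= 2)
  sd_vals > mean(sd_vals) + 3 * stats::sd(sd_vals)
}

# one high-tail threshold rule: center +/- spread pairing
threshold_mask <- function(x, center = c("median", "mean")) {
  center <- match.arg(center)
  if (center == "median") {
    m <- stats::median(x)
    s <- stats::median(abs(x - m))
  } else {
    m <- mean(x)
    s <- stats::sd(x)
  }
  x > m + 3 * s
}

#' Select informative bin-pairs for deconvolution
#'
#' Computes per-feature statistics (feature score and across-cell-type SD from
#' the step-1 profile matrix `W1`; Fano factor from the observed matrix `V`)
#' and applies a selection strategy.  Threshold-based strategies are applied
#' to the intrachromosomal and interchromosomal classes separately — each
#' class gets its own empirical threshold — and the per-class masks are
#' combined by union.
#'
#' Available strategies:
#' \describe{
#'   \item{`two_step` (default)}{high cell-type-specificity with median-based
#'     thresholds on intrachromosomal bin-pairs ([select_intra]) and high
#'     across-cell-type variation with mean-based thresholds on
#'     interchromosomal bin-pairs ([select_inter]).}
#'   \item{`none`}{keep every feature.}
#'   \item{`fano_top_n`}{the `params$n` features with the highest Fano factor
#'     (ties broken by feature order).}
#'   \item{`cts`}{feature score above `center` + 3 spread
#'     (`params$center` = `"median"` or `"mean"`).}
#'   \item{`acv`}{across-cell-type SD above `center` + 3 spread
#'     (`params$center`).}
#'   \item{`cts_acv`}{intersection of the `cts` and `acv` rules with centers
#'     `params$cts_center` and `params$acv_center`.}
#' }
#'
#' @param V observed mixture matrix ([bulk_matrix] or plain matrix).
#' @param W1 step-1 profile matrix, one row per feature of `V`.
#' @param strategy strategy name (see Details).
#' @param params list of strategy parameters.
#' @param cls per-feature class vector (`"intra"`/`"inter"`); taken from `V`
#'   when it is a [bulk_matrix].
#' @return A `feature_stats` data frame with columns `feature`, `cls`, `FS`,
#'   `SD`, `fano`, `selected`; rows whose `W1` profile is all zero get NA
#'   statistics and are never selected.
#' @export
select_features <- function(V, W1, strategy = "two_step", params = list(),
                            cls = NULL) {
  registry <- c("two_step", "none", "fano_top_n", "cts", "acv", "cts_acv")
  if (!strategy %in% registry)
    stop("unknown strategy '", strategy, "'; available: ",
         paste(registry, collapse = ", "))
  if (inherits(V, "bulk_matrix")) {
    cls <- cls %||% V$features$cls
    Vm <- V$values
  } else {
    Vm <- as.matrix(V)
    cls <- cls %||% rep("intra", nrow(Vm))
  }
  stopifnot(nrow(Vm) == nrow(W1), length(cls) == nrow(Vm))
  scored <- rowSums(W1) > 0
  p <- nrow(Vm)
  fs <- sd_v <- rep(NA_real_, p)
  fs[scored] <- feature_score(W1[scored, , drop = FALSE])
  sd_v[scored] <- across_cell_type_sd(W1[scored, , drop = FALSE])
  fano <- suppressWarnings(fano_factor(Vm))

  selected <- rep(FALSE, p)
  per_class <- function(rule_field, rule) {
    out <- rep(FALSE, p)
    for (cl in unique(cls)) {
      idx <- which(cls == cl & scored)
      if (length(idx) >= 2) out[idx] <- rule(rule_field[idx])
    }
    out
  }
  if (strategy == "none") {
    selected <- rep(TRUE, p)
  } else if (strategy == "fano_top_n") {
    n <- params$n %||% stop("fano_top_n requires params$n")
    ok <- which(!is.na(fano))
    top <- ok[order(-fano[ok])][seq_len(min(n, length(ok)))]
    selected[top] <- TRUE
  } else if (strategy == "two_step") {
    intra <- which(cls == "intra" & scored)
    inter <- which(cls == "inter" & scored)
    if (length(intra) >= 1) selected[intra] <- select_intra(fs[intra])
    if (length(inter) >= 2) selected[inter] <- select_inter(sd_v[inter])
  } else if (strategy == "cts") {
    center <- params$center %||% "median"
    selected <- per_class(fs, function(x) threshold_mask(x, center))
  } else if (strategy == "acv") {
    center <- params$center %||% "mean"
    selected <- per_class(sd_v, function(x) threshold_mask(x, center))
  } else if (strategy == "cts_acv") {
    cc <- params$cts_center %||% "median"
    ac <- params$acv_center %||% "mean"
    selected <- per_class(fs, function(x) threshold_mask(x, cc)) &
      per_class(sd_v, function(x) threshold_mask(x, ac))
  }
  out <- data.frame(
    feature = rownames(Vm) %||% as.character(seq_len(p)),
    cls = cls, FS = fs, SD = sd_v, fano = fano, selected = selected,
    stringsAsFactors = FALSE)
  attr(out, "strategy") <- strategy
  attr(out, "params") <- params
  class(out) <- c("feature_stats", "data.frame")
  out
}

#' Write selected-feature statistics as TSV
#'
#' @param stats a `feature_stats` data frame from [select_features].
#' @param path output path.
#' @export
write_feature_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
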