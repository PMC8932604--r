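# Minimum-cost perfect matching on a square cost matrix (Hungarian algorithm,
# O(n^3) potentials formulation).  Returns an integer vector `a` with a[j] =
# row assigned to column j.  Used to resolve the cluster-label permutation
# ambiguity of unsupervised deconvolution.
hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  INF <- Inf
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1) # p[j]: row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  p[seq_len(n)]
}

#' Match estimated clusters to true cell-type labels
#'
#' Unsupervised deconvolution returns clusters in arbitrary order; before any
#' accuracy metric the estimated rows must be aligned with the truth.  The
#' matching minimizes the total absolute error: the k x k cost matrix
#' `cost[i, j] = sum(|est[i, ] - truth[j, ]|)` is solved by optimal
#' assignment, so the reported error is the minimum achievable over all k!
#' labelings.
#'
#' @param est,truth k x n proportion matrices (same dimensions).
#' @return integer permutation `perm` such that `est[perm, ]` is row-aligned
#'   with `truth`: `perm[j]` is the estimated cluster matched to truth row j.
#' @export
match_clusters <- function(est, truth) {
  est <- as.matrix(est); truth <- as.matrix(truth)
  if (!all(dim(est) == dim(truth)))
    stop("est and truth must have identical dimensions")
  k <- nrow(est)
  cost <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    cost[i, j] <- sum(abs(est[i, ] - truth[j, ]))
  hungarian(cost) # perm[j] = est row assigned to truth row j
}

#' Mean absolute deviation between proportion matrices
#'
#' @param est_matched estimated proportions, rows already aligned with truth
#'   (see [match_clusters]).
#' @param truth true proportions, same dimensions.
#' @return mean over all (cell type, sample) entries of |est - truth|.
#' @export
proportion_mad <- function(est_matched, truth) {
  est_matched <- as.matrix(est_matched); truth <- as.matrix(truth)
  stopifnot(all(dim(est_matched) == dim(truth)))
  mean(abs(est_matched - truth))
}

#' Pearson correlation between proportion matrices
#'
#' Computed on the flattened (cell type x sample) entries, one summary value
#' per estimate.
#'
#' @inheritParams proportion_mad
#' @return Pearson correlation; NA with a warning if either side has zero
#'   variance.
#' @export
proportion_pearson <- function(est_matched, truth) {
  est_matched <- as.matrix(est_matched); truth <- as.matrix(truth)
  stopifnot(all(dim(est_matched) == dim(truth)))
  if (stats::sd(c(truth)) == 0 || stats::sd(c(est_matched)) == 0) {
    warning("zero variance in proportions; Pearson correlation omitted")
    return(NA_real_)
  }
  stats::cor(c(est_matched), c(truth))
}

#' Score estimated against true cell-type proportions
#'
#' Aligns clusters with [match_clusters], then reports the mean absolute
#' deviation and Pearson correlation plus per-type MADs.
#'
#' @param est,truth k x n proportion matrices.
#' @return An object of class `deconv_eval`: list with `matching`, `mad`,
#'   `pearson`, `per_type_mad`.
#' @export
evaluate_proportions <- function(est, truth) {
  perm <- match_clusters(est, truth)
  est_m <- as.matrix(est)[perm, , drop = FALSE]
  truth <- as.matrix(truth)
  out <- list(matching = perm,
              mad = proportion_mad(est_m, truth),
              pearson = proportion_pearson(est_m, truth),
              per_type_mad = rowMeans(abs(est_m - truth)))
  if (!is.null(rownames(truth))) names(out$per_type_mad) <- rownames(truth)
  class(out) <- "deconv_eval"
  out
}

#' @export
print.deconv_eval <- function(x, ...) {
  cat(sprintf("deconvolution accuracy: MAD %.4f, Pearson r %.4f\n",
              x$mad, x$pearson))
  cat("cluster -> truth matching:", paste(x$matching, collapse = " "), "\n")
  invisible(x)
}
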