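#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative p x n matrix V into W (p x k) and H (k x n) by
#' minimizing the Euclidean loss ||V - WH||^2 with the classical
#' multiplicative update rules
#' \deqn{H \leftarrow H \odot (W^T V) / (W^T W H), \quad
#'       W \leftarrow W \odot (V H^T) / (W H H^T),}
#' which keep both factors non-negative and never increase the objective.
#' Because the problem is non-convex, the factorization is repeated from
#' `restarts` independent random initializations (entries i.i.d. uniform on
#' (0, max(V))) and the run with the lowest objective is returned.
#'
#' @param V non-negative numeric matrix (or [bulk_matrix]) with no all-zero
#'   rows or columns.
#' @param k number of latent components (cell types), k >= 1.
#' @param restarts number of independent random initializations.
#' @param max_iter maximum update iterations per run.
#' @param tol stop a run when the relative decrease of the objective between
#'   successive iterations falls below `tol`.
#' @param seed integer seed making the whole multi-restart fit reproducible.
#' @return An object of class `nmf_fit`: list with `W`, `H`, `k`, `objective`
#'   (final ||V-WH||^2 of the best run), `objective_trace` (per-iteration
#'   objective of the best run), `n_iter`, `restart_objectives`, `seed`.
#' @seealso [rss()], [explained_variance()]
#' @export
nmf <- function(V, k, restarts = 30, max_iter = 2000, tol = 1e-6, seed = NULL) {
  if (inherits(V, "bulk_matrix")) V <- V$values
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be non-negative")
  if (any(rowSums(V) == 0)) stop("V has all-zero rows; drop them first")
  if (any(colSums(V) == 0)) stop("V has all-zero columns")
  stopifnot(k >= 1, restarts >= 1, max_iter >= 1)
  if (k > min(dim(V)))
    warning("k exceeds min(dim(V)); factorization is over-parameterized")
  if (is.null(seed)) seed <- sample.int(2147483646L, 1)
  run_seeds <- vapply(seq_len(restarts), function(r) derive_seed(seed, r), 1L)
  best <- NULL
  objs <- numeric(restarts)
  for (r in seq_len(restarts)) {
    fit <- nmf_single(V, k, max_iter, tol, run_seeds[r])
    objs[r] <- fit$objective
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  best$restart_objectives <- objs
  best$seed <- seed
  best$k <- k
  dimnames(best$W) <- list(rownames(V), NULL)
  dimnames(best$H) <- list(NULL, colnames(V))
  class(best) <- "nmf_fit"
  best
}

# one multiplicative-update run; eps floors denominators so a factor entry
# that hits zero stays zero without dividing by zero
nmf_single <- function(V, k, max_iter, tol, run_seed, eps = 1e-16) {
  p <- nrow(V); n <- ncol(V)
  set.seed(run_seed)
  hi <- max(V)
  W <- matrix(stats::runif(p * k, min = .Machine$double.eps, max = hi), p, k)
  H <- matrix(stats::runif(k * n, min = .Machine$double.eps, max = hi), k, n)
  trace <- numeric(max_iter)
  prev <- Inf
  n_iter <- max_iter
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V) / pmax(crossprod(W) %*% H, eps))
    W <- W * (V %*% t(H) / pmax(W %*% tcrossprod(H), eps))
    obj <- sum((V - W %*% H)^2)
    if (is.na(obj)) stop("objective became NaN at iteration ", it)
    trace[it] <- obj
    if (is.finite(prev) && prev > 0 && (prev - obj) / prev < tol) {
      n_iter <- it
      break
    }
    prev <- obj
  }
  list(W = W, H = H, objective = trace[n_iter],
       objective_trace = trace[seq_len(n_iter)], n_iter = n_iter)
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("NMF fit: %d x %d = (%d x %d)(%d x %d), objective %.6g after %d iterations (%d restart%s)\n",
              nrow(x$W), ncol(x$H), nrow(x$W), x$k, x$k, ncol(x$H),
              x$objective, x$n_iter, length(x$restart_objectives),
              if (length(x$restart_objectives) == 1) "" else "s"))
  invisible(x)
}

#' Residual sum of squares of a factorization
#'
#' @param V observed matrix.
#' @param W,H factor matrices.
#' @return sum over all entries of (V - WH)^2.
#' @export
rss <- function(V, W, H) {
  if (inherits(V, "bulk_matrix")) V <- V$values
  sum((V - W %*% H)^2)
}

#' Proportion of variance explained by a factorization
#'
#' 1 - RSS / sum(V^2), the goodness-of-fit statistic used for choosing the
#' bin size and the number of components.  The denominator is the squared
#' mass of the observed matrix, so a perfect fit gives 1 and an all-zero
#' reconstruction gives 0; badly diverging fits can be negative.
#'
#' @inheritParams rss
#' @return scalar proportion of variance explained.
#' @export
explained_variance <- function(V, W, H) {
  if (inherits(V, "bulk_matrix")) V <- V$values
  denom <- sum(V^2)
  if (denom <= 0) stop("sum(V^2) must be positive")
  1 - rss(V, W, H) / denom
}
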