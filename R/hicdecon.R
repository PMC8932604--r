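#' Two-step reference-free deconvolution of bulk Hi-C samples
#'
#' Estimates cell-type proportions and parsimonious cell-type-specific
#' contact profiles from a non-negative bin-pair x sample mixture matrix V,
#' without reference profiles.  The procedure is:
#' \enumerate{
#'   \item Step 1: factorize V ~ W1 H1 by multiplicative-update NMF ([nmf]).
#'   \item Feature selection ([select_features]): from the fitted profile
#'     matrix W1 keep the informative bin-pairs — by default those with high
#'     cell-type specificity (entropy feature score above a median-based
#'     threshold) among intrachromosomal contacts, and high across-cell-type
#'     variation (SD above a mean-based threshold) among interchromosomal
#'     contacts.
#'   \item Step 2: factorize the reduced matrix V* (the selected rows of V)
#'     into W* H*, and column-normalize H* so each sample's estimated
#'     proportions sum to one.
#' }
#'
#' @param V a [bulk_matrix], or a plain non-negative matrix (then `cls` gives
#'   the per-row contact class; default all intrachromosomal).
#' @param k assumed number of cell types (>= 2).
#' @param strategy feature-selection strategy (see [select_features]).
#' @param params strategy parameters.
#' @param restarts,max_iter,tol NMF fitting controls (see [nmf]); both NMF
#'   steps use the same settings.
#' @param seed master seed; the two NMF stages run on independent derived
#'   substreams, recorded in the result's provenance.
#' @param cls optional per-feature class vector for plain-matrix input.
#' @return An object of class `hicdecon`: list with
#'   \item{proportions}{k x n matrix, columns summing to 1.}
#'   \item{profiles}{W*, the p* x k profile matrix over selected features.}
#'   \item{selected_features}{IDs of the informative bin-pairs.}
#'   \item{feature_stats}{the full [select_features] table.}
#'   \item{pve, rss, objective}{goodness of fit of the step-2 factorization
#'     on V*.}
#'   \item{fit}{the step-2 `nmf_fit`.}
#'   \item{provenance}{seeds, strategy, fitting controls.}
#' @examples
#' study <- simulate_mixture_study("three_type", seed = 1)
#' fit <- hicdecon(study$bulk, k = 3, restarts = 5, seed = 1)
#' fit
#' evaluate_proportions(coef(fit), study$truth)
#' @export
hicdecon <- function(V, k, strategy = "two_step", params = list(),
                     restarts = 30, max_iter = 2000, tol = 1e-6,
                     seed = NULL, cls = NULL) {
  if (k < 2) stop("k must be at least 2")
  if (!inherits(V, "bulk_matrix")) {
    Vm <- as.matrix(V)
    cls <- cls %||% rep("intra", nrow(Vm))
    feats <- data.frame(chromA = "chrU", startA = seq_len(nrow(Vm)) - 1,
                        chromB = "chrU", startB = seq_len(nrow(Vm)) - 1)
    feats$cls <- cls
    if (!is.null(rownames(Vm))) {
      V <- structure(list(values = Vm,
                          features = data.frame(feats, row.names = rownames(Vm)),
                          resolution = 1), class = "bulk_matrix")
    } else {
      V <- bulk_matrix(Vm, feats, resolution = 1)
    }
  }
  if (ncol(V$values) < k)
    warning("fewer samples than cell types; estimates will be unstable")
  V <- suppressMessages(drop_zero_features(V))
  if (is.null(seed)) seed <- sample.int(2147483646L, 1)
  s1 <- derive_seed(seed, 1)
  s2 <- derive_seed(seed, 0)

  step1 <- nmf(V$values, k, restarts = restarts, max_iter = max_iter,
               tol = tol, seed = s1)
  fs <- select_features(V, step1$W, strategy = strategy, params = params)
  sel <- which(fs$selected)
  fallback <- NULL
  if (length(sel) == 0) {
    warning("no informative bin-pairs selected; falling back to the full matrix")
    fallback <- "none_selected"
    sel <- seq_len(nrow(V$values))
  } else if (length(sel) < k) {
    warning("fewer selected features than k; falling back to the top ",
            10 * k, " features by score rank")
    fallback <- "top_rank"
    score <- ifelse(fs$cls == "intra", rank(fs$FS, na.last = FALSE),
                    rank(fs$SD, na.last = FALSE)) / nrow(fs)
    sel <- order(-score)[seq_len(min(10 * k, nrow(fs)))]
  }
  Vstar <- V[sel, ]
  step2 <- nmf(Vstar$values, k, restarts = restarts, max_iter = max_iter,
               tol = tol, seed = s2)
  proportions <- normalize_proportions(step2$H)
  rownames(proportions) <- paste0("cluster", seq_len(k))
  res <- list(
    proportions = proportions,
    profiles = step2$W,
    selected_features = rownames(Vstar$values),
    feature_stats = fs,
    k = k,
    pve = explained_variance(Vstar$values, step2$W, step2$H),
    rss = rss(Vstar$values, step2$W, step2$H),
    objective = step2$objective,
    step1_objective = step1$objective,
    fit = step2,
    Vstar = Vstar,
    provenance = list(seed = seed, stage_seeds = c(step1 = s1, step2 = s2),
                      strategy = strategy, params = params,
                      restarts = restarts, max_iter = max_iter, tol = tol,
                      fallback = fallback, resolution = V$resolution,
                      p_input = nrow(V$values), p_selected = length(sel)),
    call = match.call())
  class(res) <- "hicdecon"
  res
}

#' Per-chromosome feature selection followed by one genome-wide fit
#'
#' For large intrachromosomal inputs, step 1 (NMF plus feature selection) is
#' run independently on each chromosome, the informative bin-pairs are
#' concatenated across chromosomes, and a single step-2 factorization of the
#' concatenated reduced matrix yields genome-wide proportions.  With a single
#' chromosome this reproduces [hicdecon] exactly (same derived seeds).
#'
#' @inheritParams hicdecon
#' @return a `hicdecon` object.
#' @export
hicdecon_per_chromosome <- function(V, k, strategy = "two_step",
                                    params = list(), restarts = 30,
                                    max_iter = 2000, tol = 1e-6, seed = NULL) {
  stopifnot(inherits(V, "bulk_matrix"))
  if (k < 2) stop("k must be at least 2")
  if (any(V$features$cls != "intra"))
    stop("per-chromosome mode expects intrachromosomal features only")
  V <- suppressMessages(drop_zero_features(V))
  if (is.null(seed)) seed <- sample.int(2147483646L, 1)
  chroms <- unique(V$features$chromA)
  chroms <- chroms[order(chrom_rank(chroms))]
  sel_ids <- character(0)
  stats_list <- list()
  chrom_seeds <- integer(0)
  for (ci in seq_along(chroms)) {
    idx <- which(V$features$chromA == chroms[ci])
    if (length(idx) < k) {
      warning("chromosome ", chroms[ci], " has fewer than k features; skipped")
      next
    }
    s_c <- derive_seed(seed, ci)
    chrom_seeds[chroms[ci]] <- s_c
    Vc <- V[idx, ]
    step1 <- nmf(Vc$values, k, restarts = restarts, max_iter = max_iter,
                 tol = tol, seed = s_c)
    fs <- select_features(Vc, step1$W, strategy = strategy, params = params)
    stats_list[[chroms[ci]]] <- fs
    sel_ids <- c(sel_ids, fs$feature[fs$selected])
  }
  fs_all <- do.call(rbind, stats_list)
  rownames(fs_all) <- NULL
  fallback <- NULL
  if (length(sel_ids) == 0) {
    warning("no informative bin-pairs on any chromosome; using the full matrix")
    fallback <- "none_selected"
    sel_ids <- rownames(V$values)
  }
  Vstar <- V[match(sel_ids, rownames(V$values)), ]
  s2 <- derive_seed(seed, 0)
  step2 <- nmf(Vstar$values, k, restarts = restarts, max_iter = max_iter,
               tol = tol, seed = s2)
  proportions <- normalize_proportions(step2$H)
  rownames(proportions) <- paste0("cluster", seq_len(k))
  res <- list(
    proportions = proportions,
    profiles = step2$W,
    selected_features = rownames(Vstar$values),
    feature_stats = fs_all,
    k = k,
    pve = explained_variance(Vstar$values, step2$W, step2$H),
    rss = rss(Vstar$values, step2$W, step2$H),
    objective = step2$objective,
    fit = step2,
    Vstar = Vstar,
    provenance = list(seed = seed,
                      stage_seeds = c(chrom_seeds, step2 = s2),
                      strategy = strategy, params = params,
                      restarts = restarts, max_iter = max_iter, tol = tol,
                      fallback = fallback, resolution = V$resolution,
                      p_input = nrow(V$values), p_selected = nrow(Vstar$values),
                      per_chromosome = TRUE),
    call = match.call())
  class(res) <- "hicdecon"
  res
}

#' Column-normalize a coefficient matrix into proportions
#'
#' @param H k x n non-negative matrix with positive column sums.
#' @return H with each column divided by its sum (columns sum to 1).
#' @export
normalize_proportions <- function(H) {
  cs <- colSums(H)
  if (any(cs <= 0)) {
    bad <- colnames(H)[cs <= 0] %||% which(cs <= 0)
    stop("zero column sum(s) in coefficient matrix: ", paste(bad, collapse = ", "))
  }
  sweep(H, 2, cs, "/")
}

#' Model selection over Hi-C readouts, resolutions and k
#'
#' Fits the two-step deconvolution for every combination of input matrix and
#' k and ranks the fits by the proportion of variance explained on the
#' reduced matrix V*.  PVE requires no knowledge of the true proportions,
#' making it a practical model-selection criterion.  Ties are broken in
#' favour of the larger bin size, then the smaller k (the coarser, more
#' parsimonious model).
#'
#' @param inputs named list of [bulk_matrix] objects (one per candidate
#'   readout/resolution).
#' @param k_range integer vector of candidate k values (e.g. 3:7).
#' @param ... passed to [hicdecon].
#' @param seed master seed (each fit gets a derived substream).
#' @return An object of class `hicdecon_grid`: ranked data frame (`table`)
#'   with columns input, resolution, k, pve, p_selected, plus the list of
#'   fits; `best` is the top-ranked fit.
#' @export
hicdecon_grid <- function(inputs, k_range, ..., seed = NULL) {
  stopifnot(length(inputs) >= 1, length(k_range) >= 1)
  if (is.null(names(inputs)))
    names(inputs) <- paste0("input", seq_along(inputs))
  if (is.null(seed)) seed <- sample.int(2147483646L, 1)
  rows <- list()
  fits <- list()
  idx <- 0
  for (nm in names(inputs)) for (k in k_range) {
    idx <- idx + 1
    fit <- hicdecon(inputs[[nm]], k = k, ..., seed = derive_seed(seed, 200 + idx))
    tag <- paste0(nm, "_k", k)
    fits[[tag]] <- fit
    rows[[tag]] <- data.frame(
      input = nm, resolution = fit$provenance$resolution, k = k,
      pve = fit$pve, p_selected = fit$provenance$p_selected,
      stringsAsFactors = FALSE)
  }
  tab <- rank_candidates(do.call(rbind, rows))
  structure(list(table = tab, fits = fits,
                 best = fits[[paste0(tab$input[1], "_k", tab$k[1])]]),
            class = "hicdecon_grid")
}

# PVE-descending ranking; ties prefer the larger bin size, then the smaller k
# (the coarser, more parsimonious candidate)
rank_candidates <- function(tab) {
  tab <- tab[order(-tab$pve, -tab$resolution, tab$k), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' @export
print.hicdecon_grid <- function(x, ...) {
  cat("deconvolution model selection (ranked by PVE):\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' @export
print.hicdecon <- function(x, ...) {
  cat(sprintf("two-step Hi-C deconvolution: k = %d cell types, %d samples\n",
              x$k, ncol(x$proportions)))
  cat(sprintf("  informative bin-pairs: %d of %d (strategy: %s)\n",
              x$provenance$p_selected, x$provenance$p_input,
              x$provenance$strategy))
  cat(sprintf("  proportion of variance explained (V*): %.4f\n", x$pve))
  invisible(x)
}

#' @export
summary.hicdecon <- function(object, ...) {
  cls_tab <- table(factor(
    object$feature_stats$cls[object$feature_stats$selected],
    levels = c("intra", "inter")))
  structure(list(k = object$k, n = ncol(object$proportions),
                 proportions = object$proportions,
                 p_input = object$provenance$p_input,
                 p_selected = object$provenance$p_selected,
                 selected_by_cls = cls_tab,
                 pve = object$pve, rss = object$rss,
                 strategy = object$provenance$strategy,
                 seed = object$provenance$seed),
            class = "summary.hicdecon")
}

#' @export
print.summary.hicdecon <- function(x, ...) {
  cat(sprintf("two-step Hi-C deconvolution (k = %d, %d samples)\n", x$k, x$n))
  cat(sprintf("features: %d input, %d informative (%d intra, %d inter)\n",
              x$p_input, x$p_selected,
              x$selected_by_cls[["intra"]], x$selected_by_cls[["inter"]]))
  cat(sprintf("fit on V*: PVE %.4f, RSS %.4g\n", x$pve, x$rss))
  cat("\nestimated cell type proportions:\n")
  print(round(x$proportions, 3))
  invisible(x)
}

#' @export
coef.hicdecon <- function(object, ...) object$proportions

#' @export
fitted.hicdecon <- function(object, ...) object$profiles %*% object$fit$H

#' @export
residuals.hicdecon <- function(object, ...) {
  object$Vstar$values - fitted(object)
}

#' Estimate proportions for new samples under fitted profiles
#'
#' Holds the fitted profile matrix W* fixed and solves for non-negative
#' coefficients of new sample columns (over the same selected features) by
#' the H-side multiplicative updates, then column-normalizes.
#'
#' @param object a fitted `hicdecon` model.
#' @param newdata matrix (or [bulk_matrix]) whose rows cover the model's
#'   selected features.
#' @param max_iter,tol update controls.
#' @param ... unused.
#' @return k x n_new matrix of proportion estimates.
#' @export
predict.hicdecon <- function(object, newdata, max_iter = 2000, tol = 1e-8, ...) {
  if (inherits(newdata, "bulk_matrix")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$selected_features, rownames(newdata))
  if (length(miss))
    stop("newdata lacks ", length(miss), " selected feature(s)")
  Vn <- newdata[object$selected_features, , drop = FALSE]
  W <- object$profiles
  set.seed(derive_seed(object$provenance$seed, 2))
  H <- matrix(stats::runif(ncol(W) * ncol(Vn), 0, max(Vn)), ncol(W), ncol(Vn))
  WtV <- crossprod(W, Vn)
  WtW <- crossprod(W)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (WtV / pmax(WtW %*% H, 1e-16))
    obj <- sum((Vn - W %*% H)^2)
    if (is.finite(prev) && prev > 0 && (prev - obj) / prev < tol) break
    prev <- obj
  }
  pr <- normalize_proportions(H)
  dimnames(pr) <- list(rownames(object$proportions), colnames(Vn))
  pr
}

#' Plot estimated cell-type proportions
#'
#' Stacked barplot of the per-sample proportion estimates.
#'
#' @param x a `hicdecon` object.
#' @param ... passed to [graphics::barplot].
#' @export
plot.hicdecon <- function(x, ...) {
  graphics::barplot(x$proportions, col = grDevices::hcl.colors(x$k, "Dark 3"),
                    legend.text = rownames(x$proportions),
                    las = 2, ylab = "estimated proportion", ...)
  invisible(x)
}

#' Write a fitted deconvolution to disk
#'
#' Emits the proportions TSV (samples x clusters), profiles TSV, the
#' selected-feature statistics TSV, and a JSON manifest with fit statistics
#' and provenance.
#'
#' @param fit a `hicdecon` object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_hicdecon <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(t(fit$proportions), file.path(dir, "proportions.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(data.frame(feature = fit$selected_features,
                                fit$profiles, check.names = FALSE),
                     file.path(dir, "profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_feature_stats(fit$feature_stats, file.path(dir, "features.tsv"))
  manifest <- list(k = fit$k, pve = fit$pve, rss = fit$rss,
                   objective = fit$objective,
                   seed = fit$provenance$seed,
                   strategy = fit$provenance$strategy,
                   p_input = fit$provenance$p_input,
                   p_selected = fit$provenance$p_selected)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
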