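#' Cluster-specific bin-pairs from the fitted profile matrix
#'
#' Row-normalizes W* (each bin-pair's profile sums to 1 across clusters) and
#' assigns bin-pair i to cluster j when the normalized element is at least
#' `threshold` (inclusive).  With small k a bin-pair can exceed the threshold
#' in more than one cluster and is then assigned to each.
#'
#' @param W_star p* x k profile matrix with positive row sums; row names are
#'   feature IDs.
#' @param threshold row-normalized profile cutoff in (0, 1); default 0.3.
#' @return named list (one element per cluster) of feature ID vectors, with
#'   the row-normalized matrix attached as attribute `normalized`.
#' @export
cluster_specific_binpairs <- function(W_star, threshold = 0.3) {
  stopifnot(threshold > 0, threshold < 1)
  W_star <- as.matrix(W_star)
  rs <- rowSums(W_star)
  if (any(rs <= 0)) stop("W* rows must have positive sums")
  norm <- W_star / rs
  ids <- rownames(W_star) %||% as.character(seq_len(nrow(W_star)))
  cl_names <- colnames(W_star) %||% paste0("cluster", seq_len(ncol(W_star)))
  out <- lapply(seq_len(ncol(norm)), function(j) ids[norm[, j] >= threshold])
  names(out) <- cl_names
  attr(out, "normalized") <- norm
  out
}

#' Unique 1-D bins of a set of bin-pair features
#'
#' Expands bin-pair IDs (`"chrA:s-e|chrB:s-e"`) into their anchor bins and
#' deduplicates.
#'
#' @param ids character vector of bin-pair feature IDs.
#' @return data frame with columns chrom, start, end.
#' @export
binpair_bins <- function(ids) {
  f <- parse_feature_ids(ids)
  res <- attr(f, "resolution")
  bins <- rbind(
    data.frame(chrom = f$chromA, start = f$startA, end = f$startA + res),
    data.frame(chrom = f$chromB, start = f$startB, end = f$startB + res))
  unique(bins)
}

bins_to_granges <- function(bins) {
  GenomicRanges::GRanges(bins$chrom,
                         IRanges::IRanges(start = bins$start + 1, end = bins$end))
}

#' Read a BED (3+ column) interval file
#'
#' @param path BED path (chrom, start, end, further columns ignored except
#'   name/strand when present).
#' @return data frame with columns chrom, start, end (0-based half-open) and,
#'   when present, name and strand.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED input needs at least 3 columns")
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.numeric(df[[2]]), end = as.numeric(df[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4) out$name <- as.character(df[[4]])
  if (ncol(df) >= 6) out$strand <- as.character(df[[6]])
  out
}

#' Enrichment of an annotation within a cluster's bins
#'
#' Tests whether the 1-D bins specific to a cluster overlap a cell-type
#' annotation (e.g. cell-type-specific enhancers) more often than the
#' remaining bins of the feature universe.  A bin counts as overlapping when
#' it shares at least one bp with any annotation interval.  The 2 x 2 table
#' (in/out of cluster x overlapping/not) is tested by a chi-squared test
#' with 1 df (Yates continuity correction by default).
#'
#' @param cluster_bins data frame (chrom, start, end) of the cluster's bins.
#' @param annotation data frame (chrom, start, end) of annotation intervals.
#' @param universe_bins data frame of all unique bins among selected
#'   features; must contain `cluster_bins`.
#' @param correct apply the continuity correction?
#' @return list with `statistic`, `p.value`, `table`, and `reliable` (FALSE,
#'   with a warning, when any expected cell count is below 1).
#' @export
enrichment_test <- function(cluster_bins, annotation, universe_bins,
                            correct = TRUE) {
  uni <- bins_to_granges(universe_bins)
  ann <- bins_to_granges(annotation)
  key <- function(b) paste(b$chrom, b$start, b$end)
  in_cluster <- key(universe_bins) %in% key(cluster_bins)
  overlaps <- IRanges::overlapsAny(uni, ann)
  tab <- table(factor(in_cluster, levels = c(TRUE, FALSE)),
               factor(overlaps, levels = c(TRUE, FALSE)),
               dnn = c("in_cluster", "overlapping"))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  reliable <- all(expected >= 1)
  if (!reliable)
    warning("expected cell count below 1; chi-squared p-value unreliable")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p.value = ct$p.value,
       table = tab, reliable = reliable)
}

#' Cell-type-specifically expressed genes
#'
#' A gene is specific to a cell type when its expression there exceeds the
#' mean of its expression in the other cell types by more than `margin`
#' (strict inequality, on the scale of the supplied table).
#'
#' @param expr numeric gene x cell-type matrix (row names = genes).
#' @param margin required expression difference; default 1.
#' @return named list, one gene-ID vector per cell type.
#' @export
celltype_specific_genes <- function(expr, margin = 1) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2) stop("need at least 2 cell types")
  genes <- rownames(expr) %||% as.character(seq_len(nrow(expr)))
  out <- lapply(seq_len(ncol(expr)), function(t) {
    other_mean <- rowMeans(expr[, -t, drop = FALSE])
    genes[expr[, t] - other_mean > margin]
  })
  names(out) <- colnames(expr) %||% paste0("type", seq_len(ncol(expr)))
  out
}

#' Genes whose TSS lies within a flank of a cluster's bins
#'
#' A gene is linked to a cluster when the window of `flank` bp on each side
#' of its transcription start site overlaps any of the cluster's bins
#' (half-open interval arithmetic; a TSS exactly on a bin boundary counts,
#' symmetric flank regardless of strand).
#'
#' @param cluster_bins data frame (chrom, start, end) of the cluster's bins.
#' @param tss data frame with columns chrom, start (0-based TSS position) and
#'   name (gene ID); e.g. from [read_bed].
#' @param flank half-width of the TSS window in bp; default 2000.
#' @return character vector of gene IDs.
#' @export
genes_in_binpairs <- function(cluster_bins, tss, flank = 2000) {
  if (nrow(cluster_bins) == 0) return(character(0))
  if (is.null(tss$name)) stop("tss needs a `name` column of gene IDs")
  hit <- logical(nrow(tss))
  for (i in seq_len(nrow(tss))) {
    pos <- tss$start[i]
    same <- cluster_bins$chrom == tss$chrom[i]
    hit[i] <- any(same &
                    pos - flank < cluster_bins$end &
                    pos + flank > cluster_bins$start)
  }
  unique(tss$name[hit])
}

#' Expression shift of a cluster's genes toward its assigned cell type
#'
#' For the genes linked to a cluster, tests whether their expression in the
#' cluster's assigned cell type is stochastically higher than in each other
#' cell type, by one-sided two-sample Wilcoxon rank-sum tests (assigned >
#' other).
#'
#' @param expr numeric gene x cell-type matrix.
#' @param genes gene IDs of the cluster (>= 3 required).
#' @param assigned_type column name of the assigned cell type.
#' @param other_types column names to test against (default: all others).
#' @return named numeric vector of one-sided p-values.
#' @export
expression_shift_test <- function(expr, genes, assigned_type,
                                  other_types = NULL) {
  expr <- as.matrix(expr)
  genes <- intersect(genes, rownames(expr))
  if (length(genes) < 3)
    stop("need at least 3 genes with expression values in the cluster set")
  if (!assigned_type %in% colnames(expr))
    stop("unknown assigned_type: ", assigned_type)
  other_types <- other_types %||% setdiff(colnames(expr), assigned_type)
  x <- expr[genes, assigned_type]
  p <- vapply(other_types, function(ot) {
    stats::wilcox.test(x, expr[genes, ot], alternative = "greater",
                       exact = FALSE)$p.value
  }, numeric(1))
  p
}

#' Annotate deconvolution clusters against cell-type features
#'
#' Convenience wrapper: calls cluster-specific bin-pairs from a fitted model,
#' expands them to unique bins, and tests each (cluster, annotation) pair for
#' enrichment.  Cluster-to-cell-type assignment is reported, never forced:
#' inspect the enrichment table and map labels explicitly.
#'
#' @param fit a `hicdecon` model.
#' @param annotations named list of annotation interval data frames (chrom,
#'   start, end), e.g. per-cell-type enhancers.
#' @param threshold row-normalized profile cutoff (see
#'   [cluster_specific_binpairs]).
#' @param correct continuity correction for the chi-squared tests.
#' @return data frame with one row per (cluster, annotation): statistic,
#'   p.value, n_bins, reliable.
#' @export
annotate_clusters <- function(fit, annotations, threshold = 0.3,
                              correct = TRUE) {
  W <- fit$profiles
  rownames(W) <- fit$selected_features
  sets <- cluster_specific_binpairs(W, threshold)
  universe <- binpair_bins(fit$selected_features)
  rows <- list()
  for (cl in names(sets)) {
    cl_bins <- if (length(sets[[cl]])) binpair_bins(sets[[cl]]) else
      universe[0, ]
    for (an in names(annotations)) {
      et <- if (nrow(cl_bins) == 0) {
        list(statistic = NA_real_, p.value = NA_real_, reliable = FALSE)
      } else {
        suppressWarnings(enrichment_test(cl_bins, annotations[[an]],
                                         universe, correct = correct))
      }
      rows[[paste(cl, an)]] <- data.frame(
        cluster = cl, annotation = an, statistic = et$statistic,
        p.value = et$p.value, n_bins = nrow(cl_bins),
        reliable = et$reliable, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
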