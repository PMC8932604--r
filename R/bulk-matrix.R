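#' Bin-pair by sample contact matrix
#'
#' A `bulk_matrix` holds the non-negative mixture matrix V consumed by the
#' deconvolution: one row per bin-pair feature, one column per bulk Hi-C
#' sample, together with the genomic metadata of every feature and its
#' intra/interchromosomal class.
#'
#' @param values numeric p x n matrix, all entries >= 0.
#' @param features data frame with columns `chromA`, `startA`, `chromB`,
#'   `startB` (0-based bin starts) and optionally `cls`; one row per row of
#'   `values`.
#' @param resolution bin width in bp.
#' @param samples optional character vector of sample IDs (defaults to the
#'   column names of `values`).
#' @return An object of class `bulk_matrix`: a list with elements `values`,
#'   `features`, `resolution`.
#' @export
bulk_matrix <- function(values, features, resolution, samples = NULL) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("bulk matrix entries must be non-negative")
  if (nrow(values) != nrow(features))
    stop("features must have one row per matrix row")
  if (!is.null(samples)) colnames(values) <- samples
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample", seq_len(ncol(values)))
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (is.null(features$cls))
    features$cls <- ifelse(features$chromA == features$chromB, "intra", "inter")
  ids <- feature_id(features, resolution)
  if (anyDuplicated(ids)) stop("duplicate bin-pair features")
  rownames(values) <- ids
  rownames(features) <- ids
  structure(list(values = values, features = features, resolution = resolution),
            class = "bulk_matrix")
}

feature_id <- function(features, resolution) {
  num <- function(x) format(x, scientific = FALSE, trim = TRUE)
  paste0(features$chromA, ":", num(features$startA), "-",
         num(features$startA + resolution), "|",
         features$chromB, ":", num(features$startB), "-",
         num(features$startB + resolution))
}

#' Parse bin-pair feature identifiers
#'
#' Parses IDs of the form `"chrA:start-end|chrB:start-end"` into a feature
#' data frame; the bin width is inferred from the first interval.
#'
#' @param ids character vector of feature identifiers.
#' @return data frame with columns chromA, startA, chromB, startB, cls and an
#'   attribute `resolution`.
#' @export
parse_feature_ids <- function(ids) {
  m <- regmatches(ids, regexec("^([^:|]+):(\\d+)-(\\d+)\\|([^:|]+):(\\d+)-(\\d+)$", ids))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad))
    stop("malformed feature ID(s): ", paste(utils::head(ids[bad], 3), collapse = ", "))
  get <- function(i) vapply(m, `[[`, "", i + 1L)
  feats <- data.frame(
    chromA = get(1), startA = as.numeric(get(2)),
    chromB = get(4), startB = as.numeric(get(5)),
    stringsAsFactors = FALSE)
  feats$cls <- ifelse(feats$chromA == feats$chromB, "intra", "inter")
  attr(feats, "resolution") <- as.numeric(get(3))[1] - feats$startA[1]
  feats
}

#' @export
print.bulk_matrix <- function(x, ...) {
  tab <- table(factor(x$features$cls, levels = c("intra", "inter")))
  cat(sprintf("bulk Hi-C mixture matrix: %d bin-pairs x %d samples (resolution %s bp)\n",
              nrow(x$values), ncol(x$values), format(x$resolution, big.mark = ",")))
  cat(sprintf("  intra: %d  inter: %d\n", tab[["intra"]], tab[["inter"]]))
  invisible(x)
}

#' @export
dim.bulk_matrix <- function(x) dim(x$values)

#' @export
`[.bulk_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  structure(list(values = x$values[i, j, drop = FALSE],
                 features = x$features[i, , drop = FALSE],
                 resolution = x$resolution),
            class = "bulk_matrix")
}

#' Subset a bulk matrix by contact class
#'
#' @param x a `bulk_matrix`.
#' @param cls `"intra"`, `"inter"` or `"both"`.
#' @return a `bulk_matrix` restricted to the requested class.
#' @export
subset_cls <- function(x, cls = c("both", "intra", "inter")) {
  cls <- match.arg(cls)
  if (cls == "both") return(x)
  x[x$features$cls == cls, ]
}

#' @export
as.matrix.bulk_matrix <- function(x, ...) x$values
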