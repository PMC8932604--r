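#' Read Hi-C contact data
#'
#' Reads either a long-format contact list (five tab-separated columns:
#' chrom1, pos1, chrom2, pos2, count; header optional) or a pre-binned
#' bin-pair x sample matrix whose first column carries feature IDs of the form
#' `"chrA:start-end|chrB:start-end"`.  A Matrix Market triplet file with
#' sidecar feature/sample lists is also accepted for pre-binned input.
#'
#' @param path path to the input file.
#' @param format `"long_tsv"` or `"prebinned_matrix"`.
#' @param features,samples for Matrix Market input (`path` ending in `.mtx`),
#'   paths to one-ID-per-line sidecar files naming the rows and columns.
#' @return For `"long_tsv"` a data frame of contact records (chrom1, pos1,
#'   chrom2, pos2, count); for `"prebinned_matrix"` a [bulk_matrix].
#' @export
read_contacts <- function(path, format = c("long_tsv", "prebinned_matrix"),
                          features = NULL, samples = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "long_tsv") {
    nf <- utils::count.fields(path, sep = "\t", comment.char = "")
    first <- utils::read.table(path, sep = "\t", nrows = 1,
                               colClasses = "character")
    header <- is.na(suppressWarnings(as.numeric(first[[2]])))
    body_lines <- if (header) seq_along(nf)[-1] else seq_along(nf)
    bad <- body_lines[nf[body_lines] != 5L]
    if (length(bad))
      stop("malformed contact line(s) (expected 5 tab-separated fields): line ",
           paste(utils::head(bad, 5), collapse = ", "))
    rec <- utils::read.table(path, sep = "\t", header = header,
                             col.names = c("chrom1", "pos1", "chrom2", "pos2", "count"),
                             colClasses = c("character", "numeric", "character",
                                            "numeric", "numeric"))
    bad_count <- which(is.na(rec$count) | rec$count < 0)
    if (length(bad_count))
      stop("negative or missing contact count at record ",
           paste(utils::head(bad_count, 5), collapse = ", "))
    rec
  } else {
    if (grepl("\\.mtx$", path)) {
      if (is.null(features) || is.null(samples))
        stop("Matrix Market input requires `features` and `samples` sidecar paths")
      m <- as.matrix(Matrix::readMM(path))
      ids <- readLines(features)
      sn <- readLines(samples)
      if (nrow(m) != length(ids) || ncol(m) != length(sn))
        stop("sidecar dimensions do not match the matrix")
      feats <- parse_feature_ids(ids)
      bulk_matrix(m, feats, attr(feats, "resolution"), samples = sn)
    } else {
      tab <- utils::read.table(path, sep = "\t", header = TRUE,
                               check.names = FALSE, stringsAsFactors = FALSE)
      ids <- as.character(tab[[1]])
      m <- as.matrix(tab[, -1, drop = FALSE])
      if (any(is.na(m))) stop("non-numeric entries in pre-binned matrix")
      feats <- parse_feature_ids(ids)
      bulk_matrix(m, feats, attr(feats, "resolution"))
    }
  }
}

#' Filter contact records for self-ligation artifacts and duplicates
#'
#' Removes intrachromosomal records whose genomic distance is below
#' `min_cis_distance` (short-range products of re-ligated single fragments);
#' interchromosomal records are never touched by the distance rule.
#' Optionally collapses exact duplicate records after canonical anchor
#' ordering, keeping one record per unique position pair.
#'
#' @param records contact record data frame (see [read_contacts]).
#' @param min_cis_distance minimum |pos1 - pos2| (bp) retained for
#'   intrachromosomal records; the comparison is strict (`<` removed).
#' @param dedupe collapse duplicate records to a single record with count 1?
#' @return filtered contact record data frame.
#' @export
filter_reads <- function(records, min_cis_distance = 15000, dedupe = FALSE) {
  stopifnot(min_cis_distance >= 0)
  intra <- records$chrom1 == records$chrom2
  keep <- !intra | abs(records$pos1 - records$pos2) >= min_cis_distance
  records <- records[keep, , drop = FALSE]
  if (dedupe && nrow(records)) {
    swap <- chrom_rank(records$chrom1) > chrom_rank(records$chrom2) |
      (records$chrom1 == records$chrom2 & records$pos1 > records$pos2)
    a_chrom <- ifelse(swap, records$chrom2, records$chrom1)
    a_pos <- ifelse(swap, records$pos2, records$pos1)
    b_chrom <- ifelse(swap, records$chrom1, records$chrom2)
    b_pos <- ifelse(swap, records$pos1, records$pos2)
    key <- paste(a_chrom, a_pos, b_chrom, b_pos, sep = "\r")
    first <- !duplicated(key)
    records <- records[first, , drop = FALSE]
    records$count <- 1
  }
  rownames(records) <- NULL
  records
}

#' Bin contact records into canonical bin-pairs
#'
#' Maps each record to the bin-pair (floor(pos / resolution) on both anchors),
#' canonicalizes anchor order (chromosome order, then coordinate) so that each
#' unordered pair has a single key, and accumulates counts.
#'
#' @param records contact record data frame.
#' @param resolution bin width in bp (> 0).
#' @param mode keep `"intra"`, `"inter"` or `"both"` classes.
#' @param chromosomes optional declared chromosome list; records on other
#'   chromosomes raise an error.
#' @return data frame (chromA, startA, chromB, startB, cls, count) with
#'   attribute `resolution` — a sparse bin-pair count map.
#' @export
bin_contacts <- function(records, resolution, mode = c("both", "intra", "inter"),
                         chromosomes = NULL) {
  mode <- match.arg(mode)
  stopifnot(resolution > 0)
  if (!is.null(chromosomes)) {
    seen <- unique(c(records$chrom1, records$chrom2))
    unknown <- setdiff(seen, chromosomes)
    if (length(unknown))
      stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  binA <- floor(records$pos1 / resolution) * resolution
  binB <- floor(records$pos2 / resolution) * resolution
  swap <- chrom_rank(records$chrom1) > chrom_rank(records$chrom2) |
    (records$chrom1 == records$chrom2 & binA > binB)
  feats <- data.frame(
    chromA = ifelse(swap, records$chrom2, records$chrom1),
    startA = ifelse(swap, binB, binA),
    chromB = ifelse(swap, records$chrom1, records$chrom2),
    startB = ifelse(swap, binA, binB),
    stringsAsFactors = FALSE)
  feats$cls <- ifelse(feats$chromA == feats$chromB, "intra", "inter")
  keep <- switch(mode, both = rep(TRUE, nrow(feats)),
                 intra = feats$cls == "intra", inter = feats$cls == "inter")
  feats <- feats[keep, , drop = FALSE]
  counts <- records$count[keep]
  key <- paste(feats$chromA, feats$startA, feats$chromB, feats$startB, sep = "\r")
  agg <- rowsum(counts, key)
  first <- !duplicated(key)
  out <- feats[first, , drop = FALSE]
  out$count <- agg[match(key[first], rownames(agg)), 1]
  ord <- order(chrom_rank(out$chromA), out$startA,
               chrom_rank(out$chromB), out$startB)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "resolution") <- resolution
  out
}

#' Assemble per-sample bin-pair maps into a mixture matrix
#'
#' The feature universe is the union of bin-pairs observed in any sample
#' (zeros are informative for the factorization); missing entries are 0.
#' Features are ordered deterministically by chromosome order then
#' coordinates.
#'
#' @param maps named list of bin-pair count maps from [bin_contacts], one per
#'   sample, all at the same resolution.
#' @param mode restrict the assembled features to `"intra"`, `"inter"` or keep
#'   `"both"`.
#' @return a [bulk_matrix].
#' @export
assemble_matrix <- function(maps, mode = c("both", "intra", "inter")) {
  mode <- match.arg(mode)
  stopifnot(length(maps) >= 1)
  res <- vapply(maps, function(m) attr(m, "resolution"), numeric(1))
  if (length(unique(res)) != 1)
    stop("bin-pair maps have mixed resolutions: ", paste(unique(res), collapse = ", "))
  resolution <- res[1]
  if (is.null(names(maps))) names(maps) <- paste0("sample", seq_along(maps))
  if (mode != "both")
    maps <- lapply(maps, function(m) m[m$cls == mode, , drop = FALSE])
  all_feats <- unique(do.call(rbind, lapply(maps, function(m)
    m[, c("chromA", "startA", "chromB", "startB", "cls")])))
  ord <- order(chrom_rank(all_feats$chromA), all_feats$startA,
               chrom_rank(all_feats$chromB), all_feats$startB)
  all_feats <- all_feats[ord, , drop = FALSE]
  rownames(all_feats) <- NULL
  key <- function(f) paste(f$chromA, f$startA, f$chromB, f$startB, sep = "\r")
  uk <- key(all_feats)
  values <- vapply(maps, function(m) {
    v <- numeric(nrow(all_feats))
    v[match(key(m), uk)] <- m$count
    v
  }, numeric(nrow(all_feats)))
  values <- matrix(values, nrow = nrow(all_feats),
                   dimnames = list(NULL, names(maps)))
  bulk_matrix(values, all_feats, resolution)
}

#' Contacts-per-million normalization
#'
#' Scales each sample so its total contact count is 1,000,000.  The divisor is
#' the full intrachromosomal + interchromosomal total of the sample; when the
#' matrix has already been subset to one contact class, pass the pre-subset
#' totals via `totals` so the normalization is unchanged by the subsetting.
#'
#' @param V a [bulk_matrix] (or plain matrix).
#' @param totals optional named per-sample divisors (raw contact totals); by
#'   default the column sums of `V`.
#' @return a CPM-scaled object of the same class.
#' @export
cpm_normalize <- function(V, totals = NULL) {
  m <- if (inherits(V, "bulk_matrix")) V$values else as.matrix(V)
  tot <- totals %||% colSums(m)
  if (any(tot <= 0)) {
    bad <- colnames(m)[tot <= 0] %||% which(tot <= 0)
    stop("sample(s) with zero total contacts: ", paste(bad, collapse = ", "))
  }
  scaled <- sweep(m, 2, tot / 1e6, "/")
  if (inherits(V, "bulk_matrix"))
    bulk_matrix(scaled, V$features, V$resolution)
  else scaled
}

#' Drop features with no contacts in any sample
#'
#' All-zero rows carry no information and make the entropy feature score and
#' the multiplicative NMF updates ill-defined; they are removed here.
#'
#' @param V a [bulk_matrix].
#' @return `V` without all-zero rows; the number dropped is reported via
#'   `message()` (or a warning when everything is dropped).
#' @export
drop_zero_features <- function(V) {
  zero <- rowSums(V$values) == 0
  if (all(zero)) {
    warning("all features are zero across samples")
  } else if (any(zero)) {
    message(sum(zero), " all-zero feature(s) dropped")
  }
  V[!zero, ]
}
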