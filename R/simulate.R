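#' Synthetic cell-type contact probability profiles
#'
#' Builds a shared bin-pair universe over `n_chroms` chromosomes of
#' `bins_per_chrom` bins each (all intrachromosomal pairs including the
#' diagonal plus all interchromosomal pairs) and one contact probability
#' vector per cell type.  Intrachromosomal mass follows a power-law distance
#' decay, probability proportional to (1 + d/resolution)^(-decay_exponent),
#' scaled to a fixed cis fraction of total mass; interchromosomal mass is a
#' uniform floor over all trans pairs.  Each cell type then receives a
#' disjoint random set of `marker_count` marker bin-pairs whose probability is
#' multiplied by (1 + marker_boost) before renormalization — the cell-type-
#' specific contacts (e.g. type-specific loops or territory adjacencies) that
#' make deconvolution possible.  A contact specific to one cell type is also
#' largely absent from the others, so in every other type a marker's
#' probability is scaled down to `marker_background` of the baseline.
#' `marker_boost = 0` (with `marker_background = 1`) leaves all types
#' identical.
#'
#' @param n_types number of cell types (>= 2).
#' @param n_chroms,bins_per_chrom genome layout of the simulated universe.
#' @param resolution nominal bin width in bp.
#' @param decay_exponent power-law exponent of the cis distance decay.
#' @param cis_fraction share of baseline contact mass that is
#'   intrachromosomal (real downsampled scHi-C sits well above 0.5 after the
#'   cis:trans >= 1 filter).
#' @param marker_count marker bin-pairs per type.
#' @param marker_boost multiplicative enrichment of marker probability in the
#'   marker's own type (scalar or per-type).
#' @param marker_background fraction of baseline probability a marker keeps
#'   in the other cell types (0 = fully type-exclusive, 1 = no depletion).
#' @param marker_inter_frac fraction of each type's markers placed on
#'   interchromosomal bin-pairs (NULL = drawn uniformly from the whole
#'   universe).  At multi-Mb bin sizes, cell-type identity is carried largely
#'   by chromosome-territory adjacencies, i.e. trans bin-pairs.
#' @param type_labels optional cell-type names.
#' @param seed integer seed.
#' @return An object of class `celltype_profiles`: list with `features` (the
#'   bin-pair data frame), `probs` (features x types probability matrix, each
#'   column summing to 1), `markers` (per-type marker row indices),
#'   `resolution`.
#' @export
synth_profiles <- function(n_types = 3, n_chroms = 2, bins_per_chrom = 30,
                           resolution = 1e7, decay_exponent = 1,
                           cis_fraction = 0.7, marker_count = 40,
                           marker_boost = 5, marker_background = 0.1,
                           marker_inter_frac = NULL,
                           type_labels = NULL, seed = NULL) {
  stopifnot(n_types >= 2, n_chroms >= 1, bins_per_chrom >= 2,
            all(marker_boost >= 0), marker_background >= 0,
            marker_background <= 1)
  if (!is.null(seed)) set.seed(seed)
  chroms <- paste0("chr", seq_len(n_chroms))
  feats <- list()
  for (ci in seq_len(n_chroms)) {
    idx <- expand.grid(a = 0:(bins_per_chrom - 1), b = 0:(bins_per_chrom - 1))
    idx <- idx[idx$a <= idx$b, ]
    feats[[length(feats) + 1]] <- data.frame(
      chromA = chroms[ci], startA = idx$a * resolution,
      chromB = chroms[ci], startB = idx$b * resolution,
      stringsAsFactors = FALSE)
  }
  if (n_chroms >= 2) {
    for (ci in seq_len(n_chroms - 1)) for (cj in (ci + 1):n_chroms) {
      idx <- expand.grid(a = 0:(bins_per_chrom - 1), b = 0:(bins_per_chrom - 1))
      feats[[length(feats) + 1]] <- data.frame(
        chromA = chroms[ci], startA = idx$a * resolution,
        chromB = chroms[cj], startB = idx$b * resolution,
        stringsAsFactors = FALSE)
    }
  }
  features <- do.call(rbind, feats)
  features$cls <- ifelse(features$chromA == features$chromB, "intra", "inter")
  p <- nrow(features)

  base <- numeric(p)
  intra <- features$cls == "intra"
  d <- abs(features$startB - features$startA)[intra]
  decay <- (1 + d / resolution)^(-decay_exponent)
  if (any(intra)) base[intra] <- cis_fraction * decay / sum(decay)
  if (any(!intra)) base[!intra] <- (1 - cis_fraction) / sum(!intra)

  if (is.null(type_labels)) type_labels <- paste0("type", seq_len(n_types))
  marker_boost <- rep_len(marker_boost, n_types)
  marker_count <- rep_len(marker_count, n_types)
  probs <- matrix(0, p, n_types, dimnames = list(NULL, type_labels))
  markers <- list()
  if (is.null(marker_inter_frac)) {
    pool <- sample.int(p) # disjoint marker draws across types
    offset <- 0
    for (t in seq_len(n_types)) {
      mk <- pool[offset + seq_len(marker_count[t])]
      offset <- offset + marker_count[t]
      markers[[type_labels[t]]] <- sort(mk)
    }
  } else {
    marker_inter_frac <- rep_len(marker_inter_frac, n_types)
    pool_inter <- sample(which(!intra))
    pool_intra <- sample(which(intra))
    oi <- oa <- 0
    for (t in seq_len(n_types)) {
      n_i <- round(marker_inter_frac[t] * marker_count[t])
      mk <- c(pool_inter[oi + seq_len(n_i)],
              pool_intra[oa + seq_len(marker_count[t] - n_i)])
      oi <- oi + n_i
      oa <- oa + marker_count[t] - n_i
      markers[[type_labels[t]]] <- sort(mk)
    }
  }
  for (t in seq_len(n_types)) {
    pr <- base
    pr[unlist(markers)] <- pr[unlist(markers)] * marker_background
    own <- markers[[t]]
    pr[own] <- base[own] * (1 + marker_boost[t])
    probs[, t] <- pr / sum(pr)
  }
  structure(list(features = features, probs = probs, markers = markers,
                 resolution = resolution,
                 recipe = list(decay_exponent = decay_exponent,
                               cis_fraction = cis_fraction,
                               marker_boost = marker_boost)),
            class = "celltype_profiles")
}

#' @export
print.celltype_profiles <- function(x, ...) {
  cat(sprintf("synthetic cell-type contact profiles: %d bin-pairs x %d types\n",
              nrow(x$probs), ncol(x$probs)))
  invisible(x)
}

#' Draw synthetic single-cell contact maps
#'
#' Samples cells for each cell type: a per-cell depth from a truncated
#' log-normal law, then bin-pair counts as one multinomial draw of that depth
#' from the type's probability profile.  Cells are assigned round-robin to
#' `n_libraries` sequencing libraries.
#'
#' Real single cells of one type do not share one contact distribution:
#' cell-to-cell variability of the contact distance decay (cell cycle,
#' condensation state) is one of the strongest signals in single-cell Hi-C.
#' `cell_decay_sd` emulates it: each cell's intrachromosomal decay exponent
#' is drawn from Normal(decay_exponent, cell_decay_sd) and its probability
#' profile rebuilt around that exponent (marker boosts unchanged), so bulk
#' mixtures acquire backbone variation that is unrelated to cell-type
#' composition — the nuisance structure informative-feature selection is
#' meant to be robust against.  Set it to 0 for exchangeable cells.
#'
#' @param profiles a `celltype_profiles` object.
#' @param n_cells_per_type cells per type (scalar or per-type vector).
#' @param depth_meanlog,depth_sdlog parameters of the log-normal depth law.
#' @param depth_min lower truncation of the depth law (contacts).
#' @param cell_decay_sd sd of the per-cell distance-decay exponent.
#' @param n_libraries number of libraries cells are spread over.
#' @param seed integer seed.
#' @return An object of class `sc_contacts`: list with `counts` (sparse
#'   features x cells matrix), `cells` (data frame: cell_id, cell_type,
#'   library, depth, cis_trans), `features`, `resolution`.
#' @export
sample_cells <- function(profiles, n_cells_per_type = 60,
                         depth_meanlog = log(30000), depth_sdlog = 0.5,
                         depth_min = 500, cell_decay_sd = 0.15,
                         n_libraries = 2, seed = NULL) {
  stopifnot(inherits(profiles, "celltype_profiles"), cell_decay_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  types <- colnames(profiles$probs)
  n_cells <- rep_len(n_cells_per_type, length(types))
  total <- sum(n_cells)
  intra <- profiles$features$cls == "intra"
  d_bins <- abs(profiles$features$startB - profiles$features$startA) /
    profiles$resolution
  counts <- matrix(0, nrow(profiles$probs), total)
  meta <- vector("list", length(types))
  col <- 0
  for (t in seq_along(types)) {
    depths <- stats::rlnorm(n_cells[t], depth_meanlog, depth_sdlog)
    low <- depths < depth_min
    while (any(low)) { # resample the truncated tail
      depths[low] <- stats::rlnorm(sum(low), depth_meanlog, depth_sdlog)
      low <- depths < depth_min
    }
    depths <- round(depths)
    # rmultinom takes a single size per call: draw cell by cell
    for (i in seq_len(n_cells[t])) {
      pr <- profiles$probs[, t]
      if (cell_decay_sd > 0) {
        # tilt the cis decay of this cell around the population exponent;
        # marker boosts are already baked into pr, so apply the tilt as a
        # multiplicative reweighting of the cis part
        e_cell <- stats::rnorm(1, 0, cell_decay_sd)
        tilt <- (1 + d_bins[intra])^(-e_cell)
        pr[intra] <- pr[intra] * tilt
        pr <- pr / sum(pr)
      }
      counts[, col + i] <- stats::rmultinom(1, depths[i], pr)[, 1]
    }
    cis <- colSums(counts[intra, col + seq_len(n_cells[t]), drop = FALSE])
    trans <- depths - cis
    meta[[t]] <- data.frame(
      cell_id = sprintf("%s_c%03d", types[t], seq_len(n_cells[t])),
      cell_type = types[t],
      library = paste0("L", ((col + seq_len(n_cells[t]) - 1) %% n_libraries) + 1),
      depth = depths,
      cis_trans = ifelse(trans > 0, cis / trans, Inf),
      stringsAsFactors = FALSE)
    col <- col + n_cells[t]
  }
  cells <- do.call(rbind, meta)
  rownames(cells) <- NULL
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  colnames(counts) <- cells$cell_id
  structure(list(counts = counts, cells = cells,
                 features = profiles$features,
                 resolution = profiles$resolution),
            class = "sc_contacts")
}

#' @export
print.sc_contacts <- function(x, ...) {
  cat(sprintf("single-cell contact set: %d cells, %d bin-pair features\n",
              nrow(x$cells), nrow(x$counts)))
  print(table(x$cells$cell_type))
  invisible(x)
}

#' Quality-filter single cells before mixing
#'
#' Applies the standard scHi-C cell filters: cells with fewer than
#' `min_reads` contacts or a cis:trans ratio below `min_cis_trans` are
#' removed; then, to level sequencing depth across libraries and types, only
#' cells whose depth is strictly greater than the `q_low` quantile and
#' strictly less than the `q_high` quantile of the remaining pooled depths
#' are kept.
#'
#' @param cells an `sc_contacts` object.
#' @param min_reads minimum contact count (cells with fewer are removed).
#' @param min_cis_trans minimum cis:trans ratio (removal is strict `<`).
#' @param q_low,q_high depth quantile bounds (strict inequalities).
#' @return the filtered `sc_contacts`.
#' @export
filter_cells <- function(cells, min_reads = 1000, min_cis_trans = 1,
                         q_low = 0.20, q_high = 0.90) {
  stopifnot(inherits(cells, "sc_contacts"))
  keep <- cells$cells$depth >= min_reads & cells$cells$cis_trans >= min_cis_trans
  if (!any(keep))
    stop("no cells pass the read-count/cis:trans filters; relax min_reads or min_cis_trans")
  depths <- cells$cells$depth[keep]
  ok <- rep(TRUE, length(depths))
  if (q_low > 0) ok <- ok & depths > stats::quantile(depths, q_low)
  if (q_high < 1) ok <- ok & depths < stats::quantile(depths, q_high)
  keep[keep] <- ok
  if (!any(keep))
    stop("no cells pass the depth quantile filter; widen q_low/q_high")
  subset_cells(cells, keep)
}

subset_cells <- function(x, keep) {
  structure(list(counts = x$counts[, keep, drop = FALSE],
                 cells = x$cells[keep, , drop = FALSE],
                 features = x$features, resolution = x$resolution),
            class = "sc_contacts")
}

#' Downsample every cell to the shallowest cell's depth
#'
#' Finds the minimum depth m over all cells and replaces each cell's counts
#' by one multinomial draw of size m with probabilities proportional to its
#' observed counts, so every cell ends at exactly m contacts and a bin-pair
#' unobserved in a cell stays unobserved.
#'
#' @param cells an `sc_contacts` object (>= 1 cell).
#' @param seed integer seed.
#' @return the depth-equalized `sc_contacts`.
#' @export
downsample_cells <- function(cells, seed = NULL) {
  stopifnot(inherits(cells, "sc_contacts"), nrow(cells$cells) >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- min(cells$cells$depth)
  counts <- as.matrix(cells$counts)
  intra <- cells$features$cls == "intra"
  for (i in seq_len(ncol(counts))) {
    if (sum(counts[, i]) > m)
      counts[, i] <- stats::rmultinom(1, m, counts[, i])[, 1]
  }
  cells$counts <- Matrix::Matrix(counts, sparse = TRUE)
  cells$cells$depth <- Matrix::colSums(cells$counts)
  cis <- Matrix::colSums(cells$counts[intra, , drop = FALSE])
  trans <- cells$cells$depth - cis
  cells$cells$cis_trans <- ifelse(trans > 0, cis / trans, Inf)
  cells
}

#' Mixture design: cell-type proportions per bulk sample
#'
#' @param proportions types x samples matrix; columns must sum to 1.
#' @param replicates number of replicate studies the design is used for.
#' @return an object of class `mixture_design`.
#' @export
mixture_design <- function(proportions, replicates = 1) {
  proportions <- as.matrix(proportions)
  if (any(proportions < 0)) stop("proportions must be non-negative")
  if (any(abs(colSums(proportions) - 1) > 1e-8))
    stop("design proportion columns must sum to 1")
  if (is.null(colnames(proportions)))
    colnames(proportions) <- paste0("mix", seq_len(ncol(proportions)))
  if (is.null(rownames(proportions)))
    rownames(proportions) <- paste0("type", seq_len(nrow(proportions)))
  structure(list(proportions = proportions, replicates = replicates),
            class = "mixture_design")
}

#' Three-cell-line mixture design: 3 pure samples plus 9 mixtures
#'
#' Twelve bulk samples over three cell types: one pure sample per type and
#' nine mixed samples spanning dominant, balanced and minor contributions —
#' the classic benchmark layout for expression deconvolution transplanted to
#' contact data.
#'
#' @return a `mixture_design` with a 3 x 12 proportion matrix.
#' @export
design_three_type <- function() {
  p <- cbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(0.05, 0.25, 0.70), c(0.70, 0.05, 0.25), c(0.25, 0.70, 0.05),
    c(0.10, 0.45, 0.45), c(0.45, 0.10, 0.45), c(0.45, 0.45, 0.10),
    c(0.33, 0.33, 0.34), c(0.60, 0.30, 0.10), c(0.20, 0.50, 0.30))
  rownames(p) <- paste0("type", 1:3)
  colnames(p) <- c(paste0("pure", 1:3), paste0("mix", 1:9))
  mixture_design(p)
}

#' Six-type brain-like mixture design
#'
#' Eighteen bulk samples over six brain cell types (neurons, ODC, OPC,
#' astrocytes, microglia, endothelial).  The neuronal fraction sweeps 0.40 to
#' 0.80 across samples, as in cortex tissue; the five glial/vascular types
#' share the remainder in rotating ratios so every type varies across
#' samples.
#'
#' @return a `mixture_design` with a 6 x 18 proportion matrix.
#' @export
design_six_type <- function() {
  n_samples <- 18
  labels <- c("Neuron", "ODC", "OPC", "Astro", "MG", "Endo")
  neuron <- seq(0.40, 0.80, length.out = n_samples)
  # rotating weight patterns for the 5 non-neuronal types; each type leads
  # the non-neuronal fraction in some samples and is absent from others, so
  # the proportions scatter enough for the factorization to be identifiable
  # (minor populations really do drop below detection in some dissections)
  w <- rbind(
    c(6, 2, 1, 0, 0), c(0, 6, 2, 1, 0), c(0, 0, 6, 2, 1),
    c(1, 0, 0, 6, 2), c(2, 1, 0, 0, 6), c(2, 2, 2, 2, 2))
  p <- matrix(0, 6, n_samples, dimnames = list(labels, paste0("mix", seq_len(n_samples))))
  for (s in seq_len(n_samples)) {
    ws <- w[((s - 1) %% nrow(w)) + 1, ]
    p[1, s] <- neuron[s]
    p[2:6, s] <- (1 - neuron[s]) * ws / sum(ws)
  }
  mixture_design(p)
}

#' Assemble ground-truthed bulk Hi-C mixtures from single cells
#'
#' Each bulk sample pools N cells, where N is the smallest per-type cell
#' count available after filtering.  Cells per type are apportioned by
#' largest-remainder rounding of N x design proportion (so realized counts
#' total exactly N and differ from the design by < 1/N per type), drawn
#' without replacement within a sample, summed, and CPM-normalized by each
#' sample's full intra + inter contact total.  The evaluation truth is the
#' realized cell-count fraction, which the integer rounding makes slightly
#' different from the nominal design.
#'
#' @param cells an `sc_contacts` object (typically filtered and downsampled).
#' @param design a `mixture_design`; row names must match the cell types.
#' @param seed integer seed.
#' @return list with `bulk` (CPM [bulk_matrix]), `counts` (raw summed counts
#'   matrix), `truth` (realized types x samples proportions), `design`.
#' @export
make_mixtures <- function(cells, design, seed = NULL) {
  stopifnot(inherits(cells, "sc_contacts"), inherits(design, "mixture_design"))
  if (!is.null(seed)) set.seed(seed)
  types <- rownames(design$proportions)
  missing_types <- setdiff(types, unique(cells$cells$cell_type))
  if (length(missing_types))
    stop("no cells for type(s): ", paste(missing_types, collapse = ", "))
  avail <- table(factor(cells$cells$cell_type, levels = types))
  N <- min(avail)
  n_samples <- ncol(design$proportions)
  p <- nrow(cells$counts)
  raw <- matrix(0, p, n_samples,
                dimnames = list(NULL, colnames(design$proportions)))
  truth <- matrix(0, length(types), n_samples,
                  dimnames = dimnames(design$proportions))
  counts_mat <- as.matrix(cells$counts)
  for (s in seq_len(n_samples)) {
    prop <- design$proportions[, s]
    if (N < sum(prop > 0))
      stop("mixture size N = ", N, " is smaller than the number of ",
           "contributing cell types in sample ", colnames(truth)[s])
    n_per_type <- largest_remainder(prop, N)
    for (t in seq_along(types)) {
      if (n_per_type[t] == 0) next
      pool <- which(cells$cells$cell_type == types[t])
      take <- if (length(pool) == 1) pool else
        sample(pool, n_per_type[t], replace = FALSE)
      raw[, s] <- raw[, s] + rowSums(counts_mat[, take, drop = FALSE])
    }
    truth[, s] <- n_per_type / N
  }
  bulk <- cpm_normalize(bulk_matrix(raw, cells$features, cells$resolution))
  list(bulk = bulk, counts = raw, truth = truth, design = design)
}

#' One-call synthetic mixture study
#'
#' Runs the whole simulation protocol — synthetic cell-type profiles,
#' single-cell sampling, cell filtering, depth downsampling, mixture assembly
#' — for a named preset and returns the CPM bulk matrix with its realized
#' truth.
#'
#' Presets (see the methods vignette for the rationale behind each value):
#' \describe{
#'   \item{`three_type`}{3 cell types, 12 samples (3 pure + 9 mixtures),
#'     2 chromosomes x 30 bins at nominal 10 Mb resolution, 40 markers per
#'     type at boost 5, 60 cells per type.}
#'   \item{`six_type`}{6 brain-like cell types (neurons 40-80% of every
#'     sample), 18 mixed samples, 3 chromosomes x 25 bins, 30
#'     interchromosomal markers per type with unequal boosts (6-13, weakest
#'     for the dominant neurons), 60 cells per type.}
#' }
#' Both presets draw cell depths log-normal around 1e5 contacts (deep scHi-C)
#' with per-cell decay jitter 0.25.
#'
#' @param preset `"three_type"` or `"six_type"`.
#' @param seed master seed; sub-stage seeds are derived from it.
#' @param ... overrides passed to [synth_profiles()] / [sample_cells()].
#' @return list as [make_mixtures()] plus `profiles` and `cells`.
#' @export
simulate_mixture_study <- function(preset = c("three_type", "six_type"),
                                   seed = 1, ...) {
  preset <- match.arg(preset)
  dots <- list(...)
  if (preset == "three_type") {
    prof_args <- list(n_types = 3, n_chroms = 2, bins_per_chrom = 30,
                      resolution = 1e7, decay_exponent = 1,
                      cis_fraction = 0.7, marker_count = 40,
                      marker_boost = 5, marker_background = 1,
                      type_labels = paste0("type", 1:3))
    design <- design_three_type()
    n_cells <- 60
  } else {
    design <- design_six_type()
    prof_args <- list(n_types = 6, n_chroms = 3, bins_per_chrom = 25,
                      resolution = 1e7, decay_exponent = 1,
                      cis_fraction = 0.7, marker_count = 30,
                      marker_boost = c(6, 10, 10, 11, 12, 13),
                      marker_background = 0.1, marker_inter_frac = 1,
                      type_labels = rownames(design$proportions))
    n_cells <- 60
  }
  cell_defaults <- list(depth_meanlog = log(1e5), depth_sdlog = 0.5,
                        cell_decay_sd = 0.25)
  for (nm in intersect(names(dots), names(prof_args)))
    prof_args[[nm]] <- dots[[nm]]
  profiles <- do.call(synth_profiles,
                      c(prof_args, list(seed = derive_seed(seed, 101))))
  cell_args <- c(list(profiles = profiles,
                      n_cells_per_type = dots$n_cells_per_type %||% n_cells,
                      seed = derive_seed(seed, 102)),
                 cell_defaults)
  for (nm in intersect(names(dots),
                       c("depth_meanlog", "depth_sdlog", "depth_min",
                         "cell_decay_sd")))
    cell_args[[nm]] <- dots[[nm]]
  cells <- do.call(sample_cells, cell_args)
  cells <- filter_cells(cells)
  cells <- downsample_cells(cells, seed = derive_seed(seed, 103))
  mix <- make_mixtures(cells, design, seed = derive_seed(seed, 104))
  mix$profiles <- profiles
  mix$cells <- cells
  mix
}

#' Write a simulated study to disk
#'
#' Emits one long-format contact TSV per bulk sample, the realized truth
#' table, and a JSON manifest.
#'
#' @param study result of [simulate_mixture_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mixture_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- study$bulk$features
  res <- study$bulk$resolution
  for (s in colnames(study$counts)) {
    nz <- study$counts[, s] > 0
    df <- data.frame(chrom1 = f$chromA[nz], pos1 = f$startA[nz] + res / 2,
                     chrom2 = f$chromB[nz], pos2 = f$startB[nz] + res / 2,
                     count = study$counts[nz, s])
    utils::write.table(df, file.path(dir, paste0(s, ".contacts.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(data.frame(cell_type = rownames(study$truth),
                                study$truth, check.names = FALSE),
                     file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(samples = colnames(study$counts),
                   resolution = res,
                   n_features = nrow(f),
                   cell_types = rownames(study$truth))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
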