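#' Construct a MOTU partition
#'
#' @param method Method name.
#' @param assignment Named character vector mapping specimen id to MOTU label.
#' @param parameters List of method parameters.
#' @return A `motu_partition` object.
#' @export
motu_partition <- function(method, assignment, parameters = list()) {
  if (is.null(names(assignment)) || anyNA(assignment)) {
    stop("assignment must be a fully named, NA-free vector")
  }
  structure(list(method = method,
                 assignment = assignment,
                 parameters = parameters),
            class = "motu_partition")
}

#' @export
print.motu_partition <- function(x, ...) {
  cat("motu_partition [", x$method, "]: ", length(x$assignment),
      " specimens in ", length(unique(x$assignment)), " MOTUs\n", sep = "")
  invisible(x)
}

#' Number of MOTUs in a partition
#' @param partition A `motu_partition`.
#' @return Integer count of distinct MOTU labels.
#' @export
n_motus <- function(partition) length(unique(partition$assignment))

#' MOTUs as a list of specimen-id sets
#' @param partition A `motu_partition`.
#' @return Named list of character vectors, one per MOTU.
#' @export
motu_sets <- function(partition) {
  split(names(partition$assignment), partition$assignment)
}

# Deterministic labels: MOTUs numbered by first appearance in id order.
relabel_by_first <- function(ids, membership, prefix) {
  first <- order(match(unique(membership[ids]), membership[ids]))
  lev <- unique(membership[ids])
  lab <- setNames(sprintf("%s:%04d", prefix, seq_along(lev)), lev)
  setNames(unname(lab[as.character(membership[ids])]), ids)
}

single_linkage_components <- function(d, cutoff) {
  adj <- !is.na(d) & d <= cutoff
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

#' Threshold-based MOTU partition (single linkage)
#'
#' MOTUs are the connected components of the graph joining specimen pairs at
#' K2P distance `cutoff` or less — single-linkage clustering at a fixed
#' divergence threshold, the jMOTU-style criterion.
#'
#' @param matrix A complete `k2p_dist`.
#' @param cutoff Distance threshold in percent (non-negative).
#' @return A `motu_partition` with parameter `cutoff_percent`.
#' @export
threshold_partition <- function(matrix, cutoff) {
  stopifnot(inherits(matrix, "k2p_dist"))
  if (cutoff < 0) stop("cutoff must be non-negative")
  membership <- single_linkage_components(matrix$d, cutoff)
  names(membership) <- matrix$ids
  motu_partition("threshold",
                 relabel_by_first(matrix$ids, membership, "MOTU"),
                 parameters = list(cutoff_percent = cutoff))
}

#' Sweep base-pair cutoffs across the alignment
#'
#' Converts each cutoff in base pairs to percent divergence
#' (`100 * c / alignment_length`) and runs [threshold_partition()] at each,
#' in cutoff order. The default 1–40 bp on a 658-bp barcode covers 0.15% to
#' 6.08% divergence.
#'
#' @param matrix A complete `k2p_dist`.
#' @param cutoffs_bp Integer vector of cutoffs in base pairs.
#' @param alignment_length Alignment length in bp (default 658).
#' @return Named list of `motu_partition` objects (`"1bp"`, `"2bp"`, ...),
#'   each with parameters `cutoff_bp` and `cutoff_percent`.
#' @export
threshold_sweep <- function(matrix, cutoffs_bp = 1:40,
                            alignment_length = 658L) {
  out <- lapply(cutoffs_bp, function(cbp) {
    p <- threshold_partition(matrix, 100 * cbp / alignment_length)
    p$method <- "threshold_sweep"
    p$parameters$cutoff_bp <- cbp
    p
  })
  names(out) <- paste0(cutoffs_bp, "bp")
  out
}

# Mean silhouette width over a subset of points, given integer cluster labels
# and a full distance matrix in percent. Singleton clusters score 0 (the
# usual convention).
mean_silhouette <- function(labels, d, subset) {
  k <- length(unique(labels))
  if (k < 2L || k == length(labels)) return(0)  # one cluster / all singletons
  sil <- cluster::silhouette(labels, dmatrix = d)
  if (!is.matrix(sil)) return(0)
  mean(sil[subset, "sil_width"])
}

#' Refined single-linkage clustering into local barcode clusters
#'
#' A two-stage clustering in the spirit of the refined single linkage (RESL)
#' algorithm behind barcode-index clustering. Stage 1 forms single-linkage
#' clusters at a seed threshold (2.2% by convention). Stage 2 re-examines each
#' cluster: the candidate refinement is the two-way split at the largest
#' internal single-linkage merge distance, and it is accepted when the mean
#' silhouette width of the cluster's members (computed on the K2P distances
#' against the full clustering) improves. Labels are local (`LBIN:0001`, ...)
#' and are never registry barcode-index identifiers.
#'
#' @param matrix A complete `k2p_dist`.
#' @param seed_threshold Stage-1 threshold in percent (default 2.2).
#' @return A `motu_partition` with parameter `seed_threshold` and
#'   `n_splits_accepted`.
#' @export
resl_bins <- function(matrix, seed_threshold = 2.2) {
  stopifnot(inherits(matrix, "k2p_dist"))
  mp <- missing_pairs(matrix)
  if (length(mp) > 0L) {
    stop("missing distances for pair(s): ", paste(mp, collapse = ", "))
  }
  # work on unique haplotypes (zero-distance classes), as refined single
  # linkage does: duplicated sequences otherwise degrade the silhouette
  # criterion (zero within-haplotype distances make any split look perfect)
  hap_class <- single_linkage_components(matrix$d, 0)
  reps <- !duplicated(hap_class)
  d <- matrix$d[reps, reps, drop = FALSE]
  membership <- single_linkage_components(d, seed_threshold)
  labels <- as.integer(factor(membership))
  next_label <- max(labels) + 1L
  accepted <- 0L
  for (comp in sort(unique(labels))) {
    idx <- which(labels == comp)
    if (length(idx) < 2L) next
    sub <- d[idx, idx, drop = FALSE]
    if (max(sub) <= 0) next
    hc <- hclust(as.dist(sub), method = "single")
    split2 <- cutree(hc, k = 2L)
    before <- mean_silhouette(labels, d, idx)
    cand <- labels
    cand[idx[split2 == 2L]] <- next_label
    after <- mean_silhouette(cand, d, idx)
    if (after > before) {
      labels <- cand
      next_label <- next_label + 1L
      accepted <- accepted + 1L
    }
  }
  full_labels <- labels[match(hap_class, hap_class[reps])]
  names(full_labels) <- matrix$ids
  motu_partition("resl",
                 relabel_by_first(matrix$ids, full_labels, "LBIN"),
                 parameters = list(seed_threshold = seed_threshold,
                                   n_splits_accepted = accepted))
}

#' Expand a haplotype-level partition back to all specimens
#'
#' @param partition A `motu_partition` on haplotype representatives.
#' @param haplotype_map Named vector mapping every specimen id to its
#'   representative id (attribute of [collapse_haplotypes()]).
#' @return A `motu_partition` covering all specimens.
#' @export
expand_partition <- function(partition, haplotype_map) {
  assignment <- setNames(unname(partition$assignment[haplotype_map]),
                         names(haplotype_map))
  if (anyNA(assignment)) stop("haplotype map refers to unknown representatives")
  motu_partition(partition$method, assignment, partition$parameters)
}

#' Adjusted Rand index between a partition and reference labels
#'
#' @param partition A `motu_partition` (or named label vector).
#' @param reference Named vector of reference labels (e.g. true species).
#' @return The adjusted Rand index.
#' @export
partition_ari <- function(partition, reference) {
  labels <- if (inherits(partition, "motu_partition"))
    partition$assignment else partition
  ids <- names(labels)
  if (!all(ids %in% names(reference))) {
    stop("reference labels missing for some specimens")
  }
  ari <- mclust::adjustedRandIndex(labels, reference[ids])
  if (is.nan(ari)) {
    # degenerate cases (both trivial partitions): identical grouping is
    # perfect agreement, anything else is none
    same <- identical(unname(as.integer(factor(labels, unique(labels)))),
                      unname(as.integer(factor(reference[ids],
                                               unique(reference[ids])))))
    ari <- as.numeric(same)
  }
  ari
}

#' Export partitions as a long TSV
#'
#' @param partitions List of `motu_partition` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partitions_tsv <- function(partitions, path) {
  rows <- lapply(partitions, function(p) {
    pars <- paste(names(p$parameters),
                  vapply(p$parameters, function(v)
                    paste(format(v, digits = 6), collapse = ","), ""),
                  sep = "=", collapse = ";")
    data.frame(specimen_id = names(p$assignment),
               method = p$method,
               motu_label = unname(p$assignment),
               parameters = pars,
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
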