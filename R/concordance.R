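#' Match ratio between two MOTU partitions
#'
#' `2 * N_match / (N_A + N_B)`, where `N_match` is the number of MOTUs that
#' are identical as specimen sets in the two partitions.
#'
#' @param A,B `motu_partition` objects over the same specimen set.
#' @return A value in `[0, 1]`.
#' @export
match_ratio <- function(A, B) {
  sa <- motu_sets(A)
  sb <- motu_sets(B)
  if (!setequal(unlist(sa), unlist(sb))) {
    stop("partitions cover different specimen sets")
  }
  key <- function(s) vapply(s, function(x) paste(sort(x), collapse = "\r"), "")
  n_match <- length(intersect(key(sa), key(sb)))
  2 * n_match / (length(sa) + length(sb))
}

#' Speciation events implied by a partition on a guide tree
#'
#' Operationalises "speciation events" as the internal nodes of a shared
#' guide tree whose descendant tips span two or more MOTUs of the partition —
#' the nodes on which the partition's between-species divergences hang. This
#' stays well defined even for non-monophyletic MOTUs. For a binary tree and
#' k monophyletic MOTUs there are exactly k - 1 such nodes.
#'
#' @param tree A rooted `phylo` tree whose tips are the partitioned
#'   specimens; unrooted trees are midpoint-rooted.
#' @param partition A `motu_partition` covering the tips.
#' @return Object of class `speciation_events`: list with `method` and
#'   `events` (integer ids of qualifying internal nodes).
#' @export
speciation_events <- function(tree, partition) {
  stopifnot(inherits(partition, "motu_partition"))
  if (!setequal(tree$tip.label, names(partition$assignment))) {
    stop("tree tips and partition specimens differ")
  }
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  n_tip <- length(tree$tip.label)
  labels <- partition$assignment[tree$tip.label]
  motus_below <- c(as.list(as.integer(factor(labels))),
                   vector("list", tree$Nnode))
  tr <- reorder(tree, "cladewise")
  for (e in rev(seq_len(nrow(tr$edge)))) {
    p <- tr$edge[e, 1L]
    v <- tr$edge[e, 2L]
    motus_below[[p]] <- unique(c(motus_below[[p]], motus_below[[v]]))
  }
  internal <- seq.int(n_tip + 1L, n_tip + tree$Nnode)
  events <- internal[vapply(motus_below[internal], length, 0L) >= 2L]
  structure(list(method = partition$method, events = events),
            class = "speciation_events")
}

#' Taxonomic index of congruence between two event sets
#'
#' `|A intersect B| / |A union B|`; defined as 1 when both sets are empty
#' (two identical single-MOTU partitions).
#'
#' @param A,B `speciation_events` objects on the same guide tree.
#' @return A value in `[0, 1]`.
#' @export
ctax <- function(A, B) {
  u <- union(A$events, B$events)
  if (length(u) == 0L) return(1)
  length(intersect(A$events, B$events)) / length(u)
}

#' Relative taxonomic resolving power of one method
#'
#' `|A| / |union of all methods' event sets|`.
#'
#' @param A A `speciation_events` object.
#' @param all_methods List of `speciation_events` for every compared method
#'   (including A).
#' @return A value in `(0, 1]` (1 when the union is empty).
#' @export
rtax <- function(A, all_methods) {
  u <- unique(unlist(lapply(all_methods, `[[`, "events")))
  if (length(u) == 0L) return(1)
  length(A$events) / length(u)
}

#' Taxa recovered identically by every delimitation method
#'
#' A putative taxon is consensus-recovered when, in every partition, its
#' specimens form exactly one MOTU containing no other taxon's specimens.
#'
#' @param partitions List of `motu_partition` objects over the same specimens.
#' @param taxa Named character vector mapping specimen id to its putative
#'   taxon label.
#' @return List with `count` and `taxa` (character vector of recovered taxa).
#' @export
consensus_count <- function(partitions, taxa) {
  ids <- names(partitions[[1L]]$assignment)
  tax <- taxa[ids]
  recovered <- vapply(sort(unique(tax)), function(tx) {
    own <- ids[tax == tx]
    all(vapply(partitions, function(p) {
      cl <- unique(p$assignment[own])
      length(cl) == 1L && sum(p$assignment == cl) == length(own)
    }, logical(1)))
  }, logical(1))
  list(count = sum(recovered), taxa = names(recovered)[recovered])
}

#' Pairwise concordance table across delimitation methods
#'
#' Assembles the standard method-comparison matrix: match ratio in the upper
#' triangle, taxonomic index of congruence (C_tax) in the lower triangle,
#' plus per-method mean C_tax, relative resolving power (R_tax) and MOTU
#' counts. Speciation-event sets are taken on a shared guide tree.
#'
#' @param partitions Named list of `motu_partition` objects over the same
#'   specimen set.
#' @param tree Guide tree whose tips are the specimens (the midpoint-rooted
#'   NJ tree, by convention).
#' @return A `concordance_matrix`: list with `methods`, `match_ratio` and
#'   `c_tax` (full symmetric matrices; use the respective triangles),
#'   `mean_c_tax`, `r_tax`, `n_motus`.
#' @export
concordance_table <- function(partitions, tree) {
  methods <- names(partitions)
  if (is.null(methods)) {
    methods <- vapply(partitions, `[[`, "", "method")
    names(partitions) <- methods
  }
  k <- length(partitions)
  events <- lapply(partitions, speciation_events, tree = tree)
  mr <- matrix(NA_real_, k, k, dimnames = list(methods, methods))
  ct <- matrix(NA_real_, k, k, dimnames = list(methods, methods))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      mr[i, j] <- match_ratio(partitions[[i]], partitions[[j]])
      ct[i, j] <- ctax(events[[i]], events[[j]])
    }
  }
  structure(list(methods = methods,
                 match_ratio = mr,
                 c_tax = ct,
                 mean_c_tax = rowMeans(ct, na.rm = TRUE),
                 r_tax = vapply(events, rtax, 0, all_methods = events),
                 n_motus = vapply(partitions, n_motus, 0L)),
            class = "concordance_matrix")
}

#' @export
print.concordance_matrix <- function(x, ...) {
  k <- length(x$methods)
  m <- matrix("", k, k, dimnames = list(x$methods, x$methods))
  m[upper.tri(m)] <- sprintf("%.2f", x$match_ratio[upper.tri(m)])
  m[lower.tri(m)] <- sprintf("%.2f", x$c_tax[lower.tri(m)])
  cat("Concordance (upper = match ratio, lower = C_tax):\n")
  print(m, quote = FALSE)
  cat("Mean C_tax:", sprintf("%.2f", x$mean_c_tax), "\n")
  cat("R_tax:     ", sprintf("%.2f", x$r_tax), "\n")
  cat("MOTUs:     ", sprintf("%4d", x$n_motus), "\n")
  invisible(x)
}

#' Export the concordance table as TSV
#'
#' @param x A `concordance_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_concordance_tsv <- function(x, path) {
  k <- length(x$methods)
  m <- matrix("", k, k, dimnames = list(x$methods, x$methods))
  m[upper.tri(m)] <- sprintf("%.4f", x$match_ratio[upper.tri(m)])
  m[lower.tri(m)] <- sprintf("%.4f", x$c_tax[lower.tri(m)])
  out <- rbind(m,
               mean_c_tax = sprintf("%.4f", x$mean_c_tax),
               r_tax = sprintf("%.4f", x$r_tax),
               n_motus = as.character(x$n_motus))
  df <- data.frame(row = rownames(out), out, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
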