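missing_pairs <- function(matrix) {
  bad <- which(is.na(matrix$d) & upper.tri(matrix$d), arr.ind = TRUE)
  if (nrow(bad) == 0L) return(character(0))
  paste0(matrix$ids[bad[, 1L]], "/", matrix$ids[bad[, 2L]])
}

# Move the deficit of any negative branch onto its sibling (so tip-to-tip
# paths through the parent are preserved) and clamp at zero.
fix_negative_edges <- function(tree) {
  for (pass in 1:5) {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0L) break
    for (e in neg) {
      len <- tree$edge.length[e]
      if (len >= 0) next
      parent <- tree$edge[e, 1L]
      sibs <- setdiff(which(tree$edge[, 1L] == parent), e)
      tree$edge.length[e] <- 0
      if (length(sibs) > 0L) {
        tree$edge.length[sibs[1L]] <- tree$edge.length[sibs[1L]] + len
      }
    }
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

# Closed-form unrooted tree for three taxa (the three-point formulas).
nj3 <- function(d, ids) {
  x <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  y <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  z <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 ids[1], x, ids[2], y, ids[3], z)
  ape::read.tree(text = txt)
}

#' Neighbour-joining tree from a K2P distance matrix
#'
#' Standard neighbour-joining agglomeration (the BOLD-style "taxon ID tree"
#' built on K2P distances). Negative branch lengths, which NJ can produce on
#' non-additive data, are clamped to zero with the deficit moved to the
#' sibling branch so path lengths through the parent are preserved.
#'
#' @param matrix A `k2p_dist` with at least 3 ids and no missing distances.
#' @return An unrooted `phylo` tree with branch lengths on the percent scale
#'   of the input matrix.
#' @export
nj_tree <- function(matrix) {
  stopifnot(inherits(matrix, "k2p_dist"))
  if (length(matrix$ids) < 3L) stop("need at least 3 ids for neighbour-joining")
  mp <- missing_pairs(matrix)
  if (length(mp) > 0L) {
    stop("missing distances for pair(s): ", paste(mp, collapse = ", "))
  }
  if (length(matrix$ids) == 3L) return(nj3(matrix$d, matrix$ids))
  fix_negative_edges(ape::nj(as_dist(matrix)))
}

#' UPGMA tree from a K2P distance matrix
#'
#' Average-linkage agglomeration returning a rooted ultrametric tree; each
#' node sits at half the merge distance, so cophenetic tip-to-tip paths
#' reproduce the cluster-average distances. Used here to supply the
#' ultrametric input that single-threshold GMYC requires.
#'
#' @inheritParams nj_tree
#' @return A rooted ultrametric `phylo` tree.
#' @export
upgma_tree <- function(matrix) {
  stopifnot(inherits(matrix, "k2p_dist"))
  if (length(matrix$ids) < 2L) stop("need at least 2 ids")
  mp <- missing_pairs(matrix)
  if (length(mp) > 0L) {
    stop("missing distances for pair(s): ", paste(mp, collapse = ", "))
  }
  hc <- hclust(as_dist(matrix), method = "average")
  tr <- ape::as.phylo(hc)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Read a tree from a Newick string or file
#'
#' @param text Newick text, or `NULL` to read from `file`.
#' @param file Path to a Newick file.
#' @return A `phylo` tree.
#' @export
newick_read <- function(text = NULL, file = NULL) {
  tr <- tryCatch(
    if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file),
    error = function(e) stop("newick parse error: ", conditionMessage(e)),
    warning = function(w) stop("newick parse error: ", conditionMessage(w)))
  if (is.null(tr)) stop("newick parse error: no tree found in input")
  tr$tip.label <- gsub("^'(.*)'$", "\\1", tr$tip.label)
  tr
}

#' Serialise a tree to Newick
#'
#' Round-trips labels, topology and branch lengths through [newick_read()].
#'
#' @param tree A `phylo` tree.
#' @param file Optional path; when given the text is also written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
newick_write <- function(tree, file = NULL) {
  spaced <- grepl(" ", tree$tip.label, fixed = TRUE)
  orig <- tree$tip.label[spaced]
  tree$tip.label[spaced] <- gsub(" ", "\x01", orig, fixed = TRUE)
  txt <- ape::write.tree(tree, digits = 12)
  for (i in seq_along(orig)) {
    txt <- gsub(gsub(" ", "\x01", orig[i], fixed = TRUE),
                paste0("'", orig[i], "'"), txt, fixed = TRUE)
  }
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Test whether a set of tips is monophyletic
#'
#' Unrooted trees are midpoint-rooted first (a deterministic, outgroup-free
#' convention); monophyly then means some node's descendant tip set equals
#' `tipset` exactly. Single tips are trivially monophyletic.
#'
#' @param tree A `phylo` tree.
#' @param tipset Character vector of tip labels.
#' @return Logical.
#' @export
is_monophyletic <- function(tree, tipset) {
  unknown <- setdiff(tipset, tree$tip.label)
  if (length(unknown) > 0L) {
    stop("unknown tip(s): ", paste(unknown, collapse = ", "))
  }
  if (length(tipset) <= 1L) return(TRUE)
  if (length(tipset) == length(tree$tip.label)) return(TRUE)
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  ape::is.monophyletic(tree, tips = tipset)
}

# Node heights (time before present) for an ultrametric rooted tree.
node_heights <- function(tree, tol = 1e-8) {
  depths <- ape::node.depth.edgelength(tree)
  h <- max(depths) - depths
  if (any(abs(h[seq_along(tree$tip.label)]) > tol * max(1, max(depths)))) {
    stop("tree is not ultrametric")
  }
  h
}
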