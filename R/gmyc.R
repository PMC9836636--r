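# Single-threshold general mixed Yule-coalescent (GMYC) model.
#
# The tree is ultrametric; every internal node is a branching event. A
# threshold height T separates species-level diversification (a Yule process
# over the lineages older than T, intensity lambda_spec * n(t)) from
# within-species coalescence (intensity lambda_coal * sum_k n_k(n_k - 1)/2
# over the clusters hanging below T). The likelihood is assembled over the
# inter-event intervals, sweeping from the tips towards the root: an
# interval's waiting time is survived at the total intensity of the classes
# active in it, and the branching event closing it contributes that total
# intensity (the interval-rate formulation). Below the threshold the K
# species lineages persist, so the Yule class keeps exposure lambda_spec * K
# there while no further speciation event occurs. Both rates are
# profiled analytically as events / integrated opportunity. Candidate
# thresholds are the observed node heights; the candidate at the root height
# has no Yule event and is exactly the one-class null (a single coalescing
# species), so the maximised likelihood can never fall below the null.

# Cluster root of every node for threshold T: the shallowest ancestor at or
# below T. Returns an integer vector over all nodes (0 = above T).
cluster_roots <- function(tree, heights, T, tol = 1e-12) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  croot <- integer(n_tip + tree$Nnode)
  croot[root] <- if (heights[root] <= T + tol) root else 0L
  tr <- reorder(tree, "cladewise")  # parents before children
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]
    v <- tr$edge[e, 2L]
    croot[v] <- if (croot[p] != 0L) croot[p]
                else if (heights[v] <= T + tol) v else 0L
  }
  croot
}

gmyc_eval <- function(tree, heights, T, tol = 1e-12) {
  n_tip <- length(tree$tip.label)
  internal <- seq.int(n_tip + 1L, n_tip + tree$Nnode)
  ord <- internal[order(heights[internal])]   # tips -> root
  croot <- cluster_roots(tree, heights, T, tol)
  K <- length(unique(croot[croot != 0L]))

  counts <- table(factor(croot[seq_len(n_tip)]))
  counts <- setNames(as.integer(counts), names(counts))
  sum_c <- sum(counts * (counts - 1) / 2)

  O_s <- 0
  O_c <- 0
  E_s <- 0L
  ev_ns <- numeric(length(ord))   # Yule lineage count at the event
  ev_sc <- numeric(length(ord))   # coalescent pair count at the event
  t_prev <- 0
  lineages <- n_tip
  for (i in seq_along(ord)) {
    v <- ord[i]
    h <- heights[v]
    below <- max(0, min(h, T) - t_prev)
    above <- max(0, h - max(t_prev, T))
    O_c <- O_c + sum_c * below
    O_s <- O_s + lineages * above + K * below
    if (h > T + tol) {
      E_s <- E_s + 1L
      ev_ns[i] <- lineages
      ev_sc[i] <- 0
    } else {
      ev_ns[i] <- K
      ev_sc[i] <- sum_c
      key <- as.character(croot[v])
      q <- counts[[key]]
      counts[[key]] <- q - 1L
      sum_c <- sum_c - (q - 1L)
    }
    lineages <- lineages - 1L
    t_prev <- h
  }
  E_c <- length(ord) - E_s
  lambda_s <- if (E_s > 0L) E_s / max(O_s, 1e-12) else 0
  lambda_c <- if (E_c > 0L) E_c / max(O_c, 1e-12) else 0
  rates <- lambda_s * ev_ns + lambda_c * ev_sc
  logL <- if (any(rates <= 0)) -Inf else
    sum(log(rates)) - lambda_s * O_s - lambda_c * O_c
  list(threshold = T, logL = logL, lambda_spec = lambda_s,
       lambda_coal = lambda_c, n_motus = K, croot = croot)
}

#' Single-threshold GMYC species delimitation
#'
#' Fits the single-threshold general mixed Yule-coalescent model on an
#' ultrametric tree: branching events older than a threshold height are
#' species-level (Yule) events, events below it are within-species coalescent
#' events, and both rates are profiled analytically. Every observed node
#' height is evaluated as a candidate threshold; the fit at the root height
#' has no Yule event and equals the one-class null (a single coalescing
#' species), so the maximised likelihood never falls below the null. A
#' likelihood-ratio test against that null is reported with two degrees of
#' freedom (the threshold plus the extra rate).
#'
#' @param tree A rooted ultrametric `phylo` tree with at least 3 tips
#'   (e.g. from [upgma_tree()]).
#' @return A list with `fit` (threshold, `lambda_spec`, `lambda_coal`,
#'   `logL`, `null_logL`, `n_motus`, `LR`, `p_value`) and `partition`
#'   (a `motu_partition`; clusters are the subtrees crossing the threshold).
#' @export
gmyc_single <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  tree <- ape::collapse.singles(tree)
  n_tip <- length(tree$tip.label)
  if (n_tip < 3L) stop("need at least 3 tips")
  heights <- node_heights(tree)
  internal <- seq.int(n_tip + 1L, n_tip + tree$Nnode)
  cands <- sort(unique(heights[internal]))
  fits <- lapply(cands, function(T) gmyc_eval(tree, heights, T))
  null_fit <- fits[[length(fits)]]  # threshold at the root height
  logLs <- vapply(fits, `[[`, 0, "logL")
  motus <- vapply(fits, `[[`, 0, "n_motus")
  best <- order(-logLs, motus, -vapply(fits, `[[`, 0, "threshold"))[1L]
  fit <- fits[[best]]
  membership <- setNames(fit$croot[seq_len(n_tip)], tree$tip.label)
  assignment <- relabel_by_first(tree$tip.label, membership, "GMYC")
  LR <- 2 * (fit$logL - null_fit$logL)
  out_fit <- list(threshold = fit$threshold,
                  lambda_spec = fit$lambda_spec,
                  lambda_coal = fit$lambda_coal,
                  logL = fit$logL,
                  null_logL = null_fit$logL,
                  n_motus = fit$n_motus,
                  LR = LR,
                  p_value = pchisq(LR, df = 2, lower.tail = FALSE))
  partition <- motu_partition("gmyc_single", assignment,
                              parameters = list(threshold = fit$threshold))
  list(fit = out_fit, partition = partition)
}
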