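# Maximum-likelihood Poisson tree process (PTP) delimitation.
#
# Branch lengths are in expected substitutions. A species assignment is a set
# of disjoint "crown" subtrees covering all tips; branches strictly below a
# crown node form the within-species (coalescent) class, all others --
# including each crown's stem -- the between-species (speciation) class.
# Each class is exponential with its own profiled rate; model fit is scored
# by AIC whose dimension counts the profiled rates plus the K - 1 accepted
# speciation nodes (the change-point convention: every split is a fitted
# break, which guards against oversplitting). The search is a steepest-
# descent local search whose moves either split a crown into its child
# subtrees or merge sibling crowns into their parent; it is run from both
# extreme starts (a single species, and all-singleton species) and the
# better local optimum is returned. Ties break to the smaller pre-order
# node index.

exp_class_logL <- function(m, S, eps = 1e-9) {
  if (m == 0L) return(0)
  m * (log(m / max(S, eps)) - 1)
}

ptp_aic <- function(ms, Ss, mc, Sc, K) {
  k <- (ms > 0L) + (mc > 0L) + (K - 1L)
  2 * k - 2 * (exp_class_logL(ms, Ss) + exp_class_logL(mc, Sc))
}

#' Maximum-likelihood PTP species delimitation
#'
#' Delimits species on a tree with substitution branch lengths by modelling
#' between-species and within-species branch lengths as two exponential
#' classes (the Poisson-tree-process idea: speciation changes the per-branch
#' substitution intensity). Unrooted input is midpoint-rooted first.
#'
#' @param tree A `phylo` tree with non-negative branch lengths and at least
#'   3 tips (e.g. from [nj_tree()]).
#' @return A list with `fit` (`rate_spec`, `rate_coal` — profiled exponential
#'   rates, `NA` while a class is empty —, `logL`, `aic`, `n_motus`) and
#'   `partition` (a `motu_partition` whose clusters are the crown subtrees).
#' @export
ptp_ml <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  if (length(tree$tip.label) < 3L) stop("need at least 3 tips")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (all(tree$edge.length == 0)) {
    stop("degenerate input: all branch lengths are zero")
  }
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  tree <- reorder(ape::collapse.singles(tree), "cladewise")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  n_node <- n_tip + tree$Nnode

  # per-node subtree edge counts/sums (edges strictly below the node) and
  # stem edge lengths
  cnt <- integer(n_node)
  len <- numeric(n_node)
  stem <- numeric(n_node)
  parent_of <- integer(n_node)
  po <- rev(seq_len(nrow(tree$edge)))  # children before parents
  for (e in po) {
    p <- tree$edge[e, 1L]
    v <- tree$edge[e, 2L]
    cnt[p] <- cnt[p] + cnt[v] + 1L
    len[p] <- len[p] + len[v] + tree$edge.length[e]
    stem[v] <- tree$edge.length[e]
    parent_of[v] <- p
  }
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  preorder_rank <- integer(n_node)
  preorder_rank[unique(c(root, tree$edge[, 2L]))] <- seq_len(n_node)
  tips_below <- vector("list", n_node)
  for (i in seq_len(n_tip)) tips_below[[i]] <- i
  for (e in po) {
    p <- tree$edge[e, 1L]
    v <- tree$edge[e, 2L]
    tips_below[[p]] <- c(tips_below[[p]], tips_below[[v]])
  }
  m_tot <- nrow(tree$edge)
  S_tot <- sum(tree$edge.length)

  # steepest-descent local search over split/merge moves
  search_from <- function(crowns) {
    is_crown <- logical(n_node)
    is_crown[crowns] <- TRUE
    mc <- sum(cnt[crowns])
    Sc <- sum(len[crowns])
    K <- length(crowns)
    aic <- ptp_aic(m_tot - mc, S_tot - Sc, mc, Sc, K)
    repeat {
      best <- NULL
      cr <- which(is_crown)
      # splits: crown r -> its child subtrees
      for (r in cr[cnt[cr] > 0L]) {
        ch <- children[[as.character(r)]]
        mc2 <- mc - length(ch)
        Sc2 <- Sc - sum(stem[ch])
        a2 <- ptp_aic(m_tot - mc2, S_tot - Sc2, mc2, Sc2, K + length(ch) - 1L)
        if (a2 < aic - 1e-12 &&
            (is.null(best) || a2 < best$aic - 1e-12 ||
             (abs(a2 - best$aic) <= 1e-12 &&
              preorder_rank[r] < preorder_rank[best$node]))) {
          best <- list(type = "split", node = r, ch = ch,
                       mc = mc2, Sc = Sc2, aic = a2)
        }
      }
      # merges: all children of p are crowns -> p becomes a crown
      cand_p <- unique(parent_of[cr])
      cand_p <- cand_p[cand_p != 0L & !is_crown[cand_p]]
      for (p in cand_p) {
        ch <- children[[as.character(p)]]
        if (!all(is_crown[ch])) next
        mc2 <- mc + length(ch)
        Sc2 <- Sc + sum(stem[ch])
        a2 <- ptp_aic(m_tot - mc2, S_tot - Sc2, mc2, Sc2, K - length(ch) + 1L)
        if (a2 < aic - 1e-12 &&
            (is.null(best) || a2 < best$aic - 1e-12 ||
             (abs(a2 - best$aic) <= 1e-12 &&
              preorder_rank[p] < preorder_rank[best$node]))) {
          best <- list(type = "merge", node = p, ch = ch,
                       mc = mc2, Sc = Sc2, aic = a2)
        }
      }
      if (is.null(best)) break
      if (best$type == "split") {
        is_crown[best$node] <- FALSE
        is_crown[best$ch] <- TRUE
        K <- K + length(best$ch) - 1L
      } else {
        is_crown[best$ch] <- FALSE
        is_crown[best$node] <- TRUE
        K <- K - length(best$ch) + 1L
      }
      mc <- best$mc
      Sc <- best$Sc
      aic <- best$aic
    }
    list(crowns = which(is_crown), mc = mc, Sc = Sc, aic = aic)
  }

  # Guided agglomerative path: merge all the way from singletons to a single
  # species, always taking the currently cheapest merge even when AIC rises
  # (this crosses likelihood barriers), and remember the best state passed.
  agglomerative_best <- function() {
    is_crown <- logical(n_node)
    is_crown[seq_len(n_tip)] <- TRUE
    mc <- 0L
    Sc <- 0
    K <- n_tip
    best_crowns <- seq_len(n_tip)
    best_aic <- ptp_aic(m_tot, S_tot, 0L, 0, K)
    repeat {
      cr <- which(is_crown)
      if (length(cr) == 1L) break
      cand_p <- unique(parent_of[cr])
      cand_p <- cand_p[cand_p != 0L & !is_crown[cand_p]]
      step <- NULL
      for (p in cand_p) {
        ch <- children[[as.character(p)]]
        if (!all(is_crown[ch])) next
        mc2 <- mc + length(ch)
        Sc2 <- Sc + sum(stem[ch])
        a2 <- ptp_aic(m_tot - mc2, S_tot - Sc2, mc2, Sc2, K - length(ch) + 1L)
        if (is.null(step) || a2 < step$aic - 1e-12 ||
            (abs(a2 - step$aic) <= 1e-12 &&
             preorder_rank[p] < preorder_rank[step$node])) {
          step <- list(node = p, ch = ch, mc = mc2, Sc = Sc2, aic = a2)
        }
      }
      if (is.null(step)) break
      is_crown[step$ch] <- FALSE
      is_crown[step$node] <- TRUE
      K <- K - length(step$ch) + 1L
      mc <- step$mc
      Sc <- step$Sc
      if (step$aic < best_aic - 1e-12) {
        best_aic <- step$aic
        best_crowns <- which(is_crown)
      }
    }
    best_crowns
  }

  res1 <- search_from(root)                 # single species
  res2 <- search_from(seq_len(n_tip))       # all singletons
  res3 <- search_from(agglomerative_best()) # best state on the merge path
  cands <- list(res1, res2, res3)
  res <- cands[[which.min(vapply(cands, `[[`, 0, "aic"))]]

  membership <- integer(n_tip)
  for (r in res$crowns) membership[unlist(tips_below[[r]])] <- r
  names(membership) <- tree$tip.label
  assignment <- relabel_by_first(tree$tip.label, membership, "PTP")
  ms <- m_tot - res$mc
  Ss <- S_tot - res$Sc
  fit <- list(rate_spec = if (ms > 0L) ms / max(Ss, 1e-9) else NA_real_,
              rate_coal = if (res$mc > 0L) res$mc / max(res$Sc, 1e-9)
                          else NA_real_,
              logL = (2 * ((ms > 0L) + (res$mc > 0L) +
                           length(res$crowns) - 1L) - res$aic) / 2,
              aic = res$aic,
              n_motus = length(res$crowns))
  partition <- motu_partition("ptp_ml", assignment,
                              parameters = list(n_motus = length(res$crowns)))
  list(fit = fit, partition = partition)
}
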