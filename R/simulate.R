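# Two-class (transition / transversion) substitution process -- exactly the
# structure the K2P distance estimates, which keeps estimator-recovery tests
# sharp. kappa is the expected transition/transversion ratio alpha/(2 beta);
# kappa = 0.5 is the Jukes-Cantor limit (alpha = beta). Rates are normalised
# so branch lengths are expected substitutions per site.

TS_PARTNER <- c(3L, 4L, 1L, 2L)             # A<->G, C<->T
TV_PARTNER1 <- c(2L, 1L, 2L, 1L)            # A->C, C->A, G->C, T->A
TV_PARTNER2 <- c(4L, 3L, 4L, 3L)            # A->T, C->G, G->T, T->G
BASE_LETTERS <- c("A", "C", "G", "T")

k80_probs <- function(d, kappa) {
  alpha <- kappa / (kappa + 1)
  beta <- 1 / (2 * (kappa + 1))
  e1 <- exp(-4 * beta * d)
  e2 <- exp(-2 * (alpha + beta) * d)
  c(same = 0.25 + 0.25 * e1 + 0.5 * e2,
    ts = 0.25 + 0.25 * e1 - 0.5 * e2,
    tv = 0.25 - 0.25 * e1)               # per transversion target (two)
}

# Evolve an integer-coded sequence along a branch of length d (subs/site).
evolve_codes <- function(codes, d, kappa) {
  if (d <= 0) return(codes)
  p <- k80_probs(d, kappa)
  r <- runif(length(codes))
  out <- codes
  ts_sel <- r >= p["same"] & r < p["same"] + p["ts"]
  tv1_sel <- r >= p["same"] + p["ts"] & r < p["same"] + p["ts"] + p["tv"]
  tv2_sel <- r >= p["same"] + p["ts"] + p["tv"]
  out[ts_sel] <- TS_PARTNER[codes[ts_sel]]
  out[tv1_sel] <- TV_PARTNER1[codes[tv1_sel]]
  out[tv2_sel] <- TV_PARTNER2[codes[tv2_sel]]
  out
}

is_stop_codon <- function(c1, c2, c3) {
  c1 == 4L & c2 == 1L & (c3 == 1L | c3 == 3L)   # TAA / TAG
}

# Evolve with codon awareness: codons that land on an in-frame stop are
# re-evolved from the parent codon (the parent is stop-free by induction).
evolve_codon_aware <- function(codes, d, kappa, codons, max_tries = 50L) {
  child <- evolve_codes(codes, d, kappa)
  if (nrow(codons) == 0L) return(child)
  for (try in seq_len(max_tries)) {
    bad <- which(is_stop_codon(child[codons[, 1L]], child[codons[, 2L]],
                               child[codons[, 3L]]))
    if (length(bad) == 0L) return(child)
    pos <- as.vector(t(codons[bad, , drop = FALSE]))
    child[pos] <- evolve_codes(codes[pos], d, kappa)
  }
  bad <- which(is_stop_codon(child[codons[, 1L]], child[codons[, 2L]],
                             child[codons[, 3L]]))
  if (length(bad) > 0L) {
    pos <- as.vector(t(codons[bad, , drop = FALSE]))
    child[pos] <- codes[pos]
  }
  child
}

random_root_codes <- function(length, codons) {
  codes <- sample(1:4, length, replace = TRUE)
  repeat {
    if (nrow(codons) == 0L) break
    bad <- which(is_stop_codon(codes[codons[, 1L]], codes[codons[, 2L]],
                               codes[codons[, 3L]]))
    if (length(bad) == 0L) break
    pos <- as.vector(t(codons[bad, , drop = FALSE]))
    codes[pos] <- sample(1:4, length(pos), replace = TRUE)
  }
  codes
}

codes_to_string <- function(codes) paste(BASE_LETTERS[codes], collapse = "")

string_to_codes <- function(s) {
  match(strsplit(toupper(s), "")[[1L]], BASE_LETTERS)
}

# Rescale an ultrametric species tree so the mean pairwise (cophenetic)
# distance equals `target` while no pair falls below `min_dist`: depths are
# first scaled to the target mean, shallow nodes are raised to the floor, and
# the above-floor excesses are compressed by the factor that restores the
# mean exactly. The floor emulates the minimum divergence implicit in the
# recognized species of a curated reference library.
scale_species_tree <- function(tree, target, min_dist = 0) {
  coph <- ape::cophenetic.phylo(tree)
  tree$edge.length <- tree$edge.length * target / mean(coph[upper.tri(coph)])
  if (min_dist > 0) {
    n_tip <- length(tree$tip.label)
    depth <- ape::node.depth.edgelength(tree)
    height <- max(depth) - depth
    height[seq_len(n_tip)] <- 0
    floor_d <- min_dist / 2
    mrca <- ape::mrca(tree)
    pair_d <- height[mrca[upper.tri(mrca)]]
    excess <- mean(pmax(0, pair_d - floor_d))
    s <- if (excess > 0) max(0, (mean(pair_d) - floor_d) / excess) else 0
    idx <- seq.int(n_tip + 1L, n_tip + tree$Nnode)
    height[idx] <- floor_d + s * pmax(0, height[idx] - floor_d)
    tree$edge.length <- height[tree$edge[, 1L]] - height[tree$edge[, 2L]]
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

# Within-species genealogy: coalescent topology and relative node times,
# scaled so the species' intraspecific divergence (the deepest split, an
# I_max-like quantity) equals theta.
scale_coalescent <- function(ctree, theta) {
  if (theta <= 0) {
    ctree$edge.length[] <- 0
    return(ctree)
  }
  depth <- max(ape::node.depth.edgelength(ctree))
  ctree$edge.length <- ctree$edge.length * (theta / 2) / depth
  ctree
}

#' Simulation configuration for synthetic barcode libraries
#'
#' Defaults emulate the structure of a regional orthopteran COI-5P reference
#' library: a few dozen species with a substantial singleton fraction, deep
#' interspecific and shallow intraspecific K2P divergence, transition-biased
#' substitution, a 658-bp alignment, and rare NUMT/contaminant intrusions.
#'
#' @param n_species Number of species.
#' @param specimens_per_species Mean specimens per non-singleton species.
#' @param singleton_prob Probability a species is sampled as a singleton.
#' @param n_jitter Draw non-singleton sample sizes as `2 + rpois(mean - 2)`
#'   (`TRUE`) or use `specimens_per_species` exactly (`FALSE`).
#' @param interspecific_scale Target mean between-species K2P divergence, %.
#' @param intraspecific_theta Intraspecific divergence of a species: the
#'   expected K2P distance across its deepest within-species split, %.
#' @param min_interspecific_frac Floor on sister-species divergence as a
#'   fraction of `interspecific_scale`; emulates the minimum divergence
#'   implicit in the recognized species of a curated library.
#' @param ts_tv_ratio Expected transition/transversion ratio (>= 0.5).
#' @param alignment_length Alignment length in bp (default 658).
#' @param frame Reading-frame offset in `0:2`.
#' @param numt_rate Per-record probability of NUMT replacement.
#' @param numt_burst Extra divergence of a NUMT copy, %.
#' @param numt_stop_prob Probability a NUMT carries an in-frame stop codon.
#' @param contamination_rate Per-record probability of a sample mix-up.
#' @param seed Integer seed controlling every random draw.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_species = 20L,
                       specimens_per_species = 7L,
                       singleton_prob = 0.19,
                       n_jitter = TRUE,
                       interspecific_scale = 15,
                       intraspecific_theta = 3.2,
                       min_interspecific_frac = 0.5,
                       ts_tv_ratio = 3,
                       alignment_length = 658L,
                       frame = 0L,
                       numt_rate = 0.006,
                       numt_burst = 8,
                       numt_stop_prob = 0.5,
                       contamination_rate = 0.0015,
                       seed = 1L) {
  cfg <- list(n_species = as.integer(n_species),
              specimens_per_species = as.integer(specimens_per_species),
              singleton_prob = singleton_prob,
              n_jitter = isTRUE(n_jitter),
              interspecific_scale = interspecific_scale,
              intraspecific_theta = intraspecific_theta,
              min_interspecific_frac = min_interspecific_frac,
              ts_tv_ratio = ts_tv_ratio,
              alignment_length = as.integer(alignment_length),
              frame = as.integer(frame),
              numt_rate = numt_rate,
              numt_burst = numt_burst,
              numt_stop_prob = numt_stop_prob,
              contamination_rate = contamination_rate,
              seed = as.integer(seed))
  if (cfg$n_species < 1L) stop("n_species must be >= 1")
  if (cfg$interspecific_scale <= 0) stop("interspecific_scale must be > 0")
  if (cfg$intraspecific_theta < 0) stop("intraspecific_theta must be >= 0")
  if (cfg$ts_tv_ratio < 0.5) stop("ts_tv_ratio must be >= 0.5")
  if (!cfg$frame %in% 0:2) stop("frame must be 0, 1 or 2")
  for (p in c("singleton_prob", "numt_rate", "numt_stop_prob",
              "contamination_rate")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a barcode library with known truth
#'
#' Generates a species tree by a Yule (pure-birth) process, scaled so the
#' mean between-species divergence matches `interspecific_scale` with sister
#' divergences floored at `min_interspecific_frac` of it; hangs a scaled
#' coalescent genealogy inside each species; and evolves sequences down the
#' combined genealogy under the transition-biased two-class process, with
#' in-frame stop codons (TAA/TAG at the configured frame) rejected by codon
#' resampling. Optionally injects NUMT pseudogene copies and sample-mix-up
#' contaminants at the configured rates. Identical seeds give byte-identical
#' libraries.
#'
#' @param config A [sim_config()].
#' @return List with `library` (a `barcode_library`) and `truth` (list with
#'   `species` — named vector of true assignments —, `species_tree`,
#'   `numt_ids`, `contaminant_ids`).
#' @export
simulate_library <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  K <- config$n_species
  L <- config$alignment_length
  kappa <- config$ts_tv_ratio
  codons <- codon_columns(L, config$frame)

  n_per <- vapply(seq_len(K), function(i) {
    if (runif(1) < config$singleton_prob) return(1L)
    if (config$n_jitter) 2L + rpois(1, max(0, config$specimens_per_species - 2L))
    else config$specimens_per_species
  }, integer(1))

  inter <- config$interspecific_scale / 100
  theta <- config$intraspecific_theta / 100
  if (K >= 2L) {
    sp_tree <- ape::rphylo(K, birth = 1, death = 0)
    sp_tree$tip.label <- paste0("species", sprintf("%02d", seq_len(K)))
    sp_tree <- scale_species_tree(sp_tree, inter,
                                  config$min_interspecific_frac * inter)
    depth <- ape::node.depth.edgelength(sp_tree)
    root_height <- max(depth)
  } else {
    sp_tree <- NULL
    root_height <- 0
  }

  root_codes <- random_root_codes(L, codons)

  # sequences at species-tree internal nodes, then per-species coalescents
  specimen_ids <- character(0)
  specimen_species <- character(0)
  sequences <- character(0)

  evolve_within <- function(anc_codes, ctree) {
    # returns a named list of tip code vectors
    n_tip <- length(ctree$tip.label)
    depths <- ape::node.depth.edgelength(ctree)
    seqs <- vector("list", n_tip + ctree$Nnode)
    seqs[[n_tip + 1L]] <- anc_codes
    tr <- reorder(ctree, "cladewise")
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1L]
      v <- tr$edge[e, 2L]
      seqs[[v]] <- evolve_codon_aware(seqs[[p]], tr$edge.length[e],
                                      kappa, codons)
    }
    setNames(seqs[seq_len(n_tip)], ctree$tip.label)
  }

  species_names <- paste0("species", sprintf("%02d", seq_len(K)))
  if (K >= 2L) {
    n_tip <- K
    depths <- ape::node.depth.edgelength(sp_tree)
    node_seqs <- vector("list", n_tip + sp_tree$Nnode)
    node_seqs[[n_tip + 1L]] <- root_codes
    # within-species genealogies first, so terminal branches can stop at the
    # species MRCA
    within <- lapply(seq_len(K), function(i) {
      k <- n_per[i]
      if (k == 1L) return(NULL)
      scale_coalescent(ape::rcoal(k, tip.label = sprintf("t%02d", seq_len(k))),
                       theta)
    })
    tr <- reorder(sp_tree, "cladewise")
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1L]
      v <- tr$edge[e, 2L]
      len <- tr$edge.length[e]
      if (v <= n_tip) {
        ct <- within[[v]]
        w <- if (is.null(ct)) 0 else max(ape::node.depth.edgelength(ct))
        if (w > len && w > 0) {           # coalescent deeper than the branch
          ct$edge.length <- ct$edge.length * (0.9 * len / w)
          within[[v]] <- ct
          w <- 0.9 * len
        }
        node_seqs[[v]] <- evolve_codon_aware(node_seqs[[p]], len - w,
                                             kappa, codons)
      } else {
        node_seqs[[v]] <- evolve_codon_aware(node_seqs[[p]], len,
                                             kappa, codons)
      }
    }
    for (i in seq_len(K)) {
      tips <- if (is.null(within[[i]])) {
        setNames(list(node_seqs[[i]]), "t01")
      } else {
        evolve_within(node_seqs[[i]], within[[i]])
      }
      ids <- sprintf("SIM%02d-%03d", i, seq_along(tips))
      specimen_ids <- c(specimen_ids, ids)
      specimen_species <- c(specimen_species, rep(species_names[i],
                                                  length(tips)))
      sequences <- c(sequences,
                     vapply(tips, codes_to_string, ""))
    }
  } else {
    k <- n_per[1L]
    tips <- if (k == 1L) list(root_codes) else {
      ct <- scale_coalescent(ape::rcoal(k, tip.label = sprintf("t%02d", seq_len(k))),
                             theta)
      evolve_within(root_codes, ct)
    }
    specimen_ids <- sprintf("SIM01-%03d", seq_along(tips))
    specimen_species <- rep(species_names[1L], length(tips))
    sequences <- vapply(tips, codes_to_string, "")
  }

  names(sequences) <- specimen_ids
  sp_index <- as.integer(sub("species", "", specimen_species))
  genus_idx <- (sp_index - 1L) %/% 3L + 1L
  metadata <- data.frame(
    specimen_id = specimen_ids,
    family = paste0("Family", sprintf("%02d", (genus_idx - 1L) %/% 4L + 1L)),
    genus = paste0("Genus", sprintf("%02d", genus_idx)),
    species = sub("species", "sp", specimen_species),
    bin_id = NA_character_,
    stringsAsFactors = FALSE)
  library <- build_library(sequences, metadata)

  truth <- list(species = setNames(specimen_species, specimen_ids),
                species_tree = sp_tree,
                numt_ids = character(0),
                contaminant_ids = character(0),
                config = unclass(config))

  if (config$contamination_rate > 0 && K >= 2L) {
    contam <- which(runif(length(specimen_ids)) < config$contamination_rate)
    for (k in contam) {
      donors <- which(specimen_species != specimen_species[k])
      if (length(donors) == 0L) next
      donor <- sample(donors, 1L)
      codes <- evolve_codon_aware(string_to_codes(library$sequences[donor]),
                                  0.0005, kappa, codons)
      library$sequences[k] <- codes_to_string(codes)
      truth$contaminant_ids <- c(truth$contaminant_ids, specimen_ids[k])
    }
  }

  out <- list(library = library, truth = truth)
  if (config$numt_rate > 0) {
    out <- inject_numts(out$library, out$truth, config$numt_rate,
                        seed = config$seed + 1L,
                        burst = config$numt_burst,
                        stop_prob = config$numt_stop_prob,
                        kappa = kappa, frame = config$frame)
  }
  out
}

#' Inject NUMT pseudogene copies into a library
#'
#' Replaces randomly selected records with pseudogene copies: the sequence is
#' evolved an extra `burst` percent of divergence and, with probability
#' `stop_prob`, a random in-frame codon is overwritten with a stop (TAA/TAG).
#' Stop-carrying NUMTs are caught by [qc_screen()]; stop-free ones — the
#' notorious atypical NUMTs — pass sequence QC and can only be flagged from
#' their cluster position.
#'
#' @param library A `barcode_library`.
#' @param truth Truth list as returned by [simulate_library()] (may be a
#'   fresh list for hand-built libraries).
#' @param numt_rate Per-record replacement probability.
#' @param seed Integer seed.
#' @param burst Extra divergence in percent (default 8).
#' @param stop_prob Probability of carrying an in-frame stop (default 0.5).
#' @param kappa Transition/transversion ratio for the burst (default 3).
#' @param frame Reading-frame offset (default 0).
#' @return List with modified `library` and `truth` (`numt_ids` extended).
#' @export
inject_numts <- function(library, truth, numt_rate, seed = 1L, burst = 8,
                         stop_prob = 0.5, kappa = 3, frame = 0L) {
  stopifnot(inherits(library, "barcode_library"))
  if (numt_rate < 0 || numt_rate > 1) stop("numt_rate must be in [0, 1]")
  set.seed(seed)
  if (numt_rate == 0) return(list(library = library, truth = truth))
  codons <- codon_columns(library$alignment_length, frame)
  ids <- library$records$specimen_id
  hit <- which(runif(length(ids)) < numt_rate)
  for (k in hit) {
    codes <- evolve_codon_aware(string_to_codes(library$sequences[k]),
                                burst / 100, kappa, codons)
    if (runif(1) < stop_prob && nrow(codons) > 0L) {
      cod <- codons[sample(nrow(codons), 1L), ]
      codes[cod] <- c(4L, 1L, sample(c(1L, 3L), 1L))   # TAA or TAG
    }
    library$sequences[k] <- codes_to_string(codes)
    truth$numt_ids <- c(truth$numt_ids, ids[k])
  }
  list(library = library, truth = truth)
}

#' Write simulation truth to JSON
#'
#' @param truth Truth list from [simulate_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- list(species = as.list(truth$species),
              numt_ids = truth$numt_ids,
              contaminant_ids = truth$contaminant_ids,
              species_tree = if (!is.null(truth$species_tree))
                ape::write.tree(truth$species_tree) else NULL,
              config = truth$config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
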