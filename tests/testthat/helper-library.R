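# Builders for small in-memory libraries and distance matrices.

# random stop-free coding sequence of length L (multiple of 3 padded)
random_coding_seq <- function(L, frame = 0L) {
  bases <- c("A", "C", "G", "T")
  s <- sample(bases, L, replace = TRUE)
  codons <- motulib:::codon_columns(L, frame)
  repeat {
    c1 <- s[codons[, 1L]]
    c2 <- s[codons[, 2L]]
    c3 <- s[codons[, 3L]]
    bad <- which(c1 == "T" & c2 == "A" & (c3 == "A" | c3 == "G"))
    if (length(bad) == 0L) break
    pos <- as.vector(t(codons[bad, , drop = FALSE]))
    s[pos] <- sample(bases, length(pos), replace = TRUE)
  }
  paste(s, collapse = "")
}

mk_library <- function(seqs, family = "FamA", genus = "GenA",
                       species = NA_character_, bin = NA_character_) {
  n <- length(seqs)
  build_library(seqs, data.frame(
    specimen_id = names(seqs),
    family = rep_len(family, n),
    genus = rep_len(genus, n),
    species = rep_len(species, n),
    bin_id = rep_len(bin, n),
    stringsAsFactors = FALSE))
}

mk_dist <- function(d, sites = 600L) {
  ids <- rownames(d)
  structure(list(ids = ids, d = d,
                 sites = matrix(as.integer(sites), nrow(d), ncol(d),
                                dimnames = dimnames(d)),
                 failures = data.frame(id1 = character(0),
                                       id2 = character(0),
                                       reason = character(0))),
            class = "k2p_dist")
}

sym_matrix <- function(ids, fill) {
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (r in seq_len(nrow(fill))) {
    i <- fill[r, 1L]
    j <- fill[r, 2L]
    d[i, j] <- d[j, i] <- as.numeric(fill[r, 3L])
  }
  d
}

# simulation settings used by the well-separated recovery checks
recovery_config <- function(seed) {
  sim_config(n_species = 5, specimens_per_species = 10, singleton_prob = 0,
             n_jitter = FALSE, interspecific_scale = 10,
             intraspecific_theta = 0.5, numt_rate = 0,
             contamination_rate = 0, seed = seed)
}

recovery_ari <- function(seed) {
  sim <- simulate_library(recovery_config(seed))
  dm <- build_matrix(sim$library)
  truth <- sim$truth$species
  hap <- collapse_haplotypes(sim$library)
  map <- attr(hap, "haplotype_map")
  hdm <- build_matrix(hap)
  c(threshold = partition_ari(threshold_partition(dm, 3), truth),
    resl = partition_ari(resl_bins(dm), truth),
    gmyc = partition_ari(
      expand_partition(gmyc_single(upgma_tree(hdm))$partition, map), truth),
    ptp = partition_ari(
      expand_partition(ptp_ml(nj_tree(hdm))$partition, map), truth))
}
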