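test_that("K2P closed forms match the hand-derived worked examples", {
  a <- strrep("A", 20)
  ts2 <- paste0("GG", strrep("A", 18))        # P = 0.1, Q = 0
  tv2 <- paste0("CC", strrep("A", 18))        # P = 0, Q = 0.1
  r1 <- k2p_pair(a, ts2)
  expect_equal(r1$d_percent, -50 * log(0.8), tolerance = 1e-9)
  expect_equal(r1$sites, 20L)
  expect_equal(c(r1$P, r1$Q), c(0.1, 0))
  r2 <- k2p_pair(a, tv2)
  expect_equal(r2$d_percent, -50 * log(0.9) - 25 * log(0.8), tolerance = 1e-9)
  expect_identical(k2p_pair(a, a)$d_percent, 0)
})

test_that("pairwise deletion drops gapped and ambiguous sites", {
  a <- "ANGT-ACGTA"
  b <- "ACGTTACGTN"
  r <- k2p_pair(a, b)
  expect_equal(r$sites, 7L)   # positions 2, 5, 10 excluded
  expect_equal(r$d_percent, 0)
})

test_that("degenerate pairs raise informative errors", {
  expect_error(k2p_pair("----", "AC--"), "no comparable sites")
  expect_error(k2p_pair(strrep("A", 30), strrep("C", 30)), "saturated")
  expect_error(k2p_pair("ACGT", "ACG"), "length")
})

test_that("build_matrix agrees with an independent K2P implementation", {
  set.seed(7)
  seqs <- character(6)
  base <- random_coding_seq(120)
  for (i in 1:6) {
    s <- strsplit(base, "")[[1]]
    mut <- sample(120, 12)
    s[mut] <- sample(c("A", "C", "G", "T"), 12, replace = TRUE)
    seqs[i] <- paste(s, collapse = "")
  }
  names(seqs) <- paste0("S", 1:6)
  dm <- build_matrix(mk_library(seqs))
  bin <- ape::as.DNAbin(strsplit(tolower(seqs), ""))
  ref <- 100 * as.matrix(ape::dist.dna(bin, model = "K80",
                                       pairwise.deletion = TRUE))
  expect_equal(unname(dm$d), unname(ref[dm$ids, dm$ids]), tolerance = 1e-9)
  expect_true(isSymmetric(dm$d))
  expect_true(all(diag(dm$d) == 0))
})

test_that("saturated pairs are annotated, not fatal", {
  seqs <- c(a = strrep("ACGT", 10), b = strrep("ACGT", 10),
            c = strrep("CAAC", 10))   # c vs a/b heavily transversion-divergent
  lib <- mk_library(seqs)
  dm <- build_matrix(lib)
  expect_true(nrow(dm$failures) >= 1L)
  expect_true(any(is.na(dm$d)))
  expect_match(dm$failures$reason[1], "saturated")
})

test_that("adding substitutions never decreases the K2P distance", {
  set.seed(8)
  for (rep in 1:10) {
    L <- 300
    a <- random_coding_seq(L)
    b <- strsplit(a, "")[[1]]
    d_prev <- 0
    pos <- sample(L)
    for (step in 1:8) {
      idx <- pos[(5 * step - 4):(5 * step)]   # previously untouched sites
      for (i in idx) b[i] <- setdiff(c("A", "C", "G", "T"), b[i])[sample(3, 1)]
      d_now <- k2p_pair(a, paste(b, collapse = ""))$d_percent
      expect_gte(d_now, d_prev - 1e-9)
      d_prev <- d_now
    }
  }
})

test_that("rank summary classifies pairs exactly once per divergence class", {
  ids <- c("a1", "a2", "b1", "b2")
  d <- sym_matrix(ids, rbind(c("a1", "a2", 1), c("b1", "b2", 2),
                             c("a1", "b1", 10), c("a1", "b2", 11),
                             c("a2", "b1", 12), c("a2", "b2", 13)))
  tax <- data.frame(specimen_id = ids, family = "F", genus = "G",
                    species = rep(c("G a", "G b"), each = 2))
  rs <- rank_summary(mk_dist(d), tax)
  intra <- rs[rs$rank == "intraspecific", ]
  cong <- rs[rs$rank == "congeners", ]
  expect_equal(intra$comparisons, 2L)
  expect_equal(cong$comparisons, 4L)
  expect_equal(intra$mean_d, 1.5)
  expect_equal(cong$min_d, 10)
  expect_equal(cong$taxa, 1L)  # one genus holds the congeneric pairs
  expect_false("confamilial" %in% rs$rank)
  # classes partition the classified pairs
  expect_equal(sum(rs$comparisons), 6L)
})

test_that("a single-species library yields only the intraspecific class", {
  ids <- c("x1", "x2", "x3")
  d <- sym_matrix(ids, rbind(c("x1", "x2", 1), c("x1", "x3", 2),
                             c("x2", "x3", 1.5)))
  tax <- data.frame(specimen_id = ids, family = "F", genus = "G",
                    species = "G x")
  expect_message(rs <- rank_summary(mk_dist(d), tax), "congeners")
  expect_equal(rs$rank, "intraspecific")
  expect_equal(rs$comparisons, 3L)
})

test_that("within-species distances sit far below between-species ones in a
           two-species simulation", {
  sim <- simulate_library(sim_config(n_species = 2, specimens_per_species = 6,
                                     singleton_prob = 0, n_jitter = FALSE,
                                     interspecific_scale = 10,
                                     intraspecific_theta = 0.5,
                                     numt_rate = 0, contamination_rate = 0,
                                     seed = 11))
  dm <- build_matrix(sim$library)
  sp <- sim$truth$species[dm$ids]
  same <- outer(sp, sp, "==") & upper.tri(dm$d)
  cross <- outer(sp, sp, "!=") & upper.tri(dm$d)
  expect_lt(mean(dm$d[same]), min(dm$d[cross]))
})

test_that("distance exports round-trip the matrix content", {
  set.seed(9)
  seqs <- setNames(replicate(4, random_coding_seq(90)), paste0("S", 1:4))
  dm <- build_matrix(mk_library(seqs))
  tsv <- tempfile(fileext = ".tsv")
  phy <- tempfile(fileext = ".phy")
  write_distances_tsv(dm, tsv)
  write_phylip(dm, phy)
  long <- read.delim(tsv)
  expect_equal(nrow(long), 6L)
  i <- match(long$id1, dm$ids)
  j <- match(long$id2, dm$ids)
  expect_equal(long$d_percent, dm$d[cbind(i, j)], tolerance = 1e-9)
  first <- readLines(phy)[1]
  expect_equal(as.integer(trimws(first)), 4L)
})
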