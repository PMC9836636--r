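mk_part <- function(clusters, method = "m") {
  assignment <- unlist(lapply(names(clusters), function(cl)
    setNames(rep(cl, length(clusters[[cl]])), clusters[[cl]])))
  motu_partition(method, assignment)
}

ev <- function(method, ids) structure(list(method = method, events = ids),
                                      class = "speciation_events")

test_that("the match ratio counts exactly shared clusters", {
  A <- mk_part(list(M1 = c("1", "2"), M2 = "3"))
  expect_equal(match_ratio(A, A), 1)
  B <- mk_part(list(N1 = "1", N2 = "2", N3 = "3"))
  expect_equal(match_ratio(A, B), 2 * 1 / (2 + 3))
  expect_equal(match_ratio(A, B), match_ratio(B, A))
  # the published bPTP-ML/bPTP-BI comparison: 118 shared of 119 and 120
  expect_equal(round(2 * 118 / (119 + 120), 2), 0.99)
  C <- mk_part(list(M1 = c("1", "4")))
  expect_error(match_ratio(A, C), "different specimen sets")
})

test_that("speciation events are the guide-tree nodes spanning several
           MOTUs", {
  tr <- newick_read("((t1:1,t2:1):1,t3:2);")
  n_tip <- 3L
  root <- n_tip + 1L
  A <- mk_part(list(M1 = c("t1", "t2"), M2 = "t3"))
  evA <- speciation_events(tr, A)
  expect_equal(evA$events, root)
  B <- mk_part(list(N1 = "t1", N2 = "t2", N3 = "t3"))
  evB <- speciation_events(tr, B)
  expect_setequal(evB$events, c(root, root + 1L))
  one <- mk_part(list(M = c("t1", "t2", "t3")))
  expect_equal(length(speciation_events(tr, one)$events), 0L)
})

test_that("k monophyletic MOTUs on a binary tree give k - 1 events", {
  set.seed(16)
  for (rep in 1:5) {
    tr <- ape::rcoal(12)
    h <- motulib:::node_heights(tr)
    cut <- runif(1, 0, max(h))
    croot <- motulib:::cluster_roots(tr, h, cut)
    part <- motu_partition("cut", setNames(as.character(croot[1:12]),
                                           tr$tip.label))
    k <- n_motus(part)
    expect_equal(length(speciation_events(tr, part)$events), k - 1L)
  }
})

test_that("the congruence index is intersection over union of events", {
  expect_equal(ctax(ev("a", 1:5), ev("b", 1:5)), 1)
  expect_equal(ctax(ev("a", 1:3), ev("b", 4:6)), 0)
  expect_equal(ctax(ev("a", integer(0)), ev("b", integer(0))), 1)
  expect_equal(ctax(ev("a", 1:98), ev("b", 1:131)), 98 / 131)
  expect_equal(round(98 / 131, 2), 0.75)
  expect_equal(ctax(ev("a", 1:10), ev("b", 5:20)),
               ctax(ev("b", 5:20), ev("a", 1:10)))
})

test_that("resolving power reproduces the published row from nested event
           sets with a union of 139", {
  sizes <- c(BIN = 117, ASAP = 98, jMOTU = 100, sGMYC = 104, mGMYC = 131,
             bPTP_ML = 118, bPTP_BI = 119)
  sets <- lapply(sizes, function(k) ev("m", seq_len(k)))
  # eight of the BIN method's events are seen by no other method, which
  # pushes the union beyond the largest single set
  sets$BIN$events <- c(seq_len(109), 132:139)
  union_size <- length(unique(unlist(lapply(sets, `[[`, "events"))))
  expect_equal(union_size, 139L)
  r <- vapply(sets, rtax, 0, all_methods = sets)
  expect_equal(unname(round(r, 2)),
               c(0.84, 0.71, 0.72, 0.75, 0.94, 0.85, 0.86))
  expect_true(all(r <= 1))
  expect_equal(rtax(sets[[1]], sets[1]), 1)
})

test_that("consensus recovery requires exact agreement in every partition", {
  taxa <- c(a1 = "A", a2 = "A", b1 = "B", c1 = "C", c2 = "C")
  full <- list(
    mk_part(list(M1 = c("a1", "a2"), M2 = "b1", M3 = c("c1", "c2")), "p1"),
    mk_part(list(N1 = c("a1", "a2"), N2 = "b1", N3 = c("c1", "c2")), "p2"))
  expect_equal(consensus_count(full, taxa)$count, 3L)
  split_c <- list(full[[1]],
    mk_part(list(N1 = c("a1", "a2"), N2 = "b1", N3 = "c1", N4 = "c2"), "p2"))
  res <- consensus_count(split_c, taxa)
  expect_equal(res$count, 2L)
  expect_setequal(res$taxa, c("A", "B"))
  merged <- list(full[[1]],
    mk_part(list(N1 = c("a1", "a2", "b1"), N3 = c("c1", "c2")), "p2"))
  expect_setequal(consensus_count(merged, taxa)$taxa, "C")
})

test_that("methods disagreeing only on an ambiguous species agree on the
           other three", {
  sim <- simulate_library(sim_config(n_species = 4, specimens_per_species = 5,
                                     singleton_prob = 0, n_jitter = FALSE,
                                     interspecific_scale = 12,
                                     intraspecific_theta = 0.5,
                                     numt_rate = 0, contamination_rate = 0,
                                     seed = 41))
  truth <- sim$truth$species
  ids <- names(truth)
  agree <- mk_part(split(ids, truth), "agree")
  amb <- truth
  amb[truth == "species04"] <- paste0(amb[truth == "species04"],
                                      rep(c("a", "b"),
                                          length.out = sum(truth == "species04")))
  splitter <- mk_part(split(ids, amb), "splitter")
  res <- consensus_count(list(agree, splitter), truth)
  expect_equal(res$count, 3L)
  expect_false("species04" %in% res$taxa)
})

test_that("the assembled concordance table matches direct pairwise calls and
           nested thresholds minimise the coarsest method's power", {
  sim <- simulate_library(recovery_config(51))
  dm <- build_matrix(sim$library)
  tree <- phangorn::midpoint(nj_tree(dm))
  parts <- list(c1 = threshold_partition(dm, 1),
                c2 = threshold_partition(dm, 3),
                c3 = threshold_partition(dm, 6),
                resl = resl_bins(dm))
  tab <- concordance_table(parts, tree)
  evs <- lapply(parts, speciation_events, tree = tree)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    expect_equal(tab$match_ratio[i, j], match_ratio(parts[[i]], parts[[j]]),
                 tolerance = 1e-12)
    expect_equal(tab$c_tax[i, j], ctax(evs[[i]], evs[[j]]),
                 tolerance = 1e-12)
  }
  expect_equal(unname(tab$n_motus), vapply(parts, n_motus, 0L),
               ignore_attr = TRUE)
  expect_true(all(tab$r_tax >= 0 & tab$r_tax <= 1))
  # threshold partitions are nested, so the coarsest has the fewest events
  expect_equal(unname(tab$r_tax["c3"]), min(tab$r_tax))
  # identical methods give an all-ones comparison
  same <- concordance_table(list(a = parts$c2, b = parts$c2), tree)
  expect_equal(unname(same$match_ratio[1, 2]), 1)
  expect_equal(unname(same$c_tax[2, 1]), 1)
})
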