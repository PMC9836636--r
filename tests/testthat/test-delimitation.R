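test_that("threshold partitioning forms single-linkage components", {
  ids <- c("a", "b", "c")
  d <- sym_matrix(ids, rbind(c("a", "b", 1), c("a", "c", 5), c("b", "c", 5)))
  p2 <- threshold_partition(mk_dist(d), 2)
  expect_equal(n_motus(p2), 2L)
  expect_equal(unname(p2$assignment["a"]), unname(p2$assignment["b"]))
  expect_false(p2$assignment["a"] == p2$assignment["c"])
  p6 <- threshold_partition(mk_dist(d), 6)
  expect_equal(n_motus(p6), 1L)
  expect_error(threshold_partition(mk_dist(d), -1), "non-negative")
})

test_that("cutoff 0 yields haplotype classes and a large cutoff one MOTU", {
  ids <- c("a", "b", "c", "d")
  d <- sym_matrix(ids, rbind(c("a", "b", 0), c("a", "c", 2), c("a", "d", 2),
                             c("b", "c", 2), c("b", "d", 2), c("c", "d", 1)))
  expect_equal(n_motus(threshold_partition(mk_dist(d), 0)), 3L)
  expect_equal(n_motus(threshold_partition(mk_dist(d), max(d))), 1L)
})

test_that("MOTU count is non-increasing in the cutoff and matches an
           hclust single-linkage oracle", {
  set.seed(13)
  for (rep in 1:5) {
    n <- 10
    m <- matrix(runif(n * n, 0, 10), n, n,
                dimnames = list(paste0("t", 1:n), paste0("t", 1:n)))
    d <- (m + t(m)) / 2
    diag(d) <- 0
    dm <- mk_dist(d)
    hc <- hclust(as.dist(d), method = "single")
    prev <- Inf
    for (cut in c(0.5, 1, 2, 4, 8)) {
      p <- threshold_partition(dm, cut)
      k <- n_motus(p)
      expect_lte(k, prev)
      prev <- k
      oracle <- cutree(hc, h = cut)
      expect_equal(partition_ari(p, setNames(as.character(oracle),
                                             rownames(d))), 1)
    }
  }
})

test_that("the base-pair sweep converts cutoffs to percent and plateaus at
           the true species count on well-separated data", {
  sim <- simulate_library(recovery_config(101))
  dm <- build_matrix(sim$library)
  sweep <- threshold_sweep(dm, 1:40, alignment_length = 658L)
  expect_equal(round(sweep[["1bp"]]$parameters$cutoff_percent, 2), 0.15)
  expect_equal(round(sweep[["40bp"]]$parameters$cutoff_percent, 2), 6.08)
  counts <- vapply(sweep, n_motus, 0L)
  runs <- rle(counts)
  expect_gte(max(runs$lengths[runs$values == 5L]), 8L)
})

test_that("refined single linkage separates distant clusters and keeps
           identical libraries together", {
  ids <- paste0("t", 1:6)
  pairs <- t(combn(ids, 2))
  same <- substr(pairs[, 1], 2, 2) %in% c("1", "2", "3") ==
          substr(pairs[, 2], 2, 2) %in% c("1", "2", "3")
  d <- sym_matrix(ids, cbind(pairs, ifelse(same, 0.2, 10)))
  p <- resl_bins(mk_dist(d))
  expect_equal(n_motus(p), 2L)
  z <- sym_matrix(ids, cbind(pairs, 0))
  expect_equal(n_motus(resl_bins(mk_dist(z))), 1L)
})

test_that("a within-component split is accepted exactly when the mean
           silhouette improves (hand-computed case)", {
  # component X: two tight triplets 1.8% apart (one stage-1 cluster at 2.2%),
  # plus a distant cluster Y at 10%
  ids <- c(paste0("x", 1:6), paste0("y", 1:3))
  grp <- c(rep("A", 3), rep("B", 3), rep("Y", 3))
  pairs <- t(combn(ids, 2))
  val <- apply(pairs, 1, function(p) {
    g <- grp[match(p, ids)]
    if (g[1] == g[2]) 0.1
    else if ("Y" %in% g) 10
    else 1.8
  })
  d <- sym_matrix(ids, cbind(pairs, val))
  p <- resl_bins(mk_dist(d))
  expect_equal(n_motus(p), 3L)
  expect_equal(p$parameters$n_splits_accepted, 1L)
  # hand silhouette: before s = (10 - 1.12)/10, after s = (1.8 - 0.1)/1.8
  before <- (10 - (2 * 0.1 + 3 * 1.8) / 5) / 10
  after <- (1.8 - 0.1) / 1.8
  expect_gt(after, before)

  # equidistant component: the best split lowers the silhouette -> kept whole
  val2 <- apply(pairs, 1, function(p) {
    g <- grp[match(p, ids)]
    if ("Y" %in% g && !all(g == "Y")) 10 else if (all(g == "Y")) 0.1 else 0.4
  })
  d2 <- sym_matrix(ids, cbind(pairs, val2))
  expect_equal(n_motus(resl_bins(mk_dist(d2))), 2L)
})

test_that("duplicated haplotypes cannot fake a perfect split silhouette", {
  # two haplotype groups 0.5% apart, each internally identical
  ids <- c(paste0("x", 1:6), paste0("y", 1:3))
  grp <- c(rep("A", 3), rep("B", 3), rep("Y", 3))
  pairs <- t(combn(ids, 2))
  val <- apply(pairs, 1, function(p) {
    g <- grp[match(p, ids)]
    if (g[1] == g[2]) 0
    else if ("Y" %in% g) 10
    else 0.5
  })
  d <- sym_matrix(ids, cbind(pairs, val))
  p <- resl_bins(mk_dist(d))
  expect_equal(n_motus(p), 2L)   # the 0.5% haplotype split is not a BIN split
})

test_that("partitions are true set partitions and expansion covers all
           specimens", {
  sim <- simulate_library(recovery_config(5))
  dm <- build_matrix(sim$library)
  for (p in list(threshold_partition(dm, 3), resl_bins(dm))) {
    expect_setequal(names(p$assignment), dm$ids)
    expect_false(anyNA(p$assignment))
    sets <- motu_sets(p)
    expect_equal(sum(lengths(sets)), length(dm$ids))
  }
  hap <- collapse_haplotypes(sim$library)
  hp <- threshold_partition(build_matrix(hap), 3)
  full <- expand_partition(hp, attr(hap, "haplotype_map"))
  expect_setequal(names(full$assignment), sim$library$records$specimen_id)
})
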