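test_that("nearest-neighbour distances are symmetric minima over cross
           pairs (brute force)", {
  sim <- simulate_library(sim_config(n_species = 3, specimens_per_species = 4,
                                     singleton_prob = 0, n_jitter = FALSE,
                                     interspecific_scale = 12,
                                     intraspecific_theta = 1,
                                     numt_rate = 0, contamination_rate = 0,
                                     seed = 31))
  dm <- build_matrix(sim$library)
  tax <- sim$library$records
  summ <- species_summaries(dm, tax)
  sp <- tax$species[match(dm$ids, tax$specimen_id)]
  for (r in seq_len(nrow(summ))) {
    own <- which(sp == summ$species[r])
    other <- which(sp != summ$species[r])
    expect_equal(summ$dnn[r], min(dm$d[own, other]), tolerance = 1e-9)
    intra <- dm$d[own, own][upper.tri(diag(length(own)))]
    expect_equal(summ$i_max[r], max(intra), tolerance = 1e-9)
    expect_lte(summ$i_mean[r], summ$i_max[r])
  }
})

test_that("singletons carry undefined intraspecific statistics and the gap
           flag is literally dnn > i_max", {
  ids <- c("a1", "a2", "b1", "c1", "c2")
  d <- sym_matrix(ids, rbind(
    c("a1", "a2", 6), c("a1", "b1", 4), c("a2", "b1", 5),
    c("a1", "c1", 9), c("a1", "c2", 9), c("a2", "c1", 9), c("a2", "c2", 9),
    c("b1", "c1", 7), c("b1", "c2", 8), c("c1", "c2", 1)))
  tax <- data.frame(specimen_id = ids, family = "F", genus = "G",
                    species = c("G a", "G a", "G b", "G c", "G c"))
  summ <- species_summaries(mk_dist(d), tax)
  a <- summ[summ$species == "G a", ]
  b <- summ[summ$species == "G b", ]
  c_ <- summ[summ$species == "G c", ]
  expect_true(is.na(b$i_mean) && is.na(b$i_max) && is.na(b$gap))
  expect_equal(b$dnn, 4)
  expect_false(a$gap)                   # i_max 6 > dnn 4
  expect_true(c_$gap)                   # dnn 7 > i_max 1
  expect_equal(a$nn_species, "G b")
})

test_that("a single-species library has no nearest neighbour and errors", {
  ids <- c("a1", "a2")
  d <- sym_matrix(ids, rbind(c("a1", "a2", 1)))
  tax <- data.frame(specimen_id = ids, family = "F", genus = "G",
                    species = "G a")
  expect_error(species_summaries(mk_dist(d), tax), "at least 2 species")
})

test_that("nearest-neighbour ties break to the smallest species name", {
  ids <- c("a1", "b1", "c1")
  d <- sym_matrix(ids, rbind(c("a1", "b1", 5), c("a1", "c1", 5),
                             c("b1", "c1", 9)))
  tax <- data.frame(specimen_id = ids, family = "F", genus = "G",
                    species = c("G a", "G b", "G c"))
  summ <- species_summaries(mk_dist(d), tax)
  expect_equal(summ$nn_species[summ$species == "G a"], "G b")
})

test_that("library statistics aggregate a constructed all-gap table", {
  tab <- data.frame(
    species = c("s1", "s2", "s3"),
    n = c(3L, 1L, 4L),
    n_bins = c(1L, 1L, 2L),
    bins = c("B1:3", "B2:1", "B3:2;B4:2"),
    i_mean = c(0.5, NA, 1),
    i_max = c(1, NA, 2.5),
    nn_species = c("s3", "s1", "s1"),
    dnn = c(8, 9, 8),
    gap = c(TRUE, NA, TRUE))
  ls <- library_stats(tab)
  expect_equal(ls$n_species, 3L)
  expect_equal(ls$n_records, 8L)
  expect_equal(ls$n_singletons, 1L)
  expect_equal(ls$n_gap_present, ls$n_nonsingleton)
  expect_equal(ls$mean_imax_nonsingleton, 1.75)
  expect_equal(ls$mean_dnn, mean(c(8, 9, 8)))
  expect_equal(ls$n_deep, 1L)           # only s3 exceeds 2%
  expect_equal(ls$n_deep_split, 1L)
  expect_equal(ls$n_split_species, 1L)
  expect_equal(ls$mean_bins_per_split, 2)
  expect_equal(ls$n_distinct_bins, 4L)
})

test_that("the packaged per-species table stores mutual nearest neighbours
           and singleton conventions faithfully", {
  t2 <- table2_fixture()
  mb <- t2[t2$species == "Mirollia bispina", ]
  mbo <- t2[t2$species == "Mirollia bispinosa", ]
  expect_equal(mb$dnn, 4.61)
  expect_equal(mbo$dnn, 4.61)
  expect_equal(mb$nn_species, "Mirollia bispinosa")
  expect_equal(mbo$nn_species, "Mirollia bispina")
  singles <- t2[t2$n == 1L, ]
  expect_true(all(is.na(singles$i_mean)))
  expect_true(all(is.na(singles$i_max)))
  expect_true(all(is.na(singles$gap)))
  # the four species whose deep variation erases the gap are the starred ones
  no_gap <- t2$species[!is.na(t2$gap) & !t2$gap]
  expect_setequal(no_gap, c("Melaneremus fuscoterminatus",
                            "Elimaea terminalis",
                            "Sinochlora szechwanensis",
                            "Xizicus howardi"))
})
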