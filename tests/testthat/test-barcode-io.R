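test_that("a library round-trips through FASTA + metadata files", {
  set.seed(1)
  seqs <- setNames(replicate(3, random_coding_seq(60)), c("S1", "S2", "S3"))
  lib <- mk_library(seqs, genus = "Conocephalus",
                    species = c("gladiatus", "maculatus", NA))
  fa <- tempfile(fileext = ".fasta")
  md <- tempfile(fileext = ".tsv")
  write_library(lib, fa, md)
  lib2 <- read_library(fa, md)
  expect_equal(lib2$records$specimen_id, c("S1", "S2", "S3"))
  expect_equal(unname(lib2$sequences), unname(seqs))
  expect_equal(lib2$alignment_length, 60L)
  expect_equal(lib2$records$species,
               c("Conocephalus gladiatus", "Conocephalus maculatus", NA))
})

test_that("metadata parsing joins genus and epithet into the species label", {
  seqs <- setNames(random_coding_seq(30), "DBTZC033-21")
  lib <- build_library(seqs, data.frame(
    specimen_id = "DBTZC033-21", family = "Tettigoniidae",
    genus = "Conocephalus", species = "gladiatus", bin_id = NA))
  expect_equal(lib$records$species, "Conocephalus gladiatus")
})

test_that("mismatched, duplicated and ragged inputs fail naming the record", {
  seqs <- setNames(replicate(3, random_coding_seq(30)), c("A", "B", "C"))
  meta <- data.frame(specimen_id = c("A", "B"), family = "F", genus = "G",
                     species = NA, bin_id = NA)
  expect_error(build_library(seqs, meta), "C")
  meta4 <- rbind(meta, data.frame(specimen_id = c("C", "D"), family = "F",
                                  genus = "G", species = NA, bin_id = NA))
  expect_error(build_library(seqs, meta4), "D")
  dup <- seqs
  names(dup) <- c("A", "A", "B")
  expect_error(build_library(dup, meta4), "duplicate.*A")
  ragged <- c(seqs[1:2], C = random_coding_seq(33))
  meta3 <- meta4[1:3, ]
  expect_error(build_library(ragged, meta3), "ragged.*C")
  bad <- seqs
  bad[["B"]] <- paste0("Z", substr(bad[["B"]], 2, 30))
  expect_error(build_library(bad, meta3), "non-IUPAC.*B")
})

test_that("reading frame is detected library-wide with deterministic ties", {
  set.seed(2)
  seqs <- setNames(replicate(4, random_coding_seq(60)), paste0("S", 1:4))
  lib <- mk_library(seqs)
  expect_identical(as.integer(detect_reading_frame(lib)), 0L)
  shifted <- setNames(paste0("C", substr(seqs, 1, 59)), names(seqs))
  expect_identical(as.integer(detect_reading_frame(mk_library(shifted))), 1L)
})

test_that("detected frame never has more stops than the alternatives", {
  # brute-force oracle: count TAA/TAG triplets per offset with substring scans
  oracle_counts <- function(seqs, L) {
    vapply(0:2, function(f) {
      sum(vapply(seqs, function(s) {
        starts <- seq(f + 1L, L - 2L, by = 3L)
        cods <- substring(s, starts, starts + 2L)
        sum(cods %in% c("TAA", "TAG"))
      }, numeric(1)))
    }, numeric(1))
  }
  set.seed(3)
  for (rep in 1:5) {
    seqs <- setNames(replicate(5, paste(sample(c("A", "C", "G", "T"), 66,
                                               replace = TRUE),
                                        collapse = "")), paste0("S", 1:5))
    lib <- mk_library(seqs)
    frame <- detect_reading_frame(lib)
    counts <- oracle_counts(seqs, 66L)
    expect_equal(unname(attr(frame, "stop_counts")), counts)
    expect_equal(counts[as.integer(frame) + 1L], min(counts))
    expect_identical(as.integer(frame), which.min(counts) - 1L)
  }
})

test_that("QC applies the >500 bp, <1% N, no-stop-codon criteria", {
  set.seed(4)
  clean <- random_coding_seq(658)
  short <- paste0(substr(clean, 1, 480), strrep("-", 178))
  with_stop <- paste0("TAA", substr(clean, 4, 658))
  n8 <- paste0(strrep("N", 8), substr(clean, 9, 658))    # 1.22% N
  n6 <- paste0(strrep("N", 6), substr(clean, 7, 658))    # 0.91% N
  lib <- mk_library(c(clean = clean, short = short, stop = with_stop,
                      n8 = n8, n6 = n6))
  lib <- qc_screen(lib, frame = 0L)
  qc <- lib$qc
  expect_equal(qc$passes, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(qc$ungapped_length[2], 480L)
  expect_false(qc$stop_codon[1])
  expect_true(qc$stop_codon[3])
  expect_gt(qc$n_fraction[4], 0.01)
  expect_lt(qc$n_fraction[5], 0.01)
})

test_that("codons containing ambiguity codes or gaps never count as stops", {
  s <- paste0("TAN", "T-A", "TAC", strrep("ACT", 17))   # 60 bp
  lib <- qc_screen(mk_library(c(x = s)), frame = 0L)
  expect_false(lib$qc$stop_codon[1])
})

test_that("qc_screen is idempotent and order-preserving", {
  set.seed(5)
  seqs <- setNames(replicate(6, random_coding_seq(60)), paste0("S", 6:1))
  lib <- qc_screen(mk_library(seqs), frame = 0L)
  lib2 <- qc_screen(lib, frame = 0L)
  expect_identical(lib$qc, lib2$qc)
  expect_identical(lib$qc$specimen_id, paste0("S", 6:1))
})

test_that("haplotype collapse maps every specimen to its representative", {
  set.seed(6)
  a <- random_coding_seq(60)
  b <- random_coding_seq(60)
  lib <- mk_library(c(x1 = a, x2 = a, y1 = b, x3 = a))
  hap <- collapse_haplotypes(lib)
  expect_equal(hap$records$specimen_id, c("x1", "y1"))
  map <- attr(hap, "haplotype_map")
  expect_equal(unname(map[c("x1", "x2", "x3", "y1")]),
               c("x1", "x1", "x1", "y1"))
})
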