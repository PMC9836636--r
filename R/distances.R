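# Integer encoding used for distance computation: unambiguous bases only,
# everything else (gaps, Ns, other IUPAC ambiguity codes) becomes NA and is
# excluded pairwise.
encode_sequences <- function(sequences) {
  codes <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  chars <- strsplit(sequences, "")
  m <- matrix(NA_integer_, nrow = length(chars), ncol = nchar(sequences[[1L]]))
  for (i in seq_along(chars)) {
    m[i, ] <- unname(codes[chars[[i]]])
  }
  rownames(m) <- names(sequences)
  m
}

# base class: 1 = purine (A, G), 2 = pyrimidine (C, T)
BASE_CLASS <- c(1L, 2L, 1L, 2L)

k2p_from_codes <- function(x, y, ids = c("a", "b")) {
  ok <- !is.na(x) & !is.na(y)
  sites <- sum(ok)
  if (sites == 0L) {
    stop("no comparable sites between ", ids[1L], " and ", ids[2L])
  }
  xs <- x[ok]
  ys <- y[ok]
  diff <- xs != ys
  ts <- sum(diff & BASE_CLASS[xs] == BASE_CLASS[ys])
  tv <- sum(diff) - ts
  P <- ts / sites
  Q <- tv / sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop("K2P distance saturated for pair ", ids[1L], " / ", ids[2L],
         " (P = ", signif(P, 4), ", Q = ", signif(Q, 4), ")")
  }
  d <- (-0.5 * log(w1) - 0.25 * log(w2)) + 0   # + 0 normalises IEEE -0
  list(d_percent = 100 * d, sites = sites, P = P, Q = Q)
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' Computes the K2P distance with pairwise deletion: alignment columns where
#' either sequence carries a gap or any non-ACGT code are excluded. With `P`
#' the transition and `Q` the transversion fraction over the comparable sites,
#' the distance is `-(1/2) log((1 - 2P - Q) sqrt(1 - 2Q))`, reported in
#' percent.
#'
#' @param a,b Aligned sequences of equal length (character strings,
#'   case-insensitive).
#' @return A list with `d_percent`, `sites` (comparable-site count), `P`, `Q`.
#' @examples
#' s <- paste(rep("ACGT", 15), collapse = "")
#' k2p_pair(s, s)$d_percent   # 0
#' @export
k2p_pair <- function(a, b) {
  a <- toupper(a)
  b <- toupper(b)
  if (nchar(a) != nchar(b)) {
    stop("sequences differ in aligned length (", nchar(a), " vs ",
         nchar(b), ")")
  }
  m <- encode_sequences(c(a = a, b = b))
  k2p_from_codes(m[1L, ], m[2L, ])
}

#' Pairwise K2P distance matrix for a barcode library
#'
#' Computes all pairwise K2P distances (percent) under pairwise deletion,
#' together with comparable-site counts. Pairs with no comparable sites or a
#' saturated distance are recorded as missing with the reason, never aborting
#' the whole matrix.
#'
#' @param library A `barcode_library` (typically after [filter_passing()]).
#' @return A `k2p_dist` object: list with `ids`, `d` (symmetric percent
#'   matrix, `NA` for failed pairs), `sites`, and `failures` (data frame
#'   `id1`, `id2`, `reason`).
#' @export
build_matrix <- function(library) {
  stopifnot(inherits(library, "barcode_library"))
  ids <- library$records$specimen_id
  n <- length(ids)
  if (n < 2L) stop("need at least 2 records to build a distance matrix")
  m <- encode_sequences(library$sequences)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  sites <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(sites) <- as.integer(rowSums(!is.na(m)))
  fail <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      res <- tryCatch(k2p_from_codes(m[i, ], m[j, ], ids = ids[c(i, j)]),
                      error = function(e) conditionMessage(e))
      if (is.character(res)) {
        d[i, j] <- d[j, i] <- NA_real_
        fail[[length(fail) + 1L]] <- data.frame(id1 = ids[i], id2 = ids[j],
                                                reason = res)
      } else {
        d[i, j] <- d[j, i] <- res$d_percent
        sites[i, j] <- sites[j, i] <- res$sites
      }
    }
  }
  failures <- if (length(fail)) do.call(rbind, fail) else
    data.frame(id1 = character(0), id2 = character(0), reason = character(0))
  structure(list(ids = ids, d = d, sites = sites, failures = failures),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  up <- x$d[upper.tri(x$d)]
  cat("k2p_dist:", length(x$ids), "specimens,",
      sum(!is.na(up)), "computed pairs")
  if (nrow(x$failures)) cat(",", nrow(x$failures), "failed pairs")
  cat("\n")
  if (any(!is.na(up))) {
    cat(sprintf("  distances (%%): min %.2f, mean %.2f, max %.2f\n",
                min(up, na.rm = TRUE), mean(up, na.rm = TRUE),
                max(up, na.rm = TRUE)))
  }
  invisible(x)
}

#' Summarise K2P divergence by taxonomic rank
#'
#' Classifies every specimen pair into exactly one divergence class:
#' intraspecific (same species label; only species with two or more records
#' contribute), congeners (same genus, different species), or confamilial
#' (same family, different genus). Pairs involving records without a species
#' label are only classified where the shared rank is still defined
#' (confamilial for same-family/different-genus); pairs whose class cannot be
#' determined are left out.
#'
#' @param matrix A `k2p_dist`.
#' @param taxonomy Data frame with `specimen_id`, `family`, `genus`,
#'   `species` covering all matrix ids (`species` may be `NA`).
#' @return Data frame with one row per non-empty class: `rank`, `n`
#'   (sequences involved), `taxa`, `comparisons`, `min_d`, `mean_d`, `max_d`
#'   (percent).
#' @export
rank_summary <- function(matrix, taxonomy) {
  stopifnot(inherits(matrix, "k2p_dist"))
  idx <- match(matrix$ids, taxonomy$specimen_id)
  if (anyNA(idx)) {
    stop("taxonomy missing specimen(s): ",
         paste(matrix$ids[is.na(idx)], collapse = ", "))
  }
  fam <- taxonomy$family[idx]
  gen <- taxonomy$genus[idx]
  spc <- taxonomy$species[idx]
  n <- length(matrix$ids)
  pairs <- which(upper.tri(matrix$d), arr.ind = TRUE)
  i <- pairs[, 1L]
  j <- pairs[, 2L]
  dv <- matrix$d[pairs]
  same_sp <- !is.na(spc[i]) & !is.na(spc[j]) & spc[i] == spc[j]
  same_gen <- gen[i] == gen[j]
  same_fam <- fam[i] == fam[j]
  diff_sp <- !is.na(spc[i]) & !is.na(spc[j]) & spc[i] != spc[j]
  cls <- rep(NA_character_, length(i))
  cls[same_sp] <- "intraspecific"
  cls[diff_sp & same_gen] <- "congeners"
  cls[same_fam & !same_gen] <- "confamilial"
  rows <- list()
  for (r in c("intraspecific", "congeners", "confamilial")) {
    sel <- which(cls == r & !is.na(dv))
    if (length(sel) == 0L) {
      message("rank_summary: no qualifying pairs for class '", r, "'")
      next
    }
    members <- unique(c(i[sel], j[sel]))
    taxa <- switch(r,
      intraspecific = length(unique(spc[i[sel]])),
      congeners = length(unique(gen[i[sel]])),
      confamilial = length(unique(fam[i[sel]])))
    rows[[r]] <- data.frame(rank = r,
                            n = length(members),
                            taxa = taxa,
                            comparisons = length(sel),
                            min_d = min(dv[sel]),
                            mean_d = mean(dv[sel]),
                            max_d = max(dv[sel]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a distance matrix as a PHYLIP square matrix
#'
#' @param matrix A `k2p_dist`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(matrix, path) {
  stopifnot(inherits(matrix, "k2p_dist"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", length(matrix$ids)), con)
  for (i in seq_along(matrix$ids)) {
    writeLines(paste(c(sprintf("%-10s", matrix$ids[i]),
                       sprintf("%.6f", matrix$d[i, ] / 100)),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Export pairwise distances in long format
#'
#' One row per unordered pair: `id1`, `id2`, `d_percent`, `sites`.
#'
#' @param matrix A `k2p_dist`.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_distances_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "k2p_dist"))
  pairs <- which(upper.tri(matrix$d), arr.ind = TRUE)
  out <- data.frame(id1 = matrix$ids[pairs[, 1L]],
                    id2 = matrix$ids[pairs[, 2L]],
                    d_percent = matrix$d[pairs],
                    sites = matrix$sites[pairs])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# dist view (percent scale) used by tree builders and clustering
as_dist <- function(matrix) {
  stopifnot(inherits(matrix, "k2p_dist"))
  as.dist(matrix$d)
}
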