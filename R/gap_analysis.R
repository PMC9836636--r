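# "BIN:count" strings like "ADF2751:1;AEJ4972:2" <-> data frame
parse_bins <- function(s) {
  if (is.na(s) || s == "") {
    return(data.frame(bin = character(0), n = integer(0)))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  data.frame(bin = vapply(parts, `[`, "", 1L),
             n = as.integer(vapply(parts, `[`, "", 2L)),
             stringsAsFactors = FALSE)
}

format_bins <- function(bins, counts) {
  paste0(bins, ":", counts, collapse = ";")
}

#' Per-species barcode-gap statistics
#'
#' Builds one row per named species: mean and maximum intraspecific K2P
#' distance (`i_mean`, `i_max`; undefined for singletons), the nearest
#' neighbour species and the distance to it (`dnn`, the minimum K2P distance
#' from any member to any member of another species), the cluster identifiers
#' its members carry, and the barcode-gap flag `gap = dnn > i_max`. The
#' nearest neighbour ties break to the smallest distance, then the
#' lexicographically smallest species name. Records without a species label
#' are excluded (they are censused separately at genus level).
#'
#' @param matrix A `k2p_dist`.
#' @param taxonomy Data frame with `specimen_id` and `species` (`NA` allowed)
#'   covering all matrix ids.
#' @param bins Optional named vector mapping specimen id to an externally
#'   assigned cluster/BIN label.
#' @return A `species_summary` data frame: `species`, `n`, `n_bins`, `bins`,
#'   `i_mean`, `i_max`, `nn_species`, `dnn`, `gap`.
#' @export
species_summaries <- function(matrix, taxonomy, bins = NULL) {
  stopifnot(inherits(matrix, "k2p_dist"))
  idx <- match(matrix$ids, taxonomy$specimen_id)
  if (anyNA(idx)) {
    stop("taxonomy missing specimen(s): ",
         paste(matrix$ids[is.na(idx)], collapse = ", "))
  }
  spc <- taxonomy$species[idx]
  keep <- which(!is.na(spc))
  species <- sort(unique(spc[keep]))
  if (length(species) < 2L) {
    stop("need at least 2 species for nearest-neighbour statistics")
  }
  members <- split(keep, spc[keep])
  rows <- lapply(species, function(sp) {
    own <- members[[sp]]
    n <- length(own)
    if (n >= 2L) {
      sub <- matrix$d[own, own]
      intra <- sub[upper.tri(sub)]
      i_mean <- mean(intra, na.rm = TRUE)
      i_max <- max(intra, na.rm = TRUE)
    } else {
      i_mean <- NA_real_
      i_max <- NA_real_
    }
    per_sp <- vapply(species[species != sp], function(other) {
      min(matrix$d[own, members[[other]]], na.rm = TRUE)
    }, numeric(1))
    dnn <- min(per_sp)
    nn_candidates <- sort(names(per_sp)[per_sp <= dnn + 1e-12])
    nn <- nn_candidates[1L]
    bin_str <- NA_character_
    n_bins <- NA_integer_
    if (!is.null(bins)) {
      b <- bins[matrix$ids[own]]
      tab <- table(b[!is.na(b)])
      if (length(tab) > 0L) {
        bin_str <- format_bins(names(tab), as.integer(tab))
        n_bins <- length(tab)
      }
    }
    data.frame(species = sp, n = n, n_bins = n_bins, bins = bin_str,
               i_mean = i_mean, i_max = i_max,
               nn_species = nn, dnn = dnn,
               gap = if (n >= 2L) dnn > i_max else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("species_summary", class(out))
  out
}

#' Library-level aggregates of per-species gap statistics
#'
#' Summarises a species-summary table (computed by [species_summaries()] or
#' transcribed from a published report). Means are taken at full precision;
#' the mean nearest-neighbour distance averages over *all* species rows,
#' singletons included, while the mean maximum intraspecific distance uses
#' non-singletons only (singletons have no intraspecific comparison). "Deep"
#' intraspecific divergence means `i_max` above 2%.
#'
#' @param summaries A `species_summary` data frame (columns `species`, `n`,
#'   `n_bins`, `bins`, `i_mean`, `i_max`, `dnn`, `gap`).
#' @param deep_threshold Deep-divergence cutoff in percent (default 2).
#' @return A one-row data frame: `n_species`, `n_records`, `n_singletons`,
#'   `n_nonsingleton`, `mean_imax_nonsingleton`, `mean_dnn`, `dnn_min`,
#'   `dnn_max`, `n_gap_present`, `n_deep`, `n_deep_split`, `n_split_species`,
#'   `mean_bins_per_split`, `n_distinct_bins`.
#' @export
library_stats <- function(summaries, deep_threshold = 2) {
  s <- summaries
  singleton <- s$n == 1L
  nonsing <- !singleton
  split_sp <- !is.na(s$n_bins) & s$n_bins >= 2L
  deep <- nonsing & s$i_max > deep_threshold
  all_bins <- unlist(lapply(s$bins[!is.na(s$bins)],
                            function(x) parse_bins(x)$bin))
  data.frame(
    n_species = nrow(s),
    n_records = sum(s$n),
    n_singletons = sum(singleton),
    n_nonsingleton = sum(nonsing),
    mean_imax_nonsingleton = mean(s$i_max[nonsing]),
    mean_dnn = mean(s$dnn),
    dnn_min = min(s$dnn),
    dnn_max = max(s$dnn),
    n_gap_present = sum(s$gap[nonsing]),
    n_deep = sum(deep),
    n_deep_split = sum(deep & split_sp),
    n_split_species = sum(split_sp),
    mean_bins_per_split = if (any(split_sp))
      mean(s$n_bins[split_sp]) else NA_real_,
    n_distinct_bins = length(unique(all_bins)))
}

#' Export a species summary as TSV
#'
#' @param summaries A `species_summary` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_species_summary <- function(summaries, path) {
  out <- summaries
  for (col in c("i_mean", "i_max", "dnn")) out[[col]] <- round(out[[col]], 2)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "N/A")
  invisible(path)
}
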