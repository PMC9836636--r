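#' Categorise cluster-taxon discordance
#'
#' Classifies every cluster of a partition against the named taxa of its
#' members using the four classic association patterns between Linnaean
#' species and barcode clusters:
#' \describe{
#'   \item{MATCH}{the cluster holds exactly one taxon, and that taxon occurs
#'     nowhere else;}
#'   \item{SPLIT}{the cluster holds one taxon that is spread over two or more
#'     clusters, each of them pure;}
#'   \item{MERGE}{the cluster holds two or more taxa, each wholly inside it;}
#'   \item{MIXTURE}{any configuration showing both phenomena (several taxa,
#'     at least one of them also occurring elsewhere).}
#' }
#'
#' @param partition A `motu_partition`.
#' @param taxonomy Named character vector mapping every specimen id to its
#'   species (or genus-level putative taxon) label.
#' @return A `discordance_report` data frame with one row per cluster:
#'   `cluster`, `category`, `n_taxa`, `n_specimens`, `taxa` (labels with
#'   member counts).
#' @export
discordance_categories <- function(partition, taxonomy) {
  stopifnot(inherits(partition, "motu_partition"))
  ids <- names(partition$assignment)
  missing <- setdiff(ids, names(taxonomy))
  if (length(missing) > 0L) {
    stop("taxonomy labels missing for: ", paste(missing, collapse = ", "))
  }
  taxon <- taxonomy[ids]
  cluster <- partition$assignment
  clusters_of_taxon <- tapply(cluster, taxon, function(x) length(unique(x)))
  rows <- lapply(split(seq_along(ids), cluster), function(sel) {
    taxa <- taxon[sel]
    tab <- table(taxa)
    pure_split <- vapply(names(tab), function(tx) {
      # every cluster holding tx is single-taxon
      cl_tx <- unique(cluster[taxon == tx])
      all(vapply(cl_tx, function(cl)
        length(unique(taxon[cluster == cl])) == 1L, logical(1)))
    }, logical(1))
    n_taxa <- length(tab)
    any_split <- any(clusters_of_taxon[names(tab)] > 1L)
    category <- if (n_taxa == 1L && !any_split) "MATCH"
      else if (n_taxa == 1L && all(pure_split)) "SPLIT"
      else if (n_taxa >= 2L && !any_split) "MERGE"
      else "MIXTURE"
    data.frame(cluster = cluster[sel[1L]],
               category = category,
               n_taxa = n_taxa,
               n_specimens = length(sel),
               taxa = paste0(names(tab), " (", as.integer(tab), ")",
                             collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("discordance_report", class(out))
  out
}

#' Report records whose conspecifics all cluster elsewhere
#'
#' The downstream operationalisation of the "contamination flag": a record is
#' suspicious when its species has other members in the library but none of
#' them shares its cluster. This is the only handle on NUMT pseudogenes that
#' lack stop codons (they sail through sequence-level QC) and on
#' sample-confusion contaminants.
#'
#' @inheritParams discordance_categories
#' @return Data frame `specimen_id`, `taxon`, `cluster`, `conspecific_clusters`
#'   for every flagged record (zero rows when none).
#' @export
cluster_position_report <- function(partition, taxonomy) {
  stopifnot(inherits(partition, "motu_partition"))
  ids <- names(partition$assignment)
  taxon <- taxonomy[ids]
  cluster <- partition$assignment
  flagged <- lapply(seq_along(ids), function(k) {
    mates <- which(taxon == taxon[k])
    mates <- mates[mates != k]
    if (length(mates) == 0L) return(NULL)
    if (any(cluster[mates] == cluster[k])) return(NULL)
    data.frame(specimen_id = ids[k],
               taxon = unname(taxon[k]),
               cluster = unname(cluster[k]),
               conspecific_clusters = paste(sort(unique(cluster[mates])),
                                            collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, flagged)
  if (is.null(out)) {
    out <- data.frame(specimen_id = character(0), taxon = character(0),
                      cluster = character(0),
                      conspecific_clusters = character(0))
  }
  out
}
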