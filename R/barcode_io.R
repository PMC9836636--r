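#' @keywords internal
IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")
GAP_CHAR <- "-"

#' Read an aligned barcode library from FASTA plus metadata TSV
#'
#' Reads a fixed-length alignment of COI-5P barcodes and a specimen metadata
#' table, and checks that the two agree record for record. The metadata TSV
#' must carry the header `specimen_id family genus species bin_id`; `species`
#' holds the epithet only and may be blank for specimens identified to genus
#' level, and `bin_id` (an externally assigned barcode-cluster identifier) may
#' be blank throughout.
#'
#' @param fasta_path Path to the aligned FASTA file (gap character `-`,
#'   case-insensitive IUPAC nucleotide codes).
#' @param metadata_path Path to the tab-separated metadata table.
#' @return A `barcode_library` object: a list with `records` (data frame of
#'   `specimen_id`, `family`, `genus`, `species` — the binomial, or `NA` for
#'   genus-level identifications — and `bin_id`), `sequences` (named uppercase
#'   character vector, input order preserved), `alignment_length`, and `qc`
#'   (`NULL` until [qc_screen()] is run).
#' @seealso [qc_screen()], [detect_reading_frame()], [write_qc_report()]
#' @export
read_library <- function(fasta_path, metadata_path) {
  seqs_bin <- ape::read.FASTA(fasta_path)
  seqs <- toupper(vapply(as.character(seqs_bin), paste, "", collapse = ""))
  meta <- read.delim(metadata_path, colClasses = "character",
                     na.strings = c("", "NA"))
  required <- c("specimen_id", "family", "genus", "species", "bin_id")
  if (!all(required %in% names(meta))) {
    stop("metadata is missing column(s): ",
         paste(setdiff(required, names(meta)), collapse = ", "))
  }
  build_library(seqs, meta[required])
}

#' Assemble a barcode library from in-memory sequences and metadata
#'
#' @param sequences Named character vector of aligned sequences.
#' @param metadata Data frame with columns `specimen_id`, `family`, `genus`,
#'   `species` (epithet or `NA`), `bin_id`.
#' @return A `barcode_library` object (see [read_library()]).
#' @export
build_library <- function(sequences, metadata) {
  ids <- names(sequences)
  if (is.null(ids)) stop("sequences must be named by specimen id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate specimen id(s) in FASTA: ", paste(dup, collapse = ", "))
  }
  dupm <- unique(metadata$specimen_id[duplicated(metadata$specimen_id)])
  if (length(dupm) > 0L) {
    stop("duplicate specimen id(s) in metadata: ", paste(dupm, collapse = ", "))
  }
  only_fa <- setdiff(ids, metadata$specimen_id)
  only_md <- setdiff(metadata$specimen_id, ids)
  if (length(only_fa) > 0L || length(only_md) > 0L) {
    stop("specimen ids do not match one-to-one; ",
         if (length(only_fa)) paste0("FASTA only: ",
                                     paste(only_fa, collapse = ", "), "; ") else "",
         if (length(only_md)) paste0("metadata only: ",
                                     paste(only_md, collapse = ", ")) else "")
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    off <- ids[lens != lens[1L]]
    stop("ragged alignment: record(s) ", paste(off, collapse = ", "),
         " differ in length from ", ids[1L], " (", lens[1L], " bp)")
  }
  bad <- vapply(strsplit(sequences, ""), function(ch) {
    any(!ch %in% c(IUPAC_CODES, GAP_CHAR))
  }, logical(1))
  if (any(bad)) {
    stop("non-IUPAC character(s) in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  meta <- metadata[match(ids, metadata$specimen_id), , drop = FALSE]
  rownames(meta) <- NULL
  species <- ifelse(is.na(meta$species), NA_character_,
                    paste(meta$genus, meta$species))
  records <- data.frame(specimen_id = meta$specimen_id,
                        family = meta$family,
                        genus = meta$genus,
                        species = species,
                        bin_id = meta$bin_id,
                        stringsAsFactors = FALSE)
  structure(list(records = records,
                 sequences = sequences,
                 alignment_length = unname(lens[1L]),
                 qc = NULL),
            class = "barcode_library")
}

#' @export
print.barcode_library <- function(x, ...) {
  cat("barcode_library:", nrow(x$records), "records,",
      x$alignment_length, "aligned sites\n")
  n_sp <- sum(!is.na(x$records$species))
  cat("  species-level:", n_sp, " genus-level:",
      nrow(x$records) - n_sp, "\n")
  if (!is.null(x$qc)) {
    cat("  QC: ", sum(x$qc$passes), "/", nrow(x$qc), " passing\n", sep = "")
  }
  invisible(x)
}

# Codon matrix in alignment coordinates for a frame offset: rows are codons,
# entries are the three column indices. Trailing partial codons are dropped.
codon_columns <- function(alignment_length, frame) {
  start <- frame + 1L
  n_codons <- (alignment_length - frame) %/% 3L
  if (n_codons < 1L) return(matrix(integer(0), ncol = 3L))
  matrix(start - 1L + seq_len(3L * n_codons), ncol = 3L, byrow = TRUE)
}

# Count in-frame stop codons (TAA/TAG, invertebrate mitochondrial code) for
# one record. Codons containing a gap or any ambiguity code never count.
count_stops <- function(chars, codons) {
  if (nrow(codons) == 0L) return(0L)
  c1 <- chars[codons[, 1L]]
  c2 <- chars[codons[, 2L]]
  c3 <- chars[codons[, 3L]]
  sum(c1 == "T" & c2 == "A" & (c3 == "A" | c3 == "G"))
}

#' Detect the library-wide reading frame
#'
#' Returns the frame offset (0, 1 or 2 alignment columns) minimising the total
#' number of in-frame stop codons over all records under the invertebrate
#' mitochondrial code, where only TAA and TAG terminate translation (AGA/AGG
#' encode serine). Codons are read on alignment coordinates, so records with
#' leading gaps stay in register; codons containing a gap or ambiguity code are
#' never counted as stops. Ties break to the smallest offset.
#'
#' @param library A `barcode_library`.
#' @return Integer frame offset in `0:2`, with attribute `stop_counts` giving
#'   the library-wide stop-codon total for each candidate offset.
#' @export
detect_reading_frame <- function(library) {
  stopifnot(inherits(library, "barcode_library"))
  if (nrow(library$records) == 0L) stop("library is empty")
  char_list <- strsplit(library$sequences, "")
  totals <- vapply(0:2, function(f) {
    codons <- codon_columns(library$alignment_length, f)
    sum(vapply(char_list, count_stops, integer(1), codons = codons))
  }, integer(1))
  frame <- which.min(totals) - 1L
  attr(frame, "stop_counts") <- setNames(totals, paste0("frame", 0:2))
  frame
}

#' Apply barcode quality criteria and populate QC flags
#'
#' Screens every record against the standard barcode-library quality criteria:
#' more than 500 bp of sequence (counted on non-gap characters), less than 1%
#' N among non-gap characters, and no in-frame stop codon (TAA/TAG under the
#' invertebrate mitochondrial code, read at the supplied frame offset on
#' alignment coordinates). Stop codons are the classic signature of NUMT
#' pseudogene co-amplification; NUMTs without stops pass this screen and can
#' only be caught downstream from their cluster position
#' (see [cluster_position_report()]).
#'
#' @param library A `barcode_library`.
#' @param frame Frame offset in `0:2`, typically from [detect_reading_frame()].
#' @param min_length Minimum ungapped length; passing requires strictly more
#'   than this many non-gap characters (default 500).
#' @param max_n_frac Maximum tolerated N fraction, exclusive (default 0.01).
#' @return The library with a `qc` data frame (`specimen_id`,
#'   `ungapped_length`, `n_fraction`, `stop_codon`, `frame_used`, `passes`) in
#'   input order, and attribute `failing` listing ids that fail.
#' @export
qc_screen <- function(library, frame, min_length = 500L, max_n_frac = 0.01) {
  stopifnot(inherits(library, "barcode_library"))
  frame <- as.integer(frame)
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  char_list <- strsplit(library$sequences, "")
  codons <- codon_columns(library$alignment_length, frame)
  ungapped <- vapply(char_list, function(ch) sum(ch != GAP_CHAR), integer(1))
  n_count <- vapply(char_list, function(ch) sum(ch == "N"), integer(1))
  n_fraction <- ifelse(ungapped > 0L, n_count / ungapped, 0)
  stops <- vapply(char_list, count_stops, integer(1), codons = codons)
  qc <- data.frame(specimen_id = library$records$specimen_id,
                   ungapped_length = unname(ungapped),
                   n_fraction = unname(n_fraction),
                   stop_codon = unname(stops > 0L),
                   frame_used = frame,
                   passes = unname(ungapped > min_length &
                                     n_fraction < max_n_frac & stops == 0L),
                   stringsAsFactors = FALSE)
  library$qc <- qc
  attr(library, "failing") <- qc$specimen_id[!qc$passes]
  library
}

#' Drop records that failed quality control
#'
#' @param library A `barcode_library` on which [qc_screen()] has been run.
#' @return The library restricted to passing records (order preserved).
#' @export
filter_passing <- function(library) {
  stopifnot(inherits(library, "barcode_library"))
  if (is.null(library$qc)) stop("run qc_screen() before filter_passing()")
  keep <- library$qc$passes
  library$records <- library$records[keep, , drop = FALSE]
  rownames(library$records) <- NULL
  library$sequences <- library$sequences[keep]
  library$qc <- library$qc[keep, , drop = FALSE]
  rownames(library$qc) <- NULL
  library
}

#' Write the per-record QC report as TSV
#'
#' @param library A screened `barcode_library`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(library, path) {
  if (is.null(library$qc)) stop("run qc_screen() first")
  write.table(library$qc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse a library to unique haplotypes
#'
#' Model-based delimitation is routinely run on unique haplotypes to avoid
#' zero-length branches dominating the fit. Records with byte-identical
#' aligned sequences collapse to their first representative; the mapping back
#' to all specimens is kept so partitions can be re-expanded.
#'
#' @param library A `barcode_library`.
#' @return The collapsed library, with attribute `haplotype_map`, a named
#'   character vector mapping every original specimen id to the id of its
#'   representative haplotype.
#' @export
collapse_haplotypes <- function(library) {
  stopifnot(inherits(library, "barcode_library"))
  first <- !duplicated(library$sequences)
  reps <- library$records$specimen_id[first]
  key <- library$sequences[first]
  map <- setNames(reps[match(library$sequences, key)],
                  library$records$specimen_id)
  out <- library
  out$records <- library$records[first, , drop = FALSE]
  rownames(out$records) <- NULL
  out$sequences <- library$sequences[first]
  if (!is.null(library$qc)) {
    out$qc <- library$qc[first, , drop = FALSE]
    rownames(out$qc) <- NULL
  }
  attr(out, "haplotype_map") <- map
  out
}

#' Write a library back to FASTA and metadata TSV
#'
#' @param library A `barcode_library`.
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_library <- function(library, fasta_path, metadata_path) {
  stopifnot(inherits(library, "barcode_library"))
  bin <- ape::as.DNAbin(strsplit(tolower(library$sequences), ""))
  names(bin) <- library$records$specimen_id
  ape::write.FASTA(bin, fasta_path)
  meta <- library$records
  meta$species <- ifelse(is.na(meta$species), "",
                         sub("^\\S+ ", "", meta$species))
  meta$bin_id[is.na(meta$bin_id)] <- ""
  write.table(meta, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta_path, metadata_path))
}
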