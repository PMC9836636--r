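#' Pipeline configuration
#'
#' @param input_fasta,input_metadata Input paths (see [read_library()]).
#' @param out_dir Output directory (created if absent).
#' @param qc_min_length,qc_max_n_frac QC thresholds (defaults 500 bp, 1% N).
#' @param frame Reading-frame override in `0:2`, or `NULL` to detect.
#' @param cutoffs_bp Threshold sweep in base pairs (default 1:40).
#' @param jmotu_cutoff_bp The sweep cutoff reported as the main threshold
#'   partition (default 20 bp, i.e. about 3% on a 658-bp barcode).
#' @param resl_seed Stage-1 refined single-linkage threshold, % (default 2.2).
#' @param collapse_haplotypes Collapse to unique haplotypes before the
#'   tree-based methods (default `TRUE`).
#' @param skip Character vector of stages to skip (among `"delimit"`,
#'   `"gap"`, `"concord"`).
#' @param seed Integer seed.
#' @param verbose Log to stderr as well as to `run.log`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_fasta, input_metadata, out_dir,
                            qc_min_length = 500L, qc_max_n_frac = 0.01,
                            frame = NULL, cutoffs_bp = 1:40,
                            jmotu_cutoff_bp = 20L, resl_seed = 2.2,
                            collapse_haplotypes = TRUE,
                            skip = character(0), seed = 1L,
                            verbose = TRUE) {
  if (qc_min_length <= 0 || qc_max_n_frac <= 0) {
    stop("QC thresholds must be positive")
  }
  structure(list(input_fasta = input_fasta,
                 input_metadata = input_metadata,
                 out_dir = out_dir,
                 qc_min_length = as.integer(qc_min_length),
                 qc_max_n_frac = qc_max_n_frac,
                 frame = if (is.null(frame)) NULL else as.integer(frame),
                 cutoffs_bp = as.integer(cutoffs_bp),
                 jmotu_cutoff_bp = as.integer(jmotu_cutoff_bp),
                 resl_seed = resl_seed,
                 collapse_haplotypes = isTRUE(collapse_haplotypes),
                 skip = skip,
                 seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Run the full barcode-library analysis pipeline
#'
#' Executes QC, distances, trees, delimitation, gap analysis and concordance
#' in order, writing every report to the output directory: `qc_report.tsv`,
#' `distances.tsv`, `distances.phy`, `nj.nwk`, `upgma.nwk`,
#' `partitions.tsv`, `species_summary.tsv`, `rank_summary.tsv`,
#' `concordance.tsv`, `discordance.tsv`, `run.log` and `run_config.json`.
#' A failing stage is recorded and the stages depending on it are skipped
#' with a clear status.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `status` (named character vector per
#'   stage), `outputs` (paths written) and the computed objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    writeLines(line, log_con)
    if (config$verbose) message(line)
  }
  set.seed(config$seed)
  logmsg("seed: ", config$seed)
  status <- c(qc = "pending", dist = "pending", tree = "pending",
              delimit = "pending", gap = "pending", concord = "pending")
  outputs <- character(0)
  obj <- list()
  out <- function(name) file.path(config$out_dir, name)

  run_stage <- function(name, deps, fun) {
    if (name %in% config$skip) {
      status[name] <<- "skipped"
      logmsg("stage ", name, ": skipped (requested)")
      return(invisible(NULL))
    }
    if (any(status[deps] != "ok")) {
      status[name] <<- "skipped"
      logmsg("stage ", name, ": skipped (upstream failure: ",
             paste(deps[status[deps] != "ok"], collapse = ","), ")")
      return(invisible(NULL))
    }
    res <- tryCatch({
      fun()
      status[name] <<- "ok"
      logmsg("stage ", name, ": ok")
    }, error = function(e) {
      status[name] <<- paste0("failed: ", conditionMessage(e))
      logmsg("stage ", name, " FAILED: ", conditionMessage(e))
    })
    invisible(res)
  }

  run_stage("qc", character(0), function() {
    lib <- read_library(config$input_fasta, config$input_metadata)
    frame <- if (is.null(config$frame)) detect_reading_frame(lib)
             else config$frame
    logmsg("frame offset: ", frame)
    lib <- qc_screen(lib, frame, min_length = config$qc_min_length,
                     max_n_frac = config$qc_max_n_frac)
    write_qc_report(lib, out("qc_report.tsv"))
    outputs <<- c(outputs, out("qc_report.tsv"))
    logmsg(sum(lib$qc$passes), "/", nrow(lib$qc), " records pass QC")
    obj$library <<- lib
    obj$passing <<- filter_passing(lib)
  })

  run_stage("dist", "qc", function() {
    dm <- build_matrix(obj$passing)
    write_distances_tsv(dm, out("distances.tsv"))
    write_phylip(dm, out("distances.phy"))
    outputs <<- c(outputs, out("distances.tsv"), out("distances.phy"))
    obj$dm <<- dm
    tax <- obj$passing$records
    obj$rank_summary <<- tryCatch(rank_summary(dm, tax),
                                  error = function(e) NULL)
    if (!is.null(obj$rank_summary)) {
      write.table(obj$rank_summary, out("rank_summary.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      outputs <<- c(outputs, out("rank_summary.tsv"))
    }
  })

  run_stage("tree", "dist", function() {
    obj$nj <<- nj_tree(obj$dm)
    obj$nj_rooted <<- phangorn::midpoint(obj$nj)
    obj$upgma <<- upgma_tree(obj$dm)
    newick_write(obj$nj, out("nj.nwk"))
    newick_write(obj$upgma, out("upgma.nwk"))
    outputs <<- c(outputs, out("nj.nwk"), out("upgma.nwk"))
  })

  run_stage("delimit", c("dist", "tree"), function() {
    parts <- list()
    parts$threshold <- threshold_partition(
      obj$dm, 100 * config$jmotu_cutoff_bp / obj$passing$alignment_length)
    parts$threshold$method <- "threshold"
    parts$resl <- resl_bins(obj$dm, config$resl_seed)
    if (config$collapse_haplotypes) {
      hap <- collapse_haplotypes(obj$passing)
      map <- attr(hap, "haplotype_map")
      if (nrow(hap$records) >= 3L) {
        hdm <- build_matrix(hap)
        parts$gmyc <- expand_partition(gmyc_single(upgma_tree(hdm))$partition,
                                       map)
        parts$ptp <- expand_partition(ptp_ml(nj_tree(hdm))$partition, map)
      }
    } else {
      parts$gmyc <- gmyc_single(obj$upgma)$partition
      parts$ptp <- ptp_ml(obj$nj)$partition
    }
    obj$partitions <<- parts
    write_partitions_tsv(parts, out("partitions.tsv"))
    outputs <<- c(outputs, out("partitions.tsv"))
    taxon <- setNames(
      ifelse(is.na(obj$passing$records$species),
             paste0(obj$passing$records$genus, " sp."),
             obj$passing$records$species),
      obj$passing$records$specimen_id)
    disc <- discordance_categories(parts$resl, taxon)
    write.table(disc, out("discordance.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    outputs <<- c(outputs, out("discordance.tsv"))
    logmsg("MOTU counts: ",
           paste(names(parts), vapply(parts, n_motus, 0L),
                 sep = "=", collapse = ", "))
  })

  run_stage("gap", "dist", function() {
    tax <- obj$passing$records
    bins <- setNames(tax$bin_id, tax$specimen_id)
    if (all(is.na(bins)) && !is.null(obj$partitions$resl)) {
      bins <- obj$partitions$resl$assignment
    }
    obj$species_summary <<- species_summaries(obj$dm, tax, bins = bins)
    write_species_summary(obj$species_summary, out("species_summary.tsv"))
    outputs <<- c(outputs, out("species_summary.tsv"))
    obj$library_stats <<- library_stats(obj$species_summary)
  })

  run_stage("concord", c("delimit", "tree"), function() {
    obj$concordance <<- concordance_table(obj$partitions, obj$nj_rooted)
    write_concordance_tsv(obj$concordance, out("concordance.tsv"))
    outputs <<- c(outputs, out("concordance.tsv"))
  })

  cfg_out <- config
  cfg_out$skip <- as.list(config$skip)
  jsonlite::write_json(unclass(cfg_out), out("run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  outputs <- c(outputs, out("run_config.json"), log_path)
  for (s in names(status)) logmsg("final status ", s, ": ", status[s])
  invisible(list(status = status, outputs = outputs, objects = obj))
}
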