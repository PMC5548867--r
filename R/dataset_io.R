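# Materialise synthetic datasets as standard files, read them back, and run
# the whole pipeline end to end against the recorded ground truth.

#' Write a synthetic dataset to standard file formats
#'
#' Emits `genome.fa` (+ `.fai` index), `annotation.gtf`,
#' `<TYPE>.MATS.JC.txt` / `<TYPE>.MATS.JCEC.txt` rMATS-style tables,
#' `dexseq_results.tsv`, `coverage.tsv`, `ground_truth.json` and
#' `config.yaml`. Output is byte-identical for identical configurations.
#'
#' @param ds A `synthetic_dataset` from [generate_dataset()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_dataset <- function(ds, outdir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(outdir, "genome.fa")
  Biostrings::writeXStringSet(ds$genome, fa, width = 60L)
  write_fai(ds$genome, paste0(fa, ".fai"))
  write_gtf(ds$instances, file.path(outdir, "annotation.gtf"))
  for (ty in names(ds$rmats)) {
    for (v in c("jc", "jcec")) {
      f <- file.path(outdir, sprintf("%s.MATS.%s.txt", ty, toupper(v)))
      write.table(ds$rmats[[ty]][[v]], f, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
  }
  write.table(ds$dexseq, file.path(outdir, "dexseq_results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ds$coverage, file.path(outdir, "coverage.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ds$truth, file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  yaml::write_yaml(unclass(ds$config), file.path(outdir, "config.yaml"))
  invisible(outdir)
}

# samtools-style FASTA index for a width-60 FASTA written by writeXStringSet
write_fai <- function(genome, path) {
  lens <- IRanges::width(genome)
  nms <- names(genome)
  offset <- 0
  rows <- character(length(genome))
  for (i in seq_along(genome)) {
    offset <- offset + nchar(nms[i]) + 2L        # ">name\n"
    rows[i] <- paste(nms[i], lens[i], offset, 60L, 61L, sep = "\t")
    nlines <- ceiling(lens[i] / 60L)
    offset <- offset + lens[i] + nlines
  }
  writeLines(rows, path)
  invisible(path)
}

#' Normalised pipeline inputs from an in-memory synthetic dataset
#'
#' Converts the generator's dialect tables into the same normalised form the
#' file readers produce, without touching disk.
#'
#' @param ds A `synthetic_dataset`.
#' @return List with `jc`, `jcec` (normalised events across all event
#'   types), `dexseq`, `coverage`, `genome`, `catalog`, `truth` and
#'   `window_size`.
#' @export
dataset_inputs <- function(ds) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  norm <- function(variant) {
    parts <- lapply(names(ds$rmats), function(ty) {
      normalize_rmats(ds$rmats[[ty]][[variant]], ty, variant)
    })
    do.call(rbind, parts)
  }
  list(jc = norm("jc"), jcec = norm("jcec"),
       dexseq = normalize_dexseq(ds$dexseq),
       coverage = ds$coverage, genome = ds$genome, catalog = ds$catalog,
       truth = ds$truth, window_size = ds$config$window_size)
}

#' Read a written synthetic dataset back into pipeline inputs
#'
#' @param dir Directory produced by [write_dataset()].
#' @return As [dataset_inputs()].
#' @export
read_dataset <- function(dir) {
  fa <- file.path(dir, "genome.fa")
  genome <- Biostrings::readDNAStringSet(fa)
  names(genome) <- sub("\\s.*$", "", names(genome))
  catalog <- parse_gtf(file.path(dir, "annotation.gtf"))
  files <- list.files(dir, pattern = "^(SE|A5SS|A3SS|RI)\\.MATS\\.(JC|JCEC)\\.txt$")
  read_variant <- function(variant) {
    sel <- files[grepl(paste0("\\.MATS\\.", toupper(variant), "\\.txt$"),
                       files)]
    if (length(sel) == 0L) return(rmats_skeleton())
    parts <- lapply(sel, function(f) {
      ty <- sub("\\..*$", "", f)
      read_rmats(file.path(dir, f), event_type = ty, variant = variant)
    })
    do.call(rbind, parts)
  }
  truth_file <- file.path(dir, "ground_truth.json")
  config_file <- file.path(dir, "config.yaml")
  cfg <- if (file.exists(config_file)) {
    read_synthetic_config(config_file)
  } else NULL
  list(jc = read_variant("jc"), jcec = read_variant("jcec"),
       dexseq = read_dexseq(file.path(dir, "dexseq_results.tsv")),
       coverage = read_coverage(file.path(dir, "coverage.tsv")),
       genome = genome, catalog = catalog,
       truth = if (file.exists(truth_file)) {
         jsonlite::fromJSON(truth_file, simplifyDataFrame = TRUE)
       } else NULL,
       window_size = if (!is.null(cfg)) cfg$window_size else 200L)
}

#' Run the full pipeline on a synthetic dataset and check against truth
#'
#' Executes integrate (merge, stringent intersection, comprehensive union),
#' classify, scan and enrich on the dataset, then compares the results to
#' the recorded ground truth: recovery of planted both-tool-significant
#' events in the stringent set, and exact recovery of the planted QREs in
#' the region scan.
#'
#' @param x A `synthetic_dataset`, a directory written by [write_dataset()],
#'   or a list of inputs from [dataset_inputs()].
#' @param n_iter Enrichment iterations (default 1000).
#' @param seed Master seed for the enrichment resampling.
#' @return Object of class `end_to_end_report`.
#' @export
end_to_end_check <- function(x, n_iter = 1000L, seed = 1L) {
  inp <- if (inherits(x, "synthetic_dataset")) {
    dataset_inputs(x)
  } else if (is.character(x)) {
    read_dataset(x)
  } else x

  merged <- merge_rmats_variants(inp$jc, inp$jcec)
  stringent <- annotate_events(build_stringent(merged, inp$dexseq),
                               inp$catalog)
  comprehensive <- build_comprehensive(merged, inp$dexseq, inp$catalog)
  controls <- build_control_set(inp$catalog, inp$coverage, inp$dexseq,
                                merged)
  ws <- inp$window_size %||% 200L
  results <- run_subsets(stringent, comprehensive, controls, inp$genome,
                         n_iter = n_iter, seed = seed, window_size = ws)

  truth <- inp$truth
  planted <- truth$events
  if (!is.null(planted) && NROW(planted)) {
    planted <- planted[planted$both_significant, , drop = FALSE]
  }
  str_ev <- stringent$events
  str_keys <- paste(str_ev$chrom, str_ev$strand, str_ev$exon_start,
                    str_ev$exon_end)[str_ev$event_type == "SE"]
  recovery <- if (is.null(planted) || NROW(planted) == 0L) NA_real_ else {
    mean(paste(planted$chrom, planted$strand, planted$exon_start,
               planted$exon_end) %in% str_keys)
  }

  qre <- NULL
  if (!is.null(truth$qre) && !is.null(truth$qre$region)) {
    reg <- truth$qre$region
    hits <- scan_region_qre(inp$genome, reg$chrom, reg$start, reg$end,
                            reg$strand, max_mismatch = 1L)
    want <- truth$qre$hits
    want <- want[order(want$offset, want$spacer_len), , drop = FALSE]
    got <- hits[order(hits$offset, hits$spacer_len), , drop = FALSE]
    exact <- nrow(want) == nrow(got) &&
      all(want$offset == got$offset) &&
      all(want$spacer_len == got$spacer_len) &&
      all(want$mismatches == got$mismatches)
    qre <- list(n_planted = nrow(want), n_found = nrow(got),
                exact = exact)
  }

  uni <- str_ev[str_ev$in_motif_universe, , drop = FALSE]
  flags <- if (nrow(uni)) {
    event_has_core(flanking_windows(uni, inp$genome, ws))
  } else NULL
  pos <- if (!is.null(flags)) positional_summary(uni, flags) else NULL

  structure(list(
    n_merged = nrow(merged),
    n_stringent = nrow(str_ev),
    n_comprehensive = nrow(comprehensive$events),
    n_event_genes = count_event_genes(stringent),
    n_planted_both = if (is.null(planted)) 0L else NROW(planted),
    stringent_recovery = recovery,
    n_controls = nrow(controls$exons),
    filter_log = controls$filter_log,
    enrichment = enrichment_summary(results),
    results = results,
    positional = pos,
    qre = qre
  ), class = "end_to_end_report")
}

#' @export
print.end_to_end_report <- function(x, ...) {
  cat("end-to-end report\n")
  cat("  merged rMATS events:  ", x$n_merged, "\n")
  cat("  stringent events:     ", x$n_stringent, "\n")
  cat("  comprehensive events: ", x$n_comprehensive, "\n")
  cat("  event genes:          ", x$n_event_genes, "\n")
  cat(sprintf("  planted recovery:      %s (of %d planted)\n",
              ifelse(is.na(x$stringent_recovery), "NA",
                     sprintf("%.1f%%", 100 * x$stringent_recovery)),
              x$n_planted_both))
  cat("  control exons:        ", x$n_controls, "\n")
  if (!is.null(x$qre)) {
    cat(sprintf("  QRE region: %d planted, %d found, exact = %s\n",
                x$qre$n_planted, x$qre$n_found, x$qre$exact))
  }
  cat("  enrichment:\n")
  print(x$enrichment, row.names = FALSE)
  invisible(x)
}
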