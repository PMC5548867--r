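# Readers for rMATS-style and DEXSeq-style result tables.

rmats_coord_map <- list(
  SE = c(exon_start = "exonStart_0base", exon_end = "exonEnd",
         upstream_start = "upstreamES", upstream_end = "upstreamEE",
         downstream_start = "downstreamES", downstream_end = "downstreamEE"),
  A5SS = c(exon_start = "longExonStart_0base", exon_end = "longExonEnd",
           downstream_start = "flankingES", downstream_end = "flankingEE"),
  A3SS = c(exon_start = "longExonStart_0base", exon_end = "longExonEnd",
           upstream_start = "flankingES", upstream_end = "flankingEE"),
  RI = c(exon_start = "riExonStart_0base", exon_end = "riExonEnd",
         upstream_start = "upstreamES", upstream_end = "upstreamEE",
         downstream_start = "downstreamES", downstream_end = "downstreamEE")
)

#' Read an rMATS-style result table
#'
#' Parses the v3.x column dialect of one event type. Target-exon starts are
#' 0-based in the files and kept as-is (the internal convention is 0-based
#' half-open). `upstream`/`downstream` flanking exons are transcript-oriented,
#' as in the source tables. Rows with a non-numeric p-value are rejected with
#' a warning.
#'
#' @param path TSV file with rMATS headers (`GeneID, chr, strand, ...,
#'   PValue, FDR, IncLevelDifference` plus the per-type coordinate columns).
#' @param event_type One of `"SE"`, `"A5SS"`, `"A3SS"`, `"RI"`.
#' @param variant Quantification variant: `"jc"` (junction counts only) or
#'   `"jcec"` (junction counts + reads on target).
#' @return data.frame of normalised splice events (one per row).
#' @export
read_rmats <- function(path, event_type = c("SE", "A5SS", "A3SS", "RI"),
                       variant = c("jc", "jcec")) {
  event_type <- match.arg(event_type)
  variant <- match.arg(variant)
  if (!file.exists(path)) stop("rMATS table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  normalize_rmats(df, event_type, variant, path)
}

# shared between read_rmats() and the in-memory synthetic-data path
normalize_rmats <- function(df, event_type, variant, path = "<memory>") {
  cmap <- rmats_coord_map[[event_type]]
  need <- c("GeneID", "chr", "strand", unname(cmap),
            "PValue", "FDR", "IncLevelDifference")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("rMATS ", event_type, " table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(df)
  out <- data.frame(
    event_type = rep(event_type, n),
    gene_id = as.character(df$GeneID),
    chrom = as.character(df$chr),
    strand = as.character(df$strand),
    exon_start = rep(NA_integer_, n), exon_end = rep(NA_integer_, n),
    upstream_start = rep(NA_integer_, n), upstream_end = rep(NA_integer_, n),
    downstream_start = rep(NA_integer_, n),
    downstream_end = rep(NA_integer_, n),
    stringsAsFactors = FALSE
  )
  for (field in names(cmap)) {
    out[[field]] <- as.integer(df[[cmap[[field]]]])
  }
  pv <- suppressWarnings(as.numeric(df$PValue))
  fdr <- suppressWarnings(as.numeric(df$FDR))
  inc <- suppressWarnings(as.numeric(df$IncLevelDifference))
  bad <- is.na(pv) | is.na(fdr)
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-numeric PValue/FDR rejected in ", path)
  }
  out$pvalue <- pv
  out$fdr <- fdr
  out$inc_level_diff <- inc
  out$variant <- rep(variant, n)
  out <- out[!bad, , drop = FALSE]
  if (nrow(out) && any(out$pvalue < 0 | out$pvalue > 1 |
                       out$fdr < 0 | out$fdr > 1)) {
    stop("p-values outside [0,1] in ", path)
  }
  rownames(out) <- NULL
  out
}

rmats_skeleton <- function() {
  data.frame(event_type = character(0), gene_id = character(0),
             chrom = character(0), strand = character(0),
             exon_start = integer(0), exon_end = integer(0),
             upstream_start = integer(0), upstream_end = integer(0),
             downstream_start = integer(0), downstream_end = integer(0),
             pvalue = numeric(0), fdr = numeric(0),
             inc_level_diff = numeric(0), variant = character(0),
             stringsAsFactors = FALSE)
}

rmats_event_key <- function(ev) {
  paste(ev$event_type, ev$chrom, ev$strand, ev$exon_start, ev$exon_end,
        ev$upstream_start, ev$upstream_end,
        ev$downstream_start, ev$downstream_end, sep = ":")
}

#' Read a DEXSeq-style exon-bin result table
#'
#' Accepts either the plain dialect written by this package
#' (`gene_id, bin_id, chrom, start, end, strand, pvalue, padj`) or
#' DEXSeq-results column names (`groupID, featureID, genomicData.*, padj`).
#' Input coordinates are 1-based inclusive and converted to 0-based
#' half-open. Bins shorter than `min_length` nt are flagged ineligible.
#'
#' @param path TSV file of exon-bin results.
#' @param min_length Minimum bin length in nt for eligibility (default 15).
#' @return data.frame with columns `gene_id, bin_id, chrom, start, end,
#'   strand, pvalue, padj, length, eligible`.
#' @export
read_dexseq <- function(path, min_length = 15L) {
  if (!file.exists(path)) stop("DEXSeq table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  normalize_dexseq(df, min_length, path)
}

normalize_dexseq <- function(df, min_length = 15L, path = "<memory>") {
  cols <- list(
    gene_id = c("gene_id", "groupID"),
    bin_id = c("bin_id", "featureID"),
    chrom = c("chrom", "genomicData.seqnames", "seqnames", "chr"),
    start = c("start", "genomicData.start"),
    end = c("end", "genomicData.end"),
    strand = c("strand", "genomicData.strand"),
    padj = c("padj", "adj_pvalue", "adjp")
  )
  found <- vapply(cols, function(cand) match_column(df, cand), character(1))
  if (anyNA(found[c("gene_id", "chrom", "start", "end", "padj")])) {
    stop("DEXSeq table lacks required columns (",
         paste(names(found)[is.na(found)], collapse = ", "), ") in ", path)
  }
  n <- nrow(df)
  out <- data.frame(
    gene_id = as.character(df[[found[["gene_id"]]]]),
    bin_id = if (!is.na(found[["bin_id"]]))
      as.character(df[[found[["bin_id"]]]]) else as.character(seq_len(n)),
    chrom = as.character(df[[found[["chrom"]]]]),
    start = as.integer(df[[found[["start"]]]]) - 1L,
    end = as.integer(df[[found[["end"]]]]),
    strand = if (!is.na(found[["strand"]]))
      as.character(df[[found[["strand"]]]]) else rep("*", n),
    pvalue = if (!is.na(match_column(df, "pvalue")))
      suppressWarnings(as.numeric(df[["pvalue"]])) else rep(NA_real_, n),
    padj = suppressWarnings(as.numeric(df[[found[["padj"]]]])),
    stringsAsFactors = FALSE
  )
  out$length <- out$end - out$start
  if (nrow(out) && any(out$length < 1L)) stop("DEXSeq bin with length < 1 nt")
  out$eligible <- out$length >= min_length
  out
}

#' Read a per-exon / per-gene coverage table
#'
#' @param path TSV with columns `exon_id, gene_id, exon_cov_per_nt,
#'   gene_cov_per_nt` (coverage normalised by exon resp. gene length).
#' @return data.frame of coverage values.
#' @export
read_coverage <- function(path) {
  if (!file.exists(path)) stop("coverage table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("exon_id", "gene_id", "exon_cov_per_nt", "gene_cov_per_nt")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("coverage table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(df$exon_cov_per_nt < 0 | df$gene_cov_per_nt < 0, na.rm = TRUE)) {
    stop("negative coverage values")
  }
  df
}
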