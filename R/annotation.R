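# Exon catalog: parse GTF gene models, deduplicate exons and classify each
# exon as cassette, mixed or first/last across all isoforms of its gene.
#
# Coordinates are 0-based half-open internally; GTF I/O converts at the
# boundary. Classification is per (exon, gene): an exon shared by two
# overlapping genes is treated as two records.

#' Build an exon catalog from per-transcript exon instances
#'
#' Lower-level constructor used by [parse_gtf()] and by the synthetic data
#' generator. One input row per (transcript, exon); exons with identical
#' (chrom, start, end, strand) within a gene are merged into a single record
#' with pooled transcript membership.
#'
#' "First" and "last" are transcriptional, i.e. strand-dependent, but an exon
#' is terminal in a transcript iff it is the genomically first or last exon
#' of that transcript, which is strand-symmetric. A single-exon transcript
#' counts its exon as both first and last. Classes: `cassette` (internal in
#' every containing transcript), `first_last` (terminal in all), `mixed`
#' (internal in at least one, terminal in at least one).
#'
#' @param instances data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand` ("+"/"-"), `gene_id`, `transcript_id`.
#' @return An object of class `exon_catalog`: a list with `exons` (unique
#'   classified exons), `membership` (per-transcript positional flags) and
#'   `transcripts`.
#' @export
build_exon_catalog <- function(instances) {
  required <- c("chrom", "start", "end", "strand", "gene_id", "transcript_id")
  missing_cols <- setdiff(required, names(instances))
  if (length(missing_cols)) {
    stop("instances lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  inst <- as.data.frame(instances)[required]
  if (nrow(inst) == 0L) {
    return(empty_catalog())
  }
  inst$start <- as.integer(inst$start)
  inst$end <- as.integer(inst$end)
  if (any(inst$start >= inst$end)) stop("exon with start >= end")
  if (!all(inst$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")

  # order within transcript by genomic coordinate
  inst <- inst[order(inst$gene_id, inst$transcript_id, inst$start, inst$end), ]
  tx <- paste(inst$gene_id, inst$transcript_id, sep = "\r")
  new_tx <- c(TRUE, tx[-1L] != tx[-length(tx)])
  # non-overlap within transcript
  prev_end <- c(-1L, inst$end[-nrow(inst)])
  if (any(!new_tx & inst$start < prev_end)) {
    bad <- which(!new_tx & inst$start < prev_end)[1L]
    stop("overlapping exons within transcript ", inst$transcript_id[bad])
  }
  grp <- cumsum(new_tx)
  n_in_tx <- tabulate(grp)
  pos <- sequence(n_in_tx)
  inst$is_first_genomic <- pos == 1L
  inst$is_last_genomic <- pos == n_in_tx[grp]
  # strand consistency within transcript and exon
  strand_by_tx <- tapply(inst$strand, grp, function(x) length(unique(x)))
  if (any(strand_by_tx > 1L)) stop("mixed strands within a transcript")
  # transcription-order flags (terminality is strand-symmetric; the
  # first/last assignment itself swaps on the minus strand)
  minus <- inst$strand == "-"
  inst$is_first <- ifelse(minus, inst$is_last_genomic, inst$is_first_genomic)
  inst$is_last <- ifelse(minus, inst$is_first_genomic, inst$is_last_genomic)

  inst$exon_id <- exon_key(inst$chrom, inst$start, inst$end, inst$strand,
                           inst$gene_id)
  strand_per_exon <- tapply(inst$strand, inst$exon_id,
                            function(x) length(unique(x)))
  if (any(strand_per_exon > 1L)) stop("conflicting strand for identical exon")

  membership <- inst[, c("exon_id", "gene_id", "transcript_id",
                         "is_first", "is_last")]
  rownames(membership) <- NULL

  term <- inst$is_first | inst$is_last
  cls_tab <- data.frame(
    exon_id = inst$exon_id, internal = !term, terminal = term,
    stringsAsFactors = FALSE
  )
  any_internal <- tapply(cls_tab$internal, cls_tab$exon_id, any)
  any_terminal <- tapply(cls_tab$terminal, cls_tab$exon_id, any)

  first_rows <- inst[!duplicated(inst$exon_id), ]
  ids <- first_rows$exon_id
  class <- ifelse(any_internal[ids] & !any_terminal[ids], "cassette",
                  ifelse(!any_internal[ids], "first_last", "mixed"))
  n_tx <- tapply(membership$exon_id, membership$exon_id, length)

  exons <- data.frame(
    exon_id = ids,
    chrom = first_rows$chrom,
    start = first_rows$start,
    end = first_rows$end,
    strand = first_rows$strand,
    gene_id = first_rows$gene_id,
    length = first_rows$end - first_rows$start,
    n_tx = as.integer(n_tx[ids]),
    class = unname(class),
    stringsAsFactors = FALSE
  )
  exons <- exons[order(exons$chrom, exons$start, exons$end, exons$gene_id), ]
  rownames(exons) <- NULL

  tx_first <- inst[new_tx, c("gene_id", "transcript_id", "chrom", "strand")]
  transcripts <- data.frame(tx_first, n_exons = n_in_tx,
                            stringsAsFactors = FALSE)
  rownames(transcripts) <- NULL

  structure(list(exons = exons, membership = membership,
                 transcripts = transcripts),
            class = "exon_catalog")
}

empty_catalog <- function() {
  structure(list(
    exons = data.frame(exon_id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0), gene_id = character(0),
                       length = integer(0), n_tx = integer(0),
                       class = character(0), stringsAsFactors = FALSE),
    membership = data.frame(exon_id = character(0), gene_id = character(0),
                            transcript_id = character(0),
                            is_first = logical(0), is_last = logical(0)),
    transcripts = data.frame(gene_id = character(0),
                             transcript_id = character(0),
                             chrom = character(0), strand = character(0),
                             n_exons = integer(0))
  ), class = "exon_catalog")
}

#' @export
print.exon_catalog <- function(x, ...) {
  cat("exon_catalog:", nrow(x$exons), "unique exons,",
      nrow(x$transcripts), "transcripts,",
      length(unique(x$exons$gene_id)), "genes\n")
  if (nrow(x$exons)) print(table(x$exons$class))
  invisible(x)
}

#' Parse a GTF gene model into an exon catalog
#'
#' Reads exon features (GENCODE attribute dialect) and builds a deduplicated,
#' classified [build_exon_catalog()] catalog. GTF 1-based inclusive
#' coordinates are converted to internal 0-based half-open at this boundary.
#' Non-exon features (CDS, UTR, ...) are ignored. Exon records lacking a
#' `transcript_id` are rejected with a warning.
#'
#' @param path Path to a GTF file.
#' @return An `exon_catalog`.
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L) return(empty_catalog())
  nfield <- lengths(strsplit(body, "\t", fixed = TRUE))
  if (any(nfield < 9L)) {
    bad <- which(!grepl("^#", lines) & nzchar(trimws(lines)))[which(nfield < 9L)[1L]]
    stop("malformed GTF line ", bad, ": expected 9 tab-separated fields")
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("GTF parse error in ", path, ": ",
                             conditionMessage(e))
  )
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (length(gr) == 0L) return(empty_catalog())
  tx_id <- as.character(gr$transcript_id)
  gene_id <- as.character(gr$gene_id)
  drop <- is.na(tx_id) | !nzchar(tx_id) | is.na(gene_id) | !nzchar(gene_id)
  if (any(drop)) {
    warning(sum(drop), " exon record(s) without gene_id/transcript_id rejected")
    gr <- gr[!drop]; tx_id <- tx_id[!drop]; gene_id <- gene_id[!drop]
  }
  if (length(gr) == 0L) return(empty_catalog())
  inst <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gene_id,
    transcript_id = tx_id,
    stringsAsFactors = FALSE
  )
  # merge duplicate (transcript, exon) rows before construction
  inst <- inst[!duplicated(inst), ]
  build_exon_catalog(inst)
}

#' Classify one exon against a catalog
#'
#' @param catalog An `exon_catalog`.
#' @param exon_id Exon identifier as in `catalog$exons$exon_id`, or an exon
#'   row (list/data.frame with chrom, start, end, strand, gene_id).
#' @return One of `"cassette"`, `"mixed"`, `"first_last"`.
#' @export
classify_exon <- function(catalog, exon_id) {
  stopifnot(inherits(catalog, "exon_catalog"))
  if (!is.character(exon_id)) {
    e <- as.list(exon_id)
    exon_id <- exon_key(e$chrom, e$start, e$end, e$strand, e$gene_id)
  }
  idx <- match(exon_id, catalog$exons$exon_id)
  if (any(is.na(idx))) stop("exon not in catalog: ",
                            paste(exon_id[is.na(idx)], collapse = ", "))
  catalog$exons$class[idx]
}

#' Classification table for all catalog exons
#'
#' @param catalog An `exon_catalog`.
#' @return data.frame of unique exons with their `class`.
#' @export
classify_exons <- function(catalog) {
  stopifnot(inherits(catalog, "exon_catalog"))
  catalog$exons
}

#' Drop exons that are first or last in every isoform
#'
#' Keeps only cassette and mixed exons (order-stable); terminal-in-all exons
#' are excluded from downstream motif analyses because alternative promoter
#' or terminator usage is generally not splicing-regulated.
#'
#' @param exons data.frame of catalog exons (with `exon_id`), or an
#'   `exon_catalog` (then `catalog` may be omitted).
#' @param catalog The classified `exon_catalog`.
#' @return Filtered data.frame of exons.
#' @export
exclude_terminal <- function(exons, catalog = NULL) {
  if (inherits(exons, "exon_catalog")) {
    catalog <- exons
    exons <- catalog$exons
  }
  stopifnot(inherits(catalog, "exon_catalog"))
  cls <- classify_exon(catalog, exons$exon_id)
  exons[cls != "first_last", , drop = FALSE]
}

# For each exon, the closest flanking exon boundary across all containing
# transcripts: left_bound = max end of the preceding (genomic) exon,
# right_bound = min start of the following exon. NA where no neighbour.
catalog_flank_bounds <- function(catalog, exon_ids = NULL) {
  mem <- catalog$membership
  ex <- catalog$exons
  m <- merge(mem, ex[, c("exon_id", "chrom", "start", "end")], by = "exon_id")
  key <- paste(m$gene_id, m$transcript_id, sep = "\r")
  m <- m[order(key, m$start), ]
  key <- paste(m$gene_id, m$transcript_id, sep = "\r")
  same_prev <- c(FALSE, key[-1L] == key[-nrow(m)])
  prev_end <- c(NA_integer_, m$end[-nrow(m)])
  prev_end[!same_prev] <- NA_integer_
  same_next <- c(key[-1L] == key[-nrow(m)], FALSE)
  next_start <- c(m$start[-1L], NA_integer_)
  next_start[!same_next] <- NA_integer_
  suppressWarnings({
    left <- tapply(prev_end, m$exon_id, function(x)
      if (all(is.na(x))) NA_integer_ else max(x, na.rm = TRUE))
    right <- tapply(next_start, m$exon_id, function(x)
      if (all(is.na(x))) NA_integer_ else min(x, na.rm = TRUE))
  })
  ids <- exon_ids %||% ex$exon_id
  data.frame(exon_id = ids,
             left_bound = as.integer(left[ids]),
             right_bound = as.integer(right[ids]),
             stringsAsFactors = FALSE)
}

#' Export catalog exons as BED6
#'
#' BED name is `gene_id|class`; scores are 0. Coordinates are already
#' 0-based half-open as BED requires.
#'
#' @param catalog An `exon_catalog`.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
catalog_to_bed <- function(catalog, path) {
  ex <- catalog$exons
  bed <- data.frame(ex$chrom, ex$start, ex$end,
                    paste(ex$gene_id, ex$class, sep = "|"),
                    0L, ex$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export catalog exons as TSV
#'
#' @param catalog An `exon_catalog`.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
catalog_to_tsv <- function(catalog, path) {
  write.table(catalog$exons, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# GTF writer (GENCODE attribute dialect), used by the synthetic generator.
write_gtf <- function(instances, path) {
  if (nrow(instances) == 0L) {
    writeLines("##format: gtf", path)
    return(invisible(path))
  }
  inst <- instances[order(instances$gene_id, instances$transcript_id,
                          instances$start), ]
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   inst$gene_id, inst$transcript_id)
  lines <- paste(inst$chrom, "synthetic", "exon",
                 inst$start + 1L, inst$end, ".", inst$strand, ".",
                 attrs, sep = "\t")
  writeLines(c("##format: gtf", lines), path)
  invisible(path)
}
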