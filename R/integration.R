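# Event integration: merge rMATS quantification variants, intersect with
# DEXSeq exon bins (stringent set), union both tools (comprehensive set),
# and annotate events with exon class and inclusion direction.

new_event_set <- function(label, events) {
  stopifnot(label %in% c("stringent", "comprehensive"))
  structure(list(label = label, events = events), class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat("event_set '", x$label, "': ", nrow(x$events), " events in ",
      count_event_genes(x), " genes\n", sep = "")
  if (nrow(x$events)) print(table(x$events$event_type))
  invisible(x)
}

events_of <- function(x) {
  if (inherits(x, "event_set")) x$events else x
}

#' Merge the two rMATS quantification variants into unique events
#'
#' Events sharing the full merge key (event type, chromosome, strand and all
#' defining coordinates, flanking exons included) collapse to one record that
#' retains both variants' statistics. The headline `pvalue`/`fdr` is the
#' minimum across variants, with `headline_variant` recording which one; the
#' inclusion-level difference is taken from that variant. An event is
#' `putative` if its FDR is below `sig_fdr` in either variant.
#'
#' Direction convention: `inc_level_diff` is PSI(knockout) - PSI(control);
#' `direction` is `"higher_inclusion"` iff it is positive. Set
#' `flip_sign = TRUE` if the source tables used the opposite group order.
#'
#' @param jc,jcec Event data.frames from [read_rmats()] (any event types).
#' @param sig_fdr FDR threshold for the putative flag (default 0.05).
#' @param flip_sign Flip the sign of the inclusion-level difference.
#' @return data.frame of merged events, one row per unique event.
#' @export
merge_rmats_variants <- function(jc, jcec, sig_fdr = 0.05, flip_sign = FALSE) {
  both <- rbind(jc, jcec)
  if (nrow(both) == 0L) return(merged_skeleton())
  if (flip_sign) both$inc_level_diff <- -both$inc_level_diff
  key <- rmats_event_key(both)
  nostrand <- paste(both$event_type, both$chrom, both$exon_start,
                    both$exon_end, both$upstream_start, both$upstream_end,
                    both$downstream_start, both$downstream_end, sep = ":")
  strands <- tapply(both$strand, nostrand, function(x) length(unique(x)))
  if (any(strands > 1L)) {
    stop("conflicting strand for events with identical coordinates")
  }
  # within each variant keep the best-p row per key
  pick <- function(df) {
    if (nrow(df) == 0L) return(df)
    df <- df[order(rmats_event_key(df), df$pvalue), ]
    df[!duplicated(rmats_event_key(df)), , drop = FALSE]
  }
  jc1 <- pick(both[both$variant == "jc", , drop = FALSE])
  jcec1 <- pick(both[both$variant == "jcec", , drop = FALSE])
  keys <- unique(key)
  base_rows <- both[match(keys, key), c("event_type", "gene_id", "chrom",
                                        "strand", "exon_start", "exon_end",
                                        "upstream_start", "upstream_end",
                                        "downstream_start", "downstream_end")]
  i_jc <- match(keys, rmats_event_key(jc1))
  i_ec <- match(keys, rmats_event_key(jcec1))
  out <- base_rows
  out$pvalue_jc <- jc1$pvalue[i_jc]
  out$fdr_jc <- jc1$fdr[i_jc]
  out$inc_diff_jc <- jc1$inc_level_diff[i_jc]
  out$pvalue_jcec <- jcec1$pvalue[i_ec]
  out$fdr_jcec <- jcec1$fdr[i_ec]
  out$inc_diff_jcec <- jcec1$inc_level_diff[i_ec]
  use_jc <- !is.na(out$pvalue_jc) &
    (is.na(out$pvalue_jcec) | out$pvalue_jc <= out$pvalue_jcec)
  out$headline_variant <- ifelse(use_jc, "jc", "jcec")
  out$pvalue <- ifelse(use_jc, out$pvalue_jc, out$pvalue_jcec)
  out$fdr <- pmin(out$fdr_jc, out$fdr_jcec, na.rm = TRUE)
  out$inc_level_diff <- ifelse(use_jc, out$inc_diff_jc, out$inc_diff_jcec)
  out$direction <- ifelse(is.na(out$inc_level_diff) | out$inc_level_diff == 0,
                          NA_character_,
                          ifelse(out$inc_level_diff > 0,
                                 "higher_inclusion", "higher_exclusion"))
  out$putative <- (!is.na(out$fdr_jc) & out$fdr_jc < sig_fdr) |
    (!is.na(out$fdr_jcec) & out$fdr_jcec < sig_fdr)
  out$sources <- paste0(ifelse(!is.na(out$pvalue_jc), "rmats_jc", ""),
                        ifelse(!is.na(out$pvalue_jc) &
                                 !is.na(out$pvalue_jcec), ",", ""),
                        ifelse(!is.na(out$pvalue_jcec), "rmats_jcec", ""))
  out$event_id <- keys
  rownames(out) <- NULL
  out
}

merged_skeleton <- function() {
  data.frame(event_type = character(0), gene_id = character(0),
             chrom = character(0), strand = character(0),
             exon_start = integer(0), exon_end = integer(0),
             upstream_start = integer(0), upstream_end = integer(0),
             downstream_start = integer(0), downstream_end = integer(0),
             pvalue_jc = numeric(0), fdr_jc = numeric(0),
             inc_diff_jc = numeric(0), pvalue_jcec = numeric(0),
             fdr_jcec = numeric(0), inc_diff_jcec = numeric(0),
             headline_variant = character(0), pvalue = numeric(0),
             fdr = numeric(0), inc_level_diff = numeric(0),
             direction = character(0), putative = logical(0),
             sources = character(0), event_id = character(0),
             stringsAsFactors = FALSE)
}

# events whose target exon overlaps (>= 1 bp, same chromosome) at least one
# of the given bins; strand optionally required to match
overlaps_bins <- function(events, bins, stranded = FALSE) {
  if (nrow(events) == 0L || nrow(bins) == 0L) {
    return(logical(nrow(events)))
  }
  ev_gr <- intervals_to_granges(events$chrom, events$exon_start,
                                events$exon_end, events$strand)
  bin_gr <- intervals_to_granges(bins$chrom, bins$start, bins$end,
                                 bins$strand)
  hits <- GenomicRanges::findOverlaps(ev_gr, bin_gr,
                                      ignore.strand = !stranded)
  seq_len(nrow(events)) %in% S4Vectors::queryHits(hits)
}

# deduplicate by target-exon genomic coordinates, keeping the best
# (lowest headline p) record; rows with NA p sort last
dedup_by_coords <- function(events) {
  if (nrow(events) == 0L) return(events)
  key <- paste(events$event_type, events$chrom, events$strand,
               events$exon_start, events$exon_end, sep = ":")
  p <- events$pvalue
  p[is.na(p)] <- Inf
  ord <- order(key, p)
  events <- events[ord, , drop = FALSE]
  key <- key[ord]
  out <- events[!duplicated(key), , drop = FALSE]
  out[order(out$chrom, out$exon_start, out$exon_end, out$event_type), ,
      drop = FALSE]
}

#' Build the stringent event set (rMATS intersected with DEXSeq)
#'
#' Keeps merged rMATS events significant at `p_rmats` whose target exon
#' overlaps (>= 1 bp, same chromosome) at least one eligible DEXSeq bin
#' significant at `padj_dexseq`, keeping the rMATS information, then
#' deduplicates by target-exon genomic coordinates. Overlap ignores strand by
#' default, mirroring a default-settings BED intersect.
#'
#' @param rmats Merged events from [merge_rmats_variants()].
#' @param dexseq Bins from [read_dexseq()].
#' @param p_rmats rMATS headline p-value threshold (default 0.05).
#' @param padj_dexseq DEXSeq adjusted-p threshold (default 0.05).
#' @param stranded Require matching strand for the overlap.
#' @return An `event_set` labelled `"stringent"`.
#' @export
build_stringent <- function(rmats, dexseq, p_rmats = 0.05,
                            padj_dexseq = 0.05, stranded = FALSE) {
  ev <- events_of(rmats)
  ev <- ev[!is.na(ev$pvalue) & ev$pvalue < p_rmats, , drop = FALSE]
  bins <- dexseq[dexseq$eligible & !is.na(dexseq$padj) &
                   dexseq$padj < padj_dexseq, , drop = FALSE]
  keep <- overlaps_bins(ev, bins, stranded = stranded)
  out <- dedup_by_coords(ev[keep, , drop = FALSE])
  rownames(out) <- NULL
  new_event_set("stringent", out)
}

# promote significant DEXSeq-only bins to SE-like event records
promote_dexseq_bins <- function(bins) {
  skel <- merged_skeleton()
  if (nrow(bins) == 0L) return(skel)
  out <- skel[rep(1L, 0L), ]
  out <- data.frame(
    event_type = "SE", gene_id = bins$gene_id, chrom = bins$chrom,
    strand = ifelse(bins$strand %in% c("+", "-"), bins$strand, NA_character_),
    exon_start = bins$start, exon_end = bins$end,
    upstream_start = NA_integer_, upstream_end = NA_integer_,
    downstream_start = NA_integer_, downstream_end = NA_integer_,
    pvalue_jc = NA_real_, fdr_jc = NA_real_, inc_diff_jc = NA_real_,
    pvalue_jcec = NA_real_, fdr_jcec = NA_real_, inc_diff_jcec = NA_real_,
    headline_variant = NA_character_, pvalue = NA_real_, fdr = bins$padj,
    inc_level_diff = NA_real_, direction = NA_character_, putative = TRUE,
    sources = "dexseq",
    event_id = paste("SE", bins$chrom, bins$strand, bins$start, bins$end,
                     "dexseq", sep = ":"),
    stringsAsFactors = FALSE
  )
  out
}

#' Build the comprehensive event set (union of both tools)
#'
#' Takes the union of (i) merged rMATS events with FDR below `fdr_rmats`,
#' (ii) the intersection events of [build_stringent()] with the same inputs,
#' and (iii) significant eligible DEXSeq bins, the latter promoted to
#' SE-like records when they do not overlap any retained rMATS target exon.
#' Including the intersection makes the stringent set a subset of the
#' comprehensive set by construction. Events are deduplicated by genomic
#' coordinates with rMATS information kept preferentially.
#'
#' @inheritParams build_stringent
#' @param fdr_rmats rMATS FDR threshold for the union (default 0.05).
#' @param catalog Optional `exon_catalog`; when supplied the returned set is
#'   passed through [annotate_events()].
#' @return An `event_set` labelled `"comprehensive"`.
#' @export
build_comprehensive <- function(rmats, dexseq, catalog = NULL,
                                fdr_rmats = 0.05, padj_dexseq = 0.05,
                                p_rmats = 0.05, stranded = FALSE) {
  ev <- events_of(rmats)
  by_fdr <- ev[!is.na(ev$fdr) & ev$fdr < fdr_rmats, , drop = FALSE]
  stringent <- build_stringent(ev, dexseq, p_rmats = p_rmats,
                               padj_dexseq = padj_dexseq,
                               stranded = stranded)$events
  rmats_part <- rbind(by_fdr, stringent)
  sig_bins <- dexseq[dexseq$eligible & !is.na(dexseq$padj) &
                       dexseq$padj < padj_dexseq, , drop = FALSE]
  if (nrow(sig_bins) && nrow(rmats_part)) {
    bin_gr <- intervals_to_granges(sig_bins$chrom, sig_bins$start,
                                   sig_bins$end, sig_bins$strand)
    ev_gr <- intervals_to_granges(rmats_part$chrom, rmats_part$exon_start,
                                  rmats_part$exon_end, rmats_part$strand)
    hits <- GenomicRanges::findOverlaps(bin_gr, ev_gr,
                                        ignore.strand = !stranded)
    sig_bins <- sig_bins[!(seq_len(nrow(sig_bins)) %in%
                             S4Vectors::queryHits(hits)), , drop = FALSE]
  }
  promoted <- promote_dexseq_bins(sig_bins)
  all_ev <- rbind(rmats_part, promoted)
  out <- dedup_by_coords(all_ev)
  rownames(out) <- NULL
  eset <- new_event_set("comprehensive", out)
  if (!is.null(catalog)) eset <- annotate_events(eset, catalog)
  eset
}

#' Annotate events with exon class
#'
#' SE events are matched to catalog exons by exact genomic coordinates
#' (chromosome, strand, start, end); matched events inherit the catalog
#' class, and SE events absent from the annotation are counted as `"mixed"`.
#' Non-SE events get `NA`. `in_motif_universe` marks the SE cassette/mixed
#' events that proceed to motif analysis (first/last-in-all excluded).
#'
#' @param eset An `event_set` (or plain events data.frame).
#' @param catalog A classified `exon_catalog`.
#' @return The annotated `event_set`.
#' @export
annotate_events <- function(eset, catalog) {
  ev <- events_of(eset)
  stopifnot(inherits(catalog, "exon_catalog"))
  ex <- catalog$exons
  cat_key <- paste(ex$chrom, ex$strand, ex$start, ex$end, sep = ":")
  ev_key <- paste(ev$chrom, ev$strand, ev$exon_start, ev$exon_end, sep = ":")
  idx <- match(ev_key, cat_key)
  cls <- ex$class[idx]
  cls[is.na(idx)] <- "mixed"            # unannotated SE events
  cls[ev$event_type != "SE"] <- NA_character_
  ev$exon_class <- cls
  ev$in_motif_universe <- ev$event_type == "SE" &
    !is.na(ev$exon_class) & ev$exon_class %in% c("cassette", "mixed")
  if (inherits(eset, "event_set")) {
    eset$events <- ev
    eset
  } else {
    ev
  }
}

#' Number of distinct genes carrying events
#'
#' @param eset An `event_set` or events data.frame with a `gene_id` column.
#' @return Integer count of distinct gene ids.
#' @export
count_event_genes <- function(eset) {
  ev <- events_of(eset)
  length(unique(ev$gene_id[!is.na(ev$gene_id)]))
}

#' Tally events by type and (for SE) exon class
#'
#' @param eset An annotated `event_set`.
#' @return data.frame of counts per `event_type` x `exon_class`.
#' @export
event_type_summary <- function(eset) {
  ev <- events_of(eset)
  if (nrow(ev) == 0L) {
    return(data.frame(event_type = character(0), exon_class = character(0),
                      n = integer(0)))
  }
  cls <- if ("exon_class" %in% names(ev)) ev$exon_class else NA_character_
  cls[is.na(cls)] <- "-"
  agg <- aggregate(list(n = rep(1L, nrow(ev))),
                   by = list(event_type = ev$event_type, exon_class = cls),
                   FUN = sum)
  agg[order(agg$event_type, agg$exon_class), , drop = FALSE]
}

#' Write an event set as TSV and BED6
#'
#' @param eset An `event_set`.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and `<prefix>.bed`.
#' @return Invisibly, the two paths.
#' @export
write_event_set <- function(eset, prefix) {
  ev <- events_of(eset)
  tsv <- paste0(prefix, ".tsv")
  bed <- paste0(prefix, ".bed")
  write.table(ev, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  bed_df <- data.frame(ev$chrom, ev$exon_start, ev$exon_end,
                       paste(ev$gene_id, ev$event_type, sep = "|"), 0L,
                       ifelse(is.na(ev$strand), ".", ev$strand))
  write.table(bed_df, bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(tsv, bed))
}
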