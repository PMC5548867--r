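# Strand-aware flanking-window extraction and per-event motif presence.
#
# Windows abut the target exon's splice sites, extend up to `window_size` nt
# into the adjacent intron, are clipped at the neighbouring exon boundary
# (and chromosome ends), and are reported in transcript orientation:
# minus-strand sequences are reverse-complemented, and the transcript-
# upstream window of a minus-strand exon is genomically rightward.

get_chrom <- function(genome, chrom) {
  if (!chrom %in% names(genome)) {
    stop("chromosome not present in genome: ", chrom)
  }
  genome[[chrom]]
}

# df: id, chrom, strand, exon_start, exon_end, left_bound, right_bound
make_windows <- function(df, genome, window_size = 200L) {
  n <- nrow(df)
  if (n == 0L) {
    return(data.frame(id = character(0), side = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      width = integer(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  strand <- ifelse(is.na(df$strand) | !df$strand %in% c("+", "-"),
                   "+", df$strand)
  chrlen <- setNames(IRanges::width(genome), names(genome))
  clen <- chrlen[df$chrom]
  if (anyNA(clen)) {
    stop("chromosome not present in genome: ",
         paste(unique(df$chrom[is.na(clen)]), collapse = ", "))
  }
  lb <- ifelse(is.na(df$left_bound), 0L, pmax(df$left_bound, 0L))
  rb <- ifelse(is.na(df$right_bound), clen, pmin(df$right_bound, clen))
  l_start <- pmax(df$exon_start - window_size, lb, 0L)
  l_end <- pmax(df$exon_start, l_start)
  r_start <- pmin(df$exon_end, rb)
  r_end <- pmin(df$exon_end + window_size, rb, clen)
  r_end <- pmax(r_end, r_start)

  left <- data.frame(id = df$id,
                     side = ifelse(strand == "+", "upstream", "downstream"),
                     chrom = df$chrom, start = as.integer(l_start),
                     end = as.integer(l_end), strand = strand,
                     stringsAsFactors = FALSE)
  right <- data.frame(id = df$id,
                      side = ifelse(strand == "+", "downstream", "upstream"),
                      chrom = df$chrom, start = as.integer(r_start),
                      end = as.integer(r_end), strand = strand,
                      stringsAsFactors = FALSE)
  win <- rbind(left, right)
  win$width <- win$end - win$start
  win$seq <- extract_oriented(genome, win$chrom, win$start, win$end,
                              win$strand)
  win[order(match(win$id, df$id), win$side), , drop = FALSE]
}

# transcribed-strand sequence of 0-based half-open genomic intervals;
# chromosomes are converted to plain strings once so per-window extraction
# is a single substring() call
extract_oriented <- function(genome, chrom, start, end, strand) {
  used <- unique(chrom)
  miss <- setdiff(used, names(genome))
  if (length(miss)) {
    stop("chromosome not present in genome: ", paste(miss, collapse = ", "))
  }
  cache <- lapply(setNames(used, used),
                  function(ch) as.character(genome[[ch]]))
  out <- character(length(chrom))
  nonempty <- end > start
  if (any(nonempty)) {
    out[nonempty] <- substring(unlist(cache[chrom[nonempty]]),
                               start[nonempty] + 1L, end[nonempty])
  }
  minus <- nonempty & strand == "-"
  if (any(minus)) out[minus] <- vapply(out[minus], revcomp, character(1),
                                       USE.NAMES = FALSE)
  out
}

#' Extract the two intronic flanking windows of splice events
#'
#' For each event, returns the transcript-upstream and -downstream windows of
#' at most `window_size` nt adjacent to the target exon, clipped to the
#' intron using the event's flanking-exon coordinates when available, and to
#' chromosome ends otherwise. Sequences are reported on the transcribed
#' strand.
#'
#' @param events An `event_set` or events data.frame (needs `event_id`,
#'   `chrom`, `strand`, `exon_start`, `exon_end`; flanking coordinates
#'   `upstream_*`/`downstream_*` are used for clipping when present).
#' @param genome A named [Biostrings::DNAStringSet] of chromosome sequences.
#' @param window_size Maximum window length in nt (default 200).
#' @return data.frame with one row per (event, side): `id`, `side`
#'   (`upstream`/`downstream`), genomic `start`/`end` (0-based half-open),
#'   `strand`, `width` and `seq`.
#' @export
flanking_windows <- function(events, genome, window_size = 200L) {
  ev <- events_of(events)
  # resolve transcript-oriented flank intervals into genomic left/right clips
  f1s <- ev$upstream_start; f1e <- ev$upstream_end
  f2s <- ev$downstream_start; f2e <- ev$downstream_end
  left_bound <- rep(NA_integer_, nrow(ev))
  right_bound <- rep(NA_integer_, nrow(ev))
  pick_left <- function(s, e) !is.na(e) & e <= ev$exon_start
  pick_right <- function(s, e) !is.na(s) & s >= ev$exon_end
  for (f in list(list(f1s, f1e), list(f2s, f2e))) {
    isl <- pick_left(f[[1]], f[[2]])
    left_bound[isl] <- pmax(left_bound[isl], f[[2]][isl], na.rm = TRUE)
    isr <- pick_right(f[[1]], f[[2]])
    right_bound[isr] <- pmin(right_bound[isr], f[[1]][isr], na.rm = TRUE)
  }
  df <- data.frame(id = ev$event_id, chrom = ev$chrom, strand = ev$strand,
                   exon_start = ev$exon_start, exon_end = ev$exon_end,
                   left_bound = left_bound, right_bound = right_bound,
                   stringsAsFactors = FALSE)
  make_windows(df, genome, window_size)
}

#' Extract flanking windows for catalog exons
#'
#' Used for control exons: windows are clipped at the closest neighbouring
#' exon boundary across all transcripts containing the exon.
#'
#' @param catalog An `exon_catalog`.
#' @param exon_ids Exon identifiers (default: all catalog exons).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param window_size Maximum window length in nt (default 200).
#' @return As [flanking_windows()], with `id` = exon id.
#' @export
exon_windows <- function(catalog, exon_ids = NULL, genome,
                         window_size = 200L) {
  ex <- catalog$exons
  if (!is.null(exon_ids)) {
    ex <- ex[match(exon_ids, ex$exon_id), , drop = FALSE]
    if (anyNA(ex$exon_id)) stop("exon id(s) not in catalog")
  }
  bounds <- catalog_flank_bounds(catalog, ex$exon_id)
  df <- data.frame(id = ex$exon_id, chrom = ex$chrom, strand = ex$strand,
                   exon_start = ex$start, exon_end = ex$end,
                   left_bound = bounds$left_bound,
                   right_bound = bounds$right_bound,
                   stringsAsFactors = FALSE)
  make_windows(df, genome, window_size)
}

#' Per-event core-motif presence flags
#'
#' @param windows Window data.frame from [flanking_windows()] or
#'   [exon_windows()].
#' @return data.frame with one row per id: `upstream_hit`, `downstream_hit`
#'   (>= 1 ACUAA hit in that window) and `any_hit` (either side).
#' @export
event_has_core <- function(windows) {
  ids <- unique(windows$id)
  hit <- vapply(windows$seq, function(s) length(scan_core(s)) > 0L,
                logical(1), USE.NAMES = FALSE)
  up <- tapply(hit & windows$side == "upstream", windows$id, any)
  dn <- tapply(hit & windows$side == "downstream", windows$id, any)
  data.frame(id = ids,
             upstream_hit = as.logical(up[ids]),
             downstream_hit = as.logical(dn[ids]),
             any_hit = as.logical(up[ids] | dn[ids]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Positional contingency of motif presence by inclusion direction
#'
#' Cross-tabulates QKI-repressed (higher inclusion in knockout) versus
#' QKI-activated (higher exclusion) events against the side on which the
#' core motif occurs. Events lacking a direction are excluded and counted.
#'
#' @param events Annotated events data.frame (or `event_set`) with
#'   `direction`.
#' @param flags Per-event flags from [event_has_core()].
#' @return data.frame with one row per direction and columns `n`,
#'   `upstream_only`, `downstream_only`, `both`, `neither`; the number of
#'   direction-less events is in attribute `n_excluded`.
#' @export
positional_summary <- function(events, flags) {
  ev <- events_of(events)
  idx <- match(ev$event_id, flags$id)
  up <- flags$upstream_hit[idx]
  dn <- flags$downstream_hit[idx]
  has_dir <- !is.na(ev$direction)
  out <- do.call(rbind, lapply(
    c("higher_inclusion", "higher_exclusion"),
    function(d) {
      sel <- has_dir & ev$direction == d & !is.na(up)
      data.frame(direction = d, n = sum(sel),
                 upstream_only = sum(up[sel] & !dn[sel]),
                 downstream_only = sum(!up[sel] & dn[sel]),
                 both = sum(up[sel] & dn[sel]),
                 neither = sum(!up[sel] & !dn[sel]),
                 stringsAsFactors = FALSE)
    }))
  attr(out, "n_excluded") <- sum(!has_dir)
  out
}

#' Scan a genomic region for QREs with genomic hit coordinates
#'
#' Applies [scan_qre()] to the transcribed-strand sequence of the region and
#' maps hits back to genomic coordinates.
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param chrom Chromosome name.
#' @param start,end Region as 0-based half-open genomic interval.
#' @param strand `"+"` or `"-"` (transcribed strand of the region).
#' @param max_mismatch,spacer_min,spacer_max Passed to [scan_qre()].
#' @return data.frame of hits with `offset` (in the oriented region
#'   sequence), `spacer_len`, `mismatches`, `length` and genomic
#'   `start`/`end` (0-based half-open).
#' @export
scan_region_qre <- function(genome, chrom, start, end, strand = "+",
                            max_mismatch = 1L, spacer_min = 1L,
                            spacer_max = 20L) {
  chr <- get_chrom(genome, chrom)
  if (start < 0L || end > length(chr) || start >= end) {
    stop("region out of chromosome bounds: ", chrom, ":", start, "-", end)
  }
  stopifnot(strand %in% c("+", "-"))
  seq <- extract_oriented(genome, chrom, start, end, strand)
  hits <- scan_qre(seq, max_mismatch = max_mismatch,
                   spacer_min = spacer_min, spacer_max = spacer_max)
  if (strand == "+") {
    hits$start <- start + hits$offset
    hits$end <- hits$start + hits$length
  } else {
    hits$end <- end - hits$offset
    hits$start <- hits$end - hits$length
  }
  hits$chrom <- rep(chrom, nrow(hits))
  hits$strand <- rep(strand, nrow(hits))
  hits
}

#' Write QRE hits as BED6
#'
#' @param hits Hits from [scan_region_qre()].
#' @param path Output BED file.
#' @return Invisibly, the path.
#' @export
qre_hits_to_bed <- function(hits, path) {
  name <- paste0("QRE/spacer", hits$spacer_len, "/mm", hits$mismatches)
  bed <- data.frame(hits$chrom, hits$start, hits$end, name,
                    hits$mismatches, hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
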