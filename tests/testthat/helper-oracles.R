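# Independent oracles used to check the package implementations, kept on
# deliberately different code paths (regex / character-vector enumeration /
# naive double loops) from the functions they verify.

random_seq <- function(n, probs = c(0.3, 0.2, 0.2, 0.3)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# regex sliding-window oracle for the ACUAA core (lookahead => overlapping)
oracle_scan_core <- function(seq) {
  s <- chartr("U", "T", toupper(seq))
  m <- gregexpr("(?=ACTAA)", s, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# brute-force enumeration over all offsets x spacer lengths for the QRE,
# counting mismatches position by position on a character vector
oracle_scan_qre <- function(seq, max_mismatch = 1L, spacer_min = 1L,
                            spacer_max = 20L) {
  chars <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  L <- length(chars)
  half1 <- list("A", "C", "T", "A", "A", c("C", "T"))
  half2 <- list("T", "A", "A", c("C", "T"))
  rows <- list()
  for (sp in spacer_min:spacer_max) {
    len <- 10L + sp
    if (L < len) next
    n_off <- L - len + 1L
    mm <- integer(n_off)
    for (k in seq_len(6L)) {
      mm <- mm + !(chars[seq_len(n_off) + k - 1L] %in% half1[[k]])
    }
    for (k in seq_len(4L)) {
      mm <- mm + !(chars[seq_len(n_off) + 6L + sp + k - 1L] %in% half2[[k]])
    }
    keep <- which(mm <= max_mismatch)
    if (length(keep)) {
      rows[[length(rows) + 1L]] <-
        data.frame(offset = keep - 1L, spacer_len = sp,
                   mismatches = mm[keep], length = len)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(offset = integer(0), spacer_len = integer(0),
                      mismatches = integer(0), length = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$offset, out$spacer_len), ]
  rownames(out) <- NULL
  out
}

# per-transcript positional classification oracle: explicit loops over
# transcripts, terminality by genomic min/max exon of each transcript
oracle_classify <- function(instances) {
  key <- function(df) paste(df$chrom, df$start, df$end, df$strand,
                            df$gene_id, sep = "|")
  classes <- list()
  for (tid in unique(paste(instances$gene_id, instances$transcript_id))) {
    rows <- instances[paste(instances$gene_id,
                            instances$transcript_id) == tid, ]
    lo <- min(rows$start)
    hi <- max(rows$start)
    for (i in seq_len(nrow(rows))) {
      k <- key(rows[i, ])
      terminal <- rows$start[i] == lo || rows$start[i] == hi
      classes[[k]] <- c(classes[[k]], terminal)
    }
  }
  vapply(classes, function(flags) {
    if (all(flags)) "first_last"
    else if (any(flags)) "mixed"
    else "cassette"
  }, character(1))
}

# naive all-pairs >=1 bp overlap oracle (same chromosome)
oracle_overlap_any <- function(ev, bins) {
  out <- logical(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    for (j in seq_len(nrow(bins))) {
      if (ev$chrom[i] == bins$chrom[j] &&
          ev$exon_start[i] < bins$end[j] &&
          bins$start[j] < ev$exon_end[i]) {
        out[i] <- TRUE
        break
      }
    }
  }
  out
}

# naive loops: does each exon overlap a low-adjusted-p bin / a significant
# rMATS target exon?
oracle_overlap_bins <- function(ex, dexseq, padj_floor) {
  out <- logical(nrow(ex))
  for (i in seq_len(nrow(ex))) {
    dx <- dexseq[dexseq$chrom == ex$chrom[i] &
                   dexseq$start < ex$end[i] & dexseq$end > ex$start[i], ]
    out[i] <- any(dx$padj <= padj_floor)
  }
  out
}
oracle_overlap_events <- function(ex, ev) {
  out <- logical(nrow(ex))
  for (i in seq_len(nrow(ex))) {
    out[i] <- any(ev$chrom == ex$chrom[i] &
                    ev$exon_start < ex$end[i] & ev$exon_end > ex$start[i])
  }
  out
}

# small generator configuration for fast tests
small_config <- function(seed, ...) {
  args <- list(seed = seed, n_genes = 50L, n_as_events = 20L,
               n_qres = 6L, qre_region_len = 900L,
               n_a5ss = 2L, n_a3ss = 2L, n_ri = 2L)
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_config, args)
}

toy_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  g
}

# minimal normalised rMATS-like event rows for integration tests
make_events <- function(n, chrom = "chr1", strand = "+", seed = NULL,
                        pvalue = NULL, fdr = NULL) {
  start <- sort(sample.int(50000L, n)) * 10L
  end <- start + sample(30:200, n, replace = TRUE)
  data.frame(
    event_type = rep("SE", n), gene_id = sprintf("G%03d", seq_len(n)),
    chrom = rep(chrom, length.out = n),
    strand = rep(strand, length.out = n),
    exon_start = start, exon_end = end,
    upstream_start = start - 500L, upstream_end = start - 300L,
    downstream_start = end + 300L, downstream_end = end + 500L,
    pvalue = pvalue %||% runif(n), fdr = fdr %||% runif(n),
    inc_level_diff = runif(n, -1, 1), variant = rep("jc", n),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
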