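# Control-exon universe and resampling-based motif enrichment.
#
# The control universe holds non-alternatively-spliced cassette/mixed exons
# with adequate, length-normalised coverage at both the exon and gene level.
# Enrichment of the ACUAA core in event flanking windows is tested against
# the fraction observed in repeated size-matched random draws of control
# exons, with the plus-one empirical p-value (1 + k) / (1 + n_iter).

#' Build the control exon universe
#'
#' Filters are applied conjunctively in a fixed order, with per-step removal
#' counts recorded:
#' \enumerate{
#'   \item class: cassette or mixed exons only;
#'   \item length: at least `min_length` nt;
#'   \item coverage: exon and gene coverage (per nt) strictly above the
#'     respective `cov_quantile` quantile, quantiles computed over the
#'     candidate universe remaining after the class and length filters
#'     (gene coverage over distinct genes); candidates without a coverage
#'     record are excluded and counted separately;
#'   \item non-AS: no overlap with a DEXSeq bin of adjusted p <=
#'     `dexseq_padj_floor`, and no overlap with an rMATS event target exon of
#'     p-value < `rmats_p`.
#' }
#'
#' @param catalog Classified `exon_catalog`.
#' @param coverage Coverage table from [read_coverage()].
#' @param dexseq Bins from [read_dexseq()] (may have zero rows).
#' @param rmats Merged rMATS events (may have zero rows).
#' @param min_length Minimum exon length in nt (default 15).
#' @param dexseq_padj_floor Controls must exceed this DEXSeq adjusted p
#'   (default 0.99).
#' @param rmats_p Exons overlapping rMATS events below this p-value are
#'   considered alternatively spliced and removed (default 0.05).
#' @param cov_quantile Coverage quantile cut (default 0.25, the lowest
#'   quartile); 0 disables the coverage threshold (missing-coverage
#'   candidates are still excluded).
#' @return Object of class `control_exon_set`: list with `exons` (with flank
#'   bounds attached), `filter_log` and `params`.
#' @export
build_control_set <- function(catalog, coverage, dexseq, rmats,
                              min_length = 15L, dexseq_padj_floor = 0.99,
                              rmats_p = 0.05, cov_quantile = 0.25) {
  stopifnot(inherits(catalog, "exon_catalog"))
  ex <- catalog$exons
  log <- c()
  n0 <- nrow(ex)

  ex <- ex[ex$class %in% c("cassette", "mixed"), , drop = FALSE]
  log["class"] <- n0 - nrow(ex)

  n1 <- nrow(ex)
  ex <- ex[ex$length >= min_length, , drop = FALSE]
  log["length"] <- n1 - nrow(ex)

  n2 <- nrow(ex)
  idx <- match(ex$exon_id, coverage$exon_id)
  has_cov <- !is.na(idx) & !is.na(coverage$exon_cov_per_nt[idx]) &
    !is.na(coverage$gene_cov_per_nt[idx])
  log["coverage_missing"] <- sum(!has_cov)
  ex <- ex[has_cov, , drop = FALSE]
  idx <- idx[has_cov]
  exon_cov <- coverage$exon_cov_per_nt[idx]
  gene_cov <- coverage$gene_cov_per_nt[idx]
  if (cov_quantile > 0) {
    q_exon <- quantile(exon_cov, cov_quantile, names = FALSE, type = 7)
    gene_first <- !duplicated(ex$gene_id)
    q_gene <- quantile(gene_cov[gene_first], cov_quantile, names = FALSE,
                       type = 7)
    keep_cov <- exon_cov > q_exon & gene_cov > q_gene
  } else {
    keep_cov <- rep(TRUE, nrow(ex))     # quantile 0 disables the cut
  }
  log["coverage"] <- sum(has_cov) - sum(keep_cov)
  ex <- ex[keep_cov, , drop = FALSE]

  n3 <- nrow(ex)
  as_like <- rep(FALSE, n3)
  if (n3 > 0L) {
    ex_gr <- intervals_to_granges(ex$chrom, ex$start, ex$end, ex$strand)
    sig_bins <- dexseq[!is.na(dexseq$padj) &
                         dexseq$padj <= dexseq_padj_floor, , drop = FALSE]
    if (nrow(sig_bins)) {
      bin_gr <- intervals_to_granges(sig_bins$chrom, sig_bins$start,
                                     sig_bins$end, sig_bins$strand)
      hits <- GenomicRanges::findOverlaps(ex_gr, bin_gr, ignore.strand = TRUE)
      as_like[unique(S4Vectors::queryHits(hits))] <- TRUE
    }
    rm_ev <- events_of(rmats)
    rm_ev <- rm_ev[!is.na(rm_ev$pvalue) & rm_ev$pvalue < rmats_p, ,
                   drop = FALSE]
    if (nrow(rm_ev)) {
      ev_gr <- intervals_to_granges(rm_ev$chrom, rm_ev$exon_start,
                                    rm_ev$exon_end, rm_ev$strand)
      hits <- GenomicRanges::findOverlaps(ex_gr, ev_gr, ignore.strand = TRUE)
      as_like[unique(S4Vectors::queryHits(hits))] <- TRUE
    }
  }
  log["not_alternatively_spliced"] <- sum(as_like)
  ex <- ex[!as_like, , drop = FALSE]

  bounds <- catalog_flank_bounds(catalog, ex$exon_id)
  ex$left_bound <- bounds$left_bound
  ex$right_bound <- bounds$right_bound
  rownames(ex) <- NULL
  structure(list(exons = ex, filter_log = log,
                 params = list(min_length = min_length,
                               dexseq_padj_floor = dexseq_padj_floor,
                               rmats_p = rmats_p,
                               cov_quantile = cov_quantile)),
            class = "control_exon_set")
}

#' @export
print.control_exon_set <- function(x, ...) {
  cat("control_exon_set:", nrow(x$exons), "exons\n")
  cat("removed per filter:\n")
  print(x$filter_log)
  invisible(x)
}

#' Core-motif presence flags for control exons
#'
#' @param controls A `control_exon_set`.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param window_size Flanking window size in nt (default 200).
#' @return Logical vector (one element per control exon): any ACUAA hit in
#'   either flanking window.
#' @export
control_motif_flags <- function(controls, genome, window_size = 200L) {
  ex <- controls$exons
  if (nrow(ex) == 0L) return(logical(0))
  df <- data.frame(id = ex$exon_id, chrom = ex$chrom, strand = ex$strand,
                   exon_start = ex$start, exon_end = ex$end,
                   left_bound = ex$left_bound, right_bound = ex$right_bound,
                   stringsAsFactors = FALSE)
  win <- make_windows(df, genome, window_size)
  flags <- event_has_core(win)
  flags$any_hit[match(ex$exon_id, flags$id)]
}

#' Resampling enrichment test on presence flags
#'
#' The computational core of the enrichment analysis: given per-event and
#' per-control motif-presence flags, draws `n_iter` size-matched samples of
#' control flags without replacement and returns the plus-one empirical
#' p-value `(1 + #\{null >= observed\}) / (1 + n_iter)`.
#'
#' @param event_flags Logical vector, one element per event.
#' @param control_flags Logical vector, one element per control exon; must
#'   be at least as long as `event_flags`.
#' @param n_iter Number of resampling iterations (default 1000).
#' @param seed Integer seed; the run is deterministic given the seed.
#' @param subset Label stored in the result (default `"all_SE"`).
#' @return Object of class `enrichment_result` with `observed`, the
#'   `null_fractions` vector, `p_value`, `n_events`, `n_controls`, `n_iter`
#'   and `seed`.
#' @export
motif_enrichment_test <- function(event_flags, control_flags,
                                  n_iter = 1000L, seed = 1L,
                                  subset = "all_SE") {
  n_ev <- length(event_flags)
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (n_ev == 0L) {
    return(structure(list(subset = subset, computed = FALSE,
                          n_events = 0L,
                          n_controls = length(control_flags),
                          observed = NA_real_, null_fractions = numeric(0),
                          p_value = NA_real_, n_iter = n_iter, seed = seed),
                     class = "enrichment_result"))
  }
  if (length(control_flags) < n_ev) {
    stop("fewer control exons (", length(control_flags),
         ") than events (", n_ev, ")")
  }
  observed <- mean(event_flags)
  null_fractions <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_iter),
           function(i) mean(sample(control_flags, n_ev)), numeric(1))
  })
  p <- (1 + sum(null_fractions >= observed)) / (1 + n_iter)
  structure(list(subset = subset, computed = TRUE, n_events = n_ev,
                 n_controls = length(control_flags), observed = observed,
                 null_fractions = null_fractions, p_value = p,
                 n_iter = as.integer(n_iter), seed = as.integer(seed)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  if (!isTRUE(x$computed)) {
    cat("enrichment_result '", x$subset, "': not computed (empty subset)\n",
        sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "enrichment_result '%s': observed %.1f%% (n = %d events), null mean %.1f%%, empirical p = %.4g (%d iterations)\n",
    x$subset, 100 * x$observed, x$n_events, 100 * mean(x$null_fractions),
    x$p_value, x$n_iter))
  invisible(x)
}

#' Empirical motif enrichment for one event subset
#'
#' Computes per-event ACUAA presence in the flanking windows, the same for
#' the control universe, and runs [motif_enrichment_test()].
#'
#' @param events Annotated `event_set` or events data.frame; only rows with
#'   `in_motif_universe` (when present) are used.
#' @param controls A `control_exon_set`.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param n_iter Resampling iterations (default 1000).
#' @param seed Integer seed.
#' @param window_size Window size in nt (default 200).
#' @param subset Label for the result.
#' @param control_flags Optional precomputed [control_motif_flags()] vector
#'   (avoids rescanning when testing several subsets).
#' @return An `enrichment_result`.
#' @export
empirical_enrichment <- function(events, controls, genome, n_iter = 1000L,
                                 seed = 1L, window_size = 200L,
                                 subset = "all_SE", control_flags = NULL) {
  ev <- events_of(events)
  if ("in_motif_universe" %in% names(ev)) {
    ev <- ev[ev$in_motif_universe, , drop = FALSE]
  }
  if (is.null(control_flags)) {
    control_flags <- control_motif_flags(controls, genome, window_size)
  }
  if (nrow(ev) == 0L) {
    return(motif_enrichment_test(logical(0), control_flags, n_iter, seed,
                                 subset))
  }
  win <- flanking_windows(ev, genome, window_size)
  flags <- event_has_core(win)
  ev_flags <- flags$any_hit[match(ev$event_id, flags$id)]
  motif_enrichment_test(ev_flags, control_flags, n_iter, seed, subset)
}

#' Enrichment across the standard event subsets
#'
#' Runs the motif enrichment successively for all SE events, SE events with
#' higher inclusion in the knockout (QKI-repressed) and SE events with
#' higher exclusion (QKI-activated), for both the stringent and the
#' comprehensive set, against a shared control universe. Per-subset seeds
#' are derived from the master seed with [derive_seeds()].
#'
#' @param stringent,comprehensive Annotated `event_set`s.
#' @param controls A `control_exon_set`.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param n_iter Iterations per subset (default 1000).
#' @param seed Master seed.
#' @param window_size Window size in nt (default 200).
#' @return Named list of six `enrichment_result`s
#'   (`<set>.<all|higher_inclusion|higher_exclusion>`); empty subsets are
#'   flagged `computed = FALSE`.
#' @export
run_subsets <- function(stringent, comprehensive, controls, genome,
                        n_iter = 1000L, seed = 1L, window_size = 200L) {
  control_flags <- control_motif_flags(controls, genome, window_size)
  sets <- list(stringent = stringent, comprehensive = comprehensive)
  dirs <- c("all", "higher_inclusion", "higher_exclusion")
  seeds <- derive_seeds(seed, length(sets) * length(dirs))
  out <- list()
  k <- 0L
  for (set_name in names(sets)) {
    ev <- events_of(sets[[set_name]])
    if (!"in_motif_universe" %in% names(ev)) {
      stop("event set '", set_name, "' must be annotated first")
    }
    ev <- ev[ev$in_motif_universe, , drop = FALSE]
    for (d in dirs) {
      k <- k + 1L
      sub <- if (d == "all") ev else {
        ev[!is.na(ev$direction) & ev$direction == d, , drop = FALSE]
      }
      label <- paste(set_name, d, sep = ".")
      out[[label]] <- empirical_enrichment(
        sub, controls, genome, n_iter = n_iter, seed = seeds[k],
        window_size = window_size, subset = label,
        control_flags = control_flags)
    }
  }
  out
}

#' Tidy summary of enrichment results
#'
#' @param results List of `enrichment_result`s from [run_subsets()].
#' @return data.frame with one row per subset.
#' @export
enrichment_summary <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(subset = r$subset, computed = isTRUE(r$computed),
               n_events = r$n_events,
               observed_pct = if (isTRUE(r$computed)) 100 * r$observed
               else NA_real_,
               null_mean_pct = if (isTRUE(r$computed))
                 100 * mean(r$null_fractions) else NA_real_,
               p_value = r$p_value, n_iter = r$n_iter, seed = r$seed,
               stringsAsFactors = FALSE)
  }))
}
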