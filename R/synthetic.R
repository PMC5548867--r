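# Synthetic dataset generator: genome FASTA, GTF gene models, coverage
# table, rMATS-style (JC and JCEC) and DEXSeq-style result tables, with a
# planted, fully recorded ground truth so every pipeline stage can be
# checked against known answers.
#
# Motif ground truth is exact by construction: every controlled flanking
# window is first scrubbed of ACUAA occurrences (base replacements use 'G',
# which occurs in neither ACTAA nor TAAY, so destroying a motif can never
# create one), then a motif is planted with the configured per-window
# probability. Event exons are restricted to internal exons flanked by
# introns of at least twice the window size, so event windows never share
# sequence with any other controlled window.

rint <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}
resample <- function(x, n = 1L, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), n, replace = replace, prob = prob)]
}

#' Configuration for the synthetic dataset generator
#'
#' All sizes are desk-scale by design (genome under ~2 Mb). Rates `r_as` and
#' `r_control` are per-window motif planting probabilities for event and
#' background exons respectively; the defaults emulate the study situation
#' of a clearly motif-enriched event set over a low background.
#'
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param n_genes Number of genes.
#' @param n_chroms Number of chromosomes (genes are interleaved).
#' @param tx_per_gene Range (min, max) of transcripts per gene.
#' @param exons_per_tx Range of exons in the gene's master exon chain.
#' @param exon_len,short_exon_frac,short_exon_len Exon length range in nt,
#'   plus a small fraction of very short exons (below the 15-nt eligibility
#'   cut) to exercise length filters.
#' @param intron_len,short_intron_frac,short_intron_len Intron length range;
#'   long introns are at least twice the window size (un-clipped windows),
#'   the short fraction produces clipped windows.
#' @param intergenic Range of intergenic gap lengths in nt.
#' @param base_probs Background base composition (A, C, G, T).
#' @param n_as_events Number of planted skipped-exon events significant in
#'   both tools.
#' @param prop_inclusion Fraction of planted events with higher inclusion in
#'   the knockout (QKI-repressed).
#' @param frac_rmats_only,frac_dexseq_only Extra events (as a fraction of
#'   `n_as_events`) significant in only one tool.
#' @param variant_both Probability a significant rMATS event appears in both
#'   quantification variants (the remainder split evenly between JC-only and
#'   JCEC-only).
#' @param null_rmats_frac Fraction of background internal exons that also
#'   get (non-significant) rMATS rows.
#' @param control_pool_frac Fraction of unplanted internal exons designated
#'   non-alternatively-spliced (DEXSeq adjusted p > 0.99).
#' @param r_as,r_control Per-window motif planting probabilities for event
#'   vs background exons.
#' @param side_bias Additive bias moving planted motifs upstream for
#'   QKI-repressed and downstream for QKI-activated events (0 = none).
#' @param window_size Flanking window size in nt.
#' @param n_qres,qre_region_len,qre_mismatch_frac Planted QRE count in a
#'   dedicated intergenic region (emulating an alternatively spliced 3'
#'   region), its length, and the fraction of planted QREs carrying one
#'   mismatch.
#' @param n_a5ss,n_a3ss,n_ri Counts of non-SE event rows emitted.
#' @param sig_p,null_p Uniform ranges for significant and null p-values
#'   (the FDR column mirrors the p-value).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_genes = 200L, n_chroms = 2L,
                             tx_per_gene = c(1L, 3L),
                             exons_per_tx = c(4L, 9L),
                             exon_len = c(60L, 250L),
                             short_exon_frac = 0.05,
                             short_exon_len = c(10L, 14L),
                             intron_len = c(420L, 1200L),
                             short_intron_frac = 0.15,
                             short_intron_len = c(60L, 200L),
                             intergenic = c(300L, 800L),
                             base_probs = c(A = 0.3, C = 0.2,
                                            G = 0.2, T = 0.3),
                             n_as_events = 150L, prop_inclusion = 0.5,
                             frac_rmats_only = 0.08,
                             frac_dexseq_only = 0.08,
                             variant_both = 0.8, null_rmats_frac = 0.4,
                             control_pool_frac = 0.8,
                             r_as = 0.25, r_control = 0.10, side_bias = 0,
                             window_size = 200L, n_qres = 24L,
                             qre_region_len = 4000L,
                             qre_mismatch_frac = 0.4,
                             n_a5ss = 6L, n_a3ss = 5L, n_ri = 4L,
                             sig_p = c(0, 0.01), null_p = c(0.2, 1)) {
  cfg <- as.list(environment())
  base_probs <- unlist(base_probs)
  names(base_probs) <- c("A", "C", "G", "T")
  cfg$base_probs <- base_probs
  rng_ok <- function(r) length(r) == 2L && r[1] <= r[2]
  stopifnot(
    n_genes >= 0L, n_chroms >= 1L,
    rng_ok(tx_per_gene), tx_per_gene[1] >= 1L,
    rng_ok(exons_per_tx), exons_per_tx[1] >= 3L,
    rng_ok(exon_len), rng_ok(short_exon_len), rng_ok(intron_len),
    rng_ok(short_intron_len), rng_ok(intergenic),
    intron_len[1] >= 2L * window_size, short_intron_len[1] >= 20L,
    length(base_probs) == 4L, all(base_probs > 0),
    n_as_events >= 0L,
    r_as >= 0, r_as <= 1, r_control >= 0, r_control <= 1,
    prop_inclusion >= 0, prop_inclusion <= 1,
    side_bias >= 0, side_bias <= 1,
    window_size >= 20L, n_qres >= 0L,
    qre_mismatch_frac >= 0, qre_mismatch_frac <= 1,
    rng_ok(sig_p), rng_ok(null_p)
  )
  if (n_qres > 0L && qre_region_len < n_qres * 95L) {
    stop("qre_region_len too small for ", n_qres, " planted QREs")
  }
  structure(cfg, class = "synthetic_config")
}

#' Read a generator configuration from YAML
#'
#' @param path YAML file whose keys match [synthetic_config()] arguments.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(synthetic_config)))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(synthetic_config, vals)
}

#' Generate a synthetic dataset with planted ground truth
#'
#' Emits (in memory) a genome, a gene annotation, rMATS-style tables for
#' both quantification variants, a DEXSeq-style exon-bin table, a coverage
#' table and the full ground truth. Use [write_dataset()] to materialise the
#' standard file formats.
#'
#' @param config A [synthetic_config()].
#' @return Object of class `synthetic_dataset`: list with `genome`
#'   ([Biostrings::DNAStringSet]), `instances` (per-transcript exon rows),
#'   `catalog`, `rmats` (dialect tables per type and variant), `dexseq`,
#'   `coverage`, `truth` and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(as.integer(config$seed), generate_impl(config))
}

generate_impl <- function(cfg) {
  w <- cfg$window_size
  chrom_names <- paste0("chr", seq_len(cfg$n_chroms))
  cursor <- setNames(rep(0L, cfg$n_chroms), chrom_names)

  chain_rows <- list()
  inst_rows <- list()
  for (g in seq_len(cfg$n_genes)) {
    gid <- sprintf("G%04d", g)
    ch <- chrom_names[((g - 1L) %% cfg$n_chroms) + 1L]
    strand <- resample(c("+", "-"))
    K <- rint(cfg$exons_per_tx[1], cfg$exons_per_tx[2])
    elen <- rint(cfg$exon_len[1], cfg$exon_len[2], K)
    short_e <- runif(K) < cfg$short_exon_frac
    if (any(short_e)) {
      elen[short_e] <- rint(cfg$short_exon_len[1], cfg$short_exon_len[2],
                            sum(short_e))
    }
    ilen <- rint(cfg$intron_len[1], cfg$intron_len[2], K - 1L)
    short_i <- runif(K - 1L) < cfg$short_intron_frac
    if (any(short_i)) {
      ilen[short_i] <- rint(cfg$short_intron_len[1],
                            cfg$short_intron_len[2], sum(short_i))
    }
    gap <- rint(cfg$intergenic[1], cfg$intergenic[2])
    starts <- cursor[[ch]] + gap +
      cumsum(c(0L, head(elen, -1L) + ilen))
    ends <- starts + elen
    cursor[[ch]] <- ends[K]
    chain_rows[[g]] <- data.frame(
      gene_id = gid, chrom = ch, strand = strand, idx = seq_len(K),
      start = starts, end = ends, K = K, stringsAsFactors = FALSE)

    n_tx <- rint(cfg$tx_per_gene[1], cfg$tx_per_gene[2])
    tx_sets <- list(seq_len(K))
    if (n_tx > 1L) {
      for (t in 2:n_tx) {
        a <- resample(seq_len(K - 1L))
        b <- resample(seq(a + 1L, K))
        mid <- setdiff(seq(a, b), c(a, b))
        keep <- mid[runif(length(mid)) < 0.8]
        tx_sets[[t]] <- sort(unique(c(a, keep, b)))
      }
    }
    for (t in seq_along(tx_sets)) {
      sel <- tx_sets[[t]]
      inst_rows[[length(inst_rows) + 1L]] <- data.frame(
        chrom = ch, start = starts[sel], end = ends[sel], strand = strand,
        gene_id = gid, transcript_id = sprintf("%s.T%d", gid, t),
        stringsAsFactors = FALSE)
    }
  }
  chain <- if (length(chain_rows)) do.call(rbind, chain_rows) else
    data.frame(gene_id = character(0), chrom = character(0),
               strand = character(0), idx = integer(0), start = integer(0),
               end = integer(0), K = integer(0))
  instances <- if (length(inst_rows)) do.call(rbind, inst_rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), gene_id = character(0),
               transcript_id = character(0))
  catalog <- build_exon_catalog(instances)

  # genome: random sequence, QRE region reserved at the end of chr1
  region <- NULL
  region_start <- NA_integer_
  if (cfg$n_qres > 0L) {
    region_start <- cursor[[1L]] + 500L
    region <- list(chrom = chrom_names[1L], start = region_start,
                   end = region_start + cfg$qre_region_len,
                   strand = resample(c("+", "-")))
  }
  base_raw <- charToRaw("ACGT")
  seqs <- list()
  for (i in seq_len(cfg$n_chroms)) {
    len <- cursor[[i]] + rint(cfg$intergenic[1], cfg$intergenic[2])
    if (i == 1L && !is.null(region)) len <- region$end + 200L
    len <- max(len, 1000L)
    seqs[[chrom_names[i]]] <-
      base_raw[sample.int(4L, len, replace = TRUE, prob = cfg$base_probs)]
  }

  read_win <- function(ch, s, e, strand) {
    if (e <= s) return("")
    x <- rawToChar(seqs[[ch]][(s + 1L):e])
    if (strand == "-") revcomp(x) else x
  }
  write_win <- function(ch, s, e, strand, value) {
    if (strand == "-") value <- revcomp(value)
    seqs[[ch]][(s + 1L):e] <<- charToRaw(value)
  }

  # ---- candidate exons and group assignment -------------------------------
  internal <- chain[chain$idx > 1L & chain$idx < chain$K, , drop = FALSE]
  if (nrow(internal)) {
    prev <- match(paste(internal$gene_id, internal$idx - 1L),
                  paste(chain$gene_id, chain$idx))
    nxt <- match(paste(internal$gene_id, internal$idx + 1L),
                 paste(chain$gene_id, chain$idx))
    internal$left_bound <- chain$end[prev]
    internal$right_bound <- chain$start[nxt]
    internal$exon_id <- exon_key(internal$chrom, internal$start,
                                 internal$end, internal$strand,
                                 internal$gene_id)
    internal$left_intron <- internal$start - internal$left_bound
    internal$right_intron <- internal$right_bound - internal$end
  } else {
    internal$left_bound <- integer(0); internal$right_bound <- integer(0)
    internal$exon_id <- character(0)
    internal$left_intron <- integer(0); internal$right_intron <- integer(0)
  }

  eligible <- internal[internal$left_intron >= 2L * w &
                         internal$right_intron >= 2L * w &
                         (internal$end - internal$start) >= 20L, ,
                       drop = FALSE]
  n_rm_only <- round(cfg$frac_rmats_only * cfg$n_as_events)
  n_dx_only <- round(cfg$frac_dexseq_only * cfg$n_as_events)
  n_dx_internal <- ceiling(n_dx_only / 2)
  n_dx_terminal <- n_dx_only - n_dx_internal
  need <- cfg$n_as_events + n_rm_only + n_dx_internal
  if (nrow(eligible) < need) {
    stop("not enough eligible internal exons (", nrow(eligible),
         ") for ", need, " planted events; increase n_genes")
  }
  picks <- resample(eligible$exon_id, need)
  as_ids <- picks[seq_len(cfg$n_as_events)]
  rm_only_ids <- picks[seq_len(n_rm_only) + cfg$n_as_events]
  dx_only_ids <- picks[seq_len(n_dx_internal) + cfg$n_as_events + n_rm_only]
  pool_ids <- setdiff(internal$exon_id, picks)
  direction <- ifelse(runif(cfg$n_as_events) < cfg$prop_inclusion,
                      "higher_inclusion", "higher_exclusion")
  names(direction) <- as_ids

  term_ex <- catalog$exons[catalog$exons$class == "first_last" &
                             catalog$exons$length >= 15L, , drop = FALSE]
  dx_term_ids <- resample(term_ex$exon_id, min(n_dx_terminal,
                                               nrow(term_ex)))
  control_intended <- resample(pool_ids,
                               round(cfg$control_pool_frac *
                                       length(pool_ids)))

  # ---- flanking windows of all internal exons: scrub then plant -----------
  grp <- rep("pool", nrow(internal))
  grp[internal$exon_id %in% as_ids] <- "as"
  grp[internal$exon_id %in% rm_only_ids] <- "rmats_only"
  grp[internal$exon_id %in% dx_only_ids] <- "dexseq_only"
  win <- rbind(
    data.frame(exon_id = internal$exon_id, group = grp,
               chrom = internal$chrom, strand = internal$strand,
               side = ifelse(internal$strand == "+", "upstream",
                             "downstream"),
               start = pmax(internal$start - w, internal$left_bound),
               end = internal$start, stringsAsFactors = FALSE),
    data.frame(exon_id = internal$exon_id, group = grp,
               chrom = internal$chrom, strand = internal$strand,
               side = ifelse(internal$strand == "+", "downstream",
                             "upstream"),
               start = internal$end,
               end = pmin(internal$end + w, internal$right_bound),
               stringsAsFactors = FALSE))
  win$width <- win$end - win$start
  win <- win[order(win$exon_id, win$side), , drop = FALSE]
  rownames(win) <- NULL

  for (pass in seq_len(6L)) {           # scrub accidental cores
    dirty <- FALSE
    for (i in seq_len(nrow(win))) {
      if (win$width[i] < 5L) next
      s <- read_win(win$chrom[i], win$start[i], win$end[i], win$strand[i])
      hits <- scan_core(s)
      if (length(hits)) {
        for (o in hits) substr(s, o + 3L, o + 3L) <- "G"
        write_win(win$chrom[i], win$start[i], win$end[i], win$strand[i], s)
        dirty <- TRUE
      }
    }
    if (!dirty) break
    if (pass == 6L) stop("window scrubbing did not converge")
  }

  p_plant <- ifelse(win$group == "as", cfg$r_as, cfg$r_control)
  if (cfg$side_bias > 0 && length(as_ids)) {
    dir_of <- direction[win$exon_id]
    adj <- ifelse(win$group == "as" & !is.na(dir_of),
                  ifelse((dir_of == "higher_inclusion") ==
                           (win$side == "upstream"),
                         cfg$side_bias, -cfg$side_bias), 0)
    p_plant <- pmin(1, pmax(0, p_plant + adj))
  }
  win$planted <- runif(nrow(win)) < p_plant & win$width >= 10L
  win$offset <- rep(NA_integer_, nrow(win))
  for (i in which(win$planted)) {
    s <- read_win(win$chrom[i], win$start[i], win$end[i], win$strand[i])
    pre <- scan_core(s)
    done <- FALSE
    for (try in seq_len(30L)) {
      o <- rint(0L, win$width[i] - 5L)
      s2 <- s
      substr(s2, o + 1L, o + 5L) <- "ACTAA"
      if (setequal(setdiff(scan_core(s2), pre), o)) {
        write_win(win$chrom[i], win$start[i], win$end[i], win$strand[i], s2)
        win$offset[i] <- o
        done <- TRUE
        break
      }
    }
    if (!done) win$planted[i] <- FALSE
  }
  win$has_core <- vapply(seq_len(nrow(win)), function(i) {
    length(scan_core(read_win(win$chrom[i], win$start[i], win$end[i],
                              win$strand[i]))) > 0L
  }, logical(1))

  # ---- QRE region ---------------------------------------------------------
  qre_truth <- NULL
  if (!is.null(region)) {
    rseq <- read_win(region$chrom, region$start, region$end, region$strand)
    for (pass in seq_len(10L)) {        # scrub <=1-mismatch QRE hits
      hits <- scan_qre(rseq, max_mismatch = 1L)
      if (nrow(hits) == 0L) break
      for (o in unique(hits$offset)) {
        substr(rseq, o + 3L, o + 4L) <- "GG"
      }
      if (pass == 10L) stop("QRE region scrubbing did not converge")
    }
    qre_truth <- plant_qres(rseq, cfg)
    rseq <- qre_truth$seq
    write_win(region$chrom, region$start, region$end, region$strand, rseq)
    got <- scan_qre(rseq, max_mismatch = 1L)
    want <- qre_truth$hits[order(qre_truth$hits$offset), ]
    if (!identical(got[, c("offset", "spacer_len", "mismatches")],
                   want[, c("offset", "spacer_len", "mismatches")])) {
      stop("QRE planting failed verification")
    }
    # genomic coordinates of the planted hits
    len <- 10L + want$spacer_len
    if (region$strand == "+") {
      want$start <- region$start + want$offset
      want$end <- want$start + len
    } else {
      want$end <- region$end - want$offset
      want$start <- want$end - len
    }
    qre_truth <- list(region = region, hits = want)
  }

  # ---- rMATS tables -------------------------------------------------------
  look <- function(ids, col) {
    internal[[col]][match(ids, internal$exon_id)]
  }
  tx_flank <- function(ids) {
    # transcript-oriented flanking exon coordinates from the master chain
    i <- match(ids, internal$exon_id)
    gidx <- paste(internal$gene_id[i], internal$idx[i])
    prev <- match(paste(internal$gene_id[i], internal$idx[i] - 1L),
                  paste(chain$gene_id, chain$idx))
    nxt <- match(paste(internal$gene_id[i], internal$idx[i] + 1L),
                 paste(chain$gene_id, chain$idx))
    minus <- internal$strand[i] == "-"
    data.frame(
      up_s = ifelse(minus, chain$start[nxt], chain$start[prev]),
      up_e = ifelse(minus, chain$end[nxt], chain$end[prev]),
      dn_s = ifelse(minus, chain$start[prev], chain$start[nxt]),
      dn_e = ifelse(minus, chain$end[prev], chain$end[nxt]))
  }

  sig_ids <- c(as_ids, rm_only_ids)
  n_sig <- length(sig_ids)
  vclass <- if (n_sig) {
    resample(c("both", "jc", "jcec"), n_sig, replace = TRUE,
             prob = c(cfg$variant_both, (1 - cfg$variant_both) / 2,
                      (1 - cfg$variant_both) / 2))
  } else character(0)
  inc_sig <- runif(n_sig, 0.1, 0.6)
  dir_sig <- c(direction[as_ids],
               resample(c("higher_inclusion", "higher_exclusion"),
                        length(rm_only_ids), replace = TRUE))
  inc_sig <- ifelse(dir_sig == "higher_inclusion", inc_sig, -inc_sig)

  null_ids <- pool_ids[runif(length(pool_ids)) < cfg$null_rmats_frac]
  se_rows <- function(variant) {
    keep_sig <- vclass == "both" | vclass == variant
    ids <- c(sig_ids[keep_sig], null_ids)
    if (length(ids) == 0L) return(NULL)
    fl <- tx_flank(ids)
    p <- c(runif(sum(keep_sig), cfg$sig_p[1], cfg$sig_p[2]),
           runif(length(null_ids), cfg$null_p[1], cfg$null_p[2]))
    inc <- c(inc_sig[keep_sig], runif(length(null_ids), -0.05, 0.05))
    data.frame(
      GeneID = look(ids, "gene_id"), chr = look(ids, "chrom"),
      strand = look(ids, "strand"),
      exonStart_0base = look(ids, "start"), exonEnd = look(ids, "end"),
      upstreamES = fl$up_s, upstreamEE = fl$up_e,
      downstreamES = fl$dn_s, downstreamEE = fl$dn_e,
      PValue = p, FDR = p, IncLevelDifference = inc,
      stringsAsFactors = FALSE)
  }
  finish_tab <- function(df, type) {
    if (is.null(df)) {
      df <- data.frame(GeneID = character(0), chr = character(0),
                       strand = character(0), PValue = numeric(0),
                       FDR = numeric(0), IncLevelDifference = numeric(0),
                       stringsAsFactors = FALSE)
      for (col in unname(rmats_coord_map[[type]])) df[[col]] <- integer(0)
    }
    cbind(ID = seq_len(nrow(df)), df[, 1, drop = FALSE],
          geneSymbol = df$GeneID, df[, -1, drop = FALSE])
  }

  other <- make_other_events(cfg, internal, chain, pool_ids)

  rmats <- list(SE = list(jc = finish_tab(se_rows("jc"), "SE"),
                          jcec = finish_tab(se_rows("jcec"), "SE")))
  for (ty in names(other$tables)) {
    rmats[[ty]] <- list(jc = finish_tab(other$tables[[ty]], ty),
                        jcec = finish_tab(other$tables[[ty]], ty))
  }

  # ---- DEXSeq table and coverage ------------------------------------------
  ex <- catalog$exons
  padj <- runif(nrow(ex), 0.2, 0.99)
  sig_dx <- ex$exon_id %in% c(as_ids, dx_only_ids, dx_term_ids)
  padj[sig_dx] <- runif(sum(sig_dx), 1e-6, 0.01)
  ctrl_dx <- ex$exon_id %in% control_intended
  padj[ctrl_dx] <- runif(sum(ctrl_dx), 0.9901, 0.9999)
  bin_seq <- stats::ave(seq_len(nrow(ex)), ex$gene_id, FUN = seq_along)
  dexseq <- data.frame(
    gene_id = ex$gene_id, bin_id = sprintf("E%03d", bin_seq),
    chrom = ex$chrom, start = ex$start + 1L, end = ex$end,
    strand = ex$strand, pvalue = padj, padj = padj,
    stringsAsFactors = FALSE)

  gene_ids <- unique(ex$gene_id)
  gene_cov <- setNames(rlnorm(length(gene_ids), log(8), 0.8), gene_ids)
  coverage <- data.frame(
    exon_id = ex$exon_id, gene_id = ex$gene_id,
    exon_cov_per_nt = rlnorm(nrow(ex), log(5), 1),
    gene_cov_per_nt = unname(gene_cov[ex$gene_id]),
    stringsAsFactors = FALSE)

  # ---- ground truth -------------------------------------------------------
  ev_ids <- c(as_ids, rm_only_ids, dx_only_ids, dx_term_ids)
  ev_group <- c(rep("both", length(as_ids)),
                rep("rmats_only", length(rm_only_ids)),
                rep("dexseq_only", length(dx_only_ids) +
                      length(dx_term_ids)))
  ev_dir <- c(direction[as_ids], dir_sig[seq_along(rm_only_ids) +
                                           length(as_ids)],
              rep(NA_character_, length(dx_only_ids) + length(dx_term_ids)))
  exm <- match(ev_ids, ex$exon_id)
  truth_events <- data.frame(
    exon_id = ev_ids, gene_id = ex$gene_id[exm], chrom = ex$chrom[exm],
    strand = ex$strand[exm], exon_start = ex$start[exm],
    exon_end = ex$end[exm], group = ev_group, direction = ev_dir,
    sig_rmats = ev_group %in% c("both", "rmats_only"),
    sig_dexseq = ev_group %in% c("both", "dexseq_only"),
    both_significant = ev_group == "both",
    stringsAsFactors = FALSE)
  rownames(truth_events) <- NULL

  truth <- list(events = truth_events, windows = win,
                control_pool = control_intended, qre = qre_truth,
                other_events = other$truth)

  genome <- Biostrings::DNAStringSet(vapply(seqs, rawToChar, character(1)))
  names(genome) <- names(seqs)

  structure(list(genome = genome, instances = instances, catalog = catalog,
                 rmats = rmats, dexseq = dexseq, coverage = coverage,
                 truth = truth, config = cfg),
            class = "synthetic_dataset")
}

# compose and place the planted QREs in the (already scrubbed) region
# sequence; spacers and 26-nt pads are drawn from {C,G} so that no
# unintended half-site can form within reach of a planted half-site
plant_qres <- function(rseq, cfg) {
  n <- cfg$n_qres
  L <- nchar(rseq)
  slot_w <- L %/% n
  stopifnot(slot_w >= 95L)
  rows <- vector("list", n)
  for (q in seq_len(n)) {
    spacer_len <- rint(1L, 20L)
    total <- 10L + spacer_len
    need <- 26L + total + 26L
    slot0 <- (q - 1L) * slot_w
    off_in <- rint(0L, slot_w - need)
    core0 <- slot0 + off_in + 26L
    y1 <- resample(c("C", "T")); y2 <- resample(c("C", "T"))
    spacer <- paste(resample(c("C", "G"), spacer_len, replace = TRUE),
                    collapse = "")
    qstr <- paste0("ACTAA", y1, spacer, "TAA", y2)
    mm <- 0L
    if (runif(1) < cfg$qre_mismatch_frac) {
      pos <- rint(1L, 10L)
      idx <- if (pos <= 6L) pos else 6L + spacer_len + (pos - 6L)
      substr(qstr, idx, idx) <- "G"
      mm <- 1L
    }
    lpad <- paste(resample(c("C", "G"), 26L, replace = TRUE), collapse = "")
    rpad <- paste(resample(c("C", "G"), 26L, replace = TRUE), collapse = "")
    block <- paste0(lpad, qstr, rpad)
    substr(rseq, core0 - 26L + 1L, core0 + total + 26L) <- block
    rows[[q]] <- data.frame(offset = core0, spacer_len = spacer_len,
                            mismatches = mm)
  }
  hits <- do.call(rbind, rows)

  # pads cannot interact with planted half-sites, but writing a pad can
  # complete a background half-site that straddles the pad boundary; repair
  # such spurious hits by G-mutating their constrained positions outside
  # every planted footprint (G never creates a motif, so this converges)
  protected <- unlist(lapply(seq_len(n), function(q) {
    hits$offset[q] + seq_len(10L + hits$spacer_len[q]) - 1L
  }))
  want_key <- paste(hits$offset, hits$spacer_len)
  for (pass in seq_len(20L)) {
    got <- scan_qre(rseq, max_mismatch = 1L)
    extra <- got[!paste(got$offset, got$spacer_len) %in% want_key, ,
                 drop = FALSE]
    if (nrow(extra) == 0L) break
    if (pass == 20L) stop("QRE region repair did not converge")
    for (i in seq_len(nrow(extra))) {
      pos0 <- c(extra$offset[i] + 0:5,
                extra$offset[i] + 6L + extra$spacer_len[i] + 0:3)
      mutable <- setdiff(pos0, protected)
      if (length(mutable) == 0L) stop("spurious QRE hit inside footprints")
      for (p in mutable) substr(rseq, p + 1L, p + 1L) <- "G"
    }
  }
  list(seq = rseq, hits = hits)
}

# A5SS/A3SS/RI rows in their rMATS column dialects
make_other_events <- function(cfg, internal, chain, pool_ids) {
  empty <- list(tables = list(), truth = NULL)
  counts <- c(A5SS = cfg$n_a5ss, A3SS = cfg$n_a3ss, RI = cfg$n_ri)
  counts <- counts[counts > 0L]
  if (length(counts) == 0L || nrow(internal) == 0L) return(empty)
  pool <- internal[internal$exon_id %in% pool_ids &
                     internal$left_intron >= 60L &
                     internal$right_intron >= 60L, , drop = FALSE]
  n_need <- sum(counts)
  if (nrow(pool) < n_need) counts <- pmin(counts, nrow(pool) %/% 3L)
  if (sum(counts) == 0L) return(empty)
  sel <- pool[sample.int(nrow(pool), sum(counts)), , drop = FALSE]
  sel$type <- rep(names(counts), counts)
  sel$sig <- seq_len(nrow(sel)) %% 2L == 1L   # alternate sig / null
  sel$p <- ifelse(sel$sig, runif(nrow(sel), cfg$sig_p[1], cfg$sig_p[2]),
                  runif(nrow(sel), cfg$null_p[1], cfg$null_p[2]))
  sel$inc <- ifelse(sel$sig, runif(nrow(sel), 0.1, 0.5) *
                      sign(runif(nrow(sel)) - 0.5),
                    runif(nrow(sel), -0.05, 0.05))
  prev <- match(paste(sel$gene_id, sel$idx - 1L),
                paste(chain$gene_id, chain$idx))
  nxt <- match(paste(sel$gene_id, sel$idx + 1L),
               paste(chain$gene_id, chain$idx))
  minus <- sel$strand == "-"
  delta <- pmin(40L, pmax(10L, pmin(sel$left_intron,
                                    sel$right_intron) - 10L))
  tables <- list()
  truths <- list()
  for (ty in names(counts)) {
    r <- sel[sel$type == ty, , drop = FALSE]
    m <- r$strand == "-"
    if (ty == "A5SS") {
      # donor-side extension: genomically right on +, left on -
      long_s <- ifelse(m, r$start - delta[sel$type == ty], r$start)
      long_e <- ifelse(m, r$end, r$end + delta[sel$type == ty])
      fl_i <- ifelse(m, prev[sel$type == ty], nxt[sel$type == ty])
      tab <- data.frame(
        GeneID = r$gene_id, chr = r$chrom, strand = r$strand,
        longExonStart_0base = long_s, longExonEnd = long_e,
        shortES = r$start, shortEE = r$end,
        flankingES = chain$start[fl_i], flankingEE = chain$end[fl_i],
        PValue = r$p, FDR = r$p, IncLevelDifference = r$inc,
        stringsAsFactors = FALSE)
    } else if (ty == "A3SS") {
      long_s <- ifelse(m, r$start, r$start - delta[sel$type == ty])
      long_e <- ifelse(m, r$end + delta[sel$type == ty], r$end)
      fl_i <- ifelse(m, nxt[sel$type == ty], prev[sel$type == ty])
      tab <- data.frame(
        GeneID = r$gene_id, chr = r$chrom, strand = r$strand,
        longExonStart_0base = long_s, longExonEnd = long_e,
        shortES = r$start, shortEE = r$end,
        flankingES = chain$start[fl_i], flankingEE = chain$end[fl_i],
        PValue = r$p, FDR = r$p, IncLevelDifference = r$inc,
        stringsAsFactors = FALSE)
    } else {
      nx <- nxt[sel$type == ty]
      tab <- data.frame(
        GeneID = r$gene_id, chr = r$chrom, strand = r$strand,
        riExonStart_0base = r$start, riExonEnd = chain$end[nx],
        upstreamES = ifelse(m, chain$start[nx], r$start),
        upstreamEE = ifelse(m, chain$end[nx], r$end),
        downstreamES = ifelse(m, r$start, chain$start[nx]),
        downstreamEE = ifelse(m, r$end, chain$end[nx]),
        PValue = r$p, FDR = r$p, IncLevelDifference = r$inc,
        stringsAsFactors = FALSE)
    }
    tables[[ty]] <- tab
    truths[[ty]] <- data.frame(type = ty, exon_id = r$exon_id,
                               significant = r$sig,
                               stringsAsFactors = FALSE)
  }
  list(tables = tables, truth = do.call(rbind, truths))
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", length(x$genome), "chromosome(s),",
      sum(IRanges::width(x$genome)), "bp;",
      nrow(x$catalog$exons), "exons;",
      sum(x$truth$events$both_significant), "planted both-tool events\n")
  invisible(x)
}
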