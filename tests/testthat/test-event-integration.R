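# rMATS/DEXSeq readers, variant merging, stringent and comprehensive sets.

write_tsv <- function(df, ext = ".txt") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

se_table <- function(n, chrom = "chr1", strand = "+", p = NULL) {
  start <- as.integer(seq(1000L, by = 2000L, length.out = n))
  data.frame(ID = seq_len(n), GeneID = sprintf("G%03d", seq_len(n)),
             geneSymbol = sprintf("G%03d", seq_len(n)),
             chr = rep(chrom, length.out = n),
             strand = rep(strand, length.out = n),
             exonStart_0base = start, exonEnd = start + 150L,
             upstreamES = start - 500L, upstreamEE = start - 300L,
             downstreamES = start + 450L, downstreamEE = start + 650L,
             PValue = p %||% runif(n), FDR = p %||% runif(n),
             IncLevelDifference = round(runif(n, -0.5, 0.5), 3),
             stringsAsFactors = FALSE)
}

test_that("rMATS reader keeps 0-based starts and rejects bad p-values", {
  tab <- se_table(3)
  tab$exonStart_0base[1] <- 999L
  tab$exonEnd[1] <- 1100L
  f <- write_tsv(tab)
  ev <- read_rmats(f, "SE", "jc")
  expect_equal(ev$exon_start[1], 999L)
  expect_equal(ev$exon_end[1], 1100L)
  expect_equal(nrow(ev), 3L)

  tab$PValue[2] <- "NA"
  f2 <- write_tsv(tab)
  expect_warning(ev2 <- read_rmats(f2, "SE", "jc"), "rejected")
  expect_equal(nrow(ev2), 2L)
})

test_that("a header-only rMATS table yields an empty event list", {
  f <- write_tsv(se_table(0))
  ev <- read_rmats(f, "SE", "jcec")
  expect_equal(nrow(ev), 0L)
  expect_true(all(c("event_type", "pvalue", "fdr") %in% names(ev)))
})

test_that("rMATS rows match an independent line parser field by field", {
  withr::with_seed(77, {
    tab <- se_table(100, strand = sample(c("+", "-"), 100, replace = TRUE))
  })
  f <- write_tsv(tab)
  ev <- read_rmats(f, "SE", "jc")
  # naive parser: split raw lines on tabs, index by header position
  lines <- readLines(f)
  hdr <- strsplit(lines[1], "\t")[[1]]
  fields <- strsplit(lines[-1], "\t")
  col <- function(name) vapply(fields, `[[`, character(1), match(name, hdr))
  expect_equal(ev$gene_id, col("GeneID"))
  expect_equal(ev$chrom, col("chr"))
  expect_equal(ev$strand, col("strand"))
  expect_equal(ev$exon_start, as.integer(col("exonStart_0base")))
  expect_equal(ev$upstream_end, as.integer(col("upstreamEE")))
  expect_equal(ev$pvalue, as.numeric(col("PValue")))
  expect_equal(ev$inc_level_diff, as.numeric(col("IncLevelDifference")))
})

test_that("variant merging collapses shared keys and keeps both statistics", {
  withr::with_seed(5, {
    jc <- make_events(4, pvalue = c(0.001, 0.2, 0.5, 0.9))
  })
  jcec <- jc
  jcec$variant <- "jcec"
  jcec$pvalue <- c(0.01, 0.1, 0.6, 0.95)
  jcec$fdr <- jcec$pvalue
  merged <- merge_rmats_variants(jc, jcec)
  expect_equal(nrow(merged), 4L)
  expect_true(all(merged$sources == "rmats_jc,rmats_jcec"))
  expect_equal(merged$pvalue, pmin(merged$pvalue_jc, merged$pvalue_jcec))
  # disjoint coordinates stay distinct
  jc2 <- jc
  jc2$exon_start <- jc2$exon_start + 10L
  merged2 <- merge_rmats_variants(jc2, jcec)
  expect_equal(nrow(merged2), 8L)
})

test_that("an event is putative when either variant is below the FDR cut", {
  jc <- make_events(2, pvalue = c(0.4, 0.4), fdr = c(0.4, 0.4))
  jcec <- jc
  jcec$variant <- "jcec"
  jcec$fdr <- c(0.01, 0.4)
  merged <- merge_rmats_variants(jc, jcec)
  expect_equal(merged$putative, c(TRUE, FALSE))
})

test_that("merged event count equals a brute-force grouping oracle", {
  withr::with_seed(42, {
    for (i in 1:5) {
      a <- make_events(60)
      b <- make_events(60)
      b$variant <- "jcec"
      # force overlap between the variants
      swap <- sample.int(60, 30)
      b[swap, c("exon_start", "exon_end", "upstream_start", "upstream_end",
                "downstream_start", "downstream_end")] <-
        a[swap, c("exon_start", "exon_end", "upstream_start",
                  "upstream_end", "downstream_start", "downstream_end")]
      merged <- merge_rmats_variants(a, b)
      key <- function(df) paste(df$event_type, df$chrom, df$strand,
                                df$exon_start, df$exon_end,
                                df$upstream_start, df$upstream_end,
                                df$downstream_start, df$downstream_end)
      expect_equal(nrow(merged), length(unique(c(key(a), key(b)))))
      # re-merging the same inputs is deterministic
      expect_identical(merge_rmats_variants(a, b), merged)
    }
  })
})

test_that("conflicting strands on identical coordinates are an error", {
  jc <- make_events(1, strand = "+")
  jcec <- jc
  jcec$variant <- "jcec"
  jcec$strand <- "-"
  expect_error(merge_rmats_variants(jc, jcec), "strand")
})

test_that("inclusion sign convention fixes the direction and can be flipped", {
  jc <- make_events(2)
  jc$inc_level_diff <- c(0.3, -0.2)
  merged <- merge_rmats_variants(jc, jc[0, ])
  expect_equal(merged$direction[order(merged$inc_level_diff,
                                      decreasing = TRUE)],
               c("higher_inclusion", "higher_exclusion"))
  flipped <- merge_rmats_variants(jc, jc[0, ], flip_sign = TRUE)
  expect_equal(sort(flipped$direction),
               sort(c("higher_exclusion", "higher_inclusion")))
  expect_equal(sum(flipped$inc_level_diff), -sum(merged$inc_level_diff))
})

test_that("DEXSeq bins convert coordinates and flag the 15-nt length rule", {
  tab <- data.frame(gene_id = c("g1", "g2", "g3"),
                    bin_id = c("E001", "E001", "E001"),
                    chrom = "chr1", start = c(100L, 200L, 300L),
                    end = c(113L, 214L, 400L), strand = "+",
                    pvalue = c(0.01, 0.01, 0.5),
                    padj = c(0.01, 0.01, 0.5))
  f <- write_tsv(tab, ".tsv")
  bins <- read_dexseq(f)
  expect_equal(bins$start, c(99L, 199L, 299L))   # 1-based in, 0-based out
  expect_equal(bins$length, c(14L, 15L, 101L))
  expect_equal(bins$eligible, c(FALSE, TRUE, TRUE))
})

test_that("DEXSeq eligibility flags equal an independent length check", {
  withr::with_seed(9, {
    n <- 200L
    start1 <- sample.int(100000L, n)
    len <- sample(5:60, n, replace = TRUE)
    tab <- data.frame(groupID = sprintf("g%d", seq_len(n)),
                      featureID = "E001", seqnames = "chr2",
                      start = start1, end = start1 + len - 1L,
                      strand = "+", padj = runif(n))
  })
  f <- write_tsv(tab, ".tsv")
  bins <- read_dexseq(f)                        # DEXSeq-native column names
  expect_equal(bins$eligible, (tab$end - tab$start + 1L) >= 15L)
  expect_error(read_dexseq(write_tsv(tab[, -4])), "required columns")
})

test_that("stringent intersection keeps 1-bp overlaps and needs both tools", {
  ev <- make_events(1, pvalue = 0.001, fdr = 0.001)
  ev$exon_start <- 999L
  ev$exon_end <- 1100L
  merged <- merge_rmats_variants(ev, ev[0, ])
  bins <- data.frame(gene_id = "g1", bin_id = "E001", chrom = "chr1",
                     start = 1099L, end = 1200L, strand = "+",
                     pvalue = 0.001, padj = 0.001, length = 101L,
                     eligible = TRUE)
  got <- build_stringent(merged, bins)
  expect_equal(nrow(got$events), 1L)            # exactly 1 bp of overlap
  # non-significant bins never support an event
  bins$padj <- 0.5
  expect_equal(nrow(build_stringent(merged, bins)$events), 0L)
  # touching but non-overlapping intervals do not count
  bins$padj <- 0.001
  bins$start <- 1100L
  expect_equal(nrow(build_stringent(merged, bins)$events), 0L)
})

test_that("stringent membership equals a naive all-pairs overlap oracle", {
  withr::with_seed(1234, {
    for (i in 1:3) {
      ev <- make_events(300, chrom = sample(c("chr1", "chr2"), 300,
                                            replace = TRUE))
      merged <- merge_rmats_variants(ev, ev[0, ])
      bins <- data.frame(gene_id = "g", bin_id = "E",
                         chrom = sample(c("chr1", "chr2"), 300,
                                        replace = TRUE),
                         start = sample.int(500000L, 300),
                         strand = "+", pvalue = runif(300),
                         padj = runif(300))
      bins$end <- bins$start + sample(20:300, 300, replace = TRUE)
      bins$length <- bins$end - bins$start
      bins$eligible <- bins$length >= 15L
      got <- build_stringent(merged, bins)
      sig_ev <- merged[merged$pvalue < 0.05, ]
      sig_bins <- bins[bins$padj < 0.05 & bins$eligible, ]
      want <- sig_ev[oracle_overlap_any(sig_ev, sig_bins), ]
      expect_setequal(got$events$event_id, want$event_id)
    }
  })
})

test_that("comprehensive union promotes DEXSeq-only bins and contains stringent", {
  ev <- make_events(5, pvalue = c(0.001, 0.03, 0.2, 0.5, 0.9),
                    fdr = c(0.001, 0.2, 0.2, 0.5, 0.9))
  merged <- merge_rmats_variants(ev, ev[0, ])
  # one bin overlapping event 2 (p<0.05, fdr>=0.05), one free-standing
  bins <- data.frame(gene_id = c("gB", "gC"), bin_id = "E001",
                     chrom = "chr1",
                     start = c(merged$exon_start[2] + 1L, 9000000L),
                     end = c(merged$exon_start[2] + 60L, 9000100L),
                     strand = "+", pvalue = 0.001, padj = 0.001,
                     length = c(59L, 100L), eligible = TRUE)
  stringent <- build_stringent(merged, bins)
  comp <- build_comprehensive(merged, bins)
  # stringent <= comprehensive even though event 2 fails the FDR cut
  key <- function(es) paste(es$events$chrom, es$events$exon_start,
                            es$events$exon_end)
  expect_true(all(key(stringent) %in% key(comp)))
  expect_true("dexseq" %in% comp$events$sources)
  # empty significance -> empty set
  none <- merged
  none$pvalue <- none$fdr <- 0.9
  bins0 <- bins
  bins0$padj <- 0.9
  expect_equal(nrow(build_comprehensive(none, bins0)$events), 0L)
})

test_that("comprehensive set is deduplicated by genomic coordinates", {
  ev <- make_events(6, pvalue = rep(0.001, 6), fdr = rep(0.001, 6))
  # duplicate coordinates with alternative flanking exons
  dup <- ev
  dup$upstream_start <- dup$upstream_start - 100L
  merged <- merge_rmats_variants(rbind(ev, dup), ev[0, ])
  expect_equal(nrow(merged), 12L)   # flanks make them distinct events
  comp <- build_comprehensive(merged, data.frame(gene_id = character(0),
                                                 bin_id = character(0),
                                                 chrom = character(0),
                                                 start = integer(0),
                                                 end = integer(0),
                                                 strand = character(0),
                                                 pvalue = numeric(0),
                                                 padj = numeric(0),
                                                 length = integer(0),
                                                 eligible = logical(0)))
  # ... but the final list counts unique exon coordinates once
  expect_equal(nrow(comp$events), 6L)
})

test_that("annotation attaches exon classes and flags the motif universe", {
  inst <- data.frame(
    chrom = "chr1", start = c(100L, 300L, 500L), end = c(200L, 400L, 600L),
    strand = "+", gene_id = "g1", transcript_id = "t1")
  cat1 <- build_exon_catalog(inst)
  ev <- make_events(3)
  ev$event_type <- c("SE", "SE", "RI")
  ev$exon_start <- c(300L, 7000L, 500L)
  ev$exon_end <- c(400L, 7100L, 600L)
  merged <- merge_rmats_variants(ev, ev[0, ])
  eset <- annotate_events(new_set <- qresplice:::new_event_set(
    "stringent", merged), cat1)
  got <- eset$events
  expect_equal(got$exon_class[got$exon_start == 300L], "cassette")
  expect_equal(got$exon_class[got$exon_start == 7000L], "mixed")  # unannotated
  expect_true(is.na(got$exon_class[got$event_type == "RI"]))
  expect_equal(got$in_motif_universe, got$event_type == "SE")
})

test_that("gene counting is over distinct gene ids", {
  ev <- make_events(3)
  ev$gene_id <- "G1"
  expect_equal(count_event_genes(ev), 1L)
  expect_equal(count_event_genes(ev[0, ]), 0L)
  ds <- generate_dataset(small_config(51))
  inp <- dataset_inputs(ds)
  merged <- merge_rmats_variants(inp$jc, inp$jcec)
  expect_equal(count_event_genes(merged), length(unique(merged$gene_id)))
})

test_that("builds do not mutate inputs and exports are reproducible", {
  ds <- generate_dataset(small_config(61))
  inp <- dataset_inputs(ds)
  jc_copy <- inp$jc
  merged <- merge_rmats_variants(inp$jc, inp$jcec)
  s1 <- build_stringent(merged, inp$dexseq)
  expect_identical(inp$jc, jc_copy)
  s2 <- build_stringent(merged, inp$dexseq)
  d <- withr::local_tempdir()
  write_event_set(s1, file.path(d, "a"))
  write_event_set(s2, file.path(d, "b"))
  expect_identical(readLines(file.path(d, "a.tsv")),
                   readLines(file.path(d, "b.tsv")))
})
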