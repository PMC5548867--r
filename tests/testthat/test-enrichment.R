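# Control universe construction and the resampling enrichment test.

test_that("control filters are applied conjunctively with a removal log", {
  ds <- generate_dataset(small_config(91))
  inp <- dataset_inputs(ds)
  merged <- merge_rmats_variants(inp$jc, inp$jcec)
  controls <- build_control_set(inp$catalog, inp$coverage, inp$dexseq,
                                merged)
  ex <- controls$exons
  cat_ex <- inp$catalog$exons
  expect_true(all(ex$class %in% c("cassette", "mixed")))
  expect_true(all(ex$length >= 15L))
  # independent per-filter oracle over the whole catalog
  cand <- cat_ex[cat_ex$class %in% c("cassette", "mixed") &
                   cat_ex$length >= 15L, ]
  cov <- inp$coverage[match(cand$exon_id, inp$coverage$exon_id), ]
  qe <- quantile(cov$exon_cov_per_nt, 0.25, names = FALSE)
  qg <- quantile(cov$gene_cov_per_nt[!duplicated(cand$gene_id)], 0.25,
                 names = FALSE)
  cand <- cand[cov$exon_cov_per_nt > qe & cov$gene_cov_per_nt > qg, ]
  sig_ev <- merged[merged$pvalue < 0.05, ]
  drop_as <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    dx <- inp$dexseq[inp$dexseq$chrom == cand$chrom[i] &
                       inp$dexseq$start < cand$end[i] &
                       inp$dexseq$end > cand$start[i], ]
    if (any(dx$padj <= 0.99)) drop_as[i] <- TRUE
    rm <- sig_ev[sig_ev$chrom == cand$chrom[i] &
                   sig_ev$exon_start < cand$end[i] &
                   sig_ev$exon_end > cand$start[i], ]
    if (nrow(rm)) drop_as[i] <- TRUE
  }
  expect_setequal(ex$exon_id, cand$exon_id[!drop_as])
  expect_equal(sum(controls$filter_log),
               nrow(cat_ex) - nrow(ex))
  # swapping the order of the coverage and non-AS filters (quantile base
  # held fixed on the post-class/length universe) gives the same final set
  cand_all <- cat_ex[cat_ex$class %in% c("cassette", "mixed") &
                       cat_ex$length >= 15L, ]
  cov_all <- inp$coverage[match(cand_all$exon_id, inp$coverage$exon_id), ]
  non_as_first <- cand_all[!oracle_overlap_bins(cand_all, inp$dexseq,
                                                0.99) &
                             !oracle_overlap_events(cand_all, sig_ev), ]
  cov2 <- cov_all[match(non_as_first$exon_id, cov_all$exon_id), ]
  non_as_first <- non_as_first[cov2$exon_cov_per_nt > qe &
                                 cov2$gene_cov_per_nt > qg, ]
  expect_setequal(ex$exon_id, non_as_first$exon_id)
})

test_that("exons below thresholds are excluded from the control universe", {
  inst <- data.frame(
    chrom = "chr1",
    start = c(100L, 300L, 340L, 600L, 1000L),
    end = c(200L, 320L, 500L, 614L, 1100L),   # exon 4 is 14 nt
    strand = "+", gene_id = "g1", transcript_id = "t1")
  cat1 <- build_exon_catalog(inst)
  cov <- data.frame(exon_id = cat1$exons$exon_id, gene_id = "g1",
                    exon_cov_per_nt = 5, gene_cov_per_nt = 5)
  # one internal exon has mid-range adjusted p (not > 0.99): excluded
  dex <- data.frame(gene_id = "g1", bin_id = "E001", chrom = "chr1",
                    start = 340L, end = 500L, strand = "+",
                    pvalue = 0.5, padj = 0.5, length = 160L,
                    eligible = TRUE)
  controls <- build_control_set(cat1, cov, dex, make_events(0),
                                cov_quantile = 0)
  kept <- controls$exons
  expect_false(any(kept$length < 15L))
  expect_false("chr1:340-500:+:g1" %in% kept$exon_id)
  expect_true("chr1:300-320:+:g1" %in% kept$exon_id)
  expect_equal(controls$filter_log[["length"]], 1L)
  expect_equal(controls$filter_log[["not_alternatively_spliced"]], 1L)
})

test_that("candidates with missing coverage are excluded and counted", {
  inst <- data.frame(
    chrom = "chr1", start = c(100L, 300L, 500L, 700L),
    end = c(200L, 400L, 600L, 800L),
    strand = "+", gene_id = "g1", transcript_id = "t1")
  cat1 <- build_exon_catalog(inst)
  cov <- data.frame(exon_id = "chr1:300-400:+:g1", gene_id = "g1",
                    exon_cov_per_nt = 5, gene_cov_per_nt = 5)
  dex0 <- data.frame(gene_id = character(0), bin_id = character(0),
                     chrom = character(0), start = integer(0),
                     end = integer(0), strand = character(0),
                     pvalue = numeric(0), padj = numeric(0),
                     length = integer(0), eligible = logical(0))
  controls <- build_control_set(cat1, cov, dex0, make_events(0),
                                cov_quantile = 0)
  expect_equal(controls$filter_log[["coverage_missing"]], 1L)
  expect_equal(controls$exons$exon_id, "chr1:300-400:+:g1")
})

test_that("plus-one empirical p-value follows the exact formula", {
  res <- motif_enrichment_test(rep(TRUE, 10), rep(FALSE, 1000),
                               n_iter = 1000L, seed = 1L)
  expect_equal(res$observed, 1)
  expect_true(all(res$null_fractions == 0))
  expect_equal(res$p_value, 1 / 1001)
  expect_equal(length(res$null_fractions), 1000L)
})

test_that("p is in (0, 1] and non-increasing in the observed fraction", {
  withr::with_seed(11, cflags <- runif(400) < 0.3)
  ps <- vapply(0:20, function(k) {
    motif_enrichment_test(c(rep(TRUE, k), rep(FALSE, 20 - k)), cflags,
                          n_iter = 300L, seed = 99L)$p_value
  }, numeric(1))
  expect_true(all(ps > 0 & ps <= 1))
  expect_true(all(diff(ps) <= 0))      # same seed => same null each time
})

test_that("the resampling test is deterministic given the seed", {
  withr::with_seed(12, {
    eflags <- runif(50) < 0.4
    cflags <- runif(300) < 0.2
  })
  a <- motif_enrichment_test(eflags, cflags, n_iter = 200L, seed = 7L)
  b <- motif_enrichment_test(eflags, cflags, n_iter = 200L, seed = 7L)
  expect_identical(a, b)
  c <- motif_enrichment_test(eflags, cflags, n_iter = 200L, seed = 8L)
  expect_false(identical(a$null_fractions, c$null_fractions))
})

test_that("degenerate inputs raise configuration errors", {
  expect_error(motif_enrichment_test(rep(TRUE, 10), rep(TRUE, 5)),
               "fewer control exons")
  expect_error(motif_enrichment_test(TRUE, TRUE, n_iter = 0L), "n_iter")
})

test_that("the test is calibrated when events are drawn from the controls", {
  # null replicates: event flags are a random sample of the control pool
  withr::with_seed(2024, {
    cflags <- runif(400) < 0.25
    n_rep <- 200L
    rejected <- vapply(seq_len(n_rep), function(i) {
      eflags <- sample(cflags, 40)
      motif_enrichment_test(eflags, cflags, n_iter = 500L,
                            seed = 10000L + i)$p_value <= 0.05
    }, logical(1))
  })
  rate <- mean(rejected)
  bound <- 0.05 + 2 * sqrt(0.05 * 0.95 / n_rep)
  expect_lte(rate, bound)      # super-uniform or uniform, never liberal
})

test_that("run_subsets covers all six subsets reproducibly", {
  ds <- generate_dataset(small_config(95, n_as_events = 24))
  inp <- dataset_inputs(ds)
  merged <- merge_rmats_variants(inp$jc, inp$jcec)
  stringent <- annotate_events(build_stringent(merged, inp$dexseq),
                               inp$catalog)
  comprehensive <- build_comprehensive(merged, inp$dexseq, inp$catalog)
  controls <- build_control_set(inp$catalog, inp$coverage, inp$dexseq,
                                merged)
  res <- run_subsets(stringent, comprehensive, controls, inp$genome,
                     n_iter = 200L, seed = 42L)
  expect_named(res, c("stringent.all", "stringent.higher_inclusion",
                      "stringent.higher_exclusion", "comprehensive.all",
                      "comprehensive.higher_inclusion",
                      "comprehensive.higher_exclusion"))
  res2 <- run_subsets(stringent, comprehensive, controls, inp$genome,
                      n_iter = 200L, seed = 42L)
  expect_identical(enrichment_summary(res), enrichment_summary(res2))
  # observed fractions equal a direct recount from per-event flags
  uni <- stringent$events[stringent$events$in_motif_universe, ]
  flags <- event_has_core(flanking_windows(uni, inp$genome,
                                           ds$config$window_size))
  expect_equal(res$stringent.all$observed,
               mean(flags$any_hit[match(uni$event_id, flags$id)]))
  inc <- uni[!is.na(uni$direction) & uni$direction == "higher_inclusion", ]
  expect_equal(res$stringent.higher_inclusion$observed,
               mean(flags$any_hit[match(inc$event_id, flags$id)]))
})

test_that("an empty direction subset is flagged not-computed", {
  ds <- generate_dataset(small_config(96, n_as_events = 10,
                                      prop_inclusion = 1))
  inp <- dataset_inputs(ds)
  merged <- merge_rmats_variants(inp$jc, inp$jcec)
  stringent <- annotate_events(build_stringent(merged, inp$dexseq),
                               inp$catalog)
  comprehensive <- build_comprehensive(merged, inp$dexseq, inp$catalog)
  controls <- build_control_set(inp$catalog, inp$coverage, inp$dexseq,
                                merged)
  res <- run_subsets(stringent, comprehensive, controls, inp$genome,
                     n_iter = 50L, seed = 5L)
  expect_false(res$stringent.higher_exclusion$computed)
  expect_true(is.na(res$stringent.higher_exclusion$p_value))
  expect_true(res$stringent.higher_inclusion$computed)
})
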