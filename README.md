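# qresplice

Alternative-splicing event integration and QKI response element (QRE) motif
enrichment.

## What it does and for whom

When an RNA-binding protein such as QKI is removed (for example in
oligodendrocyte-specific knockout brain), differential splicing analyses
produce two call sets of very different character: a junction-count event
caller (rMATS-style, with its JC and JC+ROT/JCEC quantification variants)
and an exon-bin usage test (DEXSeq-style). `qresplice` is for
transcriptomics analysts who need to:

- merge the two rMATS variants into unique events and combine them with
  DEXSeq bins into a **stringent** (intersection by genomic location) and a
  **comprehensive** (union) event set;
- classify target exons against a GTF as **cassette** (internal in every
  isoform), **mixed** (internal in at least one), or first/last-in-all
  (excluded, since promoter/terminator usage is not splicing);
- scan 200-nt intronic windows flanking each skipped exon for the QKI core
  motif `ACUAA`, and whole regions for the full bipartite QRE
  `ACUAAY-(N1–20)-UAAY` (Y = C/U) with up to one mismatch over the 10
  constrained positions;
- test motif enrichment against a resampled, coverage-matched universe of
  non-alternatively-spliced control exons, with the plus-one empirical
  p-value `(1 + #{null ≥ observed}) / (1 + n_iter)` over 1,000 iterations.

A deterministic synthetic-data generator emulates all five inputs (genome
FASTA, GTF, rMATS/DEXSeq tables, coverage) with planted ground truth, so
the whole pipeline is testable end to end.

## Worked example

```r
library(qresplice)

cfg <- synthetic_config(seed = 7)      # 200 genes, 150 planted SE events
ds  <- generate_dataset(cfg)
rep <- end_to_end_check(ds, n_iter = 1000, seed = 3)
rep
```

```
end-to-end report
  merged rMATS events:   463 
  stringent events:      150 
  comprehensive events:  182 
  event genes:           106 
  planted recovery:      100.0% (of 150 planted)
  control exons:         293 
  QRE region: 24 planted, 24 found, exact = TRUE
  enrichment:
                         subset computed n_events observed_pct null_mean_pct
                  stringent.all     TRUE      150     40.00000      23.53800
     stringent.higher_inclusion     TRUE       71     46.47887      23.47042
     stringent.higher_exclusion     TRUE       79     34.17722      23.67975
              comprehensive.all     TRUE      168     37.50000      23.59881
 comprehensive.higher_inclusion     TRUE       75     44.00000      23.34133
 comprehensive.higher_exclusion     TRUE       87     34.48276      23.53908
     p_value n_iter       seed
 0.000999001   1000  721735354
 0.000999001   1000 1653298151
 0.011988012   1000  438540986
 0.000999001   1000  535251819
 0.000999001   1000  333357448
 0.000999001   1000   51609930
```

Reading the output: 150 events were planted as significant in *both* tools
and all of them survive the stringent intersection ("planted recovery
100%"). 40% of stringent skipped-exon events carry `ACUAA` in a flanking
window versus ~23.5% of size-matched control draws, and the empirical
p-value sits at its floor 1/1001 ≈ 0.001 — the "p < 0.001" regime. The
effect is strongest in the higher-inclusion (QKI-repressed) subset, and the
24 QREs planted in the dedicated 3′-style region are recovered exactly by
the ≤1-mismatch region scan.

Individual stages are ordinary functions: `parse_gtf()`,
`read_rmats()`/`read_dexseq()`, `merge_rmats_variants()`,
`build_stringent()`/`build_comprehensive()`, `annotate_events()`,
`flanking_windows()`/`scan_core()`/`scan_qre()`/`scan_region_qre()`,
`build_control_set()`/`run_subsets()`. A thin command-line wrapper with
`simulate`, `integrate`, `scan-region` and `enrich` subcommands is at
`inst/scripts/qresplice-cli.R`. The methods vignette
(`vignettes/qresplice-methods.Rmd`) documents the model, conventions and
generator design.

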