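---
title: "Splicing event integration and QRE motif enrichment: methods"
author: "qresplice authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splicing event integration and QRE motif enrichment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qresplice)
```

## The analysis problem

QKI proteins are KH-domain RNA-binding proteins that regulate pre-mRNA
splicing, prominently in oligodendrocytes, by binding the bipartite QKI
response element (QRE): a core half-site `ACUAAY` separated from a second
half-site `UAAY` by an unconstrained spacer of 1–20 nt, with `Y` a
pyrimidine. When QKI is lost, exons it represses are included more and exons
it activates are included less. A standard computational strategy to connect
such splicing changes to direct binding is:

1. call differential splicing with two complementary tools — a
   junction-count event caller (rMATS-style, run in both its JC and JC+ROT
   ("JCEC") quantification variants) and an exon-bin usage test
   (DEXSeq-style);
2. intersect the two call sets by genomic location into a *stringent* event
   list, and union them into a *comprehensive* list;
3. restrict skipped-exon (SE) events to *cassette* or *mixed* exons using a
   transcript annotation, discarding exons that are first or last in every
   isoform (promoter/terminator usage is not splicing);
4. scan 200-nt intronic windows flanking each target exon for the minimal
   core `ACUAA`;
5. compare the fraction of motif-bearing events against repeated
   size-matched draws from a universe of well-expressed,
   non-alternatively-spliced control exons, giving an empirical p-value.

`qresplice` implements this pipeline with a fully synthetic data generator
so that every stage can be validated against planted ground truth.

## Exon classification

The annotation model is an exon catalog built from GTF exon features
(1-based inclusive on disk, 0-based half-open internally). Exons with
identical coordinates within a gene are merged, pooling their transcript
memberships. Classification is per (exon, gene):

* **cassette** — internal (neither first nor last) in *every* containing
  transcript;
* **mixed** — internal in at least one transcript, terminal in at least one;
* **first_last** — terminal in all.

"First" and "last" are transcriptional, so the assignment is strand-aware; a
single-exon transcript counts its exon as both first and last. Exons shared
by overlapping genes are treated as per-gene copies because the rule is
phrased over the isoforms of one gene. Events absent from the annotation are
conservatively counted as *mixed* (they cannot be shown to be terminal in
all isoforms), which keeps them in the motif universe.

## Event integration

The two rMATS quantification variants are merged on the full event key —
event type, chromosome, strand and all defining coordinates including the
flanking exons — so alternative flanking structures remain distinct events.
Both variants' statistics are retained; the headline p-value is the minimum
of the two, with the winning variant recorded. The inclusion-level
difference is PSI(knockout) − PSI(control), so `direction =
higher_inclusion` means QKI-repressed; because the sign depends on how the
source tables ordered the sample groups, a `flip_sign` switch is exposed.

The **stringent** set keeps merged events with rMATS p < 0.05 whose target
exon overlaps (≥ 1 bp, same chromosome, strand ignored by default as in a
default-settings BED intersect) at least one DEXSeq bin of length ≥ 15 nt
with adjusted p < 0.05, keeping the rMATS record and deduplicating by
target-exon coordinates. The **comprehensive** set is the union of rMATS
events at FDR < 0.05 and significant DEXSeq bins, the latter promoted to
SE-like records when no rMATS event covers them. Two filter conventions
deserve a note:

* The stringent rMATS filter uses the raw p-value and the union uses the
  FDR. These thresholds do not nest, so the naive union would not contain
  the intersection; `build_comprehensive()` therefore unions in the
  intersection events explicitly, making stringent ⊆ comprehensive an
  invariant rather than an accident of thresholds. Both thresholds are
  arguments.
* For the control universe (below), the non-alternatively-spliced criterion
  is implemented as rMATS p > 0.05. A control set *required* to be
  rMATS-significant would contradict its own definition, so the package
  fixes the convention in the direction that makes the statistic meaningful;
  the threshold is configurable.

## Motif scanning

All scanning happens on the transcribed strand with RNA templates held as
DNA (U ≡ T). `scan_core()` reports every exact `ACTAA` offset, overlapping
occurrences included; `N` never matches, and ambiguity codes other than `N`
are rejected rather than guessed. `scan_qre()` enumerates every
(offset, spacer length) pair of the bipartite element and counts mismatches
over the 10 constrained half-site positions only; a `Y` position mismatches
when the base is not a pyrimidine, and relaxing both `Y` positions counts as
two mismatches. The default budget is one mismatch, matching the convention
that a functional QRE is a perfect match or differs by a single
substitution. Hits are monotone in the mismatch budget and in the spacer
range, which the tests assert as properties.

Flanking windows abut the target exon's splice sites and extend up to 200 nt
into the adjacent intron. Windows are clipped at the neighbouring exon
boundary — shorter introns give shorter windows, never padded and never
crossing into exons — and at chromosome ends. On the minus strand the
transcript-upstream window is genomically rightward and sequences are
reverse-complemented. Event-level presence is "either side has ≥ 1 core
hit", the side-agnostic headline statistic; per-side flags feed a positional
contingency of motif side against inclusion direction, since QKI-repressed
exons tend to carry the element upstream and QKI-activated exons downstream.

`scan_region_qre()` applies the QRE scan to an arbitrary genomic region
(for example the 3′ alternatively spliced region of *qkI* itself, whose
boundaries must be supplied by the user) and maps hits back to genomic
coordinates with BED export.

## Control universe and enrichment test

Control exons are built by conjunctive filters in a fixed order, each step
logged: (1) cassette or mixed class; (2) length ≥ 15 nt; (3) exon *and*
gene coverage, normalised per nt, strictly above the 25th percentile —
quantiles are computed over the candidate universe remaining after the
class and length filters (gene coverage over distinct genes), a base that
must be pinned down for reproducibility because the description "above the
lowest quartile" does not specify it; candidates without a coverage record
are excluded and counted separately; (4) not alternatively spliced: no
overlap with a DEXSeq bin of adjusted p ≤ 0.99 nor with an rMATS event of
p < 0.05.

The enrichment test draws, in each of `n_iter = 1000` iterations, as many
control exons as there are events (without replacement within an
iteration), recomputes the motif-bearing fraction, and reports

> p = (1 + #{null ≥ observed}) / (1 + n_iter),

the plus-one empirical p-value, which cannot be zero and whose floor
1/1001 ≈ 0.001 corresponds to the conventional "p < 0.001" at 1000
iterations. Because the sample size equals the number of events, observed
and null fractions share a denominator and the ≥ comparison involves no
floating-point tolerance issues. The test is run for six subsets —
{stringent, comprehensive} × {all SE, higher inclusion, higher exclusion} —
against a shared control universe, with per-subset seeds drawn from a
master seed through a documented splitting rule (`derive_seeds()`), so the
whole analysis is bit-reproducible while subsets remain independent.

## The synthetic data generator

`generate_dataset()` emits a genome (≤ 2 chromosomes, around 1 Mb at
defaults), a GTF with 1–3 transcripts per gene over a master exon chain of
4–9 exons, rMATS-style tables in both variants, a DEXSeq-style bin table, a
length-normalised coverage table, and a ground-truth record. Design points:

* **Exact motif ground truth.** Every controlled flanking window is first
  scrubbed of accidental `ACTAA` occurrences, then a motif is planted with
  the configured per-window probability (`r_as` for event exons, default
  0.25; `r_control` for background exons, default 0.10 — at two windows per
  event these defaults give event-level rates near 45% versus a high-teens
  background, the regime the method is meant to detect). All base
  replacements use `G`, which occurs in neither `ACTAA` nor `TAAY`, so
  destroying a motif can never create one and the scrub/plant loops
  converge.
* **Isolated event windows.** Event exons are drawn only from internal
  exons whose two adjacent introns are each at least twice the window
  size, so event windows never share sequence with any other controlled
  window and realized presence equals the Bernoulli planting record
  exactly. Short introns (15% of introns, 60–200 nt) stay in the catalog
  and control pool to exercise window clipping; their overlapping windows
  can cross-contaminate, which the ground truth records as realized
  (`has_core`) flags and which can only bias the enrichment test
  conservatively.
* **Planted significance.** Significant rows draw p from U(0, 0.01) and
  null rows from U(0.2, 1), with the FDR column mirroring p — thresholds,
  not distributions, drive the pipeline. Events are significant in both
  variants with probability 0.8 (the rest split JC-only/JCEC-only), and
  extra single-tool events plus DEXSeq-only terminal-exon bins exercise the
  union logic and the terminal-exon exclusion. A handful of A5SS/A3SS/RI
  rows cover the non-SE dialects.
* **QRE region.** A dedicated intergenic region carries 24 planted QREs
  (mirroring the count reported for the *qkI* 3′ region; 40% carry one
  mismatch). Spacers and 26-nt pads are drawn from {C, G} so no unintended
  half-site can form within pairing distance of a planted half-site, and a
  bounded repair loop removes hits that arise where a pad boundary
  completes a background half-site. The region scan therefore recovers the
  planted set exactly — an identity the tests assert.

What the generator does *not* emulate: read-level noise, alignment
artefacts, isoform-abundance-driven PSI estimation, GC/length biases of
real coverage, and realistic splice-graph complexity. Green tests therefore
demonstrate the correctness of the integration, classification, scanning
and resampling machinery under known truth — not the upstream callers, and
not biological effect sizes.

## Problem sizes, numerics and limitations

Tests and the acceptance script run the generator at desk scale — 200
genes, 150 planted events and ≈ 300 control exons for single end-to-end
runs; 80 genes and 50 events per run for the 50-run calibration study; the
full 150-event geometry for the 50-run power study — sizes chosen so the
statistical checks (Type-I error below α plus binomial noise under equal
rates; p < 0.01 in ≥ 95% of runs under planted enrichment) are sharp while
a complete run stays in seconds on one CPU.

Numerical conventions worth knowing: all internal coordinates are 0-based
half-open with conversion only at file boundaries; dedup keeps the
lowest-p record with ties broken by table order; empty subsets are flagged
`computed = FALSE` rather than dropped; `cov_quantile = 0` disables the
coverage cut (a strict "above the minimum" rule would otherwise empty
degenerate single-gene inputs). Known limitations: the headline counts of
any real study (events, genes, control-universe size) depend on its raw
sequencing data and cannot be reproduced from synthetic inputs; GFF3 is
supported only insofar as `rtracklayer` can coerce it; and the
reproduction of real-genome quantities (motif fractions on mm10, the
24-QRE region count) requires the user to supply the genome, annotation
and event tables, plus the region coordinates, which are not
redistributable here.
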