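# shared internal helpers

#' Derive independent child seeds from a master seed
#'
#' Reproducible seed splitting: the master seed seeds a temporary RNG stream
#' from which `n` integer seeds are drawn. Child seeds stay below 2^31.
#'
#' @param seed Master integer seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# 0-based half-open interval -> GRanges (1-based closed)
intervals_to_granges <- function(chrom, start, end, strand = "*") {
  strand <- ifelse(is.na(strand) | strand == "", "*", strand)
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand
  )
}

# stable exon identifier used across catalog, coverage table and ground truth
exon_key <- function(chrom, start, end, strand, gene_id) {
  paste0(chrom, ":", start, "-", end, ":", strand, ":", gene_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pick the first matching column name, NA if none
match_column <- function(df, candidates) {
  hit <- intersect(candidates, names(df))
  if (length(hit) == 0L) NA_character_ else hit[[1L]]
}
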