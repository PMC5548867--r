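# Motif scanners for the QKI binding core and the bipartite QRE.
#
# All scanning is performed on the transcribed strand, with RNA templates
# held internally as DNA (U == T). The QRE consensus is ACUAAY-(N1-20)-UAAY
# where Y is a pyrimidine (C or U); the "core" is the minimal ACUAA.

CORE_DNA <- "ACTAA"

# validate and normalise a nucleotide sequence: uppercase, U -> T.
# Ambiguity codes other than N are rejected (behaviour would be undefined).
norm_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- chartr("u", "U", toupper(seq))
  s <- chartr("U", "T", s)
  if (grepl("[^ACGTN]", s)) {
    bad <- unique(strsplit(gsub("[ACGTN]", "", s), "")[[1]])
    stop("sequence contains unsupported characters (only A/C/G/T/U/N allowed): ",
         paste(bad, collapse = ", "))
  }
  s
}

#' Scan a sequence for the QKI core motif ACUAA
#'
#' Reports every start offset of an exact ACUAA (DNA: ACTAA) match on the
#' given (transcribed-strand) sequence. Overlapping occurrences are all
#' reported; `N` never matches.
#'
#' @param seq A single nucleotide string over A/C/G/T/U/N (case-insensitive).
#' @return Integer vector of 0-based start offsets (possibly empty).
#' @examples
#' scan_core("ACTAACTAA")  # overlapping hits at 0 and 4
#' @export
scan_core <- function(seq) {
  s <- charToRaw(norm_seq(seq))
  n <- length(s)
  if (n < 5L) return(integer(0))
  A <- charToRaw("A"); C <- charToRaw("C"); Tb <- charToRaw("T")
  i <- seq_len(n - 4L)
  hit <- s[i] == A & s[i + 1L] == C & s[i + 2L] == Tb &
    s[i + 3L] == A & s[i + 4L] == A
  which(hit) - 1L
}

#' Scan a sequence for the full bipartite QRE
#'
#' Finds all matches to the consensus ACUAAY-(N1-20)-UAAY, where Y is a
#' pyrimidine (C/U) and the spacer N is unconstrained. Mismatches are counted
#' as substitutions over the 10 constrained half-site positions only; a Y
#' position mismatches when the base is not a pyrimidine. `N` never matches a
#' constrained position. All (offset, spacer length) combinations within the
#' mismatch budget are reported.
#'
#' @param seq A single nucleotide string over A/C/G/T/U/N.
#' @param max_mismatch Mismatch budget over the constrained positions (0 or 1).
#' @param spacer_min,spacer_max Allowed spacer lengths in nt (defaults 1 and 20).
#' @return A data.frame with columns `offset` (0-based), `spacer_len`,
#'   `mismatches` and `length` (total match length, 10 + spacer).
#' @examples
#' scan_qre("ACTAACGTAAC")                     # one perfect hit
#' scan_qre("ACTAAGGTAAC", max_mismatch = 1)   # rescued by the budget
#' @export
scan_qre <- function(seq, max_mismatch = 1L, spacer_min = 1L, spacer_max = 20L) {
  if (spacer_min > spacer_max) {
    stop("spacer_min must be <= spacer_max")
  }
  stopifnot(max_mismatch %in% c(0L, 1L), spacer_min >= 1L)
  s <- charToRaw(norm_seq(seq))
  n <- length(s)
  empty <- data.frame(offset = integer(0), spacer_len = integer(0),
                      mismatches = integer(0), length = integer(0))
  if (n < 10L + spacer_min) return(empty)

  A <- charToRaw("A"); C <- charToRaw("C"); Tb <- charToRaw("T")
  isY <- s == C | s == Tb

  # per-position mismatch counts for the two half-sites at every offset
  n6 <- n - 5L
  i <- seq_len(n6)
  mm6 <- (s[i] != A) + (s[i + 1L] != C) + (s[i + 2L] != Tb) +
    (s[i + 3L] != A) + (s[i + 4L] != A) + (!isY[i + 5L])
  n4 <- n - 3L
  j <- seq_len(n4)
  mm4 <- (s[j] != Tb) + (s[j + 1L] != A) + (s[j + 2L] != A) + (!isY[j + 3L])

  out <- vector("list", spacer_max - spacer_min + 1L)
  k <- 0L
  for (sp in spacer_min:spacer_max) {
    len <- 10L + sp
    if (n < len) break
    idx <- seq_len(n - len + 1L)
    tot <- mm6[idx] + mm4[idx + 6L + sp]
    keep <- which(tot <= max_mismatch)
    if (length(keep)) {
      k <- k + 1L
      out[[k]] <- data.frame(offset = keep - 1L, spacer_len = sp,
                             mismatches = as.integer(tot[keep]), length = len)
    }
  }
  if (k == 0L) return(empty)
  res <- do.call(rbind, out[seq_len(k)])
  res <- res[order(res$offset, res$spacer_len), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# reverse complement of a DNA character string (kept dispatch-free: it runs
# once per window in tight generator/scanner loops)
revcomp <- function(seq) {
  if (!nzchar(seq)) return(seq)
  rawToChar(rev(charToRaw(chartr("ACGTUacgtuNn", "TGCAAtgcaaNn", seq))))
}
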