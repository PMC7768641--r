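#' Count motif copies in a repeat segment
#'
#' Estimates how many copies of `motif` a (possibly noisy) repeat-tract
#' sequence contains: the segment is aligned globally against tandem arrays
#' of the motif under unit edit costs (match +1, mismatch/indel -1) and the
#' copy number maximising the alignment score is returned (on ties, the
#' copy number closest to `nchar(segment) / nchar(motif)`, then the
#' smaller one). Exact tandem arrays return exactly their copy
#' number; an empty segment returns 0. This counting is tolerant to the
#' substitution and indel errors typical of long reads.
#'
#' @param segment Character vector of DNA segments (the read's version of
#'   the repeat tract). `NA` propagates.
#' @param motif Single repeat unit over A/C/G/T (case-insensitive).
#' @return Numeric vector of estimated copy numbers (integer-valued).
#' @examples
#' count_motif_copies(strrep("CAG", 5), "CAG")          # 5
#' count_motif_copies("CAGCAGCTGCAGCAG", "CAG")         # 5 despite one error
#' @export
count_motif_copies <- function(segment, motif) {
  if (length(motif) != 1L) stop("motif must be a single string")
  motif <- toupper(motif)
  if (is.na(motif) || !nzchar(motif) || !grepl("^[ACGT]+$", motif))
    stop("motif must be a non-empty string over A/C/G/T")
  if (length(segment) == 0L) return(numeric(0))
  tandem_copy_count_cpp(toupper(as.character(segment)), motif)
}
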