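# Extraction of the repeat tract from locus-spanning long-read alignments.

parse_cigar <- function(cigar) {
  m <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[MIDNSHP=X]$", "", m)),
       op = sub("^\\d+", "", m))
}

cigar_ref_width <- function(ops) {
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

# Number of query bases consumed by the alignment strictly before 1-based
# reference position ref_target. Soft clips and insertions count on the
# query; deletions advance only the reference.
query_offset_at <- function(ops, pos, ref_target) {
  qoff <- 0L
  ref <- pos
  for (i in seq_along(ops$op)) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      if (ref + len > ref_target) return(qoff + max(0L, ref_target - ref))
      qoff <- qoff + len
      ref <- ref + len
    } else if (op %in% c("I", "S")) {
      qoff <- qoff + len
    } else if (op %in% c("D", "N")) {
      if (ref + len > ref_target) return(qoff)
      ref <- ref + len
    }  # H, P consume nothing
  }
  qoff
}

#' Extract the repeat tract from reads spanning a locus
#'
#' Fetches primary alignments from an indexed BAM whose reference span
#' covers the locus plus `flank` bp on both sides, and returns for each the
#' read subsequence mapped between the locus start and end (the read's own
#' version of the repeat tract, via the alignment's coordinate mapping).
#' Reads that start or end inside the flanked window, and secondary or
#' supplementary alignments, are excluded. Insertions at the exact tract
#' boundaries are assigned to the flank, not the tract.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param locus One catalog locus (single-row `str_catalog` or list with
#'   `chrom`, `start`, `end`; BED half-open coordinates).
#' @param flank Required anchoring flank in bp (>= 10).
#' @return Data frame with columns `read_id` and `segment`. A locus on a
#'   contig absent from the BAM header yields an empty result with a
#'   warning; an unindexed BAM is an error.
#' @export
extract_spanning_reads <- function(bam, locus, flank = 50L) {
  if (flank < 10L) stop("flank must be >= 10 bp")
  empty <- data.frame(read_id = character(), segment = character(),
                      stringsAsFactors = FALSE)
  targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  chrom <- as.character(locus$chrom)
  if (!chrom %in% names(targets)) {
    warning(sprintf("contig '%s' absent from BAM header; no spanning reads", chrom))
    return(empty)
  }
  win_start <- locus$start - flank + 1L  # 1-based window the read must cover
  win_end <- locus$end + flank
  which <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(max(1L, win_start), win_end))
  param <- Rsamtools::ScanBamParam(
    which = which,
    what = c("qname", "pos", "cigar", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  if (length(res$qname) == 0L) return(empty)
  segs <- character(0); ids <- character(0)
  for (i in seq_along(res$qname)) {
    ops <- parse_cigar(res$cigar[i])
    ref_end <- res$pos[i] + cigar_ref_width(ops) - 1L
    if (res$pos[i] > win_start || ref_end < win_end) next  # does not span
    q1 <- query_offset_at(ops, res$pos[i], locus$start + 1L)
    q2 <- query_offset_at(ops, res$pos[i], locus$end + 1L)
    segs <- c(segs, as.character(Biostrings::subseq(res$seq[i], q1 + 1L, q2)))
    ids <- c(ids, res$qname[i])
  }
  data.frame(read_id = ids, segment = segs, stringsAsFactors = FALSE)
}

#' Genotype one STR locus from a BAM file
#'
#' Composes spanning-read extraction, edit-tolerant motif copy counting and
#' Gaussian-mixture allele calling into a per-locus genotype. Deterministic
#' for fixed inputs (the mixture initialisation is deterministic).
#'
#' @inheritParams extract_spanning_reads
#' @inheritParams call_alleles
#' @param sample_id Sample identifier carried into the call.
#' @return An `allele_call` (possibly a no-call), with per-read copy counts
#'   in `$read_counts`.
#' @export
genotype_locus <- function(bam, locus, flank = 50L, min_reads = 5L,
                           ploidy = 2L, sample_id = NA_character_) {
  reads <- extract_spanning_reads(bam, locus, flank = flank)
  counts <- if (nrow(reads)) count_motif_copies(reads$segment, locus$motif) else numeric(0)
  call <- call_alleles(counts, ploidy = ploidy, min_reads = min_reads,
                       sample_id = sample_id, locus = locus)
  call$read_counts <- counts
  call
}

# One calls-table row (external TSV schema) from an allele_call.
call_to_row <- function(call, locus, sample_id) {
  a1 <- if (call$status == "called") call$alleles[1] else NA_integer_
  a2 <- if (call$status == "called" && length(call$alleles) >= 2L)
    call$alleles[2] else NA_integer_
  s1 <- if (call$status == "called") call$support[1] else NA_integer_
  s2 <- if (call$status == "called" && length(call$support) >= 2L)
    call$support[2] else NA_integer_
  data.frame(sample = sample_id, chrom = locus$chrom, start = locus$start,
             end = locus$end, motif = locus$motif,
             allele1 = a1, allele2 = a2, support1 = s1, support2 = s2,
             n_reads = call$n_reads, stringsAsFactors = FALSE)
}

#' Write / read a per-sample allele-calls table
#'
#' Tab-separated with columns sample, chrom, start, end, motif, allele1,
#' allele2, support1, support2, n_reads; missing alleles (haploid second
#' allele, no-calls) are empty fields. This is also the input format for
#' externally determined repeat counts (e.g. wet-lab counts), so the
#' scoring stage can be used with any repeat-count estimator.
#'
#' @param calls Data frame in the calls schema.
#' @param path Output / input path.
#' @return `read_allele_calls` returns the calls data frame.
#' @export
write_allele_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_allele_calls
#' @export
read_allele_calls <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "",
                          colClasses = c(sample = "character",
                                         chrom = "character",
                                         motif = "character"))
  df
}
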