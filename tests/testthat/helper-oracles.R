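# Independent oracles and small fixture builders used across the suite.

# Brute-force tandem copy counter: align the segment globally against
# motif^k for every k (unit costs via Biostrings) and return the
# score-maximising k, ties resolved toward segment_length / motif_length
# (smaller k when equidistant). Independent of the package's DP
# implementation.
oracle_copy_count <- function(segment, motif) {
  n <- nchar(segment)
  if (n == 0L) return(0)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  kmax <- n %/% nchar(motif) + 2L
  scores <- c(-n, vapply(seq_len(kmax), function(k)
    Biostrings::pairwiseAlignment(segment, strrep(motif, k),
                                  type = "global",
                                  substitutionMatrix = submat,
                                  gapOpening = 0, gapExtension = 1,
                                  scoreOnly = TRUE), numeric(1)))
  ks <- which(scores == max(scores)) - 1L
  ks[order(abs(ks - n / nchar(motif)), ks)][1]
}

# Percentile with linear interpolation between order statistics,
# implemented directly from h = p * (n - 1).
oracle_p95 <- function(x, p = 0.95) {
  s <- sort(x)
  n <- length(s)
  if (n == 1L) return(s)
  h <- p * (n - 1)
  lo <- floor(h) + 1L
  if (lo >= n) return(s[n])
  s[lo] + (h - floor(h)) * (s[lo + 1L] - s[lo])
}

# Sample SD from the definition.
oracle_sd <- function(x) {
  if (length(x) == 1L) return(0)
  sqrt(sum((x - mean(x))^2) / (length(x) - 1))
}

# Random segment: an exact tandem array mutated at the given per-base
# error rate (60/20/20 substitution/insertion/deletion).
mutate_segment <- function(seg, rate) {
  if (rate == 0 || nchar(seg) == 0L) return(seg)
  acgt <- c("A", "C", "G", "T")
  chars <- strsplit(seg, "")[[1]]
  out <- character(0)
  for (ch in chars) {
    if (stats::runif(1) < rate) {
      ty <- sample(c("sub", "ins", "del"), 1, prob = c(0.6, 0.2, 0.2))
      if (ty == "sub") out <- c(out, sample(setdiff(acgt, ch), 1))
      else if (ty == "ins") out <- c(out, ch, sample(acgt, 1))
      # del: drop the base
    } else out <- c(out, ch)
  }
  paste(out, collapse = "")
}

rand_motif <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")

# Small in-memory catalog builder (loci 1 kb apart on one contig).
tiny_catalog <- function(motifs, copies = rep(10L, length(motifs)),
                         region_class = rep("unknown", length(motifs))) {
  tract <- nchar(motifs) * copies
  start <- seq(0L, by = 1000L, length.out = length(motifs))
  structure(data.frame(chrom = rep("chr1", length(motifs)),
                       start = start, end = start + tract,
                       motif = motifs, motif_len = nchar(motifs),
                       ref_copies = as.numeric(copies),
                       region_class = region_class,
                       stringsAsFactors = FALSE),
            class = c("str_catalog", "data.frame"))
}

# Calls table for one sample over a tiny catalog.
tiny_calls <- function(catalog, sample, allele1, allele2 = NA_integer_) {
  data.frame(sample = sample, chrom = catalog$chrom, start = catalog$start,
             end = catalog$end, motif = catalog$motif,
             allele1 = allele1, allele2 = allele2,
             support1 = NA_integer_, support2 = NA_integer_,
             n_reads = NA_integer_, stringsAsFactors = FALSE)
}

# Minimal range database from explicit per-locus summaries.
tiny_db <- function(catalog, p95, sd, n_genomes, min = 1) {
  rec <- data.frame(chrom = catalog$chrom, start = catalog$start,
                    end = catalog$end, motif = catalog$motif,
                    min = min, p95 = p95, sd = sd,
                    n_genomes = as.integer(n_genomes),
                    stringsAsFactors = FALSE)
  structure(list(records = rec, samples = character(0)),
            class = "repeat_range_db")
}

# Write a handcrafted SAM and return a sorted indexed BAM path.
sam_to_bam <- function(body, contig = "chr1", contig_len = 10000L) {
  prefix <- tempfile("handbam")
  sam <- paste0(prefix, ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_len), body), sam)
  bam0 <- Rsamtools::asBam(sam, paste0(prefix, "_u"), overwrite = TRUE,
                           indexDestination = FALSE)
  sorted <- Rsamtools::sortBam(bam0, prefix)
  Rsamtools::indexBam(sorted)
  sorted
}

sam_line <- function(qname, pos, cigar, seq, flag = 0L, rname = "chr1",
                     mapq = 60L) {
  paste(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, seq,
        strrep("I", nchar(seq)), sep = "\t")
}
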