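#' Read an STR locus catalog
#'
#' Reads a catalog of short-tandem-repeat loci either as BED4
#' (chrom, start, end, motif) or as a UCSC simpleRepeat table dump
#' (tab-separated; motif taken from the `sequence` column, reference copy
#' number from `copyNum`; a leading `bin` column is detected automatically).
#' Coordinates are BED-style throughout the package: 0-based, half-open.
#'
#' Rows violating the locus invariants (`end > start`, non-empty motif over
#' A/C/G/T) are skipped with a warning naming the offending row numbers;
#' a malformed row never aborts the read. Motifs are uppercased.
#'
#' @param path Path to a tab-separated catalog file. A header line is
#'   detected (non-numeric coordinate fields) and skipped.
#' @param format `"bed4"` or `"simpleRepeat"`.
#' @return A data frame of class `str_catalog` with columns `chrom`,
#'   `start`, `end`, `motif`, `motif_len`, `ref_copies` (NA for BED4) and
#'   `region_class` (initialised to `"unknown"`, see
#'   [attach_region_labels()]). The number of skipped data rows is stored in
#'   attribute `n_skipped`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr14\t92071010\t92071053\tCAG", bed)
#' read_str_catalog(bed, "bed4")
#' @export
read_str_catalog <- function(path, format = c("bed4", "simpleRepeat")) {
  format <- match.arg(format)
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("catalog file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_catalog())
  fields <- strsplit(lines, "\t", fixed = TRUE)

  # column positions per format; simpleRepeat may carry a leading bin column
  pick <- function(f) {
    if (format == "bed4") {
      if (length(f) < 4L) return(NULL)
      list(chrom = f[1L], start = f[2L], end = f[3L], motif = f[4L], copies = NA_character_)
    } else {
      if (length(f) < 16L) return(NULL)
      off <- if (length(f) >= 17L) 1L else 0L  # bin column present?
      list(chrom = f[1L + off], start = f[2L + off], end = f[3L + off],
           motif = f[length(f)], copies = f[6L + off])
    }
  }

  # header detection: first line with non-numeric coordinates
  first <- pick(fields[[1L]])
  has_header <- is.null(first) ||
    is.na(suppressWarnings(as.numeric(first$start))) ||
    is.na(suppressWarnings(as.numeric(first$end)))
  data_idx <- if (has_header) seq_along(fields)[-1L] else seq_along(fields)
  if (length(data_idx) == 0L) return(empty_catalog())

  rows <- vector("list", length(data_idx))
  skipped <- integer(0)
  for (k in seq_along(data_idx)) {
    i <- data_idx[k]
    f <- pick(fields[[i]])
    ok <- !is.null(f)
    if (ok) {
      start <- suppressWarnings(as.numeric(f$start))
      end <- suppressWarnings(as.numeric(f$end))
      motif <- toupper(trimws(f$motif))
      ok <- !is.na(start) && !is.na(end) && start >= 0 && end > start &&
        nzchar(motif) && grepl("^[ACGT]+$", motif)
    }
    if (!ok) {
      skipped <- c(skipped, i)
      next
    }
    rows[[k]] <- data.frame(
      chrom = f$chrom, start = start, end = end, motif = motif,
      motif_len = nchar(motif),
      ref_copies = suppressWarnings(as.numeric(f$copies)),
      region_class = "unknown",
      stringsAsFactors = FALSE
    )
  }
  if (length(skipped))
    warning(sprintf("skipped %d malformed catalog row(s): line(s) %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  cat_df <- if (length(rows)) do.call(rbind, rows) else empty_catalog()
  rownames(cat_df) <- NULL
  structure(cat_df, class = c("str_catalog", "data.frame"),
            n_skipped = length(skipped))
}

empty_catalog <- function() {
  structure(
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               motif = character(), motif_len = integer(),
               ref_copies = numeric(), region_class = character(),
               stringsAsFactors = FALSE),
    class = c("str_catalog", "data.frame"), n_skipped = 0L)
}

#' Canonical rotation of a repeat motif
#'
#' Returns the lexicographically smallest rotation of each motif, so that
#' rotational variants of the same repeat unit (CAG / AGC / GCA) share one
#' identity when catalogs are compared. Idempotent. The reverse complement
#' is deliberately not folded in: catalog motifs are reference-strand.
#'
#' @param motif Character vector of motifs over A/C/G/T (case-insensitive).
#' @return Character vector of canonical motifs, uppercase.
#' @examples
#' canonical_motif(c("CAG", "GCA", "ACAC"))  # "AGC" "AGC" "ACAC"
#' @export
canonical_motif <- function(motif) {
  motif <- toupper(motif)
  bad <- !nzchar(motif) | !grepl("^[ACGT]*$", motif) | is.na(motif)
  if (any(bad)) stop("motif must be a non-empty string over A/C/G/T")
  vapply(motif, function(m) {
    n <- nchar(m)
    if (n == 1L) return(m)
    rots <- vapply(seq_len(n) - 1L, function(k)
      paste0(substr(m, k + 1L, n), substr(m, 1L, k)), character(1))
    min(rots)
  }, character(1), USE.NAMES = FALSE)
}

#' Is a motif a poly-A or poly-T homopolymer?
#'
#' Poly-A and poly-T tracts are skipped in genome-wide screening: their
#' counts are dominated by homopolymer sequencing error rather than true
#' copy-number variation. The test applies to the literal motif of any
#' length (`"A"`, `"AA"`, `"T"`, ...).
#'
#' @param motif Character vector of motifs over A/C/G/T.
#' @return Logical vector.
#' @export
is_poly_a_or_t <- function(motif) {
  motif <- toupper(motif)
  bad <- !nzchar(motif) | !grepl("^[ACGT]*$", motif) | is.na(motif)
  if (any(bad)) stop("motif must be a non-empty string over A/C/G/T")
  grepl("^A+$", motif) | grepl("^T+$", motif)
}

#' Attach functional region labels to catalog loci
#'
#' Joins a region-annotation table (chrom, start, end, region_class; BED
#' half-open coordinates, e.g. exported from an external annotator) onto a
#' catalog. Each locus receives the `region_class` of the first interval in
#' table order whose half-open span contains the locus start; loci with no
#' containing interval get `"unknown"`. A locus start equal to a region end
#' does not match (half-open semantics).
#'
#' @param loci An `str_catalog` data frame.
#' @param regions Data frame with columns `chrom`, `start`, `end`,
#'   `region_class`, or `NULL` (all loci labelled `"unknown"`).
#' @return The catalog with `region_class` filled in.
#' @export
attach_region_labels <- function(loci, regions = NULL) {
  loci$region_class <- "unknown"
  if (is.null(regions) || nrow(loci) == 0L || NROW(regions) == 0L)
    return(loci)
  # locus start (0-based) as a 1-based point; region [s, e) -> [s+1, e]
  pts <- GenomicRanges::GRanges(loci$chrom,
                                IRanges::IRanges(loci$start + 1L, width = 1L))
  reg <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start + 1L, regions$end))
  hits <- GenomicRanges::findOverlaps(pts, reg)
  if (length(hits)) {
    h <- as.data.frame(hits)
    h <- h[order(h$queryHits, h$subjectHits), , drop = FALSE]
    h <- h[!duplicated(h$queryHits), , drop = FALSE]  # first interval in table order
    loci$region_class[h$queryHits] <- as.character(regions$region_class[h$subjectHits])
  }
  loci
}

#' @export
print.str_catalog <- function(x, ...) {
  cat(sprintf("STR catalog: %d loci", nrow(x)))
  if (nrow(x)) {
    cat(sprintf(" on %d sequence(s); motif lengths %d-%d",
                length(unique(x$chrom)), min(x$motif_len), max(x$motif_len)))
  }
  cat("\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

# locus identity key used for joins across calls / database / catalog
locus_key <- function(df) {
  paste(df$chrom, df$start, df$end, df$motif, sep = ":")
}
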