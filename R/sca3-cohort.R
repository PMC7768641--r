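# Published SCA3 case-study cohort: wet-lab determined CAG repeat counts
# in ATXN3 for 20 patients with spinocerebellar ataxia type 3 (capillary
# electrophoresis) and 5 unaffected controls (Sanger sequencing), from a
# PacBio amplicon study. Embedded verbatim so the scoring stage can be
# validated without any download; the counts are inputs to the pipeline,
# the N/P labels its expected outputs.

#' The SCA3 / ATXN3 validation cohort
#'
#' Wet-lab determined CAG repeat counts in the *ATXN3* gene for 25
#' subjects (20 SCA3 patients, 5 unaffected controls), together with their
#' established per-allele normal/pathogenic status and per-subject disease
#' status. SCA3 is autosomal dominant: one pathogenic allele suffices.
#'
#' @return Data frame with one row per subject: `sample`, `allele1`,
#'   `allele2` (repeat counts, ascending), `group` (`"patient"` /
#'   `"control"`), `expected_allele1`, `expected_allele2` (`"normal"` /
#'   `"pathogenic"`), `expected_subject` (`"affected"` / `"unaffected"`).
#' @examples
#' nrow(sca3_cohort())                      # 25 subjects
#' sum(!is.na(sca3_cohort()[, c("allele1", "allele2")]))  # 50 alleles
#' @export
sca3_cohort <- function() {
  p <- "pathogenic"; n <- "normal"
  df <- data.frame(
    sample = c("SRR5363334", "SRR5363452", "SRR5363453", "SRR5363454",
               "SRR5363455", "SRR5363456", "SRR5363457", "SRR5363458",
               "SRR5363459", "SRR5363460", "SRR5363461", "SRR5363462",
               "SRR5363463", "SRR5363464", "SRR5363465", "SRR5363466",
               "SRR5363467", "SRR5363468", "SRR5363469", "SRR5363470",
               "SRR5363471", "SRR5363472", "SRR5363473", "SRR5363480",
               "SRR5363632"),
    allele1 = c(14L, 30L, 14L, 14L, 21L, 14L, 26L, 14L, 29L, 27L, 34L, 28L,
                61L, 26L, 14L, 40L, 37L, 28L, 14L, 14L,
                14L, 27L, 28L, 14L, 14L),
    allele2 = c(77L, 66L, 69L, 71L, 72L, 77L, 71L, 63L, 70L, 71L, 75L, 89L,
                61L, 65L, 89L, 67L, 68L, 40L, 82L, 68L,
                14L, 35L, 28L, 14L, 19L),
    group = c(rep("patient", 20L), rep("control", 5L)),
    expected_allele1 = c(rep(n, 12L), p, n, n, p, n, n, n, n, rep(n, 5L)),
    expected_allele2 = c(rep(p, 20L), rep(n, 5L)),
    stringsAsFactors = FALSE
  )
  df$expected_subject <- ifelse(df$group == "patient", "affected", "unaffected")
  df
}

#' ATXN3 CAG-repeat locus definition
#'
#' The catalog entry for the CAG repeat in *ATXN3* (GRCh38, chr14), used
#' when the cohort counts are scored in targeted mode.
#'
#' @return Single-row `str_catalog`.
#' @export
atxn3_locus <- function() {
  structure(data.frame(chrom = "chr14", start = 92071010, end = 92071053,
                       motif = "CAG", motif_len = 3L, ref_copies = 14,
                       region_class = "exonic", stringsAsFactors = FALSE),
            class = c("str_catalog", "data.frame"))
}

#' ATXN3 normal-range record
#'
#' The normal repeat range of the CAG repeat in *ATXN3* as estimated from
#' a 21-genome long-read reference panel: minimum 11, 95th-percentile
#' upper bound 28, pool standard deviation 5.9. The familiar score for an
#' observed count `c` is `(c - 28) / 5.9`.
#'
#' @param min,p95,sd Range parameters; defaults are the published panel
#'   estimates.
#' @return A `repeat_range_db` with this single record, usable directly by
#'   [score_alleles()] / [predict.repeat_range_db()].
#' @export
atxn3_range_db <- function(min = 11, p95 = 28, sd = 5.9) {
  loc <- atxn3_locus()
  rec <- data.frame(chrom = loc$chrom, start = loc$start, end = loc$end,
                    motif = loc$motif, min = min, p95 = p95, sd = sd,
                    n_genomes = 21L, stringsAsFactors = FALSE)
  structure(list(records = rec, samples = character(0)),
            class = "repeat_range_db")
}

#' Cohort counts as a targeted-mode calls table
#'
#' Packages the [sca3_cohort()] wet-lab counts in the calls-table schema
#' at the [atxn3_locus()] coordinates, demonstrating that the scoring
#' stage accepts externally determined repeat counts from any estimator.
#'
#' @return Calls data frame (25 samples, 50 allele counts).
#' @export
sca3_cohort_calls <- function() {
  co <- sca3_cohort()
  loc <- atxn3_locus()
  data.frame(sample = co$sample, chrom = loc$chrom, start = loc$start,
             end = loc$end, motif = loc$motif,
             allele1 = co$allele1, allele2 = co$allele2,
             support1 = NA_integer_, support2 = NA_integer_,
             n_reads = NA_integer_, stringsAsFactors = FALSE)
}
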