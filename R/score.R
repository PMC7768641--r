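# Deviation-based expansion scoring: an observed repeat count c is scored
# against a locus's normal range as (c - upper) / sd, where upper is the
# 95th-percentile normal bound and sd the standard deviation of the pooled
# normal counts. A score above a region-dependent threshold labels the
# allele putatively pathogenic.

#' Score a repeat count against a normal-range record
#'
#' Computes `score = (count - upper) / sd_used`, where `upper` is the
#' record's 95th-percentile normal bound and `sd_used` is the record's SD,
#' floored at `sd_floor` when flooring is enabled (genome-wide screening
#' uses a floor so tiny deviations do not inflate scores). A zero `sd_used`
#' is guarded: the score is `+Inf` above the bound, `-Inf` below, 0 at it,
#' and the result is flagged degenerate.
#'
#' @param count Integer repeat count(s) observed.
#' @param record A database record: list or single-row data frame with
#'   `p95` (or `upper_count`) and `sd`.
#' @param sd_floor Minimum SD, or `NULL` to use the raw SD.
#' @return Data frame with columns `count`, `score`, `upper_used`,
#'   `sd_used`, `degenerate_sd`.
#' @examples
#' score_repeat(77, list(p95 = 28, sd = 5.9))          # (77-28)/5.9 = 8.31
#' score_repeat(40, list(p95 = 28, sd = 3), sd_floor = 5)  # 2.4
#' @export
score_repeat <- function(count, record, sd_floor = NULL) {
  upper <- if (!is.null(record$p95)) record$p95 else record$upper_count
  sd_raw <- record$sd
  if (is.null(upper) || is.null(sd_raw) || sd_raw < 0)
    stop("record must provide a p95/upper_count bound and a non-negative sd")
  sd_used <- if (!is.null(sd_floor)) max(sd_raw, sd_floor) else sd_raw
  if (sd_used == 0) {
    score <- ifelse(count > upper, Inf, ifelse(count < upper, -Inf, 0))
    degenerate <- TRUE
  } else {
    score <- (count - upper) / sd_used
    degenerate <- FALSE
  }
  data.frame(count = count, score = score, upper_used = upper,
             sd_used = sd_used, degenerate_sd = degenerate)
}

#' Classify an allele score
#'
#' Strictly above the threshold is `"pathogenic"`; at or below it,
#' `"normal"`.
#'
#' @param score Numeric score(s) from [score_repeat()].
#' @param threshold Finite score threshold.
#' @return Character vector of labels.
#' @export
classify_allele <- function(score, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  ifelse(score > threshold, "pathogenic", "normal")
}

#' Classify a subject from its allele labels
#'
#' Under the dominant inheritance model (the only model in scope) a subject
#' is `"affected"` if any allele is pathogenic, else `"unaffected"`.
#'
#' @param allele_labels Character vector of allele labels (>= 1).
#' @param inheritance Inheritance model; only `"dominant"` is supported.
#' @return `"affected"` or `"unaffected"`.
#' @export
classify_subject <- function(allele_labels, inheritance = "dominant") {
  inheritance <- match.arg(inheritance, "dominant")
  if (length(allele_labels) < 1L) stop("at least one allele label required")
  if (any(allele_labels == "pathogenic")) "affected" else "unaffected"
}

db_lookup <- function(db, calls) {
  match(locus_key(calls), locus_key(db$records))
}

#' Targeted scoring of allele calls at known loci
#'
#' Scores both alleles of every call against the database (raw SD, no
#' floor — the targeted-mode convention) and derives a dominant-model
#' subject call per sample. This is the mode used when interrogating a
#' known disease locus such as the CAG repeat in ATXN3.
#'
#' @param calls Calls data frame (one or more samples; externally
#'   determined counts are accepted via the same schema).
#' @param db A `repeat_range_db`.
#' @param threshold Score threshold (strict `>`); 2.0 is the convention for
#'   coding-region repeats.
#' @param sd_floor Optional SD floor (off by default in targeted mode).
#' @return List with `alleles` (one row per scored allele: sample, locus
#'   fields, allele index, count, score, label) and `subjects` (sample,
#'   subject_label).
#' @export
score_alleles <- function(calls, db, threshold = 2.0, sd_floor = NULL) {
  idx <- db_lookup(db, calls)
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    if (is.na(idx[i])) next
    rec <- db$records[idx[i], , drop = FALSE]
    counts <- c(calls$allele1[i], calls$allele2[i])
    counts <- counts[!is.na(counts)]
    if (length(counts) == 0L) next
    sc <- score_repeat(counts, rec, sd_floor = sd_floor)
    sc$label <- classify_allele(sc$score, threshold)
    sc$threshold <- threshold
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(sample = calls$sample[i], chrom = calls$chrom[i],
                 start = calls$start[i], end = calls$end[i],
                 motif = calls$motif[i], allele = seq_along(counts),
                 stringsAsFactors = FALSE),
      sc)
  }
  alleles <- if (length(rows)) do.call(rbind, rows) else NULL
  subjects <- NULL
  if (!is.null(alleles)) {
    subjects <- do.call(rbind, lapply(split(alleles, alleles$sample), function(d)
      data.frame(sample = d$sample[1],
                 subject_label = classify_subject(d$label),
                 stringsAsFactors = FALSE)))
    subjects <- subjects[match(unique(alleles$sample), subjects$sample), ,
                         drop = FALSE]
    rownames(subjects) <- NULL
  }
  list(alleles = alleles, subjects = subjects)
}

#' Screen a genome's calls for candidate repeat expansions
#'
#' Genome-wide expansion screening of one sample against the database.
#' Per called locus: the locus is dropped if its motif is poly-A/poly-T
#' (when `skip_poly_at`), or if the database lacks the locus or has counts
#' from fewer than `min_genomes` genomes; the larger allele is scored with
#' the SD floored at `sd_floor`; candidates must exceed
#' `threshold_coding` (stage 1), and loci outside exonic regions must
#' additionally exceed `threshold_noncoding` (stage 2 — non-coding regions
#' tolerate far more repeat variability than coding regions).
#'
#' @param calls Calls data frame for one sample.
#' @param db A `repeat_range_db`.
#' @param catalog Optional `str_catalog` carrying `region_class` labels
#'   (see [attach_region_labels()]); loci not found get `"unknown"`, which
#'   is treated as non-coding.
#' @param sd_floor SD floor (default 5).
#' @param threshold_coding Stage-1 threshold, applied to every locus and
#'   final for exonic loci (default 2.0).
#' @param threshold_noncoding Stage-2 threshold for non-exonic loci
#'   (default 10.0).
#' @param min_genomes Minimum genomes with counts at the locus (default
#'   10).
#' @param skip_poly_at Skip poly-A/poly-T motifs (default TRUE).
#' @return Data frame of candidates sorted by score (descending): locus
#'   fields, `region_class`, `count`, `score`, `upper_used`, `sd_used`,
#'   `threshold`, `label`. Empty when nothing passes.
#' @export
screen_genome <- function(calls, db, catalog = NULL, sd_floor = 5,
                          threshold_coding = 2.0, threshold_noncoding = 10.0,
                          min_genomes = 10L, skip_poly_at = TRUE) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      motif = character(), region_class = character(),
                      count = numeric(), score = numeric(),
                      upper_used = numeric(), sd_used = numeric(),
                      threshold = numeric(), label = character(),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0L) return(empty)
  region <- rep("unknown", nrow(calls))
  if (!is.null(catalog)) {
    m <- match(locus_key(calls), locus_key(catalog))
    region[!is.na(m)] <- catalog$region_class[m[!is.na(m)]]
  }
  idx <- db_lookup(db, calls)
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    counts <- c(calls$allele1[i], calls$allele2[i])
    counts <- counts[!is.na(counts)]
    if (length(counts) == 0L) next
    if (skip_poly_at && is_poly_a_or_t(calls$motif[i])) next
    if (is.na(idx[i])) next
    rec <- db$records[idx[i], , drop = FALSE]
    if (rec$n_genomes < min_genomes) next
    sc <- score_repeat(max(counts), rec, sd_floor = sd_floor)
    if (!(sc$score > threshold_coding)) next              # stage 1
    thr <- if (identical(region[i], "exonic")) threshold_coding
           else threshold_noncoding
    if (!(sc$score > thr)) next                           # stage 2
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(chrom = calls$chrom[i], start = calls$start[i],
                 end = calls$end[i], motif = calls$motif[i],
                 region_class = region[i], stringsAsFactors = FALSE),
      sc[, c("count", "score", "upper_used", "sd_used")],
      data.frame(threshold = thr, label = "pathogenic",
                 stringsAsFactors = FALSE))
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score new observations against a range database
#'
#' `predict` method for the fitted normal-range database: `mode =
#' "targeted"` scores both alleles at known loci and returns subject calls
#' ([score_alleles()]); `mode = "screen"` performs genome-wide candidate
#' screening ([screen_genome()]).
#'
#' @param object A `repeat_range_db`.
#' @param newdata Calls data frame.
#' @param mode `"targeted"` or `"screen"`.
#' @param ... Passed to [score_alleles()] or [screen_genome()].
#' @return See the respective mode's function.
#' @export
predict.repeat_range_db <- function(object, newdata,
                                    mode = c("targeted", "screen"), ...) {
  mode <- match.arg(mode)
  if (mode == "targeted") score_alleles(newdata, object, ...)
  else screen_genome(newdata, object, ...)
}
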