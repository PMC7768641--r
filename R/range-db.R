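# The normal-repeat-range database: per-locus pools of allele counts
# across presumed-unaffected genomes, summarised as minimum, 95th
# percentile and sample standard deviation. The 95th percentile (rather
# than the maximum) bounds the normal range so that extreme outliers in
# the reference panel are excluded.

#' Pool allele counts across genomes per locus
#'
#' For each locus, pools both alleles of every diploid sample and the
#' single allele of every haploid sample; no-call samples contribute
#' nothing. With, say, 19 diploid and 2 haploid genomes all called, a locus
#' pools 40 counts.
#'
#' @param calls Named list (sample -> calls data frame in the calls-table
#'   schema) as produced by [scan_genome()] / [read_allele_calls()].
#' @param sample_ploidies Named integer vector (sample -> 1 or 2). Every
#'   sample in `calls` must be present.
#' @return Named list (locus key -> list with `counts`, `per_sample`,
#'   `n_genomes`).
#' @export
aggregate_counts <- function(calls, sample_ploidies) {
  samples <- names(calls)
  missing <- setdiff(samples, names(sample_ploidies))
  if (length(missing))
    stop("sample(s) missing from ploidy map: ", paste(missing, collapse = ", "))
  pools <- list()
  for (s in samples) {
    df <- calls[[s]]
    pl <- sample_ploidies[[s]]
    for (i in seq_len(nrow(df))) {
      a <- df$allele1[i]
      if (is.na(a)) next  # no-call contributes nothing
      counts <- if (pl == 2L && !is.na(df$allele2[i])) c(a, df$allele2[i]) else a
      key <- locus_key(df[i, ])
      if (is.null(pools[[key]]))
        pools[[key]] <- list(counts = numeric(0), per_sample = list(),
                             n_genomes = 0L)
      pools[[key]]$counts <- c(pools[[key]]$counts, counts)
      pools[[key]]$per_sample[[s]] <- counts
      pools[[key]]$n_genomes <- pools[[key]]$n_genomes + 1L
    }
  }
  pools
}

#' Summarise a per-locus count pool
#'
#' Computes the normal-range summary of a pooled set of allele repeat
#' counts: the minimum, the 95th percentile with linear interpolation
#' between order statistics (index `h = 0.95 * (n - 1)` on the sorted
#' pool), and the sample standard deviation
#' `sqrt(sum((c_i - mean)^2) / (n - 1))` over the full pool (counts above
#' the 95th percentile are not excluded from the SD). Values are returned
#' unrounded; a pool of size 1 has SD 0.
#'
#' @param pool Non-empty numeric vector of repeat counts.
#' @return List with `min_count`, `upper_count`, `sd`, `n`.
#' @examples
#' summarize_locus(1:40)  # min 1, upper 38.05, sd 11.69
#' @export
summarize_locus <- function(pool) {
  if (length(pool) == 0L) stop("empty count pool")
  pool <- as.numeric(pool)
  list(min_count = min(pool),
       upper_count = unname(stats::quantile(pool, 0.95, type = 7)),
       sd = if (length(pool) == 1L) 0 else stats::sd(pool),
       n = length(pool))
}

#' Build the normal-repeat-range database
#'
#' Aggregates per-genome allele calls over a catalog into one range record
#' per locus with at least one pooled count; loci uncalled in every genome
#' are omitted from the database and reported in a message. The result is
#' the fitted population reference against which new genomes are scored
#' (see [predict.repeat_range_db()]).
#'
#' @inheritParams aggregate_counts
#' @param catalog The `str_catalog` the calls were made on.
#' @return Object of class `repeat_range_db`: list with `records` (data
#'   frame: chrom, start, end, motif, min, p95, sd, n_genomes, plus one
#'   character column per sample holding comma-separated allele counts or
#'   "." for no-call) and `samples`.
#' @export
build_range_db <- function(calls, sample_ploidies, catalog) {
  if (length(calls) < 1L) stop("at least one sample is required")
  pools <- aggregate_counts(calls, sample_ploidies)
  samples <- names(calls)
  keys <- locus_key(catalog)
  present <- keys %in% names(pools)
  if (any(!present))
    message(sprintf("%d catalog locus/loci with no calls omitted from the database",
                    sum(!present)))
  rec_list <- lapply(which(present), function(i) {
    p <- pools[[keys[i]]]
    s <- summarize_locus(p$counts)
    row <- data.frame(chrom = catalog$chrom[i], start = catalog$start[i],
                      end = catalog$end[i], motif = catalog$motif[i],
                      min = s$min_count, p95 = s$upper_count, sd = s$sd,
                      n_genomes = p$n_genomes, stringsAsFactors = FALSE)
    for (sm in samples) {
      v <- p$per_sample[[sm]]
      row[[sm]] <- if (is.null(v)) "." else paste(v, collapse = ",")
    }
    row
  })
  records <- if (length(rec_list)) do.call(rbind, rec_list) else NULL
  if (!is.null(records)) rownames(records) <- NULL
  structure(list(records = records, samples = samples),
            class = "repeat_range_db")
}

#' Serialize / deserialize the range database
#'
#' Tab-separated, one row per locus: chrom, start, end, motif, min, p95,
#' sd, n_genomes, then one column per contributing sample holding
#' comma-separated allele counts or "." for no-call. p95 and sd are written
#' at full precision (15 significant digits) so that a write/read
#' round-trip is lossless for all summarised fields.
#'
#' @param db A `repeat_range_db`.
#' @param path File path.
#' @return `read_range_db` returns the `repeat_range_db`.
#' @export
write_range_db <- function(db, path) {
  rec <- db$records
  num <- c("min", "p95", "sd")
  for (col in num) rec[[col]] <- format(rec[[col]], digits = 15, trim = TRUE,
                                        scientific = FALSE)
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_range_db
#' @export
read_range_db <- function(path) {
  rec <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  fixed <- c("chrom", "start", "end", "motif", "min", "p95", "sd", "n_genomes")
  if (!all(fixed %in% names(rec)))
    stop("malformed database: missing column(s) ",
         paste(setdiff(fixed, names(rec)), collapse = ", "))
  for (col in c("start", "end", "min", "p95", "sd")) {
    v <- suppressWarnings(as.numeric(rec[[col]]))
    if (anyNA(v) && nrow(rec))
      stop("malformed database row ", which(is.na(v))[1], ": non-numeric ", col)
    rec[[col]] <- v
  }
  rec$n_genomes <- as.integer(rec$n_genomes)
  structure(list(records = rec, samples = setdiff(names(rec), fixed)),
            class = "repeat_range_db")
}

#' @export
print.repeat_range_db <- function(x, ...) {
  n <- if (is.null(x$records)) 0L else nrow(x$records)
  cat(sprintf("Repeat normal-range database: %d loci, %d genome(s)\n",
              n, length(x$samples)))
  if (n) {
    cat(sprintf("  normal upper bound (p95): median %.1f, range %.1f-%.1f\n",
                stats::median(x$records$p95), min(x$records$p95),
                max(x$records$p95)))
  }
  invisible(x)
}

#' @export
summary.repeat_range_db <- function(object, ...) {
  rec <- object$records
  out <- list(n_loci = if (is.null(rec)) 0L else nrow(rec),
              n_samples = length(object$samples),
              p95 = if (!is.null(rec)) summary(rec$p95),
              sd = if (!is.null(rec)) summary(rec$sd),
              n_genomes = if (!is.null(rec)) summary(rec$n_genomes))
  class(out) <- "summary.repeat_range_db"
  out
}

#' @export
print.summary.repeat_range_db <- function(x, ...) {
  cat(sprintf("Repeat normal-range database: %d loci from %d genome(s)\n",
              x$n_loci, x$n_samples))
  if (x$n_loci) {
    cat("normal upper bound (95th percentile of pooled counts):\n")
    print(x$p95)
    cat("pool standard deviation:\n")
    print(x$sd)
  }
  invisible(x)
}

#' @export
as.data.frame.repeat_range_db <- function(x, ...) x$records
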