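# Deterministic synthetic-data generator: STR catalogs with a matching
# reference sequence, population allele counts across genomes, and noisy
# locus-spanning long reads as sorted indexed BAM. Everything any other
# module consumes can be generated here, seeded, with byte-identical
# re-runs.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

#' Simulation configuration
#'
#' Bundles and validates all knobs of the synthetic-data generator. The
#' defaults emulate the study conditions the pipeline assumes: a reference
#' panel of 21 genomes of which 2 are haploid (so a fully called locus
#' pools 40 allele counts), per-locus base copy numbers uniform on
#' \[5, 35\] with integer Gaussian jitter (sd 2, truncated at 1) per
#' allele, read depth 30 per allele, and a 10% per-base read error rate
#' split 60/20/20 between substitutions, insertions and deletions.
#'
#' @param seed Integer seed; a fixed seed makes every generator
#'   byte-identical across runs.
#' @param n_loci Number of catalog loci.
#' @param motif_len_weights Sampling weights for motif lengths 1..6.
#' @param n_genomes Reference-panel size.
#' @param n_haploid How many of the last genomes are haploid.
#' @param base_copy_range Per-locus base copy number range (uniform).
#' @param jitter_sd SD of the per-allele integer jitter.
#' @param expansion_spike Optional `list(locus =, count =, sample =)`
#'   planting one expanded allele (sample defaults to the first genome).
#' @param read_depth Reads per allele.
#' @param read_error_rate Per-base error rate in \[0, 0.3\].
#' @param error_profile Weights for substitution / insertion / deletion.
#' @param flank Flank length (bp) reads extend beyond the tract.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_loci = 20L,
                       motif_len_weights = c(0.10, 0.25, 0.30, 0.20, 0.10, 0.05),
                       n_genomes = 21L, n_haploid = 2L,
                       base_copy_range = c(5L, 35L), jitter_sd = 2,
                       expansion_spike = NULL,
                       read_depth = 30L, read_error_rate = 0.10,
                       error_profile = c(sub = 0.6, ins = 0.2, del = 0.2),
                       flank = 100L) {
  stopifnot(length(motif_len_weights) == 6L, all(motif_len_weights >= 0),
            sum(motif_len_weights) > 0,
            n_loci >= 1L, n_genomes >= 1L, n_haploid >= 0L,
            n_haploid <= n_genomes,
            base_copy_range[1] >= 1L, base_copy_range[2] >= base_copy_range[1],
            jitter_sd >= 0, read_depth >= 1L,
            read_error_rate >= 0, read_error_rate <= 0.3,
            length(error_profile) == 3L, all(error_profile >= 0),
            flank >= 10L)
  if (!is.null(expansion_spike))
    stopifnot(!is.null(expansion_spike$locus), !is.null(expansion_spike$count),
              expansion_spike$locus >= 1L, expansion_spike$locus <= n_loci,
              expansion_spike$count >= 1L)
  samples <- sprintf("genome%02d", seq_len(n_genomes))
  structure(list(seed = as.integer(seed), n_loci = as.integer(n_loci),
                 motif_len_weights = motif_len_weights,
                 n_genomes = as.integer(n_genomes),
                 samples = samples,
                 haploid_samples = if (n_haploid > 0)
                   samples[(n_genomes - n_haploid + 1L):n_genomes]
                 else character(0),
                 base_copy_range = as.integer(base_copy_range),
                 jitter_sd = jitter_sd, expansion_spike = expansion_spike,
                 read_depth = as.integer(read_depth),
                 read_error_rate = read_error_rate,
                 error_profile = error_profile / sum(error_profile),
                 flank = as.integer(flank), contig = "sim1"),
            class = "sim_config")
}

#' Simulate a reference sequence and matching STR catalog
#'
#' Embeds `n_loci` exact tandem arrays (motif lengths sampled from
#' `motif_len_weights`, copy numbers uniform on `base_copy_range`) in a
#' single synthetic contig, separated by random spacer sequence long
#' enough for spanning reads, and writes the FASTA plus a BED4 catalog
#' whose coordinates match the FASTA.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param starts Optional explicit 0-based locus start positions; requested
#'   loci that would overlap are an error.
#' @return List: `catalog` (an `str_catalog` with `ref_copies` filled in),
#'   `fasta`, `bed` (file paths), `ref_seq` (the contig sequence),
#'   `contig`.
#' @export
simulate_catalog <- function(config, dir = tempfile("simcat"), starts = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(config$seed, {
    mlen <- sample(1:6, config$n_loci, replace = TRUE,
                   prob = config$motif_len_weights)
    motifs <- vapply(mlen, rand_dna, character(1))
    copies <- sample(config$base_copy_range[1]:config$base_copy_range[2],
                     config$n_loci, replace = TRUE)
    tract_len <- nchar(motifs) * copies
    spacer <- config$flank + 50L
    if (is.null(starts)) {
      starts <- cumsum(c(spacer, tract_len[-config$n_loci] + spacer))
    } else {
      stopifnot(length(starts) == config$n_loci)
      o <- order(starts)
      if (any(starts[o][-1] < (starts + tract_len)[o][-config$n_loci]) ||
          starts[o][1] < spacer)
        stop("overlapping (or insufficiently spaced) loci requested")
    }
    ends <- starts + tract_len
    pieces <- character(0)
    cursor <- 0L
    for (i in seq_len(config$n_loci)) {
      pieces <- c(pieces, rand_dna(starts[i] - cursor),
                  strrep(motifs[i], copies[i]))
      cursor <- ends[i]
    }
    pieces <- c(pieces, rand_dna(spacer))
    ref_seq <- paste(pieces, collapse = "")

    fasta <- file.path(dir, "reference.fa")
    seqs <- Biostrings::DNAStringSet(ref_seq)
    names(seqs) <- config$contig
    Biostrings::writeXStringSet(seqs, fasta)
    bed <- file.path(dir, "catalog.bed")
    writeLines(sprintf("%s\t%d\t%d\t%s", config$contig, starts, ends, motifs),
               bed)
    catalog <- read_str_catalog(bed, "bed4")
    catalog$ref_copies <- as.numeric(copies)
    list(catalog = catalog, fasta = fasta, bed = bed, ref_seq = ref_seq,
         contig = config$contig)
  })
}

#' Simulate population allele counts over a catalog
#'
#' Draws per-genome integer allele counts per locus from the allele model
#' (locus base copy number plus rounded Gaussian jitter, truncated at 1);
#' haploid genomes contribute a single allele. An optional expansion spike
#' plants one outlier allele in one sample. Both the per-sample calls
#' tables and a truth table of every draw are returned.
#'
#' @param catalog Catalog from [simulate_catalog()] (uses `ref_copies` as
#'   the per-locus base copy number; loci lacking it get a freshly drawn
#'   base).
#' @param config A [sim_config()].
#' @return List: `calls` (named list sample -> calls data frame),
#'   `ploidies` (named vector), `truth` (sample, locus index, alleles).
#' @export
simulate_population_counts <- function(catalog, config) {
  with_seed(config$seed + 1L, {
    n <- nrow(catalog)
    base <- ifelse(is.na(catalog$ref_copies),
                   sample(config$base_copy_range[1]:config$base_copy_range[2],
                          n, replace = TRUE),
                   round(catalog$ref_copies))
    ploidies <- stats::setNames(
      ifelse(config$samples %in% config$haploid_samples, 1L, 2L),
      config$samples)
    draw <- function(k) pmax(1, base + round(stats::rnorm(k * n, 0, config$jitter_sd)))
    calls <- list()
    truth <- list()
    for (s in config$samples) {
      pl <- ploidies[[s]]
      a <- matrix(draw(pl), nrow = n)
      if (pl == 2L) a <- t(apply(a, 1L, sort))
      a1 <- a[, 1L]
      a2 <- if (pl == 2L) a[, 2L] else rep(NA_integer_, n)
      calls[[s]] <- data.frame(sample = s, chrom = catalog$chrom,
                               start = catalog$start, end = catalog$end,
                               motif = catalog$motif,
                               allele1 = as.integer(a1),
                               allele2 = as.integer(a2),
                               support1 = NA_integer_, support2 = NA_integer_,
                               n_reads = NA_integer_, stringsAsFactors = FALSE)
      truth[[s]] <- data.frame(sample = s, locus = seq_len(n),
                               allele1 = as.integer(a1),
                               allele2 = as.integer(a2),
                               stringsAsFactors = FALSE)
    }
    spike <- config$expansion_spike
    if (!is.null(spike)) {
      s <- if (!is.null(spike$sample)) spike$sample else config$samples[1]
      i <- spike$locus
      tgt <- if (ploidies[[s]] == 2L) "allele2" else "allele1"
      calls[[s]][[tgt]][i] <- as.integer(spike$count)
      truth[[s]][[tgt]][i] <- as.integer(spike$count)
    }
    list(calls = calls, ploidies = ploidies, truth = do.call(rbind, truth))
  })
}

# Build one noisy read spanning the locus: flank + allele-many motif copies
# + flank, with the CIGAR tracked through every planted error so the BAM
# coordinate mapping stays exact.
make_noisy_read <- function(ref_seq, locus, allele, config) {
  flank <- config$flank
  tract_read <- strrep(locus$motif, allele)
  lt <- nchar(tract_read)
  lr <- locus$end - locus$start
  read0 <- paste0(substr(ref_seq, locus$start - flank + 1L, locus$start),
                  tract_read,
                  substr(ref_seq, locus$end + 1L, locus$end + flank))
  base <- strsplit(read0, "")[[1]]
  nb <- length(base)
  # per-column alignment state: refc 1 = consumes reference (M), 0 = I;
  # template deletions (reference tract longer than read tract) are
  # appended as base-less columns after the read tract
  refc <- c(rep(1L, flank), rep(1L, min(lt, lr)),
            rep(0L, max(0L, lt - lr)), rep(1L, flank))
  keys <- seq_len(nb) * 10
  del_keys <- if (lr > lt) rep((flank + lt) * 10 + 1, lr - lt) else numeric(0)

  er <- config$read_error_rate
  drop <- logical(nb)
  ins_keys <- numeric(0); ins_base <- character(0)
  if (er > 0) {
    cand <- 2:(nb - 1L)  # keep the outermost bases error-free anchors
    hit <- cand[stats::runif(length(cand)) < er]
    if (length(hit)) {
      type <- sample(c("sub", "ins", "del"), length(hit), replace = TRUE,
                     prob = config$error_profile)
      acgt <- c("A", "C", "G", "T")
      for (k in seq_along(hit)) {
        p <- hit[k]
        if (type[k] == "sub") {
          base[p] <- sample(setdiff(acgt, base[p]), 1L)
        } else if (type[k] == "ins") {
          ins_keys <- c(ins_keys, keys[p] + 5)
          ins_base <- c(ins_base, sample(acgt, 1L))
        } else {
          if (refc[p] == 1L) base[p] <- NA_character_  # M -> D
          else drop[p] <- TRUE                          # planted I removed
        }
      }
    }
  }
  all_keys <- c(keys[!drop], ins_keys, del_keys)
  all_base <- c(base[!drop], ins_base, rep(NA_character_, length(del_keys)))
  all_refc <- c(refc[!drop], rep(0L, length(ins_keys)),
                rep(1L, length(del_keys)))
  o <- order(all_keys)
  b <- all_base[o]; rc <- all_refc[o]
  op <- ifelse(rc == 1L, ifelse(is.na(b), "D", "M"), "I")
  r <- rle(op)
  cigar <- paste0(r$lengths, r$values, collapse = "")
  seq <- paste(b[!is.na(b)], collapse = "")
  list(seq = seq, cigar = cigar, pos = locus$start - flank + 1L)
}

#' Simulate spanning reads for one locus
#'
#' Generates `read_depth` noisy reads per allele spanning the locus with
#' the configured flanks and returns them as SAM body lines with exact
#' coordinate mappings (positions, CIGARs) against the simulated
#' reference.
#'
#' @param locus Single catalog row.
#' @param alleles Integer vector of allele copy numbers (1 or 2).
#' @param config A [sim_config()].
#' @param ref_seq Contig sequence from [simulate_catalog()].
#' @param prefix Read-name prefix.
#' @param seed Optional seed (when called standalone); inside
#'   [simulate_alignments()] the stream is already seeded.
#' @return List: `sam` (character vector of alignment lines), `truth`
#'   (read_id, allele).
#' @export
simulate_reads <- function(locus, alleles, config, ref_seq,
                           prefix = "read", seed = NULL) {
  gen <- function() {
    sam <- character(0); ids <- character(0); tr <- integer(0)
    for (ai in seq_along(alleles)) {
      for (r in seq_len(config$read_depth)) {
        id <- sprintf("%s_a%d_r%03d", prefix, ai, r)
        rd <- make_noisy_read(ref_seq, locus, alleles[ai], config)
        sam <- c(sam, paste(id, 0L, config$contig, rd$pos, 60L, rd$cigar,
                            "*", 0L, 0L, rd$seq, strrep("I", nchar(rd$seq)),
                            sep = "\t"))
        ids <- c(ids, id); tr <- c(tr, alleles[ai])
      }
    }
    list(sam = sam, truth = data.frame(read_id = ids, allele = tr,
                                       stringsAsFactors = FALSE))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Simulate a sorted, indexed BAM for one genome
#'
#' Writes spanning reads for every catalog locus at the genotype given per
#' locus, converts to BAM, coordinate-sorts and indexes.
#'
#' @param catalog Catalog from [simulate_catalog()].
#' @param genotypes Data frame with one row per catalog locus, columns
#'   `allele1` and (optionally `NA`) `allele2`.
#' @param ref_seq Contig sequence.
#' @param config A [sim_config()].
#' @param out_prefix Output path prefix (the BAM will be
#'   `<out_prefix>.bam`).
#' @param sample_id Used in read names.
#' @return Path to the sorted indexed BAM.
#' @export
simulate_alignments <- function(catalog, genotypes, ref_seq, config,
                                out_prefix = tempfile("simbam"),
                                sample_id = "sim") {
  stopifnot(nrow(genotypes) == nrow(catalog))
  with_seed(config$seed + 2L, {
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", config$contig, nchar(ref_seq)))
    body <- character(0)
    for (i in seq_len(nrow(catalog))) {
      alleles <- c(genotypes$allele1[i], genotypes$allele2[i])
      alleles <- alleles[!is.na(alleles)]
      if (length(alleles) == 0L) next
      rd <- simulate_reads(catalog[i, ], alleles, config, ref_seq,
                           prefix = sprintf("%s_L%03d", sample_id, i))
      body <- c(body, rd$sam)
    }
    sam <- paste0(out_prefix, ".sam")
    writeLines(c(header, body), sam)
    bam0 <- Rsamtools::asBam(sam, paste0(out_prefix, "_unsorted"),
                             overwrite = TRUE, indexDestination = FALSE)
    sorted <- Rsamtools::sortBam(bam0, out_prefix)
    Rsamtools::indexBam(sorted)
    unlink(c(sam, bam0))
    sorted
  })
}
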