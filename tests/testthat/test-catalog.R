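test_that("BED4 catalogs are read with field mapping, case folding and skip accounting", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr14\t92071010\t92071053\tCAG",
               "chr1\t100\t130\tcag",          # lowercase motif
               "chr1\t500\t480\tCAG",          # end <= start: skipped
               "chr1\t900\t930\tCAGN"),        # non-ACGT motif: skipped
             bed)
  expect_warning(cat1 <- read_str_catalog(bed, "bed4"), "skipped 2")
  expect_s3_class(cat1, "str_catalog")
  expect_equal(nrow(cat1), 2L)
  expect_equal(attr(cat1, "n_skipped"), 2L)
  # loss counting: returned + skipped == data rows
  expect_equal(nrow(cat1) + attr(cat1, "n_skipped"), 4L)
  expect_equal(cat1$chrom[1], "chr14")
  expect_equal(cat1$start[1], 92071010)
  expect_equal(cat1$end[1], 92071053)
  expect_equal(cat1$motif, c("CAG", "CAG"))
  expect_equal(cat1$motif_len, c(3L, 3L))
})

test_that("simpleRepeat dumps are read with and without the bin column, header optional", {
  # full 17-column row (with bin), plus a header line
  row17 <- paste(c("585", "chr1", "10000", "10468", "trf", "6", "77.2", "6",
                   "95", "3", "789", "33", "51", "0", "15", "1.43",
                   "taaccc"), collapse = "\t")
  f <- tempfile()
  writeLines(c(paste(c("#bin", "chrom", "chromStart", "chromEnd", "name",
                       "period", "copyNum", "consensusSize", "perMatch",
                       "perIndel", "score", "A", "C", "G", "T", "entropy",
                       "sequence"), collapse = "\t"), row17), f)
  cat1 <- read_str_catalog(f, "simpleRepeat")
  expect_equal(nrow(cat1), 1L)
  expect_equal(cat1$chrom, "chr1")
  expect_equal(cat1$start, 10000)   # chromStart is already 0-based
  expect_equal(cat1$end, 10468)
  expect_equal(cat1$motif, "TAACCC")
  expect_equal(cat1$ref_copies, 77.2)

  # 16 columns, no bin, no header
  row16 <- paste(c("chr2", "200", "260", "trf", "3", "20", "3", "100", "0",
                   "120", "0", "33", "33", "33", "1.9", "cag"),
                 collapse = "\t")
  f2 <- tempfile()
  writeLines(row16, f2)
  cat2 <- read_str_catalog(f2, "simpleRepeat")
  expect_equal(cat2$motif, "CAG")
  expect_equal(cat2$ref_copies, 20)
})

test_that("missing files and unknown formats are fatal", {
  expect_error(read_str_catalog(tempfile(), "bed4"), "not found")
  f <- tempfile(); writeLines("chr1\t1\t10\tCAG", f)
  expect_error(read_str_catalog(f, "vcf"))
})

test_that("canonical_motif is the minimum over all rotations and is idempotent", {
  expect_equal(canonical_motif("CAG"), "AGC")
  expect_equal(canonical_motif("A"), "A")
  expect_equal(canonical_motif("ACAC"), "ACAC")
  set.seed(11)
  for (len in 1:6) {
    for (rep in 1:10) {
      m <- rand_motif(len)
      canon <- canonical_motif(m)
      # every rotation maps to the same canonical form
      rots <- vapply(seq_len(len) - 1L, function(k)
        paste0(substr(m, k + 1L, len), substr(m, 1L, k)), character(1))
      expect_true(all(canonical_motif(rots) == canon))
      expect_equal(canonical_motif(canon), canon)  # idempotent
      expect_equal(canon, min(rots))               # lexicographic minimum
    }
  }
  expect_error(canonical_motif(""), "A/C/G/T")
  expect_error(canonical_motif("CAGX"), "A/C/G/T")
})

test_that("poly-A/T detection agrees with brute force over all motifs up to length 3", {
  acgt <- c("A", "C", "G", "T")
  motifs <- unlist(lapply(1:3, function(len)
    apply(expand.grid(rep(list(acgt), len)), 1, paste, collapse = "")))
  for (m in motifs) {
    chars <- unique(strsplit(m, "")[[1]])
    expect_equal(is_poly_a_or_t(m),
                 identical(chars, "A") || identical(chars, "T"),
                 info = m)
  }
  expect_true(is_poly_a_or_t("A"))
  expect_true(is_poly_a_or_t("T"))
  expect_false(is_poly_a_or_t("CAG"))
})

test_that("region labels join by first containing interval with half-open semantics", {
  cat1 <- tiny_catalog(c("CAG", "AT", "CCG"), copies = c(10L, 10L, 10L))
  # loci start at 0, 1000, 2000
  regions <- data.frame(chrom = "chr1",
                        start = c(0, 0, 1500),
                        end = c(500, 2000, 2000),
                        region_class = c("exonic", "intronic", "intergenic"),
                        stringsAsFactors = FALSE)
  out <- attach_region_labels(cat1, regions)
  expect_equal(out$region_class[1], "exonic")    # first interval wins
  expect_equal(out$region_class[2], "intronic")
  # locus 3 starts at 2000 == region end: no match under half-open rule
  expect_equal(out$region_class[3], "unknown")
  # no table at all: everything unknown
  expect_true(all(attach_region_labels(cat1)$region_class == "unknown"))
})
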