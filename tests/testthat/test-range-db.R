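test_that("summarize_locus reproduces hand-derived min / p95 / sd values", {
  s <- summarize_locus(1:40)
  expect_equal(s$min_count, 1)
  expect_equal(s$upper_count, 38.05)        # h = 0.95 * 39 = 37.05
  expect_equal(s$sd, sqrt(sum((1:40 - 20.5)^2) / 39))
  expect_equal(s$n, 40L)

  s2 <- summarize_locus(c(10, 10, 14, 14))
  expect_equal(s2$min_count, 10)
  expect_equal(s2$sd, sqrt(16 / 3))

  s3 <- summarize_locus(c(7, 7, 7, 7))
  expect_equal(s3$upper_count, 7)
  expect_equal(s3$sd, 0)
  expect_equal(summarize_locus(5)$sd, 0)    # singleton pool
  expect_error(summarize_locus(numeric(0)), "empty")
})

test_that("summary statistics agree with the brute-force oracle on random pools", {
  set.seed(77)
  for (case in 1:200) {
    pool <- sample(1:120, sample(1:50, 1), replace = TRUE)
    s <- summarize_locus(pool)
    expect_equal(s$min_count, min(pool))
    expect_lt(abs(s$upper_count - oracle_p95(pool)), 1e-9)
    expect_lt(abs(s$sd - oracle_sd(pool)), 1e-9)
  }
})

test_that("diploid and haploid genomes pool the expected number of counts", {
  cfg <- sim_config(seed = 4, n_loci = 6, n_genomes = 21, n_haploid = 2)
  cat6 <- tiny_catalog(rep("CAG", 6), copies = rep(15L, 6))
  pop <- simulate_population_counts(cat6, cfg)
  pools <- aggregate_counts(pop$calls, pop$ploidies)
  expect_length(pools, 6L)
  for (p in pools) {
    expect_length(p$counts, 40L)            # 19 diploid pairs + 2 haploid
    expect_equal(p$n_genomes, 21L)
  }

  # a homozygous diploid contributes both alleles
  one <- list(s1 = tiny_calls(cat6[1, ], "s1", 20L, 20L))
  p1 <- aggregate_counts(one, c(s1 = 2L))
  expect_equal(p1[[1]]$counts, c(20, 20))

  # a no-call sample contributes nothing and decrements n_genomes
  two <- list(s1 = tiny_calls(cat6[1, ], "s1", 20L, 22L),
              s2 = tiny_calls(cat6[1, ], "s2", NA_integer_, NA_integer_))
  p2 <- aggregate_counts(two, c(s1 = 2L, s2 = 2L))
  expect_equal(p2[[1]]$n_genomes, 1L)
  expect_equal(p2[[1]]$counts, c(20, 22))

  expect_error(aggregate_counts(one, c(other = 2L)), "ploidy map")
})

test_that("database build is permutation-invariant in sample order and logs uncalled loci", {
  cfg <- sim_config(seed = 8, n_loci = 5, n_genomes = 6, n_haploid = 1)
  cat5 <- tiny_catalog(rep("AT", 5), copies = rep(12L, 5))
  pop <- simulate_population_counts(cat5, cfg)
  # knock out locus 3 in every genome
  calls <- lapply(pop$calls, function(df) {
    df$allele1[3] <- NA_integer_; df$allele2[3] <- NA_integer_; df
  })
  expect_message(db <- build_range_db(calls, pop$ploidies, cat5), "omitted")
  expect_equal(nrow(db$records), 4L)
  expect_false(cat5$start[3] %in% db$records$start)

  db_rev <- build_range_db(rev(calls), pop$ploidies[rev(names(calls))], cat5)
  core <- c("chrom", "start", "end", "motif", "min", "p95", "sd", "n_genomes")
  expect_equal(db$records[core], db_rev$records[core])
})

test_that("range records keep their ordering invariants when counts are added", {
  set.seed(30)
  for (case in 1:25) {
    pool <- sample(5:60, sample(2:30, 1), replace = TRUE)
    s <- summarize_locus(pool)
    expect_lte(s$min_count, s$upper_count)
    expect_lte(s$upper_count, max(pool))
    low <- min(pool) - sample(1:5, 1)
    s2 <- summarize_locus(c(pool, low))
    expect_lt(s2$min_count, s$min_count)       # new minimum lowers the floor
    expect_lte(s2$upper_count, s$upper_count)  # and never raises the bound
  }
})

test_that("database TSV round-trips losslessly, including no-call markers", {
  cfg <- sim_config(seed = 12, n_loci = 10, n_genomes = 5, n_haploid = 1)
  cat10 <- tiny_catalog(rep(c("CAG", "ATTT"), 5),
                        copies = rep(c(20L, 8L), 5))
  pop <- simulate_population_counts(cat10, cfg)
  pop$calls[["genome02"]]$allele1[4] <- NA_integer_  # plant a no-call
  pop$calls[["genome02"]]$allele2[4] <- NA_integer_
  db <- build_range_db(pop$calls, pop$ploidies, cat10)
  path <- tempfile(fileext = ".tsv")
  write_range_db(db, path)
  back <- read_range_db(path)
  expect_equal(back$records, db$records, tolerance = 1e-12)
  expect_equal(back$samples, db$samples)
  expect_equal(back$records[["genome02"]][4], ".")

  # a fractional percentile survives with at least 6 significant digits
  rec <- db$records
  rec$p95[1] <- 27.0666666666667
  db$records <- rec
  write_range_db(db, path)
  expect_equal(read_range_db(path)$records$p95[1], 27.0666666666667,
               tolerance = 1e-12)

  # malformed rows are fatal with a row number
  bad <- readLines(path)
  bad[2] <- sub("\t[0-9.]+\t", "\tnot_a_number\t", bad[2])
  writeLines(bad, path)
  expect_error(read_range_db(path), "row 1")
})
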