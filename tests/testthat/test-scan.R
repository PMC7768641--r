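# A deterministic toy runner: "genotyping" a locus just reports its
# catalog index, so combined outputs are easy to predict.
toy_catalog <- function(n) tiny_catalog(rep("CAG", n))
toy_runner <- function(locus) {
  data.frame(start = locus$start, motif = locus$motif,
             allele1 = locus$start / 1000 + 1, stringsAsFactors = FALSE)
}
unit_cost <- function(locus) 1

test_that("partitioning preserves order and covers every locus exactly once", {
  cat10 <- toy_catalog(10)
  tasks <- partition_loci(cat10, 4)
  expect_equal(vapply(tasks, function(t) length(t$idx), integer(1)),
               c(4L, 4L, 2L))
  expect_equal(unlist(lapply(tasks, `[[`, "idx")), 1:10)
  expect_length(partition_loci(toy_catalog(3), 10), 1L)
  expect_length(partition_loci(toy_catalog(0), 4), 0L)
  expect_error(partition_loci(cat10, 0), "set_size")
})

test_that("a scan with no kills returns every locus in catalog order", {
  cat10 <- toy_catalog(10)
  res <- run_scan(partition_loci(cat10, 4), toy_runner, cat10)
  expect_equal(nrow(res$results), 10L)
  expect_equal(res$results$start, cat10$start)  # catalog order
  expect_equal(nrow(res$dropped), 0L)
  expect_null(res$failed)
})

test_that("killed tasks regroup into smaller sets and still cover all loci", {
  cat10 <- toy_catalog(10)
  # cost 1/locus, budget 3: the 4-locus tasks are killed, their halves pass
  res <- run_scan(partition_loci(cat10, 4), toy_runner, cat10,
                  time_budget = 3, cost_fn = unit_cost)
  expect_equal(nrow(res$results), 10L)
  expect_equal(nrow(res$dropped), 0L)
  expect_true(any(res$task_log$status == "killed"))
  expect_true(any(res$task_log$depth > 0))
})

test_that("killed singletons are dropped, or retried without a budget on request", {
  cat4 <- toy_catalog(4)
  tasks <- partition_loci(cat4, 4)
  res_drop <- suppressWarnings(
    run_scan(tasks, toy_runner, cat4, time_budget = 0.5,
             cost_fn = unit_cost, drop_singletons = TRUE))
  expect_null(res_drop$results)
  expect_equal(nrow(res_drop$dropped), 4L)

  res_retry <- run_scan(tasks, toy_runner, cat4, time_budget = 0.5,
                        cost_fn = unit_cost, drop_singletons = FALSE)
  expect_equal(nrow(res_retry$results), 4L)
  expect_equal(nrow(res_retry$dropped), 0L)
})

test_that("scan conservation: results + dropped + failed == catalog", {
  cat10 <- toy_catalog(10)
  failing <- function(locus) {
    if (locus$start == 3000) stop("bad locus")
    toy_runner(locus)
  }
  res <- run_scan(partition_loci(cat10, 3), failing, cat10)
  expect_equal(nrow(res$results), 9L)
  expect_equal(nrow(res$failed), 1L)
  expect_match(res$failed$error, "bad locus")
  expect_equal(nrow(res$results) + nrow(res$dropped) + nrow(res$failed), 10L)

  # and under kill/drop pressure with a mix of costs
  costly <- function(locus) if (locus$start >= 8000) 10 else 1
  res2 <- suppressWarnings(
    run_scan(partition_loci(cat10, 4), failing, cat10, time_budget = 4,
             cost_fn = costly))
  n_res <- if (is.null(res2$results)) 0L else nrow(res2$results)
  n_fail <- if (is.null(res2$failed)) 0L else nrow(res2$failed)
  expect_equal(n_res + nrow(res2$dropped) + n_fail, 10L)
})

test_that("combined output is invariant to set size and byte-identical across runs", {
  cat10 <- toy_catalog(10)
  r1 <- run_scan(partition_loci(cat10, 1), toy_runner, cat10)
  r5 <- run_scan(partition_loci(cat10, 5), toy_runner, cat10)
  expect_identical(r1$results, r5$results)
  again <- run_scan(partition_loci(cat10, 5), toy_runner, cat10)
  expect_identical(r5$results, again$results)
})

test_that("a no-call row is retained in results while duplicates are fatal", {
  cat2 <- toy_catalog(2)
  nocall_runner <- function(locus) {
    data.frame(start = locus$start,
               allele1 = if (locus$start == 0) NA_integer_ else 5L,
               stringsAsFactors = FALSE)
  }
  res <- run_scan(partition_loci(cat2, 1), nocall_runner, cat2)
  expect_equal(nrow(res$results), 2L)   # no-call is not a dropped locus
  expect_true(is.na(res$results$allele1[1]))

  dup <- list(list(data.frame(x = 1, .locus_idx = 1L)),
              list(data.frame(x = 2, .locus_idx = 1L)))
  expect_error(combine_results(dup, cat2), "partition bug")
})

test_that("scan_genome applies the reference tract length filter", {
  cfg <- sim_config(seed = 13, n_loci = 4, n_genomes = 1, n_haploid = 0,
                    read_depth = 6, read_error_rate = 0)
  sim <- simulate_catalog(cfg)
  gt <- data.frame(allele1 = sim$catalog$ref_copies,
                   allele2 = sim$catalog$ref_copies)
  bam <- simulate_alignments(sim$catalog, gt, sim$ref_seq, cfg)
  tract <- sim$catalog$end - sim$catalog$start
  keep <- tract <= stats::median(tract)
  res <- scan_genome(bam, sim$catalog, "g1", set_size = 2,
                     max_tract_len = stats::median(tract))
  expect_equal(nrow(res$results), sum(keep))
  expect_equal(res$results$start, sim$catalog$start[keep])
  expect_equal(res$results$allele1, as.integer(sim$catalog$ref_copies[keep]))
})
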