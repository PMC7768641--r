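# Divide-and-conquer genome scan: loci are grouped into fixed-size tasks;
# a task exceeding its time budget is killed and its loci regrouped into
# smaller tasks, recursively, until tasks are singletons. Killed singletons
# are dropped (or retried once without a budget).

new_scan_task <- function(task_id, idx, depth = 0L) {
  structure(list(task_id = task_id, idx = as.integer(idx),
                 status = "pending", depth = as.integer(depth)),
            class = "scan_task")
}

#' Partition catalog loci into scan tasks
#'
#' @param loci An `str_catalog` (or any data frame of loci in catalog
#'   order).
#' @param set_size Number of loci per task (>= 1); the last task may be
#'   smaller.
#' @return List of `scan_task` objects preserving catalog order; each locus
#'   appears in exactly one task.
#' @export
partition_loci <- function(loci, set_size) {
  if (set_size < 1L) stop("set_size must be >= 1")
  n <- nrow(loci)
  if (n == 0L) return(list())
  starts <- seq(1L, n, by = set_size)
  lapply(seq_along(starts), function(i) {
    idx <- starts[i]:min(starts[i] + set_size - 1L, n)
    new_scan_task(sprintf("task%04d", i), idx)
  })
}

#' Run a genome scan with kill-and-regroup semantics
#'
#' Executes `runner` on every locus of every task under a per-task time
#' budget. A task whose cost exceeds the budget is killed and its loci are
#' re-partitioned into sets of `ceiling(size / regroup_factor)` as new
#' pending tasks; regrouping recurses until tasks hold a single locus. A
#' killed singleton is dropped (`drop_singletons = TRUE`, with a warning)
#' or retried once with an unlimited budget. A locus on which the runner
#' raises an error is recorded as failed (distinct from dropped) and the
#' scan continues.
#'
#' Budget accounting has two modes. With `cost_fn` supplied (a function
#' locus-row -> abstract cost units), a task's cost is the sum over its
#' loci and is known before execution, so kills are deterministic. Without
#' it, wall-clock seconds are accumulated and the task is killed at the
#' first locus boundary past the budget, discarding its partial results.
#'
#' @param tasks List of `scan_task`s from [partition_loci()].
#' @param runner Function taking a single-row locus data frame and
#'   returning a one-row data frame (the calls-table row for that locus).
#' @param catalog The catalog the tasks index into.
#' @param time_budget Per-task budget (seconds, or `cost_fn` units).
#' @param regroup_factor Integer >= 2; shrink factor for killed tasks.
#' @param drop_singletons Drop a killed singleton instead of retrying it
#'   once without a budget.
#' @param cost_fn Optional deterministic cost model for testing.
#' @return List of class `scan_result`: `results` (combined per-locus
#'   rows in catalog order), `dropped` (loci abandoned after kill),
#'   `failed` (loci whose runner errored, with messages), `task_log`.
#' @export
run_scan <- function(tasks, runner, catalog, time_budget = Inf,
                     regroup_factor = 2L, drop_singletons = TRUE,
                     cost_fn = NULL) {
  if (regroup_factor < 2L) stop("regroup_factor must be >= 2")
  queue <- tasks
  outputs <- list()
  dropped_idx <- integer(0)
  failed_idx <- integer(0)
  failed_msg <- character(0)
  log <- list()
  n_spawned <- length(tasks)

  exec_task <- function(task, budget) {
    # returns list(status, rows, failed_idx, failed_msg)
    rows <- vector("list", length(task$idx))
    f_idx <- integer(0); f_msg <- character(0)
    t0 <- proc.time()[["elapsed"]]
    for (j in seq_along(task$idx)) {
      i <- task$idx[j]
      row <- tryCatch(runner(catalog[i, , drop = FALSE]),
                      error = function(e) structure(conditionMessage(e),
                                                    class = "locus_failure"))
      if (inherits(row, "locus_failure")) {
        f_idx <- c(f_idx, i); f_msg <- c(f_msg, unclass(row))
      } else {
        row$.locus_idx <- i
        rows[[j]] <- row
      }
      if (is.null(cost_fn) && is.finite(budget) &&
          proc.time()[["elapsed"]] - t0 > budget && j < length(task$idx)) {
        return(list(status = "killed"))
      }
    }
    list(status = "done", rows = rows, failed_idx = f_idx, failed_msg = f_msg)
  }

  while (length(queue)) {
    task <- queue[[1]]
    queue <- queue[-1]
    killed <- FALSE
    if (!is.null(cost_fn)) {
      cost <- sum(vapply(task$idx, function(i)
        as.numeric(cost_fn(catalog[i, , drop = FALSE])), numeric(1)))
      killed <- cost > time_budget
    }
    if (!killed) {
      out <- exec_task(task, time_budget)
      killed <- identical(out$status, "killed")
    }
    if (killed) {
      if (length(task$idx) > 1L) {
        sub_size <- ceiling(length(task$idx) / regroup_factor)
        starts <- seq(1L, length(task$idx), by = sub_size)
        for (s in seq_along(starts)) {
          n_spawned <- n_spawned + 1L
          sub <- task$idx[starts[s]:min(starts[s] + sub_size - 1L, length(task$idx))]
          queue <- c(queue, list(new_scan_task(sprintf("task%04d", n_spawned),
                                               sub, task$depth + 1L)))
        }
        log[[length(log) + 1L]] <- data.frame(
          task_id = task$task_id, n_loci = length(task$idx),
          depth = task$depth, status = "killed", stringsAsFactors = FALSE)
        next
      }
      if (drop_singletons) {
        warning(sprintf("locus %d exceeded the scan budget and was dropped",
                        task$idx))
        dropped_idx <- c(dropped_idx, task$idx)
        log[[length(log) + 1L]] <- data.frame(
          task_id = task$task_id, n_loci = 1L, depth = task$depth,
          status = "dropped", stringsAsFactors = FALSE)
        next
      }
      out <- exec_task(task, Inf)  # one retry, unlimited budget
    }
    outputs[[length(outputs) + 1L]] <- out$rows
    failed_idx <- c(failed_idx, out$failed_idx)
    failed_msg <- c(failed_msg, out$failed_msg)
    log[[length(log) + 1L]] <- data.frame(
      task_id = task$task_id, n_loci = length(task$idx), depth = task$depth,
      status = "done", stringsAsFactors = FALSE)
  }

  results <- combine_results(outputs, catalog)
  failed <- if (length(failed_idx)) {
    cbind(catalog[failed_idx, , drop = FALSE],
          data.frame(error = failed_msg, stringsAsFactors = FALSE))
  } else NULL
  structure(list(results = results,
                 dropped = catalog[sort(dropped_idx), , drop = FALSE],
                 failed = failed,
                 task_log = if (length(log)) do.call(rbind, log) else NULL),
            class = "scan_result")
}

#' Combine per-task scan outputs into one per-locus table
#'
#' Binds task outputs into a single table with one row per successfully
#' genotyped locus, ordered by catalog order regardless of task execution
#' order. A locus appearing in more than one task output indicates a
#' partitioning bug and is a fatal error. No-call rows (empty allele
#' fields) are retained: a no-call is not a dropped locus.
#'
#' @param task_outputs List (one element per task) of lists of one-row data
#'   frames carrying a `.locus_idx` column.
#' @param catalog The catalog scanned.
#' @return Data frame in catalog order (the `.locus_idx` helper column is
#'   removed).
#' @export
combine_results <- function(task_outputs, catalog) {
  rows <- unlist(task_outputs, recursive = FALSE)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(NULL)
  df <- do.call(rbind, rows)
  if (anyDuplicated(df$.locus_idx))
    stop("locus present in more than one task output (partition bug)")
  df <- df[order(df$.locus_idx), , drop = FALSE]
  df$.locus_idx <- NULL
  rownames(df) <- NULL
  df
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan result: %d genotyped, %d dropped, %d failed\n",
              if (is.null(x$results)) 0L else nrow(x$results),
              nrow(x$dropped),
              if (is.null(x$failed)) 0L else nrow(x$failed)))
  invisible(x)
}

#' Scan a whole BAM over a catalog
#'
#' Convenience wrapper wiring [genotype_locus()] as the runner of
#' [run_scan()], producing a calls table for one sample.
#'
#' @inheritParams run_scan
#' @inheritParams genotype_locus
#' @param catalog The `str_catalog` to scan.
#' @param set_size Loci per task.
#' @param max_tract_len Optional filter: loci whose reference tract exceeds
#'   this length (bp) are excluded from the scan before partitioning.
#' @return A `scan_result` whose `results` element is a calls table.
#' @export
scan_genome <- function(bam, catalog, sample_id, set_size = 100L,
                        flank = 50L, min_reads = 5L, ploidy = 2L,
                        time_budget = Inf, regroup_factor = 2L,
                        drop_singletons = TRUE, max_tract_len = NULL,
                        cost_fn = NULL) {
  if (!is.null(max_tract_len))
    catalog <- catalog[(catalog$end - catalog$start) <= max_tract_len, ,
                       drop = FALSE]
  runner <- function(locus) {
    call <- genotype_locus(bam, locus, flank = flank, min_reads = min_reads,
                           ploidy = ploidy, sample_id = sample_id)
    call_to_row(call, locus, sample_id)
  }
  tasks <- partition_loci(catalog, set_size)
  run_scan(tasks, runner, catalog, time_budget = time_budget,
           regroup_factor = regroup_factor,
           drop_singletons = drop_singletons, cost_fn = cost_fn)
}
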