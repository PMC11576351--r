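# Batch execution across simulated worker slots. Pairs are assigned
# dynamically from a shared monotone counter, workers interrupt at the
# nominal score cap, and interrupted pairs are recovered by an unrestricted
# fallback aligner. Workers are sequential simulated slots with a
# deterministic round-robin event order; the contract is scheduling
# semantics, not concurrency.

#' Create a batch execution plan
#'
#' @param workers Number of simulated worker slots (> 0).
#' @param batch_size Pairs per batch (> 0).
#' @param score_cap Maximum nominal score on the worker path; `Inf` for
#'   unlimited.
#' @return An environment of class `batch_plan` holding the shared
#'   `next_pair_id` counter (0-based).
#' @export
batch_plan <- function(workers = 4L, batch_size = 64L, score_cap = Inf) {
  stopifnot(workers >= 1L, batch_size >= 1L, score_cap >= 0)
  e <- new.env(parent = emptyenv())
  e$workers <- as.integer(workers)
  e$batch_size <- as.integer(batch_size)
  e$score_cap <- score_cap
  e$next_pair_id <- 0L
  class(e) <- "batch_plan"
  e
}

#' Draw the next pair id from the shared counter
#'
#' Ids are issued exactly once, in monotone order of request; when the work
#' is exhausted `NA` signals end-of-work.
#'
#' @param plan A [batch_plan()].
#' @param n_total Total number of pairs available.
#' @return Integer id (0-based), or `NA_integer_` when exhausted.
#' @examples
#' pl <- batch_plan()
#' dynamic_assign(pl, 2)  # 0
#' dynamic_assign(pl, 2)  # 1
#' dynamic_assign(pl, 2)  # NA
#' @export
dynamic_assign <- function(plan, n_total) {
  if (plan$next_pair_id >= n_total) return(NA_integer_)
  id <- plan$next_pair_id
  plan$next_pair_id <- plan$next_pair_id + 1L
  id
}

#' Run a dataset through batched workers with hybrid recovery
#'
#' Pairs are processed in batches; within a batch, worker slots draw pair
#' ids round-robin from the shared counter and align with
#' [align_unrolled()] under the plan's score cap. Pairs interrupted at the
#' cap are flagged and re-aligned from scratch by the unrestricted fallback
#' ([wfa_align()] with no cap, memory-unconstrained). Recovery of batch `i`
#' is interleaved after the start of batch `i + 1` in the event log,
#' modelling compute/recovery overlap; results are emitted in input order
#' regardless of completion order.
#'
#' @param pairs List of [sequence_pair()] (non-empty). Ids are taken from
#'   list position (0-based).
#' @param penalties Uniform [penalties()].
#' @param plan A [batch_plan()].
#' @param budget A [memory_budget()].
#' @param ledger Optional [access_ledger()] shared across the run.
#' @param mode `"fused"` or `"unfused"`.
#' @return List with `alignments` (input order; each carries `path` =
#'   `"worker"` or `"recovery"`), `report` (a `recovery_report`: totals,
#'   recovered fraction, per-pair status data.frame) and `events`
#'   (data.frame of the logical event order).
#' @export
run_batches <- function(pairs, penalties = biwave::penalties(),
                        plan = batch_plan(), budget = memory_budget(),
                        ledger = NULL, mode = c("fused", "unfused")) {
  mode <- match.arg(mode)
  stopifnot(length(pairs) > 0L)
  n <- length(pairs)
  alns <- vector("list", n)
  recovered <- logical(n)
  ev_type <- character(0); ev_batch <- integer(0); ev_detail <- integer(0)
  log_ev <- function(type, batch, detail = NA_integer_) {
    i <- length(ev_type) + 1L
    ev_type[i] <<- type; ev_batch[i] <<- batch; ev_detail[i] <<- detail
  }

  pending_recovery <- integer(0)   # pair ids from the previous batch
  batch_no <- 0L
  repeat {
    # draw one batch of ids through the shared counter, round-robin workers
    ids <- integer(0)
    while (length(ids) < plan$batch_size) {
      id <- dynamic_assign(plan, n)
      if (is.na(id)) break
      ids <- c(ids, id)
    }
    if (length(ids) == 0L) break
    batch_no <- batch_no + 1L
    log_ev("batch_compute_start", batch_no)
    for (j in seq_along(ids)) {
      id <- ids[j]
      worker <- (j - 1L) %% plan$workers
      log_ev("worker_align", batch_no, id)
      al <- align_unrolled(pairs[[id + 1L]], penalties, budget,
                           score_cap = plan$score_cap, ledger = ledger,
                           mode = mode)
      al$pair_id <- id
      if (al$status == "interrupted") {
        recovered[id + 1L] <- TRUE
        log_ev("flagged_for_recovery", batch_no, id)
      }
      alns[[id + 1L]] <- al
    }
    # recovery of the previous batch overlaps this batch in the event log
    for (id in pending_recovery) {
      log_ev("cpu_recover", batch_no - 1L, id)
      al <- wfa_align(pairs[[id + 1L]], penalties)
      al$pair_id <- id
      al$path <- "recovery"
      alns[[id + 1L]] <- al
    }
    pending_recovery <- ids[vapply(ids, function(i) recovered[i + 1L], logical(1))]
  }
  for (id in pending_recovery) {
    log_ev("cpu_recover", batch_no, id)
    al <- wfa_align(pairs[[id + 1L]], penalties)
    al$pair_id <- id
    al$path <- "recovery"
    alns[[id + 1L]] <- al
  }

  status <- data.frame(
    pair_id = 0:(n - 1L),
    score = vapply(alns, function(a) as.integer(a$score), integer(1)),
    path = ifelse(recovered, "recovery", "worker"),
    stringsAsFactors = FALSE)
  report <- structure(list(
    total_pairs = n,
    recovered_pairs = sum(recovered),
    recovered_fraction = sum(recovered) / n,
    status = status), class = "recovery_report")
  list(alignments = alns, report = report,
       events = data.frame(type = ev_type, batch = ev_batch,
                           pair_id = ev_detail, stringsAsFactors = FALSE))
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d pairs, %d recovered (%.2f%%)\n",
              x$total_pairs, x$recovered_pairs, 100 * x$recovered_fraction))
  invisible(x)
}
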