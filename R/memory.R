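# Logical two-tier memory model: a fast scratch tier (64 KB per worker by
# default) and a bulk tier (64 MB), with counters for element and block
# transfers between them. The model counts logical accesses; it does not
# simulate latency.

#' Create an access ledger
#'
#' Mutable counters of bulk-tier traffic: wavefront element reads/writes,
#' wavefront elements computed, block-granularity reads/writes, sequence
#' block reads, spilled wavefront elements, and a log of the transfer sizes
#' used at each kernel iteration.
#'
#' @return An environment of class `access_ledger`.
#' @examples
#' led <- access_ledger()
#' charge_fused(led, 10)
#' ledger_report(led)
#' @export
access_ledger <- function() {
  e <- new.env(parent = emptyenv())
  e$wf_elem_reads <- 0
  e$wf_elem_writes <- 0
  e$wf_elems_computed <- 0
  e$wf_block_reads <- 0
  e$wf_block_writes <- 0
  e$seq_block_reads <- 0
  e$spill_elems <- 0
  e$next_run <- 0L
  e$tl_run <- integer(0)
  e$tl_iter <- integer(0)
  e$tl_bytes <- numeric(0)
  class(e) <- "access_ledger"
  e
}

ledger_next_run <- function(ledger) {
  ledger$next_run <- ledger$next_run + 1L
  ledger$next_run
}

ledger_log_transfer <- function(ledger, run, iter, bytes) {
  i <- length(ledger$tl_run) + 1L
  ledger$tl_run[i] <- run
  ledger$tl_iter[i] <- iter
  ledger$tl_bytes[i] <- bytes
  invisible(ledger)
}

#' Transfer-size log of a ledger
#'
#' @param ledger An [access_ledger()].
#' @return data.frame with columns `run` (kernel invocation), `iteration`
#'   and `bytes`.
#' @export
transfer_log <- function(ledger) {
  data.frame(run = ledger$tl_run, iteration = ledger$tl_iter,
             bytes = ledger$tl_bytes)
}

#' Charge bulk accesses for the separate compute-then-extend path
#'
#' The unfused path loads 3 wavefronts and writes 2 per element computed
#' (5 bulk accesses per wavefront element).
#'
#' @param ledger An [access_ledger()].
#' @param elements Number of wavefront elements computed (>= 0).
#' @return The ledger, invisibly.
#' @export
charge_unfused <- function(ledger, elements) {
  stopifnot(elements >= 0)
  ledger$wf_elem_reads <- ledger$wf_elem_reads + 3 * elements
  ledger$wf_elem_writes <- ledger$wf_elem_writes + 2 * elements
  ledger$wf_elems_computed <- ledger$wf_elems_computed + elements
  invisible(ledger)
}

#' Charge bulk accesses for the fused compute+extend path
#'
#' The fused kernel reads 2 wavefronts and writes 1 per element computed
#' (3 bulk accesses per wavefront element, a 40% reduction over the
#' separate path's 5).
#'
#' @inheritParams charge_unfused
#' @return The ledger, invisibly.
#' @export
charge_fused <- function(ledger, elements) {
  stopifnot(elements >= 0)
  ledger$wf_elem_reads <- ledger$wf_elem_reads + 2 * elements
  ledger$wf_elem_writes <- ledger$wf_elem_writes + elements
  ledger$wf_elems_computed <- ledger$wf_elems_computed + elements
  invisible(ledger)
}

charge_blocks <- function(ledger, reads = 0, writes = 0) {
  ledger$wf_block_reads <- ledger$wf_block_reads + reads
  ledger$wf_block_writes <- ledger$wf_block_writes + writes
  invisible(ledger)
}

charge_spill <- function(ledger, elements) {
  ledger$spill_elems <- ledger$spill_elems + elements
  invisible(ledger)
}

#' Summarise a ledger
#'
#' @param ledger An [access_ledger()].
#' @return A list of counters plus `accesses_per_element`, the total bulk
#'   wavefront element accesses divided by elements computed.
#' @export
ledger_report <- function(ledger) {
  acc <- ledger$wf_elem_reads + ledger$wf_elem_writes
  list(wf_elem_reads = ledger$wf_elem_reads,
       wf_elem_writes = ledger$wf_elem_writes,
       wf_elems_computed = ledger$wf_elems_computed,
       accesses_per_element = if (ledger$wf_elems_computed > 0)
         acc / ledger$wf_elems_computed else NA_real_,
       wf_block_reads = ledger$wf_block_reads,
       wf_block_writes = ledger$wf_block_writes,
       seq_block_reads = ledger$seq_block_reads,
       spill_elems = ledger$spill_elems,
       transfers_logged = length(ledger$tl_run))
}

#' Write a ledger report to disk
#'
#' @param ledger An [access_ledger()].
#' @param path Output path; `.json` gets the machine-readable form,
#'   anything else a flat `key<TAB>count` text table.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  rep <- ledger_report(ledger)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  } else {
    writeLines(paste(names(rep), unlist(rep), sep = "\t"), path)
  }
  invisible(path)
}

#' @export
print.access_ledger <- function(x, ...) {
  rep <- ledger_report(x)
  cat("<access_ledger>\n")
  for (k in names(rep)) cat(sprintf("  %-22s %s\n", k, format(rep[[k]])))
  invisible(x)
}

#' Transfer sizing policy
#'
#' Bulk transfers start at 8 bytes and grow by powers of two as the wavefront
#' grows, up to the 2048-byte transfer limit; every bulk address is 8-byte
#' aligned and sequence transfers are limited to 16 characters.
#'
#' @param initial_bytes,max_bytes,alignment_bytes,sequence_chunk Integers.
#' @return Object of class `transfer_policy`.
#' @export
transfer_policy <- function(initial_bytes = 8L, max_bytes = 2048L,
                            alignment_bytes = 8L, sequence_chunk = 16L) {
  stopifnot(initial_bytes >= 1L, max_bytes >= initial_bytes,
            alignment_bytes >= 1L, sequence_chunk >= 1L)
  structure(list(initial_bytes = as.integer(initial_bytes),
                 max_bytes = as.integer(max_bytes),
                 alignment_bytes = as.integer(alignment_bytes),
                 sequence_chunk = as.integer(sequence_chunk)),
            class = "transfer_policy")
}

#' Adaptive transfer size for the current iteration
#'
#' The smallest power of two at least the current wavefront demand, never
#' below the policy's initial size (8 bytes), never above the policy maximum
#' (2048 bytes) or the largest power of two fitting the fast buffer, and
#' never below `current` so sizes are non-decreasing across iterations of
#' one alignment.
#'
#' @param demand_bytes Current wavefront size in bytes (> 0).
#' @param policy A [transfer_policy()].
#' @param fast_buffer_bytes Fast-tier buffer allocation bound.
#' @param current Transfer size of the previous iteration.
#' @return Integer number of bytes.
#' @examples
#' adaptive_transfer_size(4)        # 8
#' adaptive_transfer_size(100000)   # 2048
#' @export
adaptive_transfer_size <- function(demand_bytes, policy = transfer_policy(),
                                   fast_buffer_bytes = Inf,
                                   current = policy$initial_bytes) {
  stopifnot(demand_bytes > 0, fast_buffer_bytes > 0)
  cap <- min(policy$max_bytes, 2^floor(log2(fast_buffer_bytes)))
  cap <- max(cap, policy$initial_bytes)
  want <- 2^ceiling(log2(max(demand_bytes, policy$initial_bytes)))
  as.integer(min(cap, max(want, current, policy$initial_bytes)))
}

#' Memory budget of one worker
#'
#' Capacities of the fast scratch tier and the bulk tier, the wavefront
#' element width (32-bit offsets by default), and the derived largest WFA
#' score whose full retained wavefront set fits the fast tier: a score-`s`
#' run retains wavefronts 0..s, the score-`t` wavefront spanning `2t + 1`
#' diagonals, `(s + 1)^2` elements in total.
#'
#' @param fast_capacity_bytes Fast-tier capacity (default 65536, 64 KB).
#' @param wavefront_element_bytes Bytes per offset (default 4).
#' @param bulk_capacity_bytes Bulk-tier capacity (default 64 MB).
#' @return Object of class `memory_budget` with derived
#'   `base_case_max_score`.
#' @export
memory_budget <- function(fast_capacity_bytes = 65536L,
                          wavefront_element_bytes = 4L,
                          bulk_capacity_bytes = 64L * 1048576L) {
  stopifnot(fast_capacity_bytes >= 1, wavefront_element_bytes >= 1,
            bulk_capacity_bytes >= fast_capacity_bytes)
  s_max <- floor(sqrt(fast_capacity_bytes / wavefront_element_bytes)) - 1L
  structure(list(fast_capacity_bytes = as.numeric(fast_capacity_bytes),
                 wavefront_element_bytes = as.integer(wavefront_element_bytes),
                 bulk_capacity_bytes = as.numeric(bulk_capacity_bytes),
                 base_case_max_score = as.integer(max(s_max, 0L))),
            class = "memory_budget")
}

#' Bulk-tier sequence store with alignment padding
#'
#' Holds a byte sequence padded to a multiple of the policy alignment so
#' aligned reverse reads near the boundaries never address outside the
#' store.
#'
#' @param data A raw vector or character scalar.
#' @param policy A [transfer_policy()].
#' @return Object of class `bulk_store`.
#' @export
bulk_store <- function(data, policy = transfer_policy()) {
  if (is.character(data)) data <- charToRaw(data)
  stopifnot(is.raw(data))
  al <- policy$alignment_bytes
  padded <- as.integer(ceiling(length(data) / al) * al)
  structure(list(data = data, length = length(data), padded_length = padded,
                 policy = policy),
            class = "bulk_store")
}

#' Read a window of a bulk store in reverse
#'
#' Returns the bytes of `[start, start + length)` (0-based) ordered
#' last-to-first, without materialising a reversed copy of the store. Every
#' modeled bulk access is aligned: the charged window is rounded outward to
#' the policy alignment and read in sequence-chunk blocks (16 characters by
#' default).
#'
#' @param store A [bulk_store()].
#' @param start 0-based start address within the store.
#' @param length Number of bytes.
#' @param ledger Optional [access_ledger()] charged with the block reads.
#' @return Raw vector of `length` bytes in reverse order.
#' @export
reverse_block_read <- function(store, start, length, ledger = NULL) {
  stopifnot(start >= 0, length >= 0)
  if (start + length > store$padded_length)
    stop("read of [", start, ", ", start + length,
         ") exceeds padded store of ", store$padded_length, " bytes")
  pol <- store$policy
  if (!is.null(ledger) && length > 0) {
    a0 <- floor(start / pol$alignment_bytes) * pol$alignment_bytes
    a1 <- ceiling((start + length) / pol$alignment_bytes) * pol$alignment_bytes
    ledger$seq_block_reads <- ledger$seq_block_reads +
      ceiling((a1 - a0) / pol$sequence_chunk)
  }
  if (length == 0) return(raw(0))
  idx <- seq.int(start + length, start + 1L)      # 1-based, reversed
  out <- raw(length)
  inside <- idx <= store$length                    # padding bytes read as 0
  out[inside] <- store$data[idx[inside]]
  out
}

#' Place a wavefront in the fast or bulk tier
#'
#' Elements beyond the fast-tier allocation spill to the bulk tier; spilled
#' elements are charged to the ledger and all further accesses to them count
#' as bulk traffic.
#'
#' @param wf A [wavefront()].
#' @param budget A [memory_budget()].
#' @param ledger Optional [access_ledger()].
#' @param fast_allocation_bytes Fast-tier allocation for this wavefront
#'   (defaults to a quarter of the fast capacity, one of the four live
#'   buffers).
#' @return List with `placement` (`"fast"` or `"bulk"`) and
#'   `spilled_elements`.
#' @export
spill_wavefront <- function(wf, budget, ledger = NULL,
                            fast_allocation_bytes = budget$fast_capacity_bytes / 4) {
  eb <- budget$wavefront_element_bytes
  elems <- length(wf$off)
  bytes <- elems * eb
  if (bytes > budget$bulk_capacity_bytes)
    stop("wavefront of ", bytes, " bytes exceeds bulk capacity of ",
         budget$bulk_capacity_bytes, " bytes")
  if (bytes <= fast_allocation_bytes)
    return(list(placement = "fast", spilled_elements = 0L))
  spilled <- elems - as.integer(floor(fast_allocation_bytes / eb))
  if (!is.null(ledger)) charge_spill(ledger, spilled)
  list(placement = "bulk", spilled_elements = spilled)
}
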