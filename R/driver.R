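# Breakpoint-unrolled pipeline: an explicit work queue of segments replaces
# BiWFA's recursion. Segments whose score bound fits the base-case budget are
# solved by classic WFA entirely in the fast tier; larger segments are split
# at a breakpoint into two children with exactly known half scores. Base-case
# transcripts are emitted with an order index so the final CIGAR is a plain
# in-order concatenation.

#' Base-case decision rule
#'
#' A segment with (exact) score bound `s` becomes a base case when a full WFA
#' of score up to `4 * s` fits into the fast-tier space repurposed from the
#' four live bidirectional wavefront buffers: `(4 s + 1)^2` retained elements
#' must fit `fast_capacity_bytes`.
#'
#' @param budget A [memory_budget()].
#' @param current_biwfa_score Non-negative integer score bound of the segment.
#' @return Logical.
#' @examples
#' base_case_threshold(memory_budget(), 0)    # TRUE
#' base_case_threshold(memory_budget(), 31)   # TRUE  (4 s = 124 <= 127)
#' base_case_threshold(memory_budget(), 32)   # FALSE
#' @export
base_case_threshold <- function(budget, current_biwfa_score) {
  stopifnot(current_biwfa_score >= 0)
  (4 * current_biwfa_score + 1)^2 * budget$wavefront_element_bytes <=
    budget$fast_capacity_bytes
}

#' Assemble base-case outputs into one alignment
#'
#' Concatenates partial CIGARs in `order_index` order (arrival order is
#' irrelevant); adjacent runs merge across boundaries. The assembled score
#' is the penalty-weighted cost of the whole transcript, which equals the
#' sum of the part scores.
#'
#' @param parts List of parts, each a list with fields `order_index` and
#'   `cigar`.
#' @param penalties A [penalties()] used to score the result.
#' @param pair_id Identifier for the resulting [alignment()].
#' @return An [alignment()].
#' @export
assemble_output <- function(parts, penalties = biwave::penalties(),
                            pair_id = NA_integer_) {
  stopifnot(length(parts) > 0L)
  idx <- vapply(parts, function(p) {
    if (is.null(p$order_index) || is.na(p$order_index))
      stop("assemble_output: part is missing its order_index")
    as.integer(p$order_index)
  }, integer(1))
  if (anyDuplicated(idx)) stop("assemble_output: duplicate order_index")
  cigs <- vapply(parts, function(p) p$cigar, character(1))[order(idx)]
  cig <- cigar_concat(cigs)
  alignment(cigar_score(cig, penalties), cig, pair_id = pair_id)
}

sub_pair <- function(pair, q0, q1, r0, r1) {
  sequence_pair(substr(pair$query, q0 + 1L, q1),
                substr(pair$reference, r0 + 1L, r1),
                pair_id = pair$pair_id)
}

#' Align a pair by the unrolled breakpoint pipeline
#'
#' Maintains an explicit queue of segments (half-open query/reference
#' intervals with an inherited exact score bound). Each segment is either
#' emitted directly (empty or zero-score), solved as a WFA base case in the
#' fast tier, or split at a bidirectional breakpoint into two children whose
#' bounds are the exact half scores. Base cases are written with order
#' indexes so the final transcript is an in-order concatenation; the peak
#' fast-tier residency never exceeds the budget (larger wavefronts spill to
#' the bulk tier and are charged to the ledger).
#'
#' @param pair A [sequence_pair()].
#' @param penalties Uniform [penalties()].
#' @param budget A [memory_budget()].
#' @param score_cap Maximum nominal score; exceeding it interrupts the pair
#'   and flags it for recovery.
#' @param ledger Optional [access_ledger()].
#' @param mode `"fused"` or `"unfused"` kernel accounting.
#' @param policy A [transfer_policy()].
#' @return An [alignment()]; attribute `"stats"` carries `splits`,
#'   `base_cases`, `segments`, `peak_fast_bytes`, `peak_queue` and
#'   `base_case_bulk_spill` (spilled elements charged during base cases,
#'   zero whenever the threshold formula is honoured).
#' @examples
#' p <- sequence_pair("ACGTACGTAA", "ACGAACGTAA")
#' align_unrolled(p)
#' @export
align_unrolled <- function(pair, penalties = biwave::penalties(),
                           budget = memory_budget(), score_cap = Inf,
                           ledger = NULL, mode = c("fused", "unfused"),
                           policy = transfer_policy()) {
  mode <- match.arg(mode)
  require_uniform(penalties)

  queue <- list(list(q0 = 0L, q1 = pair$n, r0 = 0L, r1 = pair$m,
                     bound = NA_integer_))
  parts <- list()
  splits <- 0L; base_cases <- 0L
  peak_fast <- 0; peak_queue <- 1L
  spill_before <- if (is.null(ledger)) 0 else ledger$spill_elems
  base_spill <- 0

  while (length(queue) > 0L) {
    peak_queue <- max(peak_queue, length(queue))
    seg <- queue[[1L]]; queue <- queue[-1L]
    sp <- sub_pair(pair, seg$q0, seg$q1, seg$r0, seg$r1)

    if (sp$n == 0L && sp$m == 0L) next
    if (sp$n == 0L || sp$m == 0L) {
      cig <- if (sp$m > 0L) paste0(sp$m, "D") else paste0(sp$n, "I")
      parts[[length(parts) + 1L]] <-
        list(q0 = seg$q0, r0 = seg$r0, cigar = cig)
      next
    }
    if (!is.na(seg$bound) && seg$bound == 0L) {
      parts[[length(parts) + 1L]] <-
        list(q0 = seg$q0, r0 = seg$r0, cigar = paste0(sp$n, "M"))
      next
    }

    if (!is.na(seg$bound) &&
        (base_case_threshold(budget, seg$bound) || seg$bound <= 1L)) {
      s0 <- if (is.null(ledger)) 0 else ledger$spill_elems
      al <- wfa_align(sp, penalties, score_cap = 4 * seg$bound, mode = mode,
                      ledger = ledger, budget = budget, tier = "fast",
                      policy = policy)
      if (al$status != "complete")
        stop("base case exceeded its inherited score bound (internal error)")
      base_cases <- base_cases + 1L
      st <- attr(al, "stats")
      peak_fast <- max(peak_fast, st$peak_fast_bytes)
      if (!is.null(ledger)) base_spill <- base_spill + (ledger$spill_elems - s0)
      parts[[length(parts) + 1L]] <-
        list(q0 = seg$q0, r0 = seg$r0, cigar = al$cigar)
      next
    }

    cap <- if (is.na(seg$bound)) score_cap else seg$bound
    bp <- biwfa_find_breakpoint(sp, penalties, score_cap = cap, mode = mode,
                                ledger = ledger, budget = budget,
                                policy = policy)
    if (bp$status == "interrupted") {
      res <- alignment(NA_integer_, NA_character_, status = "interrupted",
                       pair_id = pair$pair_id)
      attr(res, "stats") <- list(splits = splits, base_cases = base_cases,
                                 segments = length(parts),
                                 peak_fast_bytes = peak_fast,
                                 peak_queue = peak_queue,
                                 base_case_bulk_spill = base_spill)
      return(res)
    }
    st <- attr(bp, "stats")
    peak_fast <- max(peak_fast, st$peak_fast_bytes)
    s <- bp$forward_score + bp$backward_score
    if (s == 0L) {
      # whole segment is matches; no split recorded
      parts[[length(parts) + 1L]] <-
        list(q0 = seg$q0, r0 = seg$r0, cigar = paste0(sp$n, "M"))
      next
    }
    splits <- splits + 1L
    queue <- c(queue, list(
      list(q0 = seg$q0, q1 = seg$q0 + bp$q_pos,
           r0 = seg$r0, r1 = seg$r0 + bp$r_pos, bound = bp$forward_score),
      list(q0 = seg$q0 + bp$q_pos, q1 = seg$q1,
           r0 = seg$r0 + bp$r_pos, r1 = seg$r1, bound = bp$backward_score)))
  }

  # order by position in the tiling; parts carry their interval starts
  ord <- order(vapply(parts, `[[`, integer(1), "r0"),
               vapply(parts, `[[`, integer(1), "q0"))
  parts <- parts[ord]
  for (i in seq_along(parts)) parts[[i]]$order_index <- i
  res <- assemble_output(parts, penalties, pair_id = pair$pair_id)
  attr(res, "stats") <- list(splits = splits, base_cases = base_cases,
                             segments = length(parts),
                             peak_fast_bytes = peak_fast,
                             peak_queue = peak_queue,
                             base_case_bulk_spill = base_spill)
  res
}
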