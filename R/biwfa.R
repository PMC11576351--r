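# Bidirectional WFA: forward and backward frontiers advance in score order
# until they meet on a diagonal; the meeting point is a breakpoint on an
# optimal path and the two frontier scores sum to the optimal score.
#
# Overlap rule (unit-cost argument, validated against the DP oracle in the
# test suite): frontiers overlap when, on some shared diagonal, the forward
# offset h_f plus the backward offset h_b (measured on the reversed
# sequences) covers the reference, h_f + h_b >= m. Checking after every
# single-direction step under lower-score-first alternation visits each
# combined score exactly once, so the first overlap yields the optimal score
# s = s_fwd + s_rev with no correction term: detection is never late (split
# an optimal path at prefix score s_fwd; furthest-reaching monotonicity puts
# both frontiers past the split point) and never early (the edit-distance DP
# is non-decreasing along diagonals, so the cost of cutting at the forward
# furthest-reaching point is bounded by s_fwd + s_rev).

#' Construct a breakpoint
#'
#' A coordinate `(q_pos, r_pos)` on an optimal alignment path, with the exact
#' optimal scores of the prefix (`forward_score`) and suffix
#' (`backward_score`) halves.
#'
#' @param q_pos,r_pos Integer cut positions in `[0, n]` and `[0, m]`.
#' @param forward_score,backward_score Non-negative integers.
#' @param status `"complete"` or `"interrupted"`.
#' @return Object of class `breakpoint`.
#' @export
breakpoint <- function(q_pos, r_pos, forward_score, backward_score,
                       status = "complete") {
  structure(list(q_pos = as.integer(q_pos), r_pos = as.integer(r_pos),
                 forward_score = as.integer(forward_score),
                 backward_score = as.integer(backward_score),
                 status = status),
            class = "breakpoint")
}

#' @export
print.breakpoint <- function(x, ...) {
  if (x$status == "interrupted") cat("<breakpoint> interrupted\n")
  else cat(sprintf("<breakpoint> (%d, %d) fwd=%d rev=%d\n",
                   x$q_pos, x$r_pos, x$forward_score, x$backward_score))
  invisible(x)
}

# scan for an overlapping diagonal; returns NULL or list(k, h_f)
biwfa_overlap <- function(fw, bw, n, m) {
  kd <- m - n                      # backward diagonal k' maps to k = kd - k'
  klo <- max(fw$lo, kd - bw$hi)
  khi <- min(fw$hi, kd - bw$lo)
  if (klo > khi) return(NULL)
  ks <- klo:khi
  hf <- fw$off[ks - fw$lo + 1L]
  hb <- bw$off[(kd - ks) - bw$lo + 1L]
  ok <- hf != WF_SENTINEL & hb != WF_SENTINEL & (hf + hb) >= m
  if (!any(ok)) return(NULL)
  k <- ks[ok][1L]                  # first (lowest) overlapping diagonal
  list(k = k, h_f = hf[ok][1L])
}

#' Find the optimal-score breakpoint by bidirectional search
#'
#' Runs forward and backward wavefronts (the backward frontier is the forward
#' kernel applied to the reversed sequences) with lower-score-first
#' alternation (ties advance forward) until they overlap. Only the live
#' frontier wavefronts are retained, so peak wavefront memory is O(s)
#' elements. Returns a [breakpoint()] whose half scores are exact and sum to
#' the optimal alignment score, or status `"interrupted"` if the combined
#' score would exceed `score_cap`.
#'
#' Empty sequences bypass the search: the trivial all-indel breakpoint at
#' `(0, 0)` is returned (the backward frontier is undefined on an empty
#' sequence).
#'
#' @param pair A [sequence_pair()].
#' @param penalties Uniform [penalties()].
#' @param score_cap Maximum combined score before interruption.
#' @param mode,ledger,budget,policy Kernel accounting controls as in
#'   [wfa_align()]; wavefronts stream through the bulk tier, with spill
#'   accounting against `budget` when given.
#' @return A [breakpoint()]; attribute `"stats"` carries `steps`,
#'   `live_trace` (number of occupied wavefront buffers at each step),
#'   `peak_live_elements` and `peak_fast_bytes`.
#' @examples
#' biwfa_find_breakpoint(sequence_pair("ACGTACGT", "ACGAACGT"))
#' @export
biwfa_find_breakpoint <- function(pair, penalties = biwave::penalties(),
                                  score_cap = Inf,
                                  mode = c("fused", "unfused"), ledger = NULL,
                                  budget = NULL, policy = transfer_policy()) {
  mode <- match.arg(mode)
  p <- require_uniform(penalties)
  n <- pair$n; m <- pair$m

  if (n == 0L || m == 0L) {
    sc <- (n + m) * p
    if (sc > score_cap)
      return(breakpoint(0L, 0L, 0L, 0L, status = "interrupted"))
    bp <- breakpoint(0L, 0L, 0L, sc)
    attr(bp, "stats") <- list(steps = 0L, live_trace = 0L,
                              peak_live_elements = 0L, peak_fast_bytes = 0L)
    return(bp)
  }

  rp_f <- raw_pair(pair)
  rp_b <- raw_pair(pair, reverse = TRUE)
  eb <- if (is.null(budget)) 4L else budget$wavefront_element_bytes
  tstate <- new_tstate(ledger, policy)

  # four wavefront buffers: previous + current per direction
  prev_f <- NULL; cur_f <- wf_seed(rp_f); df <- 0L
  prev_b <- NULL; cur_b <- wf_seed(rp_b); db <- 0L

  live_elems <- function()
    length(cur_f$off) + length(cur_b$off) +
      (if (is.null(prev_f)) 0L else length(prev_f$off)) +
      (if (is.null(prev_b)) 0L else length(prev_b$off))
  live_bufs <- function()
    2L + (!is.null(prev_f)) + (!is.null(prev_b))

  live_trace <- live_bufs()
  peak_elems <- live_elems()
  steps <- 0L

  charge_live <- function(wf) {
    if (!is.null(budget) && !is.null(ledger))
      spill_wavefront(wf, budget, ledger,
                      fast_allocation_bytes = budget$fast_capacity_bytes / 4)
  }

  repeat {
    hit <- biwfa_overlap(cur_f, cur_b, n, m)
    if (!is.null(hit)) {
      bp <- breakpoint(q_pos = hit$h_f - hit$k, r_pos = hit$h_f,
                       forward_score = df, backward_score = db)
      attr(bp, "stats") <- list(
        steps = steps, live_trace = live_trace,
        peak_live_elements = peak_elems,
        peak_fast_bytes = min(peak_elems * eb,
                              if (is.null(budget)) Inf else budget$fast_capacity_bytes))
      return(bp)
    }
    if (df + db + p > score_cap)
      return(breakpoint(0L, 0L, 0L, 0L, status = "interrupted"))
    if (df <= db) {
      prev_f <- cur_f
      cur_f <- wf_step(prev_f, rp_f, p, mode, ledger, eb, policy, tstate)
      df <- df + p
      charge_live(cur_f)
    } else {
      prev_b <- cur_b
      cur_b <- wf_step(prev_b, rp_b, p, mode, ledger, eb, policy, tstate)
      db <- db + p
      charge_live(cur_b)
    }
    steps <- steps + 1L
    live_trace <- c(live_trace, live_bufs())
    peak_elems <- max(peak_elems, live_elems())
  }
}

#' Number of live wavefront buffers held by the bidirectional search
#'
#' Two buffers per direction (previous and current frontier) are required to
#' step the search, so four under uniform penalties; before the first step
#' only the two score-0 frontiers exist. The instrumented trace returned by
#' [biwfa_find_breakpoint()] verifies the bound at run time.
#'
#' @param penalties Uniform [penalties()].
#' @return Integer, 4.
#' @export
live_wavefront_count <- function(penalties = biwave::penalties()) {
  require_uniform(penalties)
  4L
}
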