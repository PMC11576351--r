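# WFA primitives: wavefront container, LCP extend, compute, the fused
# compute+extend step, and the full base-case aligner with traceback.
#
# Coordinate convention (fixed package-wide): 0-based, half-open intervals;
# diagonal k = (reference offset h) - (query offset v); the stored offset is
# h. The terminal cell is k_end = m - n at offset m. Under this convention a
# mismatch advances the same diagonal by one, a deletion (reference-consuming)
# feeds diagonal k from k - 1 with offset + 1, and an insertion
# (query-consuming) feeds k from k + 1 with the offset unchanged.

#' Construct a wavefront
#'
#' The set of furthest-reaching reference offsets, one per diagonal
#' `k in [lo, hi]`, for a given score. Unreachable diagonals hold a sentinel
#' ordered below every valid offset.
#'
#' @param score Non-negative integer score of the wavefront.
#' @param lo,hi Integer diagonal range, `lo <= hi`.
#' @param offsets Integer vector of length `hi - lo + 1`.
#' @return Object of class `wavefront` with fields `score`, `lo`, `hi`, `off`.
#' @export
wavefront <- function(score, lo, hi, offsets) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  stopifnot(lo <= hi, length(offsets) == hi - lo + 1L)
  structure(list(score = as.integer(score), lo = lo, hi = hi,
                 off = as.integer(offsets)),
            class = "wavefront")
}

#' Sentinel marking unreachable diagonals in a wavefront
#' @return Integer sentinel value.
#' @export
wf_sentinel <- function() WF_SENTINEL

# offset at diagonal k, sentinel when outside [lo, hi]
wf_at <- function(wf, k) {
  i <- k - wf$lo + 1L
  if (i < 1L || i > length(wf$off)) return(WF_SENTINEL)
  wf$off[i]
}

raw_pair <- function(pair, reverse = FALSE) {
  q <- charToRaw(pair$query); r <- charToRaw(pair$reference)
  if (reverse) { q <- rev(q); r <- rev(r) }
  list(q = q, r = r, n = pair$n, m = pair$m)
}

wf_extend_raw <- function(wf, rp) {
  wf$off <- wf_extend_cpp(rp$q, rp$r, wf$lo, wf$off, WF_SENTINEL)
  wf
}

#' Extend a wavefront by longest common prefixes
#'
#' Advances every reachable offset by the length of the longest common prefix
#' of the remaining query/reference suffixes on its diagonal (free matches).
#' The backward direction extends over the reversed sequences, i.e. matches
#' remaining prefixes read right to left. No offset decreases.
#'
#' @param wf A [wavefront()] whose offsets are valid for `pair`.
#' @param pair A [sequence_pair()].
#' @param direction `"forward"` or `"backward"`.
#' @return The extended wavefront.
#' @export
extend_wavefront <- function(wf, pair, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  wf_extend_raw(wf, raw_pair(pair, reverse = direction == "backward"))
}

wf_compute_raw <- function(prev, rp, step) {
  n <- rp$n; m <- rp$m
  lo <- max(prev$lo - 1L, -n); hi <- min(prev$hi + 1L, m)
  ks <- lo:hi
  src <- function(kk) {
    i <- kk - prev$lo + 1L
    v <- rep.int(WF_SENTINEL, length(kk))
    ok <- i >= 1L & i <= length(prev$off)
    v[ok] <- prev$off[i[ok]]
    v
  }
  mis <- src(ks)                 # mismatch: same diagonal, advance one
  del <- src(ks - 1L)            # deletion: from k - 1, advance one
  ins <- src(ks + 1L)            # insertion: from k + 1, offset unchanged
  # a predecessor is only usable while its cell still has the consumed
  # characters left; mask boundary cells before taking the maximum
  mis[mis != WF_SENTINEL & mis >= pmin(m, n + ks)] <- WF_SENTINEL
  del[del != WF_SENTINEL & del >= m] <- WF_SENTINEL
  ins[ins != WF_SENTINEL & ins > n + ks] <- WF_SENTINEL
  off <- pmax(mis + 1L, del + 1L, ins)
  off[off < 0L] <- WF_SENTINEL
  # trim sentinel fringes so the stored range stays tight
  live <- which(off != WF_SENTINEL)
  if (length(live) == 0L) stop("wavefront died; sequences unalignable (internal error)")
  a <- live[1L]; b <- live[length(live)]
  wavefront(prev$score + step, lo + a - 1L, lo + b - 1L, off[a:b])
}

#' Compute the successor wavefront
#'
#' Derives the wavefront one penalty step ahead from an extended wavefront:
#' for each diagonal the best furthest-reaching offset over the mismatch,
#' insertion and deletion predecessors, with out-of-matrix results marked
#' unreachable. Requires uniform penalties (see [penalties()]).
#'
#' @param prev An extended [wavefront()].
#' @param pair The [sequence_pair()] being aligned (bounds the diagonals).
#' @param penalties Uniform [penalties()].
#' @return The wavefront at `prev$score + penalty`.
#' @export
compute_wavefront <- function(prev, pair, penalties = biwave::penalties()) {
  p <- require_uniform(penalties)
  wf_compute_raw(prev, raw_pair(pair), p)
}

#' Fused compute+extend step
#'
#' Semantically identical to `extend_wavefront(compute_wavefront(prev))`; the
#' two passes are merged so each produced wavefront element costs 2 bulk
#' reads and 1 bulk write instead of the separate path's 3 reads and 2 writes
#' (5 versus 3 accesses per element). When a ledger is supplied the fused
#' accounting is charged.
#'
#' @inheritParams compute_wavefront
#' @param ledger Optional [access_ledger()] charged per element.
#' @param direction `"forward"` or `"backward"`.
#' @return The extended successor wavefront.
#' @export
fused_compute_extend <- function(prev, pair, penalties = biwave::penalties(),
                                 ledger = NULL,
                                 direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  p <- require_uniform(penalties)
  rp <- raw_pair(pair, reverse = direction == "backward")
  nxt <- wf_extend_raw(wf_compute_raw(prev, rp, p), rp)
  if (!is.null(ledger)) charge_fused(ledger, length(nxt$off))
  nxt
}

wf_seed <- function(rp) {
  wf_extend_raw(wavefront(0L, 0L, 0L, 0L), rp)
}

wf_done <- function(wf, rp) {
  wf_at(wf, rp$m - rp$n) >= rp$m
}

# one instrumented kernel step: compute+extend, ledger charges, transfer log
wf_step <- function(prev, rp, step, mode, ledger, eb, policy, tstate) {
  nxt <- wf_extend_raw(wf_compute_raw(prev, rp, step), rp)
  if (!is.null(ledger)) {
    elems <- length(nxt$off)
    if (mode == "fused") charge_fused(ledger, elems)
    else charge_unfused(ledger, elems)
    bytes <- elems * eb
    ts <- adaptive_transfer_size(bytes, policy, current = tstate$size)
    tstate$size <- ts
    tstate$iter <- tstate$iter + 1L
    ledger_log_transfer(ledger, tstate$run, tstate$iter, ts)
    blocks <- as.integer(ceiling(bytes / ts))
    if (mode == "fused") charge_blocks(ledger, reads = 2L * blocks, writes = blocks)
    else charge_blocks(ledger, reads = 3L * blocks, writes = 2L * blocks)
  }
  nxt
}

new_tstate <- function(ledger, policy) {
  e <- new.env(parent = emptyenv())
  e$size <- policy$initial_bytes
  e$iter <- 0L
  e$run <- if (is.null(ledger)) 0L else ledger_next_run(ledger)
  e
}

#' Align a pair with the wavefront algorithm
#'
#' Classic score-ordered WFA with full traceback: wavefronts are computed in
#' increasing score order, every wavefront is retained (O(s^2) elements for
#' final score s), and the optimal CIGAR is recovered by walking the
#' predecessors backwards. Traceback ties prefer mismatch, then deletion,
#' then insertion. If the optimal score exceeds `score_cap` the run stops
#' with status `"interrupted"` and no CIGAR.
#'
#' @param pair A [sequence_pair()].
#' @param penalties Uniform [penalties()].
#' @param score_cap Maximum nominal score; `Inf` disables interruption.
#' @param mode `"fused"` or `"unfused"` kernel accounting (results identical).
#' @param ledger Optional [access_ledger()]; with `tier = "bulk"` every
#'   computed wavefront element is charged per the mode, with `tier = "fast"`
#'   wavefronts stay in the fast tier and only overflow past the budget is
#'   charged as spill.
#' @param budget Optional [memory_budget()] (required for `tier = "fast"`
#'   spill accounting).
#' @param tier Where wavefronts notionally reside: `"bulk"` (streaming, the
#'   device model) or `"fast"` (base-case mode).
#' @param policy [transfer_policy()] used for transfer-size logging.
#' @return An [alignment()]; attribute `"stats"` carries `steps`,
#'   `peak_elements` (total retained wavefront elements) and
#'   `peak_fast_bytes`.
#' @examples
#' wfa_align(sequence_pair("ACGT", "AGGT"))
#' @export
wfa_align <- function(pair, penalties = biwave::penalties(), score_cap = Inf,
                      mode = c("fused", "unfused"), ledger = NULL,
                      budget = NULL, tier = c("bulk", "fast"),
                      policy = transfer_policy()) {
  mode <- match.arg(mode); tier <- match.arg(tier)
  p <- require_uniform(penalties)
  n <- pair$n; m <- pair$m

  if (n == 0L || m == 0L) {
    cig <- if (m > 0L) paste0(m, "D") else if (n > 0L) paste0(n, "I") else ""
    sc <- if (m > 0L) m * p else n * p
    res <- alignment(as.integer(sc), cig, pair_id = pair$pair_id)
    attr(res, "stats") <- list(steps = 0L, peak_elements = 0L, peak_fast_bytes = 0L)
    return(res)
  }

  rp <- raw_pair(pair)
  eb <- if (is.null(budget)) 4L else budget$wavefront_element_bytes
  tstate <- new_tstate(ledger, policy)
  bulk_ledger <- if (tier == "bulk") ledger else NULL

  wfs <- vector("list", 64L)
  wfs[[1L]] <- wf_seed(rp)
  total_elems <- 1L
  steps <- 0L
  spilled <- FALSE

  while (!wf_done(wfs[[steps + 1L]], rp)) {
    if ((steps + 1L) * p > score_cap) {
      res <- alignment(NA_integer_, NA_character_, status = "interrupted",
                       pair_id = pair$pair_id)
      attr(res, "stats") <- list(steps = steps, peak_elements = total_elems,
                                 peak_fast_bytes = if (tier == "fast") total_elems * eb else 0L)
      return(res)
    }
    nxt <- wf_step(wfs[[steps + 1L]], rp, p, mode, bulk_ledger, eb, policy, tstate)
    steps <- steps + 1L
    if (steps + 1L > length(wfs)) wfs <- c(wfs, vector("list", length(wfs)))
    wfs[[steps + 1L]] <- nxt
    total_elems <- total_elems + length(nxt$off)
    if (tier == "fast" && !is.null(budget) && !is.null(ledger) &&
        total_elems * eb > budget$fast_capacity_bytes) {
      charge_spill(ledger, length(nxt$off))
      spilled <- TRUE
    }
  }

  score <- steps * p
  cig <- wfa_traceback(wfs, steps, rp)
  res <- alignment(as.integer(score), cig, pair_id = pair$pair_id)
  attr(res, "stats") <- list(
    steps = steps, peak_elements = total_elems,
    peak_fast_bytes = if (tier == "fast") total_elems * eb else 0L,
    spilled = spilled)
  res
}

# Walk back from the terminal cell. At score index s, diagonal k, offset h:
# the pre-extension offset is the best predecessor value; the gap h - pre is
# a run of matches. Tie order: mismatch, deletion, insertion.
wfa_traceback <- function(wfs, steps, rp) {
  k <- rp$m - rp$n; h <- rp$m
  op <- character(0); len <- integer(0)
  push <- function(o, l) {
    if (l <= 0L) return(invisible())
    kk <- length(op)
    if (kk > 0L && op[kk] == o) len[kk] <<- len[kk] + l
    else { op[kk + 1L] <<- o; len[kk + 1L] <<- l }
  }
  s <- steps
  while (s > 0L) {
    prev <- wfs[[s]]
    mis <- wf_at(prev, k)
    del <- wf_at(prev, k - 1L)
    ins <- wf_at(prev, k + 1L)
    cand <- c(if (mis != WF_SENTINEL) mis + 1L else WF_SENTINEL,
              if (del != WF_SENTINEL) del + 1L else WF_SENTINEL,
              ins)
    # offsets above h cannot explain this cell
    cand[cand > h] <- WF_SENTINEL
    pre <- max(cand)
    push("M", h - pre)
    pick <- which(cand == pre)[1L]   # mismatch > deletion > insertion
    if (pick == 1L) { push("X", 1L); h <- pre - 1L }
    else if (pick == 2L) { push("D", 1L); k <- k - 1L; h <- pre - 1L }
    else { push("I", 1L); k <- k + 1L; h <- pre }
    s <- s - 1L
  }
  push("M", h)   # score-0 wavefront: leading matches on diagonal 0
  cigar_build(rev(op), rev(len))
}
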