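# Full-matrix Needleman-Wunsch under edit penalties (match 0). Serves as the
# independent correctness oracle for every wavefront aligner in the package.

#' Global alignment by full dynamic programming
#'
#' Computes the (n+1) x (m+1) score matrix `M[i, j]` = cost of aligning the
#' first `i` query characters to the first `j` reference characters, with
#' `M[0, j] = j * deletion`, `M[i, 0] = i * insertion`, and interior cells the
#' minimum over substitution, insertion (query-consuming) and deletion
#' (reference-consuming) predecessors. Traceback prefers match/mismatch, then
#' deletion, then insertion, giving a deterministic transcript; any optimal
#' transcript is acceptable when comparing aligners on score.
#'
#' @param pair A [sequence_pair()].
#' @param penalties A [penalties()] object (general `{X, I, D}` supported).
#' @param max_cells Guard on `(n+1) * (m+1)`; exceeding it is an error.
#' @return An [alignment()] with optimal `score` and a CIGAR whose replay
#'   reproduces the reference.
#' @examples
#' nw_align(sequence_pair("ACGT", "ACGT"))   # score 0, "4M"
#' @export
nw_align <- function(pair, penalties = biwave::penalties(), max_cells = 1e8) {
  n <- pair$n; m <- pair$m
  if ((n + 1) * (m + 1) > max_cells)
    stop("nw_align: DP matrix of ", (n + 1) * (m + 1), " cells exceeds guard of ",
         max_cells)
  xp <- penalties$mismatch; ip <- penalties$insertion; dp <- penalties$deletion
  q <- charToRaw(pair$query); r <- charToRaw(pair$reference)

  M <- matrix(0, n + 1L, m + 1L)
  M[1L, ] <- (0:m) * dp
  if (n > 0L) M[, 1L] <- (0:n) * ip
  if (n > 0L && m > 0L) {
    jw <- (0:m) * dp
    for (i in seq_len(n)) {
      sub <- xp * (q[i] != r)
      t <- pmin(M[i, 1:m] + sub, M[i, 2:(m + 1L)] + ip)
      # row-wise deletions resolved by cumulative minimum:
      # M[i+1, j] = min_{j' <= j} entry[j'] + (j - j') * dp
      entry <- c(i * ip, t)
      M[i + 1L, ] <- cummin(entry - jw) + jw
    }
  }

  # traceback, tie order: match/mismatch, then deletion, then insertion
  op <- character(0); len <- integer(0)
  push <- function(o) {
    k <- length(op)
    if (k > 0L && op[k] == o) len[k] <<- len[k] + 1L
    else { op[k + 1L] <<- o; len[k + 1L] <<- 1L }
  }
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    here <- M[i + 1L, j + 1L]
    if (i > 0L && j > 0L) {
      sub <- if (q[i] == r[j]) 0 else xp
      if (here == M[i, j] + sub) {
        push(if (sub == 0) "M" else "X"); i <- i - 1L; j <- j - 1L; next
      }
    }
    if (j > 0L && here == M[i + 1L, j] + dp) { push("D"); j <- j - 1L; next }
    push("I"); i <- i - 1L
  }
  alignment(score = as.integer(M[n + 1L, m + 1L]),
            cigar = cigar_build(rev(op), rev(len)),
            pair_id = pair$pair_id)
}
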