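# CIGAR algebra. Extended SAM conventions: M/X consume query and reference,
# I consumes query only, D consumes reference only; "=" is accepted on input
# as a synonym for M and emitted only on request.

CIGAR_OPS <- c("M", "X", "I", "D", "=")

#' Parse a CIGAR string into operation runs
#'
#' @param cigar CIGAR string such as `"5M1X3M"`.
#' @return A data.frame with columns `op` (character) and `len` (integer).
#' @examples
#' cigar_ops("2M1I3M")
#' @export
cigar_ops <- function(cigar) {
  stopifnot(is.character(cigar), length(cigar) == 1L, !is.na(cigar))
  if (cigar == "") return(data.frame(op = character(), len = integer()))
  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Za-z=]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar))
    stop("malformed CIGAR string: ", cigar)
  op <- substr(toks, nchar(toks), nchar(toks))
  if (!all(op %in% CIGAR_OPS))
    stop("malformed CIGAR op code(s): ",
         paste(unique(op[!op %in% CIGAR_OPS]), collapse = ", "))
  len <- as.integer(substr(toks, 1L, nchar(toks) - 1L))
  if (any(len < 0L) || any(is.na(len))) stop("malformed CIGAR run length")
  op[op == "="] <- "M"
  data.frame(op = op, len = len, stringsAsFactors = FALSE)
}

# Merge adjacent runs with the same op and drop zero-length runs.
merge_runs <- function(op, len) {
  keep <- len > 0L
  op <- op[keep]; len <- len[keep]
  if (length(op) == 0L) return(data.frame(op = character(), len = integer()))
  new_run <- c(TRUE, op[-1L] != op[-length(op)])
  grp <- cumsum(new_run)
  data.frame(op = op[new_run], len = as.integer(rowsum(len, grp)[, 1L]),
             stringsAsFactors = FALSE)
}

#' Build a canonical CIGAR string from runs
#'
#' Adjacent runs sharing an op are merged and zero-length runs dropped, so
#' the result is run-length canonical.
#'
#' @param op Character vector of ops in `M`, `X`, `I`, `D`.
#' @param len Integer vector of run lengths, same length as `op`.
#' @param eq_for_match Emit `=` instead of `M` for match runs.
#' @return A CIGAR string.
#' @export
cigar_build <- function(op, len, eq_for_match = FALSE) {
  stopifnot(length(op) == length(len))
  runs <- merge_runs(as.character(op), as.integer(len))
  if (nrow(runs) == 0L) return("")
  o <- runs$op
  if (eq_for_match) o[o == "M"] <- "="
  paste0(runs$len, o, collapse = "")
}

#' Penalty-weighted cost of a CIGAR transcript
#'
#' Matches cost zero; each mismatch, inserted or deleted base contributes its
#' penalty.
#'
#' @param cigar CIGAR string.
#' @param penalties A [penalties()] object.
#' @return Integer score.
#' @examples
#' cigar_score("4M", penalties())        # 0
#' cigar_score("1M1X2M", penalties())    # 1
#' @export
cigar_score <- function(cigar, penalties = biwave::penalties()) {
  runs <- cigar_ops(cigar)
  w <- c(M = 0L, X = penalties$mismatch, I = penalties$insertion,
         D = penalties$deletion)
  sum(w[runs$op] * runs$len)
}

#' Number of query/reference bases consumed by a CIGAR
#'
#' @param cigar CIGAR string.
#' @return Integer.
#' @export
cigar_query_length <- function(cigar) {
  runs <- cigar_ops(cigar)
  sum(runs$len[runs$op %in% c("M", "X", "I")])
}

#' @rdname cigar_query_length
#' @export
cigar_reference_length <- function(cigar) {
  runs <- cigar_ops(cigar)
  sum(runs$len[runs$op %in% c("M", "X", "D")])
}

#' Concatenate partial CIGARs
#'
#' Partial transcripts produced for consecutive segments of one pair are
#' joined in order; runs that meet across a boundary with the same op are
#' merged, so the result is canonical and its score is the sum of the part
#' scores.
#'
#' @param parts Non-empty character vector (or list) of CIGAR strings, in
#'   transcript order.
#' @return A single CIGAR string.
#' @examples
#' cigar_concat(c("2M", "3M"))      # "5M"
#' cigar_concat(c("1X", "2M1I"))    # "1X2M1I"
#' @export
cigar_concat <- function(parts) {
  parts <- unlist(parts, use.names = FALSE)
  if (length(parts) == 0L) stop("cigar_concat: no parts given")
  runs <- do.call(rbind, lapply(parts, cigar_ops))
  cigar_build(runs$op, runs$len)
}

#' Replay a CIGAR against a pair
#'
#' Validates the transcript and reconstructs the reference from the query:
#' `M` runs must match character-for-character, `X` runs must differ at every
#' position, `I` consumes query only, `D` consumes reference only, and the
#' run totals must consume the two sequences exactly. The reconstructed
#' string equals the reference if and only if the transcript is a valid
#' alignment of the pair.
#'
#' @param query,reference Character scalars.
#' @param cigar CIGAR string.
#' @return The reconstructed reference string (invisibly identical to
#'   `reference` when valid); errors describe the first violation.
#' @export
cigar_replay <- function(query, cigar, reference) {
  runs <- cigar_ops(cigar)
  n <- nchar(query); m <- nchar(reference)
  if (cigar_query_length(cigar) != n)
    stop("CIGAR consumes ", cigar_query_length(cigar), " query bases, expected ", n)
  if (cigar_reference_length(cigar) != m)
    stop("CIGAR consumes ", cigar_reference_length(cigar), " reference bases, expected ", m)
  if (nrow(runs) == 0L) return(reference)
  opv <- rep(runs$op, runs$len)
  cq <- opv %in% c("M", "X", "I")
  cr <- opv %in% c("M", "X", "D")
  qi <- cumsum(cq); ri <- cumsum(cr)
  qc <- strsplit(query, "", fixed = TRUE)[[1L]]
  rc <- strsplit(reference, "", fixed = TRUE)[[1L]]
  is_m <- opv == "M"; is_x <- opv == "X"
  if (any(is_m) && !all(qc[qi[is_m]] == rc[ri[is_m]]))
    stop("M run covers mismatching characters")
  if (any(is_x) && any(qc[qi[is_x]] == rc[ri[is_x]]))
    stop("X run covers matching characters")
  out <- character(m)
  out[ri[is_m]] <- qc[qi[is_m]]           # matches reproduce query chars
  oth <- cr & !is_m                       # X and D take reference chars
  out[ri[oth]] <- rc[ri[oth]]
  paste0(out, collapse = "")
}
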