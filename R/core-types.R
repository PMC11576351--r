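#' Construct a sequence pair
#'
#' A query/reference pair of ASCII sequences, the unit of work for every
#' aligner in the package. The query has length `n`, the reference length `m`.
#'
#' @param query Character scalar (may be empty). No newline characters.
#' @param reference Character scalar (may be empty). No newline characters.
#' @param pair_id Non-negative integer identifier, unique within a batch.
#' @return An object of class `sequence_pair` with fields `query`,
#'   `reference`, `n`, `m`, `pair_id`.
#' @examples
#' sequence_pair("ACGT", "ACCT")
#' @export
sequence_pair <- function(query, reference, pair_id = 0L) {
  stopifnot(is.character(query), length(query) == 1L, !is.na(query),
            is.character(reference), length(reference) == 1L, !is.na(reference))
  if (grepl("\n", query, fixed = TRUE) || grepl("\n", reference, fixed = TRUE))
    stop("sequences must not contain newline characters")
  pair_id <- as.integer(pair_id)
  stopifnot(length(pair_id) == 1L, !is.na(pair_id), pair_id >= 0L)
  structure(
    list(query = query, reference = reference,
         n = nchar(query), m = nchar(reference), pair_id = pair_id),
    class = "sequence_pair")
}

#' @export
print.sequence_pair <- function(x, ...) {
  cat(sprintf("<sequence_pair #%d> n=%d m=%d\n", x$pair_id, x$n, x$m))
  invisible(x)
}

#' Construct an edit-penalty set
#'
#' Match costs 0; mismatch, insertion and deletion are positive integers.
#' The default (all 1) is unit-cost edit distance. The wavefront kernels
#' require uniform penalties (`mismatch == insertion == deletion`), since a
#' wavefront step advances the score by exactly one penalty unit;
#' [nw_align()] and [cigar_score()] accept arbitrary positive penalties.
#'
#' @param mismatch,insertion,deletion Positive integer costs.
#' @return An object of class `penalties`.
#' @examples
#' penalties()            # edit distance
#' penalties(2, 3, 3)     # heavier gaps
#' @export
penalties <- function(mismatch = 1L, insertion = 1L, deletion = 1L) {
  p <- c(mismatch = as.integer(mismatch), insertion = as.integer(insertion),
         deletion = as.integer(deletion))
  if (any(is.na(p)) || any(p < 1L)) stop("all penalties must be integers >= 1")
  structure(list(mismatch = p[["mismatch"]], insertion = p[["insertion"]],
                 deletion = p[["deletion"]], match = 0L),
            class = "penalties")
}

is_uniform <- function(penalties) {
  penalties$mismatch == penalties$insertion &&
    penalties$mismatch == penalties$deletion
}

require_uniform <- function(penalties) {
  if (!is_uniform(penalties))
    stop("wavefront kernels require uniform penalties (mismatch == insertion == deletion); ",
         "use nw_align() for general penalties")
  penalties$mismatch
}

#' Construct an alignment result
#'
#' @param score Non-negative integer optimal score, or `NA` when interrupted.
#' @param cigar CIGAR string (`M`/`X`/`I`/`D` runs), or `NA` when interrupted.
#' @param status `"complete"` or `"interrupted"`.
#' @param pair_id Identifier of the aligned pair.
#' @param path Which execution path produced it (`"worker"` or `"recovery"`).
#' @return Object of class `alignment`.
#' @export
alignment <- function(score, cigar, status = "complete", pair_id = NA_integer_,
                      path = "worker") {
  stopifnot(status %in% c("complete", "interrupted"))
  structure(list(score = score, cigar = cigar, status = status,
                 pair_id = as.integer(pair_id), path = path),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cig <- if (is.na(x$cigar)) "-" else
    if (nchar(x$cigar) > 60) paste0(substr(x$cigar, 1, 57), "...") else x$cigar
  cat(sprintf("<alignment> score=%s status=%s cigar=%s\n",
              format(x$score), x$status, cig))
  invisible(x)
}
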