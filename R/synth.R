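# Synthetic pair generation and pair-file I/O. Datasets follow the simulated
# workload recipe: fixed-length uniform random references, queries derived by
# applying round(length * error_rate) edits at distinct uniform positions,
# each edit a mismatch or an indel. A heterogeneous mode draws lengths
# log-uniformly to emulate mixed-length long-read workloads.

#' Describe a synthetic dataset
#'
#' @param num_pairs Number of pairs (>= 0).
#' @param length Sequence length; either a scalar (fixed-length dataset) or
#'   `c(min, max)` for the heterogeneous mode (per-pair lengths drawn
#'   log-uniformly).
#' @param error_rate Fraction of positions edited, in `[0, 1]`.
#' @param indel_fraction Share of edits that are indels (split evenly
#'   between insertions and deletions); the default 2/3 makes mismatch,
#'   insertion and deletion equally likely.
#' @param alphabet Character vector of symbols.
#' @param seed Integer seed; with the pair index it fully determines each
#'   pair.
#' @return Object of class `dataset_spec`.
#' @examples
#' dataset_spec(10, 150, 0.05)
#' @export
dataset_spec <- function(num_pairs, length, error_rate,
                         indel_fraction = 2 / 3,
                         alphabet = c("A", "C", "G", "T"), seed = 42L) {
  stopifnot(num_pairs >= 0, length(length) %in% c(1L, 2L), all(length >= 1),
            error_rate >= 0, error_rate <= 1,
            indel_fraction >= 0, indel_fraction <= 1,
            base::length(alphabet) >= 2L)
  if (base::length(length) == 2L) stopifnot(length[1] <= length[2])
  structure(list(num_pairs = as.integer(num_pairs), length = as.integer(length),
                 error_rate = error_rate, indel_fraction = indel_fraction,
                 alphabet = alphabet, seed = as.integer(seed)),
            class = "dataset_spec")
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

pair_seed <- function(spec, index) {
  as.integer((abs(spec$seed) %% 1048576L) * 2039L + (index %% 1048573L) + 1L)
}

#' Generate one synthetic pair
#'
#' The reference is drawn uniformly over the alphabet; the query applies
#' `round(length * error_rate)` edits at distinct uniform positions
#' (mismatch to a different symbol, deletion, or insertion after the
#' position). Reproducible from `(spec$seed, index)` alone.
#'
#' @param spec A [dataset_spec()].
#' @param index 0-based pair index (becomes `pair_id`).
#' @return A [sequence_pair()]; attribute `"n_edits"` records the number of
#'   edits applied.
#' @export
generate_pair <- function(spec, index) {
  with_local_seed(pair_seed(spec, index), {
    len <- if (length(spec$length) == 2L) {
      as.integer(round(exp(stats::runif(1, log(spec$length[1]),
                                        log(spec$length[2])))))
    } else spec$length
    ref_chars <- sample(spec$alphabet, len, replace = TRUE)
    reference <- paste0(ref_chars, collapse = "")
    n_edits <- as.integer(round(len * spec$error_rate))
    n_edits <- min(n_edits, len)
    if (n_edits == 0L) {
      p <- sequence_pair(reference, reference, pair_id = index)
      attr(p, "n_edits") <- 0L
      return(p)
    }
    pos <- sort(sample.int(len, n_edits))
    u <- stats::runif(n_edits)
    is_indel <- u < spec$indel_fraction
    is_ins <- is_indel & stats::runif(n_edits) < 0.5
    chunks <- character(0)
    prev <- 0L
    for (i in seq_len(n_edits)) {
      pp <- pos[i]
      if (pp > prev + 1L)
        chunks <- c(chunks, substr(reference, prev + 1L, pp - 1L))
      if (!is_indel[i]) {                       # mismatch
        others <- setdiff(spec$alphabet, ref_chars[pp])
        chunks <- c(chunks, sample(others, 1L))
      } else if (is_ins[i]) {                   # insertion after the position
        chunks <- c(chunks, ref_chars[pp], sample(spec$alphabet, 1L))
      }                                         # deletion: emit nothing
      prev <- pp
    }
    if (prev < len) chunks <- c(chunks, substr(reference, prev + 1L, len))
    p <- sequence_pair(paste0(chunks, collapse = ""), reference,
                       pair_id = index)
    attr(p, "n_edits") <- n_edits
    p
  })
}

#' Generate a whole dataset
#'
#' @param spec A [dataset_spec()].
#' @return List of [sequence_pair()] with `pair_id` 0..num_pairs-1.
#' @export
generate_dataset <- function(spec) {
  lapply(seq_len(spec$num_pairs) - 1L, function(i) generate_pair(spec, i))
}

#' Read sequence pairs from disk
#'
#' The `seqpair` dialect holds one pair per two lines: a `>`-prefixed
#' query/pattern line followed by a `<`-prefixed reference/text line.
#' `fasta` pairs consecutive records of an interleaved FASTA file
#' (query record, then reference record).
#'
#' @param path Input file.
#' @param format `"seqpair"` or `"fasta"`.
#' @return List of [sequence_pair()].
#' @export
read_pairs <- function(path, format = c("seqpair", "fasta")) {
  format <- match.arg(format)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) %% 2L != 0L)
      stop("format error: interleaved FASTA has an odd number of records (",
           length(set), ")")
    seqs <- unname(as.character(set))
    return(lapply(seq_len(length(seqs) / 2L), function(i)
      sequence_pair(seqs[2L * i - 1L], seqs[2L * i], pair_id = i - 1L)))
  }
  lines <- readLines(path)
  if (length(lines) %% 2L != 0L)
    stop("format error: odd number of lines (", length(lines), ") in ", path)
  out <- vector("list", length(lines) / 2L)
  for (i in seq_along(out)) {
    lq <- lines[2L * i - 1L]; lr <- lines[2L * i]
    if (!startsWith(lq, ">"))
      stop("format error at line ", 2L * i - 1L,
           ": expected '>' query prefix, got: ", substr(lq, 1L, 20L))
    if (!startsWith(lr, "<"))
      stop("format error at line ", 2L * i,
           ": expected '<' reference prefix, got: ", substr(lr, 1L, 20L))
    q <- substr(lq, 2L, nchar(lq)); r <- substr(lr, 2L, nchar(lr))
    if (nchar(q) == 0L || nchar(r) == 0L)
      stop("format error at line ", 2L * i - 1L, ": empty sequence")
    out[[i]] <- sequence_pair(q, r, pair_id = i - 1L)
  }
  out
}

#' Write sequence pairs to disk
#'
#' @param path Output file.
#' @param pairs List of [sequence_pair()].
#' @param format `"seqpair"` or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(path, pairs, format = c("seqpair", "fasta")) {
  format <- match.arg(format)
  if (format == "fasta") {
    seqs <- unlist(lapply(pairs, function(p) c(p$query, p$reference)))
    set <- Biostrings::BStringSet(seqs)
    names(set) <- unlist(lapply(pairs, function(p)
      paste0("pair", p$pair_id, c("/query", "/reference"))))
    Biostrings::writeXStringSet(set, path, width = 20000L)
    return(invisible(path))
  }
  lines <- unlist(lapply(pairs, function(p)
    c(paste0(">", p$query), paste0("<", p$reference))))
  if (is.null(lines)) lines <- character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Write alignment results
#'
#' `tsv` columns: `pair_id`, `score`, `cigar`, `status`, `path`, ordered by
#' `pair_id`. `sam_like` emits a minimal SAM-flavoured record per pair.
#'
#' @param path Output file.
#' @param alignments List of [alignment()].
#' @param format `"tsv"` or `"sam_like"`.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(path, alignments, format = c("tsv", "sam_like")) {
  format <- match.arg(format)
  df <- data.frame(
    pair_id = vapply(alignments, function(a) a$pair_id, integer(1)),
    score = vapply(alignments, function(a) as.integer(a$score), integer(1)),
    cigar = vapply(alignments, function(a) as.character(a$cigar), character(1)),
    status = vapply(alignments, function(a) a$status, character(1)),
    path = vapply(alignments, function(a) a$path, character(1)),
    stringsAsFactors = FALSE)
  df <- df[order(df$pair_id), , drop = FALSE]
  if (format == "sam_like") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("@HD\tVN:1.6\tSO:unsorted", con)
    writeLines(sprintf("pair%d\t0\tref%d\t1\t255\t%s\t*\t0\t0\t*\t*\tAS:i:%d",
                       df$pair_id, df$pair_id, df$cigar, df$score), con)
    return(invisible(path))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV alignment file written by [write_alignments()]
#'
#' @param path Input file.
#' @return data.frame with the written columns.
#' @export
read_alignments <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("integer", "integer", "character",
                                   "character", "character"),
                    stringsAsFactors = FALSE)
}
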