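# Shared fixtures: random sequences, an independent memoized edit-distance
# oracle, and random valid CIGARs with consistent sequence pairs.

DNA <- c("A", "C", "G", "T")

rnd_seq <- function(n, alphabet = DNA) {
  if (n == 0L) return("")
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

rnd_pair <- function(max_len = 80L, min_len = 1L) {
  sequence_pair(rnd_seq(sample(min_len:max_len, 1L)),
                rnd_seq(sample(min_len:max_len, 1L)))
}

# pair with a controlled number of edits relative to a common core
noisy_pair <- function(len, error_rate, seed = NULL) {
  spec <- dataset_spec(1L, len, error_rate,
                       seed = if (is.null(seed)) sample.int(10000L, 1L) else seed)
  generate_pair(spec, 0L)
}

# Independent oracle: plain memoized recursion on suffix lengths, no shared
# code with nw_align's vectorized row recurrence.
ed_memo <- function(q, r, xp = 1L, ip = 1L, dp = 1L) {
  qc <- strsplit(q, "", fixed = TRUE)[[1L]]
  rc <- strsplit(r, "", fixed = TRUE)[[1L]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j * dp)
    if (j == 0L) return(i * ip)
    key <- paste0(i, ",", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    sub <- if (qc[i] == rc[j]) 0L else xp
    v <- min(rec(i - 1L, j - 1L) + sub, rec(i - 1L, j) + ip,
             rec(i, j - 1L) + dp)
    memo[[key]] <- v
    v
  }
  rec(nchar(q), nchar(r))
}

# A random valid CIGAR plus a (query, reference) pair consistent with it.
rnd_cigar_case <- function(max_runs = 12L) {
  n_runs <- sample.int(max_runs, 1L)
  op <- sample(c("M", "X", "I", "D"), n_runs, replace = TRUE,
               prob = c(0.4, 0.2, 0.2, 0.2))
  len <- sample.int(5L, n_runs, replace = TRUE)
  q <- character(0); r <- character(0)
  for (i in seq_len(n_runs)) {
    for (b in seq_len(len[i])) {
      if (op[i] == "M") { ch <- sample(DNA, 1L); q <- c(q, ch); r <- c(r, ch) }
      else if (op[i] == "X") {
        ch <- sample(DNA, 2L); q <- c(q, ch[1L]); r <- c(r, ch[2L])
      } else if (op[i] == "I") q <- c(q, sample(DNA, 1L))
      else r <- c(r, sample(DNA, 1L))
    }
  }
  list(cigar = cigar_build(op, len),
       op = op, len = len,
       query = paste0(q, collapse = ""),
       reference = paste0(r, collapse = ""))
}
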