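test_that("extend_wavefront advances offsets by exact longest common prefixes", {
  p <- sequence_pair("AAAA", "AAAA")
  wf <- wavefront(0L, 0L, 0L, 0L)
  expect_equal(extend_wavefront(wf, p)$off, 4L)
  p2 <- sequence_pair("TAAA", "AAAA")
  expect_equal(extend_wavefront(wf, p2)$off, 0L)
  # naive per-character scan oracle on random wavefronts
  set.seed(301)
  for (i in 1:30) {
    p <- rnd_pair(max_len = 40L, min_len = 5L)
    n <- p$n; m <- p$m
    lo <- -sample.int(min(n, 4L), 1L); hi <- sample.int(min(m, 4L), 1L)
    off <- vapply(lo:hi, function(k) {
      lim_lo <- max(0L, k); lim_hi <- min(m, n + k)
      lim_lo + sample.int(lim_hi - lim_lo + 1L, 1L) - 1L
    }, integer(1))
    got <- extend_wavefront(wavefront(0L, lo, hi, off), p)$off
    qc <- strsplit(p$query, "")[[1]]; rc <- strsplit(p$reference, "")[[1]]
    want <- vapply(seq_along(off), function(j) {
      k <- lo + j - 1L; h <- off[j]; v <- h - k
      while (h < m && v < n && qc[v + 1L] == rc[h + 1L]) { h <- h + 1L; v <- v + 1L }
      h
    }, integer(1))
    expect_equal(got, want)
    expect_true(all(got >= off))   # no offset decreases
  }
})

test_that("backward extension equals forward extension of reversed sequences", {
  set.seed(302)
  for (i in 1:10) {
    p <- rnd_pair(max_len = 30L, min_len = 3L)
    wf <- wavefront(0L, 0L, 0L, 0L)
    rev_p <- sequence_pair(paste(rev(strsplit(p$query, "")[[1]]), collapse = ""),
                           paste(rev(strsplit(p$reference, "")[[1]]), collapse = ""))
    expect_equal(extend_wavefront(wf, p, "backward")$off,
                 extend_wavefront(wf, rev_p, "forward")$off)
  }
})

test_that("compute_wavefront grows the diagonal range and terminates a substitution at score 1", {
  p <- sequence_pair("AGGT", "ACGT")
  w0 <- extend_wavefront(wavefront(0L, 0L, 0L, 0L), p)
  w1 <- compute_wavefront(w0, p)
  expect_equal(c(w1$lo, w1$hi), c(-1L, 1L))
  p1 <- sequence_pair("A", "G")
  w0 <- extend_wavefront(wavefront(0L, 0L, 0L, 0L), p1)
  w1 <- extend_wavefront(compute_wavefront(w0, p1), p1)
  expect_gte(w1$off[0L - w1$lo + 1L], 1L)  # terminal (k = 0, offset 1) reached
  expect_equal(wfa_align(p1)$score, 1L)
})

test_that("wavefront offsets are monotone non-decreasing in score per diagonal", {
  set.seed(303)
  for (i in 1:10) {
    p <- noisy_pair(60L, 0.15)
    cur <- extend_wavefront(wavefront(0L, 0L, 0L, 0L), p)
    s <- nw_align(p)$score
    if (s == 0L) next
    for (step in seq_len(s)) {
      nxt <- extend_wavefront(compute_wavefront(cur, p), p)
      shared <- max(cur$lo, nxt$lo):min(cur$hi, nxt$hi)
      a <- cur$off[shared - cur$lo + 1L]
      b <- nxt$off[shared - nxt$lo + 1L]
      ok <- a != wf_sentinel() & b != wf_sentinel()
      expect_true(all(b[ok] >= a[ok]))
      # a diagonal only leaves the frontier once it is fully consumed
      gone <- a != wf_sentinel() & b == wf_sentinel()
      expect_true(all(a[gone] == pmin(p$m, p$n + shared[gone])))
      cur <- nxt
    }
  }
})

test_that("wfa_align equals the DP oracle and replays on random pairs", {
  set.seed(304)
  for (i in 1:120) {
    p <- rnd_pair(max_len = 100L)
    o <- nw_align(p)
    w <- wfa_align(p)
    expect_equal(w$score, o$score)
    expect_identical(cigar_replay(p$query, w$cigar, p$reference), p$reference)
    expect_equal(cigar_score(w$cigar), w$score)
  }
})

test_that("wfa_align handles identity and score-cap interruption", {
  p <- sequence_pair(strrep("A", 150), strrep("A", 150))
  a <- wfa_align(p, score_cap = 1000)
  expect_equal(a$score, 0L)
  expect_identical(a$cigar, "150M")
  set.seed(305)
  p2 <- noisy_pair(120L, 0.2)
  s <- nw_align(p2)$score
  expect_gt(s, 5L)
  capped <- wfa_align(p2, score_cap = 5)
  expect_identical(capped$status, "interrupted")
  expect_true(is.na(capped$cigar))
  uncapped <- wfa_align(p2, score_cap = s)
  expect_identical(uncapped$status, "complete")
  expect_equal(uncapped$score, s)
})

test_that("fused and unfused kernels produce identical wavefront sequences", {
  set.seed(306)
  for (i in 1:25) {
    p <- rnd_pair(max_len = 60L, min_len = 2L)
    cur <- extend_wavefront(wavefront(0L, 0L, 0L, 0L), p)
    s <- nw_align(p)$score
    for (step in seq_len(max(s, 1L))) {
      fused <- fused_compute_extend(cur, p)
      unfused <- extend_wavefront(compute_wavefront(cur, p), p)
      expect_identical(fused, unfused)
      cur <- fused
    }
    expect_identical(wfa_align(p, mode = "fused")$cigar,
                     wfa_align(p, mode = "unfused")$cigar)
  }
})

test_that("kernels reject non-uniform penalties", {
  p <- sequence_pair("ACGT", "ACGG")
  expect_error(wfa_align(p, penalties(1L, 2L, 1L)), "uniform")
  expect_error(biwfa_find_breakpoint(p, penalties(2L, 1L, 1L)), "uniform")
  # uniform non-unit penalties scale the edit distance
  expect_equal(wfa_align(p, penalties(3L, 3L, 3L))$score, 3L)
})
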