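test_that("zero error rate reproduces the reference exactly", {
  spec <- dataset_spec(5L, 150L, 0, seed = 21L)
  for (i in 0:4) {
    p <- generate_pair(spec, i)
    expect_identical(p$query, p$reference)
    expect_equal(attr(p, "n_edits"), 0L)
  }
})

test_that("the edit count follows round(length * error_rate)", {
  spec <- dataset_spec(10L, 150L, 0.05, seed = 22L)
  for (i in 0:9) expect_equal(attr(generate_pair(spec, i), "n_edits"), 8L)
  expect_equal(attr(generate_pair(dataset_spec(1L, 100L, 0.1, seed = 1L), 0L),
                    "n_edits"), 10L)
})

test_that("generation is deterministic from (seed, index) and leaves the RNG alone", {
  spec <- dataset_spec(6L, 200L, 0.08, seed = 23L)
  d1 <- generate_dataset(spec)
  set.seed(999); runif(3)   # perturb the global RNG between calls
  d2 <- generate_dataset(spec)
  expect_identical(d1, d2)
  set.seed(42L); before <- runif(1)
  set.seed(42L); generate_pair(spec, 0L); after <- runif(1)
  expect_identical(before, after)
  # different indexes give different pairs
  expect_false(identical(d1[[1]]$reference, d1[[2]]$reference))
})

test_that("applied edits bound the optimal score from above", {
  spec <- dataset_spec(30L, 150L, 0.1, seed = 24L)
  for (i in 0:29) {
    p <- generate_pair(spec, i)
    expect_lte(nw_align(p)$score, attr(p, "n_edits"))
  }
})

test_that("mean optimal score sits in the expected band below the applied edit count", {
  spec <- dataset_spec(1000L, 150L, 0.05, seed = 25L)
  pairs <- generate_dataset(spec)
  scores <- vapply(pairs, function(p) wfa_align(p)$score, integer(1))
  edits <- vapply(pairs, attr, integer(1), "n_edits")
  # edits can cancel or merge, never inflate: the per-pair score is bounded
  # by the applied edit count and the mean stays well inside the band
  expect_true(all(scores <= edits))
  expect_gte(mean(scores), 0.6 * mean(edits))
  expect_lte(mean(scores), 1.0 * mean(edits))
})

test_that("the heterogeneous mode draws lengths inside the requested range", {
  spec <- dataset_spec(40L, c(100L, 2000L), 0.05, seed = 26L)
  lens <- vapply(generate_dataset(spec), `[[`, integer(1), "m")
  expect_true(all(lens >= 100L & lens <= 2000L))
  expect_gt(length(unique(lens)), 10L)
})

test_that("seqpair files round-trip and report format errors with line numbers", {
  set.seed(603)
  pairs <- generate_dataset(dataset_spec(25L, 60L, 0.1, seed = 27L))
  f <- tempfile(fileext = ".seq")
  write_pairs(f, pairs)
  back <- read_pairs(f)
  expect_equal(length(back), 25L)
  for (i in seq_along(pairs)) {
    expect_identical(back[[i]]$query, pairs[[i]]$query)
    expect_identical(back[[i]]$reference, pairs[[i]]$reference)
  }
  writeLines(c("<ACGT", ">ACGT"), f)
  expect_error(read_pairs(f), "line 1")
  writeLines(c(">ACGT", "<ACGT", ">AA"), f)
  expect_error(read_pairs(f), "odd number")
  writeLines(c(">ACGT", "<"), f)
  expect_error(read_pairs(f), "empty sequence")
  writeLines(c(">ACGT\n<ACGT"), f)
  one <- read_pairs(f)
  expect_identical(one[[1]]$query, "ACGT")
})

test_that("interleaved FASTA files round-trip through Biostrings", {
  pairs <- generate_dataset(dataset_spec(8L, 120L, 0.05, seed = 28L))
  f <- tempfile(fileext = ".fa")
  write_pairs(f, pairs, format = "fasta")
  back <- read_pairs(f, format = "fasta")
  expect_equal(length(back), 8L)
  for (i in seq_along(pairs)) {
    expect_identical(back[[i]]$query, pairs[[i]]$query)
    expect_identical(back[[i]]$reference, pairs[[i]]$reference)
  }
  # odd record count is a format error
  writeLines(c(">a", "ACGT", ">b", "ACGT", ">c", "AC"), f)
  expect_error(read_pairs(f, format = "fasta"), "odd number")
})

test_that("alignment TSVs have the documented row shape and round-trip", {
  a <- alignment(0L, "4M", pair_id = 0L)
  f <- tempfile(fileext = ".tsv")
  write_alignments(f, list(a))
  lines <- readLines(f)
  expect_identical(lines[2L], "0\t0\t4M\tcomplete\tworker")
  alns <- list(alignment(3L, "2M1X2M1I", pair_id = 1L),
               alignment(0L, "5M", pair_id = 0L, path = "recovery"))
  write_alignments(f, alns)
  back <- read_alignments(f)
  expect_equal(back$pair_id, c(0L, 1L))     # sorted by pair id
  expect_equal(back$cigar, c("5M", "2M1X2M1I"))
  write_alignments(f, list())
  expect_length(readLines(f), 1L)           # header only
  # SAM-flavoured output keeps the CIGAR and score per record
  write_alignments(f, alns, format = "sam_like")
  sam <- readLines(f)
  expect_true(startsWith(sam[1L], "@HD"))
  expect_match(sam[2L], "\t5M\t.*AS:i:0$")
  expect_match(sam[3L], "\t2M1X2M1I\t.*AS:i:3$")
})
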