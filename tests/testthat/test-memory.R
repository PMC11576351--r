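test_that("fused and unfused charges accumulate linearly at 3 and 5 per element", {
  led <- access_ledger()
  charge_fused(led, 0)
  expect_equal(ledger_report(led)$wf_elems_computed, 0)
  set.seed(601)
  total <- 0
  for (i in 1:20) {
    k <- sample.int(50L, 1L)
    charge_fused(led, k)
    total <- total + k
  }
  rep <- ledger_report(led)
  expect_equal(rep$wf_elem_reads, 2 * total)
  expect_equal(rep$wf_elem_writes, total)
  expect_equal(rep$accesses_per_element, 3)
  led2 <- access_ledger()
  charge_unfused(led2, total)
  rep2 <- ledger_report(led2)
  expect_equal(rep2$wf_elem_reads + rep2$wf_elem_writes, 5 * total)
  # fusion saves exactly 40% of the bulk accesses
  expect_equal(1 - (rep$wf_elem_reads + rep$wf_elem_writes) /
                 (rep2$wf_elem_reads + rep2$wf_elem_writes), 0.4)
})

test_that("adaptive_transfer_size is the clamped least power of two over demand", {
  expect_equal(adaptive_transfer_size(4), 8L)
  expect_equal(adaptive_transfer_size(100000), 2048L)
  pol <- transfer_policy()
  for (demand in c(1, 7, 8, 9, 63, 64, 65, 511, 2047, 2048, 1e6)) {
    got <- adaptive_transfer_size(demand, pol)
    pow2 <- 2^(3:11)
    want <- min(max(pow2[pow2 >= min(demand, 2048)][1], 8L), 2048L)
    expect_equal(got, want)
  }
  # never decreases across iterations, bounded by the fast buffer
  expect_equal(adaptive_transfer_size(16, pol, current = 512L), 512L)
  expect_equal(adaptive_transfer_size(100, pol, fast_buffer_bytes = 200), 128L)
})

test_that("reverse_block_read returns reversed windows with aligned block charges", {
  set.seed(602)
  s <- rnd_seq(100L)
  store <- bulk_store(s)
  raw_s <- charToRaw(s)
  expect_identical(reverse_block_read(store, 0, 100), rev(raw_s))
  for (i in 1:30) {
    start <- sample(0:99, 1L)
    len <- sample.int(100L - start, 1L)
    got <- reverse_block_read(store, start, len)
    expect_identical(got, rev(raw_s[(start + 1L):(start + len)]))
  }
  # charged blocks cover the alignment-rounded window in 16-byte chunks
  led <- access_ledger()
  reverse_block_read(store, 3, 4, ledger = led)   # [0, 8) -> one chunk
  expect_equal(led$seq_block_reads, 1)
  reverse_block_read(store, 7, 18, ledger = led)  # [0, 32) -> two chunks
  expect_equal(led$seq_block_reads, 3)
  # reads into the alignment padding succeed; beyond it fail
  expect_length(reverse_block_read(store, 96, store$padded_length - 96), 8)
  expect_error(reverse_block_read(store, 0, store$padded_length + 1), "exceeds")
})

test_that("spill_wavefront places overflow in the bulk tier and charges it", {
  b <- memory_budget(fast_capacity_bytes = 64L, wavefront_element_bytes = 4L)
  small <- wavefront(0L, 0L, 2L, c(0L, 1L, 2L))
  led <- access_ledger()
  res <- spill_wavefront(small, b, led)   # 12 bytes vs 16-byte allocation
  expect_identical(res$placement, "fast")
  expect_equal(led$spill_elems, 0)
  big <- wavefront(0L, -5L, 5L, 0:10)     # 44 bytes
  res2 <- spill_wavefront(big, b, led)
  expect_identical(res2$placement, "bulk")
  expect_equal(res2$spilled_elements, 11L - 4L)
  expect_equal(led$spill_elems, 7)
  tiny_bulk <- memory_budget(fast_capacity_bytes = 64L,
                             bulk_capacity_bytes = 64L)
  huge <- wavefront(0L, 0L, 99L, rep(0L, 100L))
  expect_error(spill_wavefront(huge, tiny_bulk), "bulk capacity")
})

test_that("bulk spill charges grow with the optimal score", {
  set.seed(603)
  budget <- memory_budget(fast_capacity_bytes = 512L)
  spills <- vapply(c(0.02, 0.1, 0.25), function(e) {
    led <- access_ledger()
    p <- noisy_pair(300L, e, seed = 700L)
    biwfa_find_breakpoint(p, ledger = led, budget = budget)
    led$spill_elems
  }, numeric(1))
  expect_true(all(diff(spills) >= 0))
  expect_gt(spills[3], 0)
})

test_that("instrumented runs log power-of-two, non-decreasing transfer sizes", {
  set.seed(604)
  led <- access_ledger()
  for (i in 1:10) align_unrolled(noisy_pair(300L, 0.1), ledger = led)
  tl <- transfer_log(led)
  expect_gt(nrow(tl), 0L)
  expect_true(all(tl$bytes %in% 2^(3:11)))
  for (r in unique(tl$run)) {
    sizes <- tl$bytes[tl$run == r]
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("ledger reports round-trip to disk in both formats", {
  led <- access_ledger()
  charge_fused(led, 10)
  jf <- tempfile(fileext = ".json"); tf <- tempfile(fileext = ".txt")
  write_ledger(led, jf); write_ledger(led, tf)
  back <- jsonlite::read_json(jf)
  expect_equal(back$wf_elems_computed, 10)
  expect_equal(back$accesses_per_element, 3)
  txt <- read.table(tf, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(as.numeric(txt$V2[txt$V1 == "wf_elem_reads"]), 20)
})
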