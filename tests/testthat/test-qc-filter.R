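test_that("masking replaces sub-threshold bases with N and nothing else", {
  r <- qread("ACG", c(30L, 19L, 30L))
  m <- mask_low_quality(r)
  expect_identical(m$bases, "ANG")
  expect_identical(m$qual, r$qual)       # qualities unchanged
  expect_identical(mask_low_quality(m)$bases, m$bases) # idempotent
  # boundary: Q20 kept unmasked, Q19 masked
  r2 <- qread("AC", c(20L, 19L))
  expect_identical(mask_low_quality(r2)$bases, "AN")
  # all above threshold: unchanged; empty read: empty
  r3 <- qread("ACGT", c(20L, 25L, 40L, 21L))
  expect_identical(mask_low_quality(r3)$bases, "ACGT")
  r4 <- qread("", integer(0))
  expect_identical(mask_low_quality(r4)$bases, "")
})

test_that("filtering applies strict mean-quality and N-count boundaries", {
  pol <- filter_policy()
  # 7 Ns at high quality: dropped for Ns; 6 Ns kept
  r7 <- qread(paste0(strrep("N", 7), strrep("A", 20)), rep(35L, 27))
  r6 <- qread(paste0(strrep("N", 6), strrep("A", 20)), rep(30L, 26))
  expect_equal(filter_read(r7, pol), "too_many_n")
  expect_equal(filter_read(r6, pol), "keep")
  # mean exactly 25 kept; just below dropped
  r25 <- qread(strrep("A", 4), c(20L, 30L, 20L, 30L))
  r24 <- qread(strrep("A", 4), c(20L, 30L, 20L, 29L))
  expect_equal(filter_read(mask_low_quality(r25, pol), pol), "keep")
  expect_equal(filter_read(mask_low_quality(r24, pol), pol), "low_mean_q")
  # zero-length read drops as empty
  expect_equal(filter_read(qread("", integer(0)), pol), "empty")
  # low mean takes precedence over N count
  rboth <- qread(strrep("N", 8), rep(10L, 8))
  expect_equal(filter_read(rboth, pol), "low_mean_q")
})

test_that("filtering is monotone in its thresholds", {
  set.seed(303)
  n <- 200
  reads <- read_set(sprintf("r%03d", 1:n),
                    vapply(1:n, function(i) random_seq(40, c("A", "C", "G", "T", "N")),
                           character(1)),
                    lapply(1:n, function(i) sample(5:45, 40, replace = TRUE)))
  reads <- mask_low_quality(reads)
  kept_at <- function(minq, maxn)
    nrow(filter_reads(reads, filter_policy(20, minq, maxn)))
  for (q in c(15, 20, 25, 30))
    expect_gte(kept_at(q, 6), kept_at(q + 3, 6))
  for (nn in c(10, 6, 3))
    expect_gte(kept_at(25, nn), kept_at(25, nn - 2))
})

test_that("clean simulated reads all pass; degraded reads all fail", {
  panel <- tiny_panel()
  sp <- tiny_spec()
  bcs <- tiny_barcodes()
  good <- simulate_run(panel, sp, bcs,
                       platform_error_model(quality_model = list(type = "flat", q = 35)),
                       n_reads = 50, seed = 5)
  g <- mask_low_quality(good$reads)
  expect_true(all(filter_read(g) == "keep"))
  bad <- simulate_run(panel, sp, bcs,
                      platform_error_model(quality_model = list(type = "flat", q = 18)),
                      n_reads = 50, seed = 6)
  b <- mask_low_quality(bad$reads)
  expect_true(all(filter_read(b) != "keep"))
})

test_that("quality summaries aggregate by position and length", {
  reads <- read_set(c("a", "b"), c("AC", "GT"),
                    list(c(10L, 20L), c(30L, 40L)))
  qs <- summarize_quality(reads)
  expect_equal(qs$per_position_quality$mean, c(20, 30))
  expect_equal(qs$per_position_quality$count, c(2L, 2L))
  expect_equal(as.integer(qs$read_length_histogram["2"]), 2L)
  expect_equal(qs$reads_in, 2L)
  # single read: quartiles collapse onto its values
  one <- qread("ACG", c(12L, 14L, 16L))
  q1 <- summarize_quality(one)
  expect_equal(q1$per_position_quality$q25, c(12, 14, 16))
  expect_equal(q1$per_position_quality$q75, c(12, 14, 16))
  # empty input
  q0 <- summarize_quality(read_set(character(0), character(0), character(0)))
  expect_equal(q0$reads_in, 0L)
  expect_equal(nrow(q0$per_position_quality), 0L)
})
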