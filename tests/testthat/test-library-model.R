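test_that("assembled constructs concatenate the documented layout", {
  sp <- tiny_spec()
  out <- assemble_construct(sp, "AAAA", "CCGGT")
  expect_identical(out, paste0("ACGTACCTGA", "AAAA", "GGTTCACTGC", "CCGGT",
                               revcomp("TAATACGACT"), revcomp("TTGACCTGAC")))
  # empty insert: flanks only
  expect_identical(assemble_construct(sp, "AAAA", ""),
                   paste0("ACGTACCTGA", "AAAA", "GGTTCACTGC",
                          revcomp("TAATACGACT"), revcomp("TTGACCTGAC")))
  expect_error(assemble_construct(sp, "AAAAA", "CC"), "barcode length")
})

test_that("construct length is additive for the packaged 454 preset", {
  sp <- construct_preset("flx454")
  bc <- barcode_preset("flx454")$entries[[1]]
  insert <- random_seq(350)
  flank <- nchar(sp$adapter5) + sp$barcode_len + nchar(sp$linker_fwd) +
    nchar(sp$linker_rev) + nchar(sp$adapter3)
  expect_equal(nchar(assemble_construct(sp, bc, insert)), 350 + flank)
})

test_that("barcode sets enforce the unambiguity distance invariant", {
  expect_error(barcode_set(c(a = "AAAA", b = "AATA"), max_mismatch = 1),
               "Hamming")
  expect_error(barcode_set(c(a = "AAAA", b = "TTT")), "same length")
  expect_silent(bs <- barcode_set(c(a = "AAAA", b = "TTTT"), max_mismatch = 1))
  for (p in c("flx454", "pgm", "miseq"))
    expect_s3_class(barcode_preset(p), "barcode_set")
})

test_that("demultiplexing assigns within max_mismatch and else unassigns", {
  sp <- tiny_spec()
  bcs <- tiny_barcodes()
  mk <- function(bc_window) {
    b <- paste0(sp$adapter5, bc_window, sp$linker_fwd, "CCGGT")
    qread(b, rep(40L, nchar(b)))
  }
  expect_equal(demultiplex(mk("AAAA"), bcs, sp)$sample_id, "s1")   # exact
  expect_equal(demultiplex(mk("AATA"), bcs, sp)$sample_id, "s1")   # distance 1
  expect_equal(demultiplex(mk("AATT"), bcs, sp)$sample_id, NA_character_)
  expect_equal(demultiplex(mk("ANAA"), bcs, sp)$sample_id, "s1")   # N = mismatch
  # read shorter than offset + barcode length: unassigned, not an error
  short <- qread("ACGTACCTG", rep(40L, 9))
  expect_equal(demultiplex(short, bcs, sp)$sample_id, NA_character_)
})

test_that("demultiplexing is unambiguous: exhaustive small-alphabet check", {
  sp <- tiny_spec()
  bcs <- tiny_barcodes()
  hd <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  windows <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 4)),
                   1, paste, collapse = "")
  reads <- read_set(sprintf("w%03d", seq_along(windows)),
                    paste0(sp$adapter5, windows, sp$linker_fwd),
                    vapply(windows, function(w)
                      strrep("I", nchar(sp$adapter5) + 4 +
                               nchar(sp$linker_fwd)), character(1)))
  got <- demultiplex(reads, bcs, sp)$sample_id
  for (i in seq_along(windows)) {
    within <- names(bcs$entries)[
      vapply(bcs$entries, hd, 1, b = windows[i]) <= bcs$max_mismatch]
    expect_lte(length(within), 1) # invariant: never ambiguous
    expect_equal(got[i],
                 if (length(within)) within else NA_character_,
                 info = windows[i])
  }
})

test_that("trim/assemble/demultiplex invert each other", {
  sp <- tiny_spec()
  bcs <- tiny_barcodes()
  set.seed(11)
  for (k in 1:20) {
    insert <- random_seq(sample(30:60, 1))
    smp <- sample(names(bcs$entries), 1)
    cons <- assemble_construct(sp, bcs$entries[[smp]], insert)
    rd <- qread(cons, rep(38L, nchar(cons)))
    expect_equal(demultiplex(rd, bcs, sp)$sample_id, smp)
    tr <- trim_construct(rd, sp)
    expect_true(tr$trimmed)
    expect_identical(tr$bases, insert)
    expect_equal(nchar(tr$qual), nchar(insert))
  }
})

test_that("trimming handles truncated and unrecognised reads", {
  sp <- tiny_spec()
  bcs <- tiny_barcodes()
  set.seed(77)
  insert <- random_seq(50)
  cons <- assemble_construct(sp, "AAAA", insert)
  # truncated before the 3' linker: 5'-trimmed only
  cut <- substr(cons, 1, nchar(sp$adapter5) + 4 + nchar(sp$linker_fwd) + 30)
  tr <- trim_construct(qread(cut, rep(38L, nchar(cut))), sp)
  expect_true(tr$trimmed)
  expect_identical(tr$bases, substr(insert, 1, 30))
  # no recognisable adapter: unchanged and flagged
  noise <- qread(random_seq(80), rep(38L, 80))
  tr2 <- trim_construct(noise, sp)
  expect_false(tr2$trimmed)
  expect_identical(tr2$bases, noise$bases)
})
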