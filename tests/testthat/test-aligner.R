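test_that("exact, substituted and reverse-complement reads align as expected", {
  panel <- tiny_panel()
  refA <- panel$ampA$seq
  # exact substring: all M, score = 2 * length
  sub <- substr(refA, 11, 50)
  a <- align_read(sub, panel)
  expect_true(a$aligned)
  expect_equal(a$ref_name, "ampA")
  expect_equal(a$strand, "+")
  expect_equal(a$ops, strrep("M", 40))
  expect_equal(a$score, 2L * 40L)
  expect_equal(a$ref_start, 10L)
  expect_equal(a$ref_end, 50L)
  # one substitution in the middle: exactly one X column
  ch <- strsplit(sub, "")[[1]]
  ch[20] <- setdiff(c("A", "C", "G", "T"), ch[20])[1]
  b <- align_read(paste(ch, collapse = ""), panel)
  expect_equal(sum(strsplit(b$ops, "")[[1]] == "X"), 1L)
  expect_equal(b$score, 39L * 2L - 4L)
  # reverse complement: strand -, all M, ops in reference coordinates
  d <- align_read(revcomp(sub), panel)
  expect_equal(d$strand, "-")
  expect_equal(d$ops, strrep("M", 40))
  expect_equal(d$score, 2L * 40L)
  expect_equal(d$ref_start, 10L)
})

test_that("a deleted-base read matches the frozen oracle alignment", {
  # read ACGTCGTAC = ref ACGTACGTAC minus its fifth base; independent
  # memoized-recursion oracle scores this 11 (9 matches, one 1-base gap)
  expect_equal(sw_oracle_score("ACGTCGTAC", "ACGTACGTAC"), 11)
  a <- align_read("ACGTCGTAC", c(ref = "ACGTACGTAC"))
  expect_equal(a$score, 11L)
  expect_equal(a$ops, "MMMMDMMMMM")
})

test_that("scores equal the brute-force oracle on random small instances", {
  set.seed(1234)
  for (k in 1:120) {
    rd <- random_seq(sample(3:50, 1), c("A", "C", "G", "T", "N"))
    rf <- random_seq(sample(3:50, 1))
    a <- amperr:::.sw_pair_cpp(rd, rf, 2L, -4L, -6L, -1L)
    expect_equal(a$score, sw_oracle_score(rd, rf),
                 info = paste(rd, rf))
  }
})

test_that("strand symmetry: reverse-complemented reads score identically", {
  panel <- tiny_panel()
  set.seed(55)
  for (k in 1:15) {
    # panel-derived read with two substitutions: a unique best alignment
    rd <- strsplit(substr(panel$ampB$seq, 20, 70), "")[[1]]
    at <- sample(5:45, 2)
    rd[at] <- vapply(rd[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    rd <- paste(rd, collapse = "")
    a <- align_read(rd, panel)
    b <- align_read(revcomp(rd), panel)
    expect_equal(a$score, b$score)
    expect_equal(a$ref_name, b$ref_name)
    expect_true(a$strand != b$strand)
  }
})

test_that("emitted alignments are ops/score consistent", {
  panel <- tiny_panel()
  sp <- tiny_spec()
  bcs <- tiny_barcodes()
  sim <- simulate_run(panel, sp, bcs,
                      platform_error_model(subst_rate = 0.02, indel_rate = 0.01),
                      n_reads = 60, seed = 8)
  ins <- trim_construct(demultiplex(sim$reads, bcs, sp), sp)
  aln <- batch_align(ins, panel)
  scheme <- scoring_scheme()
  for (i in which(aln$aligned)) {
    ref <- panel[[aln$ref_name[i]]]
    expect_equal(
      score_from_ops(aln$ops[i], aln$oriented_bases[i], ref$seq,
                     aln$read_start[i], aln$ref_start[i], scheme),
      aln$score[i])
    o <- strsplit(aln$ops[i], "")[[1]]
    # column bookkeeping: ref span and read span match the ops
    expect_equal(sum(o %in% c("M", "X", "D")),
                 aln$ref_end[i] - aln$ref_start[i])
    expect_equal(sum(o %in% c("M", "X", "I")),
                 aln$read_end[i] - aln$read_start[i])
  }
})

test_that("batch alignment rate counts exact and random reads correctly", {
  panel <- tiny_panel()
  set.seed(21)
  exact <- vapply(1:8, function(i) substr(panel$ampA$seq, i, i + 59),
                  character(1))
  junk <- vapply(1:4, function(i) random_seq(60), character(1))
  aln <- batch_align(c(exact, junk), panel)
  expect_equal(sum(aln$aligned), 8L)
  expect_equal(attr(aln, "alignment_rate"), 100 * 8 / 12)
  all_ok <- batch_align(exact, panel)
  expect_equal(attr(all_ok, "alignment_rate"), 100)
  none <- batch_align(junk, panel)
  expect_equal(attr(none, "alignment_rate"), 0)
})

test_that("ties break deterministically by panel order and + strand", {
  # identical references: the first panel entry and + strand must win
  panel <- as_amplicon_panel(list(
    amplicon_reference("first", "ACGTTGCAACGGTCAT"),
    amplicon_reference("second", "ACGTTGCAACGGTCAT")))
  a <- align_read("ACGTTGCAACGGTCAT", panel)
  expect_equal(a$ref_name, "first")
  expect_equal(a$strand, "+")
  # a palindromic read scores equally on both strands: + wins
  pal <- "ACGTACGTACGTACGT"
  p2 <- align_read(pal, as_amplicon_panel(list(
    amplicon_reference("p", pal))))
  expect_equal(p2$strand, "+")
})
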