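test_that("exclusion masks flag homopolymers and GC-rich windows", {
  expect_equal(build_exclusion_mask("ACGTACGTACGT"), rep(FALSE, 12))
  expect_equal(build_exclusion_mask("AAAATCG"),
               c(rep(TRUE, 4), rep(FALSE, 3)))
  expect_true(all(build_exclusion_mask(strrep("G", 10))))
  # every 10-window with >= 8 G/C flags all its positions: the windows
  # starting at 9, 10 and 11 qualify here, excluding positions 9-20
  m <- build_exclusion_mask(paste0("ATATATATAT", "GCGCGCGCAT", "ATATATATAT"),
                            exclusion_policy(gc_min_fraction = 0.8))
  expect_equal(which(m), 9:20)
  # run of 3 below the default threshold stays included
  expect_false(any(build_exclusion_mask("AAATCGATCG")))
  # thresholds are configurable
  expect_true(any(build_exclusion_mask("AAATCGATCG",
                                       exclusion_policy(homopolymer_min_run = 3))))
})

test_that("accumulate tallies columns per the classification rules", {
  ref <- amplicon_reference("amp", paste0("AAAA", "CGTGCA", "TTTT"))
  # positions 1-4 and 11-14 are excluded (homopolymers), 5-10 are not
  prof <- error_profile("amp")
  mk_aln <- function(ops, oriented, ref_start = 0L) {
    structure(list(read_id = "r", ref_name = "amp", strand = "+",
                   score = 0L, ref_start = ref_start,
                   ref_end = ref_start + sum(strsplit(ops, "")[[1]] %in% c("M", "X", "D")),
                   read_start = 0L, read_end = sum(strsplit(ops, "")[[1]] %in% c("M", "X", "I")),
                   ops = ops, aligned = TRUE, oriented_bases = oriented),
              class = "alignment_result")
  }
  # clean full-length alignment
  p1 <- accumulate(prof, mk_aln(strrep("M", 14), ref$seq), ref)
  expect_equal(p1$per_amplicon$aligned_bases, 14)
  expect_equal(p1$per_amplicon$subst_bases, 0)
  expect_equal(unname(p1$per_base_totals), c(1, 2, 2, 1)) # non-excluded only
  # one substitution at non-excluded ref position 5 (C -> T)
  p2 <- accumulate(prof, mk_aln(paste0("MMMM", "X", strrep("M", 9)),
                                paste0("AAAA", "T", "GTGCA", "TTTT")), ref)
  expect_equal(p2$per_amplicon$subst_bases, 1)
  expect_equal(p2$subst_matrix_counts["C", "T"], 1)
  # substitution inside an excluded homopolymer: counted in subst_bases only
  p3 <- accumulate(prof, mk_aln(paste0("X", strrep("M", 13)),
                                paste0("G", "AAA", "CGTGCA", "TTTT")), ref)
  expect_equal(p3$per_amplicon$subst_bases, 1)
  expect_true(all(p3$subst_matrix_counts == 0))
  # read-N columns: aligned but excluded from substitution statistics
  p4 <- accumulate(prof, mk_aln(strrep("M", 14),
                                paste0("AAAA", "NGTGCA", "TTTT")), ref)
  expect_equal(p4$per_amplicon$aligned_bases, 14)
  expect_equal(p4$per_amplicon$subst_bases, 0)
  expect_equal(unname(p4$per_base_totals), c(1, 1, 2, 1))
  # indel columns count bases, not events
  p5 <- accumulate(prof, mk_aln(paste0(strrep("M", 4), "III", strrep("M", 10)),
                                paste0("AAAA", "CCC", "CGTGCA", "TTTT")), ref)
  expect_equal(p5$per_amplicon$ins_bases, 3)
  p6 <- accumulate(prof, mk_aln(paste0(strrep("M", 4), "DD", strrep("M", 8)),
                                paste0("AAAA", "TGCA", "TTTT")), ref)
  expect_equal(p6$per_amplicon$del_bases, 2)
  # malformed ops are a hard error
  expect_error(accumulate(prof, mk_aln(strrep("M", 15),
                                       paste0(ref$seq, "A")), ref),
               "mismatch")
})

test_that("rates implement the definitional ratios", {
  # 10 reads x 100 aligned columns with 5 substitutions and 2 insertions
  prof <- error_profile(aligned_reads = 10, aligned_bases = 1000,
                        subst_bases = 5, ins_bases = 2)
  r <- rates(prof)[1, ]
  expect_equal(r$subst_pct, 0.5)
  expect_equal(r$indel_pct, 0.2)
  expect_equal(r$subs_per_read, 0.5)
  expect_equal(r$indels_per_read, 0.2)
  # no aligned reads: rates reported as 0 and flagged undefined
  r0 <- rates(error_profile())[1, ]
  expect_equal(r0$subst_pct, 0)
  expect_false(r0$defined)
})

test_that("substitution matrix percentages and totals are consistent", {
  prof <- error_profile("amp")
  prof$per_base_totals[] <- c(A = 1000, C = 500, G = 500, T = 1000)
  prof$subst_matrix_counts["A", "G"] <- 2
  sm <- substitution_matrix(prof)
  expect_equal(sm$matrix["A", "G"], 0.2)
  expect_equal(unname(sm$total["A"]), 0.2)
  expect_true(is.na(sm$matrix["A", "A"]))
  expect_equal(unname(sm$total["C"]), 0)
  # row totals are exactly the sum of the off-diagonal entries
  prof$subst_matrix_counts["T", c("A", "C", "G")] <- c(1, 2, 3)
  sm2 <- substitution_matrix(prof)
  expect_equal(unname(sm2$total["T"]),
               sum(sm2$matrix["T", c("A", "C", "G")]))
  # a zero per-base total reports an undefined row
  prof$per_base_totals["C"] <- 0
  expect_true(all(is.na(substitution_matrix(prof)$matrix["C", ])))
})

test_that("transition/transversion rates average the right cells", {
  m <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  diag(m) <- NA
  m["A", "G"] <- 0.04
  tt <- classify_transitions(m)
  expect_equal(tt$transition_rate, 0.01)
  expect_equal(tt$transversion_rate, 0)
  m2 <- matrix(0.03, 4, 4, dimnames = dimnames(m))
  diag(m2) <- NA
  tt2 <- classify_transitions(m2)
  expect_equal(tt2$transition_rate, 0.03)
  expect_equal(tt2$transversion_rate, 0.03)
})

test_that("compiled tally agrees with the reference accumulate loop", {
  panel <- tiny_panel()
  sp <- tiny_spec()
  bcs <- tiny_barcodes()
  sim <- simulate_run(panel, sp, bcs,
                      platform_error_model(subst_rate = 0.03, indel_rate = 0.015),
                      n_reads = 80, seed = 31)
  fit <- profile_errors(sim$reads, panel, sp, bcs)
  aln <- attr(fit, "alignments")
  slow <- error_profile(names(panel))
  for (i in which(aln$aligned)) {
    a <- as.list(aln[i, ])
    class(a) <- "alignment_result"
    slow <- accumulate(slow, a, panel[[a$ref_name]])
  }
  expect_equal(slow$per_amplicon$aligned_bases, fit$per_amplicon$aligned_bases)
  expect_equal(slow$per_amplicon$subst_bases, fit$per_amplicon$subst_bases)
  expect_equal(slow$per_amplicon$ins_bases, fit$per_amplicon$ins_bases)
  expect_equal(slow$per_amplicon$del_bases, fit$per_amplicon$del_bases)
  expect_equal(slow$subst_matrix_counts, fit$subst_matrix_counts)
  expect_equal(slow$per_base_totals, fit$per_base_totals)
  # per-amplicon counters sum to the pooled counters
  pooled <- rates(fit)[1, ]
  expect_equal(pooled$aligned_bases, sum(fit$per_amplicon$aligned_bases))
  expect_equal(pooled$subst_bases, sum(fit$per_amplicon$subst_bases))
})
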