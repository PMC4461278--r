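# Shared in-code fixtures: a miniature construct/barcode configuration with
# short flanks (fast to align) and a two-target reference panel.

tiny_spec <- function() {
  construct_spec("miseq",
                 adapter5 = "ACGTACCTGA", adapter3 = "TTGACCTGAC",
                 linker_fwd = "GGTTCACTGC", linker_rev = "TAATACGACT",
                 barcode_len = 4)
}

tiny_barcodes <- function(max_mismatch = 1) {
  barcode_set(c(s1 = "AAAA", s2 = "TTTT"), max_mismatch = max_mismatch)
}

tiny_panel <- function(policy = exclusion_policy()) {
  set.seed(4242)
  as_amplicon_panel(list(
    amplicon_reference("ampA", random_seq(80), policy),
    amplicon_reference("ampB", random_seq(90), policy)))
}

# one-row read_set shorthand
qread <- function(bases, quals, id = "r1") {
  read_set(id, bases, if (is.character(quals)) quals else list(quals))
}
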