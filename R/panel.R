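# Packaged amplicon reference panel.
#
# The pipeline was developed around five exonic amplicons (325-370 bp) of the
# CREBBP gene; the actual target sequences are not redistributable here, so
# the packaged panel consists of five SYNTHETIC stand-in sequences of the
# same lengths, named after the exons they stand in for and carrying the
# compositional features relevant to error profiling: a 7-base A run (E16),
# a 13-base T run (E18.01) and a GC-rich patch (E30). They are fixed
# constants, not drawn at run time.

.PANEL_SEQS <- c(
  E16    = "CCGGTGCTGTATTCACTCACACGGAGGGAATACGTTATCTGCCGGATTACCTCGGGGATTTTACAGTGATACTTAATAAAGCATTAGCACATCGTGCGAGCCGAGTCTAGAATCGCCGAAAAAAAATAACTGCGTCGTATGAACTGGTAAAATGTTCCGTTCGGATGCTCGCTATTACCGCACCATAGTCTGTCCCAGTAGTATGGTGATTAGGCGAATGCCATGTCACTCCTCTGACGCATCCTAATAGATGAATGCCGAAGACCGTATCTCCACTAACTGGCAAAAAGGGTGCGTCGTAAGATAAGTATAGTAATTAAGTTAAACTAAATTACCGAATAGCTCACACT",
  E18.01 = "ATGGGTAATCATTCTATTTTACGCGCCAGAGGCCCAGTGACGCCACGTGTGCTACGTTGCACGGCCTTTTGCTTCGAGTAGAGGCGGTTTCCGGGTCGAGTGTGCACAAAGTAATGATGACGGTCCGCGTGGTGCTGTCACGGTCCGTACTAAATATTATGCCGTTGACGAATCCGACACCGATATATGCACGGTGGAATTTTTTTTTTTTTGAAAGTTTTGACTGCCCGCGCACTATGTTAACGTACGCTAAAAGGTGCATACCCCCATTAACAGCTCCGCGTACGACCTAACGCACGACTCGAGGAGTATTATAACTCAGGGAAATGTCTGGCTTCGGCGGACGATCCTTCGCTTCCA",
  E26    = "AGCCCACTAGGTTATATAAATGGCTCTGTGAACCGAATTATCTGAGACAAGCGTCAAGCGTGCGCAGCCAGTCTCAGGACTACTGACTGTACACCGTTCTGACGACTAGGACCTTCTGTGACGACCCGTAGTACAGTTCCCCCATCGGCGGTATGACGACGAAAACTGCTCGTCCTAGAGCTTCTAACGCCCGGTTGACGTATCGTCGCTCAGTTGATGAGCGACACGTACGTTTTCGGTCTACGCCCTCAAAACCCTACACTAGACATACGCGCCAGTTGATATCTATTACCACAGGTATCTCGTGTATGGTGGCGAGGTTTAC",
  E30    = "GGCAGACCAGAACGCCGGGCCTGGATCGTTTTCTTAAAATTCTGGGGTGGGGAGGCGGCCGCGGGCTTAGAATCCATACCATTCTTCGCCGTAGGAGGCTCGGTTTTCCGAAGCCGGTTAGGGCCACCCTCTTGCTGCTTCCTATATTACTAGTTGTTGGGCCACAAGGAGACCGACAGTAGACACGTCTCACCGCCCCAGATCCCTTCCAACGCGGATTTGAATTCCTCCGGAGGTAACGAGTGTAAAGGAGTTCAGCCAGTCTCCGCAGTCCGTATGCACGACCCCTCTACACTTGGGATACATTCTGTTTTTCTTCGAGATAATGGAGTCGCGAGTCTGTATCATTCTTGCTTGGGATCAATGAAAG",
  E31    = "CAGATCGCATCTCGACCTGGGGATTGGTACAAACTCGTCGCTACCAGCTCCTGGCTTTTGTTCGTACAGTCAATGGGAGTACGCCTAAAAGAGGTAAAGGGCCCCAAATGCATGCTATCCAAGGCCTTATGCTGTCCGGACAAGCGGTTCCCCGCAGCTCGGTAAAGAAGCCAAAATGTATAAGAATTAAGGAATCACTGCTGCTTACATGTCATTGGATGGCTGATAGTGGGGGTATTGAAGTACTAGTAAAAGCAGGGTACAAAGGGCTGCCCTGGCGGAGTCTGAAAAATAGTAACCATATTAGAAGCCAGCGAGCGCTCCCACTATTGCGATC"
)

#' Packaged amplicon reference panel (synthetic)
#'
#' Returns the packaged panel of five synthetic 325-370 bp amplicon
#' stand-ins (`E16`, `E18.01`, `E26`, `E30`, `E31`) with exclusion masks
#' computed under `policy`. The sequences are synthetic: they mirror the
#' lengths and the error-relevant composition of the real exonic amplicons
#' (homopolymer runs, a GC-rich patch) without reproducing them.
#'
#' @param policy an [exclusion_policy].
#' @return an `amplicon_panel`.
#' @examples
#' amplicon_panel()
#' @export
amplicon_panel <- function(policy = exclusion_policy()) {
  as_amplicon_panel(lapply(names(.PANEL_SEQS), function(nm)
    amplicon_reference(nm, .PANEL_SEQS[[nm]], policy)))
}
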