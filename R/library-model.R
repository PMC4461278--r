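# Two-step PCR library model: constructs, barcodes, demultiplexing, trimming.
#
# Reads of a two-step amplicon library have the layout
#   adapter5 | barcode | linker_fwd | insert | rc(linker_rev) | rc(adapter3)
# where the linkers are the universal tails introduced by first-round PCR
# and adapter/barcode are fused in the second round.

#' Describe a two-step PCR library construct
#'
#' @param platform_tag one of `"flx454"`, `"pgm"`, `"miseq"`.
#' @param adapter5,adapter3 platform adapter sequences (5' as read; 3' given
#'   in its forward orientation and reverse-complemented on assembly).
#' @param linker_fwd universal linker on the forward gene-specific primer.
#' @param linker_rev T7-style linker on the reverse gene-specific primer.
#' @param barcode_len barcode length in bases.
#' @return an object of class `construct_spec`.
#' @seealso [construct_preset] for the packaged per-platform presets.
#' @export
construct_spec <- function(platform_tag = c("flx454", "pgm", "miseq"),
                           adapter5, adapter3, linker_fwd, linker_rev,
                           barcode_len) {
  platform_tag <- match.arg(platform_tag)
  for (s in c(adapter5, adapter3, linker_fwd, linker_rev))
    .check_alphabet(s, what = "construct part")
  barcode_len <- as.integer(barcode_len)
  stopifnot(barcode_len > 0)
  structure(list(platform_tag = platform_tag,
                 adapter5 = toupper(adapter5), adapter3 = toupper(adapter3),
                 linker_fwd = toupper(linker_fwd),
                 linker_rev = toupper(linker_rev),
                 barcode_len = barcode_len),
            class = "construct_spec")
}

#' Packaged construct presets
#'
#' Returns a ready-made [construct_spec] per platform. Adapters are the
#' public library adapters of each platform (454 Titanium A/B, Ion A/trP1,
#' Illumina P5/P7); the two universal linkers are representative synthetic
#' sequences with the documented structure -- the forward linker starts with
#' a 4-base G run (the short homopolymer known to depress early-cycle
#' quality on 454), the reverse linker is the T7 promoter. Barcode lengths
#' are 10 bp (454 MIDs, Ion barcodes) and 8 bp (Illumina index). The
#' pipeline itself is sequence-agnostic given any `construct_spec`.
#'
#' @param platform one of `"flx454"`, `"pgm"`, `"miseq"`.
#' @return a [construct_spec].
#' @examples
#' construct_preset("flx454")
#' @export
construct_preset <- function(platform = c("flx454", "pgm", "miseq")) {
  platform <- match.arg(platform)
  linker_fwd <- "GGGGACACTGACGACATGGTTCTACA"
  linker_rev <- "TAATACGACTCACTATAGGG" # T7 promoter
  switch(platform,
    flx454 = construct_spec("flx454",
      adapter5 = "CGTATCGCCTCCCTCGCGCCATCAG",
      adapter3 = "CTATGCGCCTTGCCAGCCCGCTCAG",
      linker_fwd = linker_fwd, linker_rev = linker_rev, barcode_len = 10),
    pgm = construct_spec("pgm",
      adapter5 = "CCATCTCATCCCTGCGTGTCTCCGACTCAG",
      adapter3 = "CCTCTCTATGGGCAGTCGGTGAT",
      linker_fwd = linker_fwd, linker_rev = linker_rev, barcode_len = 10),
    miseq = construct_spec("miseq",
      adapter5 = "AATGATACGGCGACCACCGAGATCTACAC",
      adapter3 = "CAAGCAGAAGACGGCATACGAGAT",
      linker_fwd = linker_fwd, linker_rev = linker_rev, barcode_len = 8))
}

#' Define a barcode set
#'
#' Maps sample identifiers to barcodes of equal length. The pairwise
#' Hamming distance between barcodes must exceed `2 * max_mismatch`, which
#' guarantees that at most one barcode lies within `max_mismatch` of any
#' read window, making demultiplexing unambiguous.
#'
#' @param entries named character vector: `sample_id -> barcode`.
#' @param max_mismatch maximum Hamming distance tolerated at assignment
#'   (default 1).
#' @return an object of class `barcode_set`.
#' @export
barcode_set <- function(entries, max_mismatch = 1) {
  stopifnot(length(entries) >= 1, !is.null(names(entries)),
            all(nzchar(names(entries))), max_mismatch >= 0)
  entries <- toupper(entries)
  .check_alphabet(entries, what = "barcode")
  if (length(unique(nchar(entries))) != 1)
    stop("all barcodes must have the same length")
  if (anyDuplicated(names(entries)))
    stop("duplicate sample ids in barcode set")
  n <- length(entries)
  if (n > 1) {
    sp <- strsplit(entries, "", fixed = TRUE)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- sum(sp[[i]] != sp[[j]])
      if (d <= 2 * max_mismatch)
        stop(sprintf(
          "barcodes '%s' and '%s' are only Hamming distance %d apart; need > %d for unambiguous assignment at max_mismatch = %d",
          entries[i], entries[j], d, 2 * max_mismatch, max_mismatch))
    }
  }
  structure(list(entries = entries, max_mismatch = as.integer(max_mismatch)),
            class = "barcode_set")
}

#' Packaged barcode presets
#'
#' Ten-sample barcode sets per platform: the public Roche MID 1-10
#' multiplex identifiers for `"flx454"`, and synthetic 10-bp (`"pgm"`) and
#' 8-bp (`"miseq"`, single index) sets with pairwise Hamming distance >= 4.
#' A 16-bp concatenated dual index can be supplied through a custom
#' [barcode_set] if dual-index demultiplexing is to be modelled.
#'
#' @param platform one of `"flx454"`, `"pgm"`, `"miseq"`.
#' @param max_mismatch tolerated Hamming distance (default 1).
#' @return a [barcode_set] with samples `S01` ... `S10`.
#' @export
barcode_preset <- function(platform = c("flx454", "pgm", "miseq"),
                           max_mismatch = 1) {
  platform <- match.arg(platform)
  bc <- switch(platform,
    flx454 = c("ACGAGTGCGT", "ACGCTCGACA", "AGACGCACTC", "AGCACTGTAG",
               "ATCAGACACG", "ATATCGCGAG", "CGTGTCTCTA", "CTCGCGTGTC",
               "TAGTATCAGC", "TCTCTATGCG"),
    pgm = c("AAAACTCCAT", "GTGTAACTCC", "GGAAGTAGAA", "TCTTGCACTC",
            "GGCCTTTCCA", "TATCTCGTGA", "ACCCCCTGCA", "CGCCCTAAAG",
            "TACAATTAGG", "ATATTCATCC"),
    miseq = c("CCTCAATC", "GTCACACT", "GAAGGGCC", "GATTATCT", "AAAGCTTG",
              "CAGTATTA", "GTTTCCAT", "GTACTCCA", "ATTAATAG", "ACGCATGG"))
  names(bc) <- sprintf("S%02d", seq_along(bc))
  barcode_set(bc, max_mismatch = max_mismatch)
}

#' Assemble a full library construct
#'
#' Concatenates `adapter5 + barcode + linker_fwd + insert +
#' rc(linker_rev) + rc(adapter3)`.
#'
#' @param spec a [construct_spec].
#' @param barcode barcode sequence of length `spec$barcode_len`.
#' @param insert insert sequence over `{A,C,G,T}` (may be empty).
#' @return the construct sequence (character scalar).
#' @examples
#' sp <- construct_preset("flx454")
#' bc <- barcode_preset("flx454")$entries[[1]]
#' nchar(assemble_construct(sp, bc, strrep("A", 350)))
#' @export
assemble_construct <- function(spec, barcode, insert) {
  stopifnot(inherits(spec, "construct_spec"))
  barcode <- toupper(barcode)
  .check_alphabet(barcode, what = "barcode")
  if (nchar(barcode) != spec$barcode_len)
    stop(sprintf("barcode length %d does not match spec barcode_len %d",
                 nchar(barcode), spec$barcode_len))
  insert <- toupper(insert)
  .check_alphabet(insert, what = "insert")
  paste0(spec$adapter5, barcode, spec$linker_fwd, insert,
         revcomp(spec$linker_rev), revcomp(spec$adapter3))
}

# 5'/3' flank lengths of a construct around the insert
construct_flanks <- function(spec) {
  c(five_prime = nchar(spec$adapter5) + spec$barcode_len + nchar(spec$linker_fwd),
    three_prime = nchar(spec$linker_rev) + nchar(spec$adapter3))
}

#' Demultiplex reads by barcode
#'
#' Inspects the barcode window of each read (at the fixed offset after the
#' 5' adapter given by `spec`) and assigns the unique sample whose barcode
#' lies within `max_mismatch` Hamming distance; `N` counts as a mismatch.
#' Reads too short to contain the window, or with no barcode within range,
#' stay unassigned (`NA`), which is not an error.
#'
#' @param reads a [read_set].
#' @param barcodes a [barcode_set].
#' @param spec a [construct_spec] (supplies the window offset).
#' @return the `read_set` with `sample_id` filled in (`NA` = unassigned).
#' @export
demultiplex <- function(reads, barcodes, spec) {
  stopifnot(inherits(reads, "read_set"), inherits(barcodes, "barcode_set"),
            inherits(spec, "construct_spec"))
  if (nrow(reads) == 0) return(reads)
  bl <- unique(nchar(barcodes$entries))
  if (bl != spec$barcode_len)
    stop("barcode set length does not match construct spec barcode_len")
  offset <- nchar(spec$adapter5)
  best <- rep.int(.Machine$integer.max, nrow(reads))
  pick <- rep(NA_character_, nrow(reads))
  for (s in names(barcodes$entries)) {
    d <- .hamming_window_cpp(reads$bases, barcodes$entries[[s]], offset)
    d[d < 0] <- .Machine$integer.max # read shorter than offset + barcode_len
    hit <- d < best
    best[hit] <- d[hit]
    pick[hit] <- s
  }
  pick[best > barcodes$max_mismatch] <- NA_character_
  reads$sample_id <- pick
  reads
}

#' Trim a construct read down to its insert
#'
#' Strips the 5' adapter + barcode + forward linker (a fixed-length prefix,
#' accepted when the adapter matches within `max_mismatch_per10` mismatches
#' per 10 adapter bases) and, when present, the 3' reverse linker + adapter
#' (located by approximate search, so reads truncated before the 3' linker
#' are 5'-trimmed only). Qualities are trimmed in lockstep; orientation is
#' unchanged. Reads whose 5' adapter is not recognised are passed through
#' unchanged and flagged (`trimmed = FALSE`): downstream alignment decides
#' their fate.
#'
#' @param reads a [read_set].
#' @param spec a [construct_spec].
#' @param max_mismatch_per10 tolerated mismatches per 10 bases of matched
#'   flank sequence (default 1).
#' @return the `read_set` with a logical `trimmed` column added.
#' @export
trim_construct <- function(reads, spec, max_mismatch_per10 = 1) {
  stopifnot(inherits(reads, "read_set"), inherits(spec, "construct_spec"))
  if (nrow(reads) == 0) { reads$trimmed <- logical(0); return(reads) }
  a5 <- spec$adapter5
  allow5 <- ceiling(nchar(a5) / 10) * max_mismatch_per10
  d5 <- .hamming_window_cpp(reads$bases, a5, 0L)
  cut5 <- unname(construct_flanks(spec)["five_prime"])
  ok <- d5 >= 0 & d5 <= allow5 & nchar(reads$bases) > cut5
  # 3' flank: search for the reverse-complemented reverse linker
  l3 <- revcomp(spec$linker_rev)
  allow3 <- ceiling(nchar(l3) / 10) * max_mismatch_per10
  end <- nchar(reads$bases)
  if (any(ok)) {
    pos3 <- .find_approx_cpp(reads$bases[ok], l3, allow3, cut5)
    end[ok] <- ifelse(is.na(pos3), end[ok], pos3 - 1L)
  }
  reads$bases[ok] <- substr(reads$bases[ok], cut5 + 1L, end[ok])
  reads$qual[ok] <- substr(reads$qual[ok], cut5 + 1L, end[ok])
  reads$trimmed <- ok
  reads
}
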