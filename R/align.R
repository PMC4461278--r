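# Local alignment of insert reads against the amplicon panel.

#' Alignment scoring scheme
#'
#' Integer scores for local alignment with affine gaps. A gap of length k
#' costs `gap_open + k * gap_extend`, so a single-base gap scores
#' `gap_open + gap_extend` (-7 at the defaults). `N` mismatches every base.
#'
#' @param match match score (> 0), default +2.
#' @param mismatch mismatch penalty (< 0), default -4.
#' @param gap_open gap opening penalty (< 0), default -6.
#' @param gap_extend per-base gap extension penalty (< 0, `>= gap_open`),
#'   default -1.
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -4L, gap_open = -6L,
                           gap_extend = -1L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0,
            gap_open <= gap_extend)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_scheme")
}

.panel_seqs <- function(refs) {
  if (inherits(refs, "amplicon_panel"))
    return(vapply(refs, `[[`, character(1), "seq"))
  if (inherits(refs, "amplicon_reference"))
    return(structure(refs$seq, names = refs$name))
  if (is.character(refs) && !is.null(names(refs))) return(refs)
  stop("refs must be an amplicon_panel, amplicon_reference, or named character vector")
}

#' Align reads against an amplicon panel
#'
#' Computes a local (Smith-Waterman, affine-gap) alignment of every read
#' against every panel reference in both orientations and keeps the
#' highest-scoring combination per read (ties: panel order, then `+`
#' strand). A read counts as aligned when its best score reaches
#' `min_score_fraction * match * read length`. For `-` strand hits the
#' reported operations, coordinates and tallies refer to the
#' reverse-complemented read, i.e. everything is expressed in reference
#' coordinates. Reference coordinates are 0-based half-open.
#'
#' The per-column operation string uses `M` (match), `X` (substitution),
#' `I` (insertion in the read) and `D` (deletion from the reference);
#' columns where the read base is `N` are reported as `M` and excluded from
#' substitution statistics downstream.
#'
#' @param reads a [read_set] (or character vector of sequences).
#' @param refs an `amplicon_panel` (or named character vector).
#' @param scheme a [scoring_scheme].
#' @param min_score_fraction alignment acceptance threshold as a fraction
#'   of the maximum attainable score (default 0.30: permissive enough for
#'   indel-rich platform reads, strict enough to reject random sequence).
#' @return a data frame of class `alignment_set` with one row per read
#'   (columns `read_id`, `ref_name`, `strand`, `score`, `ref_start`,
#'   `ref_end`, `read_start`, `read_end`, `ops`, `aligned`, `oriented_bases`)
#'   and attribute `alignment_rate` (percent of reads aligned).
#' @export
batch_align <- function(reads, refs, scheme = scoring_scheme(),
                        min_score_fraction = 0.30) {
  seqs <- .panel_seqs(refs)
  if (is.character(reads)) {
    ids <- if (is.null(names(reads))) sprintf("read%d", seq_along(reads)) else names(reads)
    bases <- unname(toupper(reads))
  } else {
    stopifnot(inherits(reads, "read_set"))
    ids <- reads$read_id
    bases <- reads$bases
  }
  if (length(bases) == 0) {
    out <- data.frame(read_id = character(0), ref_name = character(0),
                      strand = character(0), score = integer(0),
                      ref_start = integer(0), ref_end = integer(0),
                      read_start = integer(0), read_end = integer(0),
                      ops = character(0), aligned = logical(0),
                      oriented_bases = character(0), stringsAsFactors = FALSE)
    class(out) <- c("alignment_set", "data.frame")
    attr(out, "alignment_rate") <- NaN
    return(out)
  }
  res <- .align_batch_cpp(bases, unname(seqs), scheme$match, scheme$mismatch,
                          scheme$gap_open, scheme$gap_extend,
                          min_score_fraction)
  oriented <- ifelse(res$strand == "-", revcomp(bases), bases)
  out <- data.frame(read_id = ids, ref_name = names(seqs)[res$ref_idx],
                    strand = res$strand, score = res$score,
                    ref_start = res$ref_start, ref_end = res$ref_end,
                    read_start = res$read_start, read_end = res$read_end,
                    ops = res$ops, aligned = res$aligned,
                    oriented_bases = oriented, stringsAsFactors = FALSE)
  class(out) <- c("alignment_set", "data.frame")
  attr(out, "alignment_rate") <- 100 * mean(out$aligned)
  out
}

#' Align a single read
#'
#' @param read a single-row [read_set] or a character scalar.
#' @inheritParams batch_align
#' @return an object of class `alignment_result`: a list with fields
#'   `read_id`, `ref_name`, `strand`, `score`, `ref_start`, `ref_end`,
#'   `read_start`, `read_end`, `ops`, `aligned` and `oriented_bases`.
#' @export
align_read <- function(read, refs, scheme = scoring_scheme(),
                       min_score_fraction = 0.30) {
  if (is.character(read)) stopifnot(length(read) == 1)
  else stopifnot(inherits(read, "read_set"), nrow(read) == 1)
  aln <- batch_align(read, refs, scheme, min_score_fraction)
  out <- as.list(aln[1, , drop = FALSE])
  class(out) <- "alignment_result"
  out
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("read %s -> %s (%s) score %d, ref %d-%d (1-based), %s\n",
              x$read_id, x$ref_name, x$strand, x$score,
              x$ref_start + 1L, x$ref_end, if (x$aligned) "aligned" else "unaligned"))
  invisible(x)
}

#' Recompute an alignment score from its operation string
#'
#' Walks the per-column operations and re-derives the score under a
#' [scoring_scheme]: `M`/`X` columns score match/mismatch according to the
#' actual bases (an `N` column counts as a mismatch even though it is
#' reported as `M`), and every maximal run of `I` or `D` costs
#' `gap_open + k * gap_extend`. Used to verify the ops/score consistency of
#' emitted alignments.
#'
#' @param ops operation string over `{M,X,I,D}`.
#' @param read the (orientation-resolved) read sequence.
#' @param ref the reference sequence.
#' @param read_start,ref_start 0-based alignment start offsets.
#' @param scheme a [scoring_scheme].
#' @return integer score.
#' @export
score_from_ops <- function(ops, read, ref, read_start, ref_start,
                           scheme = scoring_scheme()) {
  o <- strsplit(ops, "", fixed = TRUE)[[1]]
  rd <- strsplit(read, "", fixed = TRUE)[[1]]
  rf <- strsplit(ref, "", fixed = TRUE)[[1]]
  i <- read_start; j <- ref_start
  score <- 0L
  k <- 1L
  n <- length(o)
  while (k <= n) {
    op <- o[k]
    if (op %in% c("M", "X")) {
      a <- rd[i + 1L]; b <- rf[j + 1L]
      score <- score +
        if (a == b && a != "N" && b != "N") scheme$match else scheme$mismatch
      i <- i + 1L; j <- j + 1L; k <- k + 1L
    } else {
      run <- 0L
      while (k <= n && o[k] == op) { run <- run + 1L; k <- k + 1L }
      score <- score + scheme$gap_open + run * scheme$gap_extend
      if (op == "I") i <- i + run else j <- j + run
    }
  }
  score
}
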