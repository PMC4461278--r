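# Quality masking, read filtering and run-level quality summaries.

#' Quality filter policy
#'
#' The masking/filtering rule set: bases with Phred quality below
#' `mask_below` are replaced by `N`; reads with mean Phred quality below
#' `min_mean_q`, or containing more than `max_n` `N` bases after masking,
#' are removed. Boundary semantics are strict: quality 20 is kept unmasked
#' under the default, mean quality exactly 25 is kept, and exactly 6 `N`s
#' are kept (the 7th drops the read). The mean is the arithmetic mean of
#' Phred scores over all positions, masked ones included.
#'
#' @param mask_below Phred threshold for masking (default 20).
#' @param min_mean_q mean Phred threshold for keeping a read (default 25).
#' @param max_n maximum tolerated `N` count (default 6). Pre-existing `N`s
#'   from the sequencer count together with masked ones.
#' @return an object of class `filter_policy`.
#' @export
filter_policy <- function(mask_below = 20, min_mean_q = 25, max_n = 6) {
  stopifnot(mask_below >= 0, min_mean_q >= 0, max_n >= 0)
  structure(list(mask_below = as.integer(mask_below),
                 min_mean_q = min_mean_q, max_n = as.integer(max_n)),
            class = "filter_policy")
}

#' Mask low-quality bases
#'
#' Replaces every base whose Phred score is below `policy$mask_below` with
#' `N`. Qualities and read lengths are unchanged; masking is idempotent.
#'
#' @param reads a [read_set].
#' @param policy a [filter_policy].
#' @return the masked `read_set`.
#' @export
mask_low_quality <- function(reads, policy = filter_policy()) {
  stopifnot(inherits(reads, "read_set"), inherits(policy, "filter_policy"))
  if (nrow(reads) == 0) return(reads)
  reads$bases <- .mask_bases_cpp(reads$bases, reads$qual, policy$mask_below)
  reads
}

#' Classify each read as kept or dropped
#'
#' Applies the read-removal rules to (already masked) reads. A zero-length
#' read drops with reason `"empty"`; then a read with mean Phred quality
#' `< min_mean_q` drops as `"low_mean_q"`; then a read with more than
#' `max_n` `N` bases drops as `"too_many_n"`; anything else is `"keep"`.
#'
#' @param reads a [read_set].
#' @param policy a [filter_policy].
#' @return character vector of decisions per read: `"keep"`, `"empty"`,
#'   `"low_mean_q"` or `"too_many_n"`.
#' @seealso [filter_reads] for the subsetting wrapper.
#' @export
filter_read <- function(reads, policy = filter_policy()) {
  stopifnot(inherits(reads, "read_set"), inherits(policy, "filter_policy"))
  n <- nrow(reads)
  if (n == 0) return(character(0))
  decision <- rep("keep", n)
  empty <- nchar(reads$bases) == 0
  meanq <- .mean_phred_cpp(reads$qual)
  nn <- .count_char_cpp(reads$bases, "N")
  decision[!empty & nn > policy$max_n] <- "too_many_n"
  decision[!empty & meanq < policy$min_mean_q] <- "low_mean_q"
  decision[empty] <- "empty"
  decision
}

#' Filter a read set
#'
#' @param reads a [read_set] (masked by [mask_low_quality]).
#' @param policy a [filter_policy].
#' @return the kept `read_set`, with attribute `drop_reasons` (a named
#'   integer table of the reasons among dropped reads).
#' @export
filter_reads <- function(reads, policy = filter_policy()) {
  decision <- filter_read(reads, policy)
  kept <- reads[decision == "keep", , drop = FALSE]
  class(kept) <- class(reads)
  dropped <- decision[decision != "keep"]
  attr(kept, "drop_reasons") <- table(factor(
    dropped, levels = c("empty", "low_mean_q", "too_many_n")))
  kept
}

#' Summarise per-position quality and read lengths
#'
#' Computes, over the reads covering each position, the mean and quartiles
#' of the Phred scores, plus the read-length histogram -- the standard
#' run-QC views (per-base quality profile and length distribution).
#'
#' @param reads a [read_set].
#' @return an object of class `qc_summary` with elements
#'   `per_position_quality` (data frame: position, count, mean, q25, median,
#'   q75), `read_length_histogram` (named table) and counts `reads_in`.
#' @export
summarize_quality <- function(reads) {
  stopifnot(inherits(reads, "read_set"))
  n <- nrow(reads)
  if (n == 0) {
    out <- list(per_position_quality = data.frame(
                  position = integer(0), count = integer(0), mean = numeric(0),
                  q25 = numeric(0), median = numeric(0), q75 = numeric(0)),
                read_length_histogram = table(integer(0)), reads_in = 0L)
    class(out) <- "qc_summary"
    return(out)
  }
  lens <- nchar(reads$qual)
  q <- unlist(phred_decode(reads$qual), use.names = FALSE)
  pos <- sequence(lens)
  byq <- split(q, pos)
  pq <- data.frame(
    position = as.integer(names(byq)),
    count = lengths(byq),
    mean = vapply(byq, mean, numeric(1)),
    q25 = vapply(byq, quantile, numeric(1), probs = 0.25, names = FALSE),
    median = vapply(byq, quantile, numeric(1), probs = 0.5, names = FALSE),
    q75 = vapply(byq, quantile, numeric(1), probs = 0.75, names = FALSE),
    row.names = NULL)
  pq <- pq[order(pq$position), , drop = FALSE]
  out <- list(per_position_quality = pq,
              read_length_histogram = table(lens),
              reads_in = n)
  class(out) <- "qc_summary"
  out
}

#' @export
print.qc_summary <- function(x, ...) {
  cat(sprintf("QC summary: %d reads, lengths %s\n", x$reads_in,
              if (x$reads_in) paste(range(as.integer(names(x$read_length_histogram))),
                                    collapse = "-") else "-"))
  if (x$reads_in) {
    m <- x$per_position_quality$mean
    cat(sprintf("  per-position mean quality: %.1f-%.1f\n", min(m), max(m)))
  }
  invisible(x)
}
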