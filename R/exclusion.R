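#' Exclusion policy for substitution-matrix tallies
#'
#' Reference positions inside homopolymer runs or GC-rich windows are
#' excluded from the base-specific substitution matrix (they are dominated
#' by platform-specific artefacts rather than representative substitution
#' behaviour). Excluded positions still count towards the overall
#' substitution and indel rates; the exclusion applies to the matrix only.
#'
#' @param homopolymer_min_run minimum run length of identical bases for a
#'   position to be excluded (default 4: runs of four identical bases are
#'   already artefact-prone on pyrosequencing/semiconductor platforms).
#' @param gc_window window width for the GC-richness rule (default 10).
#' @param gc_min_fraction minimum G+C fraction within a window for all its
#'   positions to be excluded (default 0.8).
#' @return an object of class `exclusion_policy`.
#' @export
exclusion_policy <- function(homopolymer_min_run = 4, gc_window = 10,
                             gc_min_fraction = 0.8) {
  stopifnot(homopolymer_min_run >= 2, gc_window >= 1,
            gc_min_fraction > 0, gc_min_fraction <= 1)
  structure(list(homopolymer_min_run = as.integer(homopolymer_min_run),
                 gc_window = as.integer(gc_window),
                 gc_min_fraction = gc_min_fraction),
            class = "exclusion_policy")
}

#' Build the excluded-position mask for a reference sequence
#'
#' A position is excluded when it lies inside a run of at least
#' `homopolymer_min_run` identical bases, or inside any window of
#' `gc_window` consecutive bases whose G+C fraction is at least
#' `gc_min_fraction`.
#'
#' @param seq a single reference sequence over `{A,C,G,T}`.
#' @param policy an [exclusion_policy].
#' @return logical vector, `TRUE` = excluded.
#' @examples
#' build_exclusion_mask("AAAATCG") # positions 1-4 excluded
#' @export
build_exclusion_mask <- function(seq, policy = exclusion_policy()) {
  seq <- toupper(seq)
  .check_alphabet(seq, c("A", "C", "G", "T"), "reference sequence")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  mask <- logical(n)
  if (n == 0) return(mask)
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$lengths >= policy$homopolymer_min_run))
    mask[starts[k]:ends[k]] <- TRUE
  w <- policy$gc_window
  if (n >= w) {
    gc <- as.integer(ch %in% c("G", "C"))
    roll <- cumsum(gc)
    roll <- roll[w:n] - c(0, roll)[1:(n - w + 1)]
    for (s in which(roll / w >= policy$gc_min_fraction))
      mask[s:(s + w - 1L)] <- TRUE
  }
  mask
}

#' Construct an amplicon reference
#'
#' @param name reference name (e.g. an exon label).
#' @param seq sequence over `{A,C,G,T}` (normalised to upper case).
#' @param policy an [exclusion_policy] used to compute the excluded-position
#'   mask, or a precomputed logical mask of the same length as `seq`.
#' @return an object of class `amplicon_reference` with fields `name`,
#'   `seq` and `excluded_mask`.
#' @export
amplicon_reference <- function(name, seq, policy = exclusion_policy()) {
  seq <- unname(toupper(seq))
  .check_alphabet(seq, c("A", "C", "G", "T"), "reference sequence")
  if (is.logical(policy)) {
    if (length(policy) != nchar(seq))
      stop("excluded_mask length must equal sequence length")
    mask <- policy
  } else {
    mask <- build_exclusion_mask(seq, policy)
  }
  structure(list(name = unname(as.character(name)), seq = seq,
                 excluded_mask = unname(mask)),
            class = "amplicon_reference")
}

#' Coerce a list of amplicon references into a panel
#'
#' @param refs list of `amplicon_reference` objects with unique names.
#' @return an `amplicon_panel` (named list).
#' @export
as_amplicon_panel <- function(refs) {
  stopifnot(all(vapply(refs, inherits, logical(1), "amplicon_reference")))
  nm <- vapply(refs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate reference names in panel")
  names(refs) <- nm
  structure(refs, class = "amplicon_panel")
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat(sprintf("Amplicon reference panel: %d targets\n", length(x)))
  for (r in x)
    cat(sprintf("  %-8s %4d bp, %d excluded positions\n",
                r$name, nchar(r$seq), sum(r$excluded_mask)))
  invisible(x)
}
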