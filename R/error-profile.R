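# Error-profile counters and derived statistics: run/amplicon error rates
# and the base-specific substitution matrix.

.BASES <- c("A", "C", "G", "T")

.empty_counters <- function(amplicons) {
  data.frame(amplicon = amplicons,
             aligned_reads = 0, aligned_bases = 0, subst_bases = 0,
             ins_bases = 0, del_bases = 0,
             fwd_reads = 0, rev_reads = 0,
             stringsAsFactors = FALSE)
}

#' Construct an error profile
#'
#' The error profile holds the alignment-column tallies from which all
#' reported statistics derive: per-amplicon and pooled counts of aligned
#' reads, aligned bases (`M`/`X` columns), substituted bases, inserted and
#' deleted bases, plus the 4x4 substitution-count table and per-base totals
#' restricted to non-excluded reference positions. Usually produced by
#' [profile_errors] or grown with [accumulate]; counts can also be supplied
#' directly (e.g. to recompute rates from published count tables).
#'
#' @param amplicons character vector of amplicon names (default a single
#'   stratum `"all"`; the pooled row reported by [rates] is always labelled
#'   `"run"`).
#' @param aligned_reads,aligned_bases,subst_bases,ins_bases,del_bases
#'   optional per-amplicon counts (recycled to `length(amplicons)`).
#' @return an object of class `error_profile`.
#' @examples
#' p <- error_profile(aligned_reads = 801259, aligned_bases = 270606795,
#'                    subst_bases = 191942, ins_bases = 460650)
#' rates(p)
#' @export
error_profile <- function(amplicons = "all", aligned_reads = 0,
                          aligned_bases = 0, subst_bases = 0,
                          ins_bases = 0, del_bases = 0) {
  per <- .empty_counters(amplicons)
  per$aligned_reads <- rep_len(aligned_reads, nrow(per))
  per$aligned_bases <- rep_len(aligned_bases, nrow(per))
  per$subst_bases <- rep_len(subst_bases, nrow(per))
  per$ins_bases <- rep_len(ins_bases, nrow(per))
  per$del_bases <- rep_len(del_bases, nrow(per))
  structure(list(
    per_amplicon = per,
    subst_matrix_counts = matrix(0, 4, 4, dimnames = list(.BASES, .BASES)),
    per_base_totals = structure(numeric(4), names = .BASES),
    stage_counts = NULL),
    class = "error_profile")
}

#' Accumulate one alignment into an error profile
#'
#' Walks the per-column operations of an aligned read in reference
#' coordinates and updates the counters: `M`/`X` columns increment aligned
#' bases (and, when the reference position is non-excluded and the read
#' base is not `N`, the per-base totals and -- for substitutions -- the
#' substitution-count matrix); `I`/`D` columns increment inserted/deleted
#' base counts. Columns with read base `N` count as aligned but enter no
#' substitution statistic. This is the reference implementation of the
#' tally; [profile_errors] uses a compiled equivalent.
#'
#' @param profile an [error_profile] whose amplicon strata include
#'   `alignment$ref_name`.
#' @param alignment an `alignment_result` from [align_read] (must be
#'   aligned).
#' @param ref the matching `amplicon_reference`.
#' @return the updated `error_profile`.
#' @export
accumulate <- function(profile, alignment, ref) {
  stopifnot(inherits(profile, "error_profile"),
            inherits(ref, "amplicon_reference"))
  if (!isTRUE(alignment$aligned))
    stop("cannot accumulate an unaligned read")
  if (!alignment$ref_name %in% profile$per_amplicon$amplicon)
    stop(sprintf("amplicon '%s' not in profile", alignment$ref_name))
  o <- strsplit(alignment$ops, "", fixed = TRUE)[[1]]
  nref <- sum(o %in% c("M", "X", "D"))
  if (alignment$ref_start + nref != alignment$ref_end ||
      alignment$ref_end > nchar(ref$seq))
    stop("ops/reference length mismatch")
  rd <- strsplit(alignment$oriented_bases, "", fixed = TRUE)[[1]]
  rf <- strsplit(ref$seq, "", fixed = TRUE)[[1]]
  k <- which(profile$per_amplicon$amplicon == alignment$ref_name)
  i <- alignment$read_start; j <- alignment$ref_start
  pa <- profile$per_amplicon
  pa$aligned_reads[k] <- pa$aligned_reads[k] + 1
  if (identical(alignment$strand, "-")) pa$rev_reads[k] <- pa$rev_reads[k] + 1
  else pa$fwd_reads[k] <- pa$fwd_reads[k] + 1
  for (op in o) {
    if (op == "I") { pa$ins_bases[k] <- pa$ins_bases[k] + 1; i <- i + 1 }
    else if (op == "D") { pa$del_bases[k] <- pa$del_bases[k] + 1; j <- j + 1 }
    else {
      qb <- rd[i + 1]; rb <- rf[j + 1]
      pa$aligned_bases[k] <- pa$aligned_bases[k] + 1
      if (qb != "N") {
        excl <- ref$excluded_mask[j + 1]
        if (qb != rb) {
          pa$subst_bases[k] <- pa$subst_bases[k] + 1
          if (!excl) profile$subst_matrix_counts[rb, qb] <-
              profile$subst_matrix_counts[rb, qb] + 1
        }
        if (!excl) profile$per_base_totals[rb] <-
            profile$per_base_totals[rb] + 1
      }
      i <- i + 1; j <- j + 1
    }
  }
  profile$per_amplicon <- pa
  profile
}

# pooled counters across amplicons
.pooled <- function(profile) {
  pa <- profile$per_amplicon
  c(aligned_reads = sum(pa$aligned_reads), aligned_bases = sum(pa$aligned_bases),
    subst_bases = sum(pa$subst_bases), ins_bases = sum(pa$ins_bases),
    del_bases = sum(pa$del_bases))
}

#' Error rates from an error profile
#'
#' Derives the headline statistics, pooled (`amplicon = "run"`) and per
#' amplicon: substitution rate `100 * subst_bases / aligned_bases`, indel
#' rate `100 * (ins_bases + del_bases) / aligned_bases`, and the per-read
#' counts `subst_bases / aligned_reads` and
#' `(ins_bases + del_bases) / aligned_reads`. Indels are counted in bases
#' (a 3-base insertion contributes 3), not events. Strata without aligned
#' reads report 0 with `defined = FALSE`.
#'
#' @param profile an [error_profile].
#' @return a data frame with one row per stratum: `amplicon`,
#'   `aligned_reads`, `aligned_bases`, `subst_bases`, `indel_bases`,
#'   `subst_pct`, `indel_pct`, `subs_per_read`, `indels_per_read`,
#'   `defined`. Rates are unrounded; reports round half-up to 2 decimals.
#' @export
rates <- function(profile) {
  stopifnot(inherits(profile, "error_profile"))
  pa <- profile$per_amplicon
  if (any(pa$amplicon == "run"))
    stop("'run' is reserved for the pooled stratum; rename the amplicon")
  pool <- .pooled(profile)
  tab <- data.frame(
    amplicon = c("run", pa$amplicon),
    aligned_reads = c(pool["aligned_reads"], pa$aligned_reads),
    aligned_bases = c(pool["aligned_bases"], pa$aligned_bases),
    subst_bases = c(pool["subst_bases"], pa$subst_bases),
    indel_bases = c(pool["ins_bases"] + pool["del_bases"],
                    pa$ins_bases + pa$del_bases),
    row.names = NULL, stringsAsFactors = FALSE)
  ok <- tab$aligned_reads > 0 & tab$aligned_bases > 0
  tab$subst_pct <- ifelse(ok, 100 * tab$subst_bases / tab$aligned_bases, 0)
  tab$indel_pct <- ifelse(ok, 100 * tab$indel_bases / tab$aligned_bases, 0)
  tab$subs_per_read <- ifelse(ok, tab$subst_bases / tab$aligned_reads, 0)
  tab$indels_per_read <- ifelse(ok, tab$indel_bases / tab$aligned_reads, 0)
  tab$defined <- ok
  tab
}

#' Base-specific substitution matrix
#'
#' Converts the substitution-count table (tallied over non-excluded
#' reference positions only) into percentages: entry (ref -> read) is
#' `100 * count / per_base_total(ref)`. The diagonal is `NA`; each row
#' total is the sum of its three off-diagonal entries. Rows whose per-base
#' total is zero are reported as `NA` (undefined).
#'
#' @param profile an [error_profile].
#' @return a list with `matrix` (4x4 percentages, `NA` diagonal), `total`
#'   (named per-row totals), `counts` (raw 4x4 counts) and
#'   `per_base_totals`.
#' @export
substitution_matrix <- function(profile) {
  stopifnot(inherits(profile, "error_profile"))
  cnt <- profile$subst_matrix_counts
  tot <- profile$per_base_totals
  m <- matrix(NA_real_, 4, 4, dimnames = list(.BASES, .BASES))
  for (b in .BASES) {
    if (tot[b] > 0) m[b, ] <- 100 * cnt[b, ] / tot[b]
  }
  diag(m) <- NA_real_
  row_total <- apply(m, 1, function(r) sum(r, na.rm = !all(is.na(r))))
  list(matrix = m, total = row_total, counts = cnt, per_base_totals = tot)
}

#' Transition and transversion rates
#'
#' Summarises a substitution matrix into the mean transition rate (mean of
#' the A<->G and C<->T entries) and mean transversion rate (mean of the
#' remaining eight off-diagonal entries).
#'
#' @param matrix a 4x4 percentage matrix as produced by
#'   [substitution_matrix] (the `matrix` element), rows/columns A,C,G,T.
#' @return list with `transition_rate` and `transversion_rate`.
#' @export
classify_transitions <- function(matrix) {
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(4, 4)))
  ti <- c(matrix["A", "G"], matrix["G", "A"], matrix["C", "T"], matrix["T", "C"])
  off <- !diag(4) &
    !(row(matrix) == 1 & col(matrix) == 3) & !(row(matrix) == 3 & col(matrix) == 1) &
    !(row(matrix) == 2 & col(matrix) == 4) & !(row(matrix) == 4 & col(matrix) == 2)
  tv <- matrix[off]
  list(transition_rate = mean(ti), transversion_rate = mean(tv))
}

#' @export
print.error_profile <- function(x, ...) {
  r <- rates(x)[1, ]
  fmt <- function(v) sprintf("%.2f", round_half_up(v, 2))
  cat("Amplicon sequencing error profile\n")
  cat(sprintf("  aligned reads: %s   aligned bases: %s\n",
              format(r$aligned_reads, big.mark = ","),
              format(r$aligned_bases, big.mark = ",")))
  cat(sprintf("  substitutions: %s (%s%%, %s subs/read)\n",
              format(r$subst_bases, big.mark = ","), fmt(r$subst_pct),
              fmt(r$subs_per_read)))
  cat(sprintf("  indels:        %s (%s%%, %s indels/read)\n",
              format(r$indel_bases, big.mark = ","), fmt(r$indel_pct),
              fmt(r$indels_per_read)))
  if (!r$defined) cat("  (no aligned reads: rates undefined, reported as 0)\n")
  invisible(x)
}

#' @export
summary.error_profile <- function(object, ...) {
  out <- list(rates = rates(object),
              substitution_matrix = substitution_matrix(object),
              stage_counts = object$stage_counts)
  out$transitions <- classify_transitions(out$substitution_matrix$matrix)
  class(out) <- "summary.error_profile"
  out
}

#' @export
print.summary.error_profile <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.2f", round_half_up(v, 2)))
  r <- x$rates
  cat("Error rates (percent of aligned bases; per-read counts):\n")
  disp <- data.frame(amplicon = r$amplicon,
                     reads = r$aligned_reads, bases = r$aligned_bases,
                     subst_pct = fmt(r$subst_pct),
                     subs_read = fmt(r$subs_per_read),
                     indel_pct = fmt(r$indel_pct),
                     indels_read = fmt(r$indels_per_read))
  print(disp, row.names = FALSE)
  cat("\nSubstitution matrix (% per non-excluded reference base):\n")
  m <- x$substitution_matrix$matrix
  md <- matrix(fmt(m), 4, 4, dimnames = dimnames(m))
  diag(md) <- "."
  print(cbind(md, Total = fmt(x$substitution_matrix$total)), quote = FALSE)
  tt <- x$transitions
  cat(sprintf("\nMean transition rate: %s%%  mean transversion rate: %s%%\n",
              fmt(tt$transition_rate), fmt(tt$transversion_rate)))
  if (!is.null(x$stage_counts)) {
    cat("\nPipeline stage counts:\n")
    print(x$stage_counts)
  }
  invisible(x)
}

#' @export
coef.error_profile <- function(object, ...) {
  r <- rates(object)[1, ]
  c(subst_pct = r$subst_pct, indel_pct = r$indel_pct,
    subs_per_read = r$subs_per_read, indels_per_read = r$indels_per_read)
}

#' @export
plot.error_profile <- function(x, ...) {
  r <- rates(x)
  r <- r[r$amplicon != "run", , drop = FALSE]
  if (nrow(r) == 0) {
    warning("no per-amplicon strata to plot")
    return(invisible(x))
  }
  h <- rbind(subst = r$subst_pct, indel = r$indel_pct)
  graphics::barplot(h, beside = TRUE, names.arg = r$amplicon,
                    legend.text = c("substitutions", "indels"),
                    ylab = "% of aligned bases",
                    main = "Per-amplicon error rates", ...)
  invisible(x)
}
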