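#' Construct a set of quality reads
#'
#' A `read_set` is the package's container for sequencing reads: a data frame
#' with one row per read and columns `read_id`, `bases` (over A,C,G,T,N),
#' `qual` (Phred+33-encoded string, same length as `bases`), `sample_id`
#' (NA until demultiplexed) and `orientation` (`"forward"`, `"reverse"` or
#' `"unknown"`). A single-read `read_set` plays the role of one quality read.
#'
#' @param read_id character vector of read identifiers.
#' @param bases character vector of base strings over `{A,C,G,T,N}`.
#' @param quals per-read qualities: either a character vector of Phred+33
#'   strings or a list of integer vectors of Phred scores in `[0, 60]`.
#' @param sample_id optional character vector of sample assignments.
#' @param orientation `"forward"`, `"reverse"` or `"unknown"` per read.
#' @return a data frame of class `read_set`.
#' @examples
#' read_set("r1", "ACGT", list(c(40, 40, 40, 40)))
#' @export
read_set <- function(read_id, bases, quals, sample_id = NA_character_,
                     orientation = "unknown") {
  read_id <- as.character(read_id)
  bases <- toupper(as.character(bases))
  .check_alphabet(bases, c("A", "C", "G", "T", "N"), "read bases")
  if (is.list(quals)) quals <- phred_encode(quals)
  quals <- as.character(quals)
  if (length(bases) != length(read_id) || length(quals) != length(read_id))
    stop("read_id, bases and quals must have equal length")
  bad <- nchar(bases) != nchar(quals)
  if (any(bad))
    stop(sprintf("bases/quality length mismatch for read '%s'",
                 read_id[which(bad)[1]]))
  .check_phred_range(quals)
  out <- data.frame(read_id = read_id, bases = bases, qual = quals,
                    sample_id = rep_len(as.character(sample_id), length(read_id)),
                    orientation = rep_len(orientation, length(read_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("read_set", "data.frame")
  out
}

.check_phred_range <- function(qual_strings) {
  if (length(qual_strings) == 0) return(invisible(NULL))
  codes <- utf8ToInt(paste(qual_strings, collapse = ""))
  if (length(codes) && (min(codes) < 33L || max(codes) > 93L))
    stop("Phred scores outside [0, 60] (encoding is fixed to Phred+33)")
  invisible(NULL)
}

#' Encode and decode Phred+33 quality strings
#'
#' @param quals list of integer vectors of Phred scores (or one vector).
#' @return `phred_encode`: character vector; `phred_decode`: list of integer
#'   vectors.
#' @examples
#' phred_encode(list(c(40, 40)))
#' phred_decode("II!")
#' @export
phred_encode <- function(quals) {
  if (!is.list(quals)) quals <- list(quals)
  vapply(quals, function(q) {
    if (length(q) == 0) return("")
    q <- as.integer(q)
    if (any(q < 0L | q > 60L)) stop("Phred scores must lie in [0, 60]")
    intToUtf8(q + 33L)
  }, character(1))
}

#' @rdname phred_encode
#' @param x character vector of Phred+33 strings.
#' @export
phred_decode <- function(x) {
  lapply(as.character(x), function(s) {
    if (nchar(s) == 0) return(integer(0))
    utf8ToInt(s) - 33L
  })
}

#' Read a FASTQ file into a read set
#'
#' Reads 4-line-record FASTQ with Phred+33 quality encoding (the modern
#' export format of all three supported platforms; Phred+64 input is
#' rejected by the quality-range check, not auto-detected). Record order is
#' preserved. A record whose sequence and quality lines differ in length is
#' a hard error naming the record.
#'
#' @param path path to a FASTQ file.
#' @return a [read_set].
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0)
    return(read_set(character(0), character(0), character(0)))
  if (length(lines) %% 4L != 0L)
    stop(sprintf("FASTQ '%s': number of lines (%d) is not a multiple of 4",
                 path, length(lines)))
  hd <- lines[seq(1, length(lines), by = 4)]
  sq <- lines[seq(2, length(lines), by = 4)]
  pl <- lines[seq(3, length(lines), by = 4)]
  qu <- lines[seq(4, length(lines), by = 4)]
  if (any(substr(hd, 1, 1) != "@"))
    stop(sprintf("FASTQ '%s': malformed header at record %d", path,
                 which(substr(hd, 1, 1) != "@")[1]))
  if (any(substr(pl, 1, 1) != "+"))
    stop(sprintf("FASTQ '%s': malformed separator at record %d", path,
                 which(substr(pl, 1, 1) != "+")[1]))
  ids <- sub("\\s.*$", "", substring(hd, 2))
  bad <- nchar(sq) != nchar(qu)
  if (any(bad))
    stop(sprintf("FASTQ '%s': sequence/quality length mismatch in record '%s'",
                 path, ids[which(bad)[1]]))
  read_set(ids, sq, qu)
}

#' Write a read set to FASTQ
#'
#' @param reads a [read_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  if (nrow(reads) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  out <- rbind(paste0("@", reads$read_id), reads$bases, "+", reads$qual)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Read an amplicon reference panel from FASTA
#'
#' Loads a FASTA file of amplicon target sequences and computes each
#' sequence's exclusion mask (homopolymeric and GC-rich positions, see
#' [build_exclusion_mask]). Record names must be unique; sequences are
#' normalised to upper case and must contain only A, C, G, T.
#'
#' @param path path to a FASTA file.
#' @param policy an [exclusion_policy].
#' @return an `amplicon_panel`: a named list of `amplicon_reference` objects
#'   (fields `name`, `seq`, `excluded_mask`).
#' @export
read_reference_panel <- function(path, policy = exclusion_policy()) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm))
    stop(sprintf("duplicate reference name '%s' in '%s'",
                 nm[duplicated(nm)][1], path))
  sq <- toupper(as.character(seqs))
  .check_alphabet(sq, c("A", "C", "G", "T"), "reference sequence")
  refs <- lapply(seq_along(sq), function(i)
    amplicon_reference(nm[i], sq[i], policy))
  as_amplicon_panel(refs)
}

#' Write an amplicon panel to FASTA
#'
#' @param panel an `amplicon_panel` (or named character vector of sequences).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_panel <- function(panel, path) {
  if (inherits(panel, "amplicon_panel"))
    panel <- vapply(panel, `[[`, character(1), "seq")
  x <- Biostrings::DNAStringSet(panel)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write report tables for an error profile
#'
#' Externalises an estimated [error_profile] as deterministic TSV tables --
#' a run summary (`run_rates.tsv`), per-amplicon rates (`amplicon_rates.tsv`)
#' and the base-specific substitution matrix (`subst_matrix.tsv`) -- plus a
#' machine-readable JSON twin (`report.json`). Percentages and per-read
#' counts are printed rounded half-up to two decimals; the JSON twin also
#' carries the raw counts and unrounded rates.
#'
#' @param profile an [error_profile].
#' @param dir output directory (created if missing).
#' @return character vector of the files written, invisibly.
#' @export
write_report <- function(profile, dir) {
  stopifnot(inherits(profile, "error_profile"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rt <- rates(profile)
  fmt <- function(x) sprintf("%.2f", round_half_up(x, 2))
  disp <- data.frame(
    amplicon = rt$amplicon,
    aligned_reads = rt$aligned_reads,
    aligned_bases = rt$aligned_bases,
    subst = rt$subst_bases,
    subst_per_read = fmt(rt$subs_per_read),
    subst_pct = fmt(rt$subst_pct),
    indels = rt$indel_bases,
    indels_per_read = fmt(rt$indels_per_read),
    indel_pct = fmt(rt$indel_pct),
    stringsAsFactors = FALSE)
  f_run <- file.path(dir, "run_rates.tsv")
  f_amp <- file.path(dir, "amplicon_rates.tsv")
  f_mat <- file.path(dir, "subst_matrix.tsv")
  f_json <- file.path(dir, "report.json")
  write.table(disp[disp$amplicon == "run", , drop = FALSE], f_run,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(disp[disp$amplicon != "run", , drop = FALSE], f_amp,
              sep = "\t", quote = FALSE, row.names = FALSE)
  sm <- substitution_matrix(profile)
  mdisp <- matrix(fmt(sm$matrix), 4, 4, dimnames = dimnames(sm$matrix))
  diag(mdisp) <- ""
  mtab <- data.frame(correct_base = rownames(mdisp), mdisp,
                     Total = fmt(sm$total), stringsAsFactors = FALSE)
  write.table(mtab, f_mat, sep = "\t", quote = FALSE, row.names = FALSE)
  json <- list(
    run = as.list(rt[rt$amplicon == "run", ]),
    amplicons = rt[rt$amplicon != "run", ],
    substitution_matrix = list(
      percent = sm$matrix, total = sm$total,
      counts = sm$counts, per_base_totals = sm$per_base_totals),
    transitions = classify_transitions(sm$matrix),
    stage_counts = as.list(profile$stage_counts))
  jsonlite::write_json(json, f_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(c(f_run, f_amp, f_mat, f_json))
}
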