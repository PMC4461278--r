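# Pipeline orchestration: demultiplex -> mask/filter -> align -> profile.

#' Estimate an error profile from reads
#'
#' The package's central estimator: runs the in-memory pipeline --
#' demultiplex and trim (when a construct spec and barcode set are given),
#' mask low-quality bases, filter reads, align against the panel, tally
#' alignment columns -- and returns the fitted [error_profile]. Reads are
#' demultiplexed before masking (barcode recognition needs intact bases).
#' Unassigned reads are dropped after demultiplexing; reads whose 5'
#' adapter is not recognised are passed to alignment untrimmed.
#'
#' @param reads a [read_set].
#' @param panel an `amplicon_panel`.
#' @param spec optional [construct_spec]; when supplied together with
#'   `barcodes`, reads are demultiplexed and trimmed first (raw insert
#'   reads can be profiled by omitting both).
#' @param barcodes optional [barcode_set].
#' @param filter a [filter_policy].
#' @param scheme a [scoring_scheme].
#' @param min_score_fraction alignment acceptance threshold (see
#'   [batch_align]).
#' @return an [error_profile] with per-amplicon strata, a `stage_counts`
#'   element (reads_in, assigned, unassigned, trimmed, kept, dropped,
#'   aligned, unaligned) and the alignment set as attribute `alignments`.
#' @examples
#' panel <- amplicon_panel()
#' spec <- construct_preset("miseq")
#' bcs <- barcode_preset("miseq")
#' sim <- simulate_run(panel, spec, bcs, preset_error_model("miseq"),
#'                     n_reads = 50, seed = 1)
#' fit <- profile_errors(sim$reads, panel, spec, bcs)
#' print(fit)
#' @export
profile_errors <- function(reads, panel, spec = NULL, barcodes = NULL,
                           filter = filter_policy(),
                           scheme = scoring_scheme(),
                           min_score_fraction = 0.30) {
  stopifnot(inherits(reads, "read_set"), inherits(panel, "amplicon_panel"))
  counts <- c(reads_in = nrow(reads))
  if (!is.null(spec) || !is.null(barcodes)) {
    if (is.null(spec) || is.null(barcodes))
      stop("demultiplexing needs both a construct spec and a barcode set")
    reads <- demultiplex(reads, barcodes, spec)
    assigned <- !is.na(reads$sample_id)
    counts <- c(counts, assigned = sum(assigned),
                unassigned = sum(!assigned))
    reads <- reads[assigned, , drop = FALSE]
    class(reads) <- c("read_set", "data.frame")
    reads <- trim_construct(reads, spec)
    counts <- c(counts, trimmed = sum(reads$trimmed))
  } else {
    counts <- c(counts, assigned = nrow(reads), unassigned = 0L,
                trimmed = 0L)
  }
  reads <- mask_low_quality(reads, filter)
  kept <- filter_reads(reads, filter)
  counts <- c(counts, kept = nrow(kept),
              dropped = nrow(reads) - nrow(kept))
  aln <- batch_align(kept, panel, scheme, min_score_fraction)
  counts <- c(counts, aligned = sum(aln$aligned),
              unaligned = sum(!aln$aligned))
  ok <- aln[aln$aligned, , drop = FALSE]
  tal <- .tally_cpp(ok$ops, match(ok$ref_name, names(panel)), ok$ref_start,
                    ok$read_start, ok$oriented_bases,
                    vapply(panel, `[[`, character(1), "seq"),
                    lapply(panel, `[[`, "excluded_mask"))
  prof <- error_profile(names(panel))
  prof$per_amplicon$aligned_reads <- tal$aligned_reads
  prof$per_amplicon$aligned_bases <- tal$aligned_bases
  prof$per_amplicon$subst_bases <- tal$subst_bases
  prof$per_amplicon$ins_bases <- tal$ins_bases
  prof$per_amplicon$del_bases <- tal$del_bases
  strand_tab <- table(factor(ok$ref_name, levels = names(panel)),
                      factor(ok$strand, levels = c("+", "-")))
  prof$per_amplicon$fwd_reads <- as.integer(strand_tab[, "+"])
  prof$per_amplicon$rev_reads <- as.integer(strand_tab[, "-"])
  dimnames(tal$subst_matrix_counts) <- list(.BASES, .BASES)
  prof$subst_matrix_counts <- tal$subst_matrix_counts
  prof$per_base_totals <- structure(tal$per_base_totals, names = .BASES)
  prof$stage_counts <- counts
  attr(prof, "alignments") <- aln
  attr(prof, "alignment_rate") <- attr(aln, "alignment_rate")
  prof
}

#' Pipeline configuration
#'
#' File-level configuration for [run_pipeline]. `reads`, `refs` and
#' `outdir` are required; `barcodes`/`construct` enable demultiplexing and
#' trimming. Can also be loaded from a YAML or JSON file via
#' [read_pipeline_config].
#'
#' @param reads path to a FASTQ file.
#' @param refs path to the reference panel FASTA.
#' @param outdir output directory for reports and the run log.
#' @param barcodes optional path to a barcode sheet
#'   (TSV: `sample_id<TAB>barcode`, no header) or a [barcode_set].
#' @param construct optional platform preset name (`"flx454"`, `"pgm"`,
#'   `"miseq"`), path to a JSON/YAML construct description, or a
#'   [construct_spec].
#' @param filter a [filter_policy].
#' @param scheme a [scoring_scheme].
#' @param exclusion an [exclusion_policy].
#' @param min_score_fraction alignment acceptance threshold.
#' @param seed seed used for subsampling.
#' @param subsample_n optional cap on the number of reads entering the
#'   pipeline (uniform subsample drawn with `seed`).
#' @param max_mismatch barcode mismatch tolerance when `barcodes` is a path.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(reads, refs, outdir, barcodes = NULL,
                            construct = NULL, filter = filter_policy(),
                            scheme = scoring_scheme(),
                            exclusion = exclusion_policy(),
                            min_score_fraction = 0.30, seed = 1,
                            subsample_n = NULL, max_mismatch = 1) {
  for (p in c(reads, refs)) if (!file.exists(p))
    stop(sprintf("input file '%s' does not exist", p))
  if (is.character(barcodes) && !file.exists(barcodes))
    stop(sprintf("barcode sheet '%s' does not exist", barcodes))
  structure(list(reads = reads, refs = refs, outdir = outdir,
                 barcodes = barcodes, construct = construct, filter = filter,
                 scheme = scheme, exclusion = exclusion,
                 min_score_fraction = min_score_fraction,
                 seed = as.integer(seed), subsample_n = subsample_n,
                 max_mismatch = max_mismatch),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Scalar fields mirror the [pipeline_config] arguments; policy blocks
#' (`filter`, `scheme`, `exclusion`) are given as named sub-maps of the
#' respective constructor arguments.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [pipeline_config].
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  need <- setdiff(c("reads", "refs", "outdir"), names(cfg))
  if (length(need))
    stop(sprintf("config '%s' is missing required fields: %s", path,
                 paste(need, collapse = ", ")))
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p) || grepl("^/", p)) p else file.path(base, p)
  pipeline_config(
    reads = rel(cfg$reads), refs = rel(cfg$refs), outdir = rel(cfg$outdir),
    barcodes = rel(cfg$barcodes), construct = cfg$construct,
    filter = do.call(filter_policy, as.list(cfg$filter %||% list())),
    scheme = do.call(scoring_scheme, as.list(cfg$scheme %||% list())),
    exclusion = do.call(exclusion_policy, as.list(cfg$exclusion %||% list())),
    min_score_fraction = cfg$min_score_fraction %||% 0.30,
    seed = cfg$seed %||% 1, subsample_n = cfg$subsample_n,
    max_mismatch = cfg$max_mismatch %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a barcode sheet
#'
#' @param path TSV file with two columns, `sample_id` and `barcode`
#'   (no header).
#' @param max_mismatch tolerated Hamming distance.
#' @return a [barcode_set].
#' @export
read_barcode_sheet <- function(path, max_mismatch = 1) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 2)
    stop(sprintf("barcode sheet '%s' must have two columns", path))
  barcode_set(structure(tab[[2]], names = tab[[1]]),
              max_mismatch = max_mismatch)
}

.resolve_construct <- function(construct) {
  if (is.null(construct) || inherits(construct, "construct_spec"))
    return(construct)
  if (is.character(construct) && construct %in% c("flx454", "pgm", "miseq"))
    return(construct_preset(construct))
  if (is.character(construct) && file.exists(construct)) {
    cfg <- if (grepl("\\.ya?ml$", construct, ignore.case = TRUE))
      yaml::read_yaml(construct)
    else jsonlite::read_json(construct, simplifyVector = TRUE)
    return(do.call(construct_spec, cfg))
  }
  stop("construct must be a preset name, a spec file, or a construct_spec")
}

#' Run the full pipeline on files
#'
#' Orchestrates the whole analysis deterministically: read FASTQ, optional
#' seeded subsampling, demultiplex/trim (when configured), mask, filter,
#' align, tally, and write the report bundle (see [write_report]) plus a
#' machine-parseable `run.log` of stage counts to `outdir`. Rerunning the
#' same configuration on the same inputs reproduces the outputs byte for
#' byte.
#'
#' @param config a [pipeline_config] or path to a YAML/JSON config file.
#' @return the fitted [error_profile], invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  panel <- read_reference_panel(config$refs, config$exclusion)
  reads <- read_fastq(config$reads)
  n_total <- nrow(reads)
  if (!is.null(config$subsample_n) && nrow(reads) > config$subsample_n) {
    set.seed(config$seed)
    keep <- sort(sample.int(nrow(reads), config$subsample_n))
    reads <- reads[keep, , drop = FALSE]
    class(reads) <- c("read_set", "data.frame")
  }
  barcodes <- config$barcodes
  if (is.character(barcodes))
    barcodes <- read_barcode_sheet(barcodes, config$max_mismatch)
  spec <- .resolve_construct(config$construct)
  prof <- profile_errors(reads, panel, spec, barcodes,
                         filter = config$filter, scheme = config$scheme,
                         min_score_fraction = config$min_score_fraction)
  prof$stage_counts <- c(reads_total = n_total, prof$stage_counts)
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
  write_report(prof, config$outdir)
  log_lines <- sprintf("%s\t%d", names(prof$stage_counts),
                       as.integer(prof$stage_counts))
  writeLines(log_lines, file.path(config$outdir, "run.log"))
  message(paste(log_lines, collapse = "\n"))
  invisible(prof)
}
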