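# Read simulator: emits FASTQ-style reads of two-step PCR constructs with
# platform-style error profiles and a full ground-truth event log, so the
# pipeline's statistics can be validated by parameter recovery.

#' Platform error model for the read simulator
#'
#' Errors are injected per template base as independent Bernoulli draws
#' (which keeps the binomial recovery arithmetic exact): a substitution with
#' probability `subst_rate` (replacement base drawn from `subst_bias`), and
#' an indel with probability `indel_rate` scaled by
#' `homopolymer_indel_factor^(run_length - 1)` inside homopolymer runs. An
#' indel event is a single-base insertion (after the template base) with
#' probability `indel_ins_prob`, otherwise a single-base deletion.
#'
#' @param subst_rate per-base substitution probability.
#' @param indel_rate per-base indel probability (outside homopolymers).
#' @param subst_bias optional 4x4 matrix (rows/cols A,C,G,T): row `b` gives
#'   the conditional distribution of the emitted base given a substitution
#'   at a `b` template base (zero diagonal, rows sum to 1). `NULL` = uniform
#'   over the three alternatives.
#' @param homopolymer_indel_factor multiplicative indel-rate inflation per
#'   unit of homopolymer run length above 1 (1 = no homopolymer effect).
#' @param length_model list: `list(type = "full")` emits the whole
#'   construct; `list(type = "fixed", value = L)` truncates to `L` bases;
#'   `list(type = "truncated", tail_prob =, tail_mean =)` truncates a
#'   fraction `tail_prob` of reads by a geometric tail with mean
#'   `tail_mean`.
#' @param quality_model list: `list(type = "flat", q =)`,
#'   `list(type = "declining", q_start =, slope =)` (per base), or
#'   `list(type = "noisy", q_mean =, sd =)`. Qualities are clamped to
#'   `[2, 60]`; they are cosmetic unless deliberately degraded to exercise
#'   the quality filter.
#' @param indel_ins_prob probability that an indel event is an insertion
#'   (default 0.5).
#' @return an object of class `platform_error_model`.
#' @export
platform_error_model <- function(subst_rate = 0, indel_rate = 0,
                                 subst_bias = NULL,
                                 homopolymer_indel_factor = 1,
                                 length_model = list(type = "full"),
                                 quality_model = list(type = "flat", q = 38),
                                 indel_ins_prob = 0.5) {
  stopifnot(subst_rate >= 0, subst_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            homopolymer_indel_factor > 0,
            indel_ins_prob >= 0, indel_ins_prob <= 1)
  if (!is.null(subst_bias)) {
    stopifnot(is.matrix(subst_bias), all(dim(subst_bias) == c(4, 4)))
    dimnames(subst_bias) <- list(.BASES, .BASES)
    if (any(abs(diag(subst_bias)) > 1e-12))
      stop("subst_bias must have a zero diagonal")
    if (any(abs(rowSums(subst_bias) - 1) > 1e-8))
      stop("subst_bias rows must sum to 1")
  }
  stopifnot(length_model$type %in% c("full", "fixed", "truncated"),
            quality_model$type %in% c("flat", "declining", "noisy"))
  structure(list(subst_rate = subst_rate, indel_rate = indel_rate,
                 subst_bias = subst_bias,
                 homopolymer_indel_factor = homopolymer_indel_factor,
                 length_model = length_model, quality_model = quality_model,
                 indel_ins_prob = indel_ins_prob),
            class = "platform_error_model")
}

#' Packaged platform error-model presets
#'
#' Error models matching the three platforms' published headline behaviour:
#' `"flx454"` (substitutions 0.07%, indels 0.18%, homopolymer-inflated
#' indels, slowly declining quality, full-length reads), `"pgm"`
#' (substitutions 0.13%, indels 0.60%, homopolymer-inflated indels, noisy
#' moderate quality, a short-read tail) and `"miseq"` (substitutions 1.53%,
#' indels 0.04%, flat Q38 quality, fixed 250-base reads, substitution bias
#' following the platform's transversion-heavy base-specific pattern).
#' Indels on the two flow-chemistry platforms are deletion-dominant
#' (`indel_ins_prob` 0.25), the undercall mode of homopolymer miscalls.
#'
#' @param platform one of `"flx454"`, `"pgm"`, `"miseq"`.
#' @return a [platform_error_model].
#' @examples
#' preset_error_model("miseq")$subst_rate
#' @export
preset_error_model <- function(platform = c("flx454", "pgm", "miseq")) {
  platform <- match.arg(platform)
  bias <- function(rows) {
    m <- do.call(rbind, rows)
    dimnames(m) <- list(.BASES, .BASES)
    m / rowSums(m)
  }
  switch(platform,
    flx454 = platform_error_model(
      subst_rate = 0.0007, indel_rate = 0.0018,
      # transition-only bias: base-specific errors on this platform are
      # dominated by transitions
      subst_bias = bias(list(c(0, 0, 1, 0), c(0, 0, 0, 1),
                             c(1, 0, 0, 0), c(0, 1, 0, 0))),
      homopolymer_indel_factor = 2, indel_ins_prob = 0.25,
      length_model = list(type = "full"),
      quality_model = list(type = "declining", q_start = 40, slope = -0.01)),
    pgm = platform_error_model(
      subst_rate = 0.0013, indel_rate = 0.0060,
      subst_bias = bias(list(c(0, 0, 2, 1), c(0, 0, 0, 1),
                             c(1, 0, 0, 0), c(0, 2, 1, 0))),
      homopolymer_indel_factor = 2, indel_ins_prob = 0.25,
      length_model = list(type = "truncated", tail_prob = 0.25, tail_mean = 80),
      quality_model = list(type = "noisy", q_mean = 33, sd = 1)),
    miseq = platform_error_model(
      subst_rate = 0.0153, indel_rate = 0.0004,
      # transversion-heavy base-specific pattern
      subst_bias = bias(list(c(0, 9, 5, 2), c(6, 0, 1, 2),
                             c(3, 2, 0, 5), c(3, 4, 10, 0))),
      homopolymer_indel_factor = 1,
      length_model = list(type = "fixed", value = 250),
      quality_model = list(type = "flat", q = 38)))
}

# quality string for one read
.sim_quals <- function(model, len) {
  qm <- model$quality_model
  q <- switch(qm$type,
    flat = rep.int(as.integer(qm$q), len),
    declining = as.integer(round(qm$q_start + qm$slope * (seq_len(len) - 1))),
    noisy = as.integer(round(rnorm(len, qm$q_mean, qm$sd))))
  q <- pmin(60L, pmax(2L, q))
  if (len == 0) "" else intToUtf8(q + 33L)
}

# read length for one emitted sequence
.sim_len <- function(model, full_len) {
  lm <- model$length_model
  switch(lm$type,
    full = full_len,
    fixed = min(lm$value, full_len),
    truncated = {
      if (runif(1) < lm$tail_prob)
        max(30L, full_len - rgeom(1, 1 / lm$tail_mean))
      else full_len
    })
}

#' Simulate a sequencing run with ground truth
#'
#' Emits `n_reads` reads of fully assembled two-step PCR constructs: each
#' read picks an amplicon (weights `amplicon_weights`, default uniform), a
#' sample barcode (uniform) and a strand (probability `strand_prob` of
#' forward), assembles the construct, injects substitution and indel errors
#' per the error model, truncates per the length model and attaches
#' qualities per the quality model. Every injected event is logged with its
#' template and emitted-read position, so runs are fully replayable (see
#' [replay_truth]) and recovery can be audited against the log. Fully
#' reproducible given `seed`.
#'
#' @param panel an `amplicon_panel` (see [amplicon_panel]).
#' @param spec a [construct_spec].
#' @param barcodes a [barcode_set].
#' @param model a [platform_error_model].
#' @param n_reads number of reads (> 0).
#' @param seed integer seed; recorded in the truth log.
#' @param amplicon_weights optional per-amplicon sampling weights.
#' @param strand_prob probability of a forward-strand read (default 0.5).
#' @param fastq optional path: write the reads as FASTQ.
#' @return a list of class `sim_run`: `reads` (a [read_set], unassigned and
#'   orientation-unknown, as a sequencer would emit them) and `truth`, a
#'   list with `reads` (read_id, amplicon, sample_id, strand, template_len,
#'   read_len), `events` (read_id, template_pos, emit_pos, type, ref_base,
#'   emitted_base) and `seed`.
#' @export
simulate_run <- function(panel, spec, barcodes, model, n_reads, seed,
                         amplicon_weights = NULL, strand_prob = 0.5,
                         fastq = NULL) {
  stopifnot(inherits(panel, "amplicon_panel"), inherits(spec, "construct_spec"),
            inherits(barcodes, "barcode_set"),
            inherits(model, "platform_error_model"), n_reads > 0)
  namp <- length(panel)
  if (is.null(amplicon_weights)) amplicon_weights <- rep(1, namp)
  stopifnot(length(amplicon_weights) == namp, all(amplicon_weights >= 0))
  min_tpl <- min(vapply(panel, function(r) nchar(r$seq), numeric(1))) +
    sum(construct_flanks(spec))
  if ((1 - model$indel_rate * (1 - model$indel_ins_prob)) * min_tpl < 1)
    stop("error rates imply an expected read length below 1 base")
  set.seed(as.integer(seed))

  # precompute one template per (amplicon, sample, strand) combination
  samples <- names(barcodes$entries)
  combos <- expand.grid(amp = seq_len(namp), smp = seq_along(samples),
                        str = c("+", "-"), stringsAsFactors = FALSE)
  tpl <- vector("list", nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    ref <- panel[[combos$amp[ci]]]
    insert <- if (combos$str[ci] == "-") revcomp(ref$seq) else ref$seq
    s <- assemble_construct(spec, barcodes$entries[[combos$smp[ci]]], insert)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    r <- rle(ch)
    run_len <- rep.int(r$lengths, r$lengths)
    p_ind <- pmin(0.5, model$indel_rate *
                    model$homopolymer_indel_factor^(run_len - 1))
    tpl[[ci]] <- list(str = s, ch = ch, L = length(ch), p_ind = p_ind)
  }
  key <- function(a, s, st) (st == "-") * namp * length(samples) +
    (s - 1) * namp + a
  combo_id <- key(combos$amp, combos$smp, combos$str)
  tpl <- tpl[order(combo_id)] # tpl[[key]] lookup

  # per-base substitution alternatives and their cumulative bias
  alt <- lapply(.BASES, function(b) setdiff(.BASES, b))
  names(alt) <- .BASES
  cumbias <- lapply(.BASES, function(b) {
    p <- if (is.null(model$subst_bias)) rep(1 / 3, 3)
         else model$subst_bias[b, alt[[b]]]
    cumsum(p / sum(p))
  })
  names(cumbias) <- .BASES

  amp_i <- sample.int(namp, n_reads, replace = TRUE, prob = amplicon_weights)
  smp_i <- sample.int(length(samples), n_reads, replace = TRUE)
  strand <- ifelse(runif(n_reads) < strand_prob, "+", "-")
  ids <- sprintf("sim%06d", seq_len(n_reads))

  bases <- character(n_reads)
  quals <- character(n_reads)
  read_len <- integer(n_reads)
  tpl_len <- integer(n_reads)
  ev <- vector("list", n_reads)
  no_err <- model$subst_rate == 0 && model$indel_rate == 0
  for (r in seq_len(n_reads)) {
    t <- tpl[[key(amp_i[r], smp_i[r], strand[r])]]
    L <- t$L
    tpl_len[r] <- L
    if (no_err) {
      sub_pos <- ins_pos <- del_pos <- integer(0)
    } else {
      ind_pos <- which(runif(L) < t$p_ind)
      is_ins <- runif(length(ind_pos)) < model$indel_ins_prob
      ins_pos <- ind_pos[is_ins]
      del_pos <- ind_pos[!is_ins]
      sub_pos <- which(runif(L) < model$subst_rate)
      sub_pos <- setdiff(sub_pos, del_pos) # a deleted base emits nothing
    }
    if (length(sub_pos) + length(ins_pos) + length(del_pos) == 0L) {
      emitted <- t$str
      len <- .sim_len(model, L)
      ev[[r]] <- NULL
    } else {
      parts <- t$ch
      sub_base <- character(length(sub_pos))
      if (length(sub_pos)) {
        for (k in seq_along(sub_pos)) {
          b <- t$ch[sub_pos[k]]
          sub_base[k] <- alt[[b]][findInterval(runif(1), cumbias[[b]]) + 1L]
        }
        parts[sub_pos] <- sub_base
      }
      ins_base <- if (length(ins_pos))
        .BASES[sample.int(4, length(ins_pos), replace = TRUE)] else character(0)
      if (length(ins_pos))
        parts[ins_pos] <- paste0(parts[ins_pos], ins_base)
      if (length(del_pos)) parts[del_pos] <- ""
      emitted <- paste(parts, collapse = "")
      len <- .sim_len(model, nchar(emitted))
      # emitted-read coordinates of each event
      ends <- cumsum(nchar(parts))
      starts <- ends - nchar(parts) + 1L
      ev[[r]] <- list(
        read_id = rep.int(ids[r],
                          length(sub_pos) + length(ins_pos) + length(del_pos)),
        template_pos = c(sub_pos, ins_pos, del_pos),
        emit_pos = c(starts[sub_pos], starts[ins_pos] + 1L,
                     ends[del_pos] + 1L),
        type = rep(c("sub", "ins", "del"),
                   c(length(sub_pos), length(ins_pos), length(del_pos))),
        ref_base = c(t$ch[sub_pos], rep("-", length(ins_pos)), t$ch[del_pos]),
        emitted_base = c(sub_base, ins_base, rep("-", length(del_pos))))
    }
    read_len[r] <- min(len, nchar(emitted))
    bases[r] <- substr(emitted, 1L, read_len[r])
    quals[r] <- .sim_quals(model, read_len[r])
  }
  ev <- ev[!vapply(ev, is.null, logical(1))]
  pull <- function(f, cast) cast(unlist(lapply(ev, `[[`, f), use.names = FALSE))
  events <- data.frame(
    read_id = pull("read_id", as.character),
    template_pos = pull("template_pos", as.integer),
    emit_pos = pull("emit_pos", as.integer),
    type = pull("type", as.character),
    ref_base = pull("ref_base", as.character),
    emitted_base = pull("emitted_base", as.character),
    stringsAsFactors = FALSE)
  reads <- read_set(ids, bases, quals)
  truth <- list(
    reads = data.frame(read_id = ids, amplicon = names(panel)[amp_i],
                       sample_id = samples[smp_i], strand = strand,
                       template_len = tpl_len, read_len = read_len,
                       stringsAsFactors = FALSE),
    events = events, seed = as.integer(seed))
  if (!is.null(fastq)) write_fastq(reads, fastq)
  structure(list(reads = reads, truth = truth), class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf("Simulated run: %d reads, %d injected events (seed %d)\n",
              nrow(x$reads), nrow(x$truth$events), x$truth$seed))
  invisible(x)
}

#' Replay a ground-truth log
#'
#' Rebuilds every emitted read from the truth log alone: the construct is
#' re-assembled from the logged amplicon/sample/strand, the logged events
#' are applied at their template positions, and the result is truncated to
#' the logged read length. Replaying must reproduce the simulator's output
#' byte for byte (log-fidelity invariant).
#'
#' @param truth the `truth` element of a [simulate_run] result.
#' @param panel,spec,barcodes the inputs the run was simulated from.
#' @return character vector of rebuilt read sequences, named by read id.
#' @export
replay_truth <- function(truth, panel, spec, barcodes) {
  evs <- split(truth$events, truth$events$read_id)
  out <- character(nrow(truth$reads))
  names(out) <- truth$reads$read_id
  for (r in seq_len(nrow(truth$reads))) {
    info <- truth$reads[r, ]
    ref <- panel[[info$amplicon]]
    insert <- if (info$strand == "-") revcomp(ref$seq) else ref$seq
    tplt <- assemble_construct(spec, barcodes$entries[[info$sample_id]], insert)
    parts <- strsplit(tplt, "", fixed = TRUE)[[1]]
    e <- evs[[info$read_id]]
    if (!is.null(e)) {
      sub <- e[e$type == "sub", ]
      ins <- e[e$type == "ins", ]
      del <- e[e$type == "del", ]
      parts[sub$template_pos] <- sub$emitted_base
      if (nrow(ins))
        parts[ins$template_pos] <- paste0(parts[ins$template_pos],
                                          ins$emitted_base)
      parts[del$template_pos] <- ""
    }
    out[r] <- substr(paste(parts, collapse = ""), 1L, info$read_len)
  }
  out
}
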