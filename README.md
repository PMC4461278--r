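# amperr — error profiling for amplicon deep sequencing

`amperr` estimates platform-specific sequencing error profiles from deep
amplicon sequencing runs. High-coverage amplicon sequencing makes even rare
base-calling errors visible, and each platform errs in its own way:
flow-chemistry instruments (pyrosequencing, semiconductor) miscall
homopolymer lengths and produce mostly insertion/deletion errors, while
reversible-terminator chemistry produces mostly substitutions with a
base-dependent, transversion-heavy pattern. Quantifying those profiles on
mutation-free target amplicons is the prerequisite for calling
low-frequency variants against them.

The package implements the full measurement pipeline for two-step PCR
amplicon libraries (reads laid out as
`adapter5 | barcode | linker_fwd | insert | rc(linker_rev) | rc(adapter3)`):

* **Quality handling** — every base with Phred quality < 20 is masked to
  `N`; reads with mean quality < 25 or more than 6 `N`s are removed
  (strict boundaries).
* **Demultiplexing and trimming** — barcode assignment within a Hamming
  tolerance whose unambiguity is enforced by the barcode-set validator;
  construct trimming down to the insert.
* **Alignment** — full local Smith–Waterman with affine gaps (match +2,
  mismatch −4, gap open −6, extend −1; a length-*k* gap costs
  `gap_open + k·gap_extend`) against every panel reference in both
  orientations, implemented in C++ and verified against an independent
  brute-force oracle.
* **Error statistics** — per-run and per-amplicon rates
  `subst% = 100·subst_bases/aligned_bases`,
  `indel% = 100·(ins+del bases)/aligned_bases`, plus per-read counts, and
  a base-specific substitution matrix
  `entry(ref→read) = 100·count(ref→read)/count(aligned ref columns)`
  tallied outside homopolymeric (run ≥ 4) and GC-rich (≥ 80% G+C per
  10-base window) reference regions, with transition/transversion
  summaries.
* **A read simulator** — platform-style error models (published headline
  rates, homopolymer-scaled indels, platform-like length and quality
  models) with a complete ground-truth event log, so every statistic is
  validated by parameter recovery.

The packaged five-amplicon reference panel is **synthetic**: it mirrors the
lengths (325–370 bp) and error-relevant composition of the exonic targets
the pipeline was designed around without reproducing their sequences.

## A worked example

Simulate a reversible-terminator-style run on the packaged panel and fit
its error profile:

```r
library(amperr)
panel <- amplicon_panel()
spec  <- construct_preset("miseq")
bcs   <- barcode_preset("miseq")
sim   <- simulate_run(panel, spec, bcs, preset_error_model("miseq"),
                      n_reads = 400, seed = 42)
fit   <- profile_errors(sim$reads, panel, spec, bcs)
print(fit)
```

```
Amplicon sequencing error profile
  aligned reads: 390   aligned bases: 72,858
  substitutions: 1,095 (1.50%, 2.81 subs/read)
  indels:        23 (0.03%, 0.06 indels/read)
```

The injected model carries a 1.53% per-base substitution rate and a 0.04%
indel rate; the fitted profile recovers 1.50% and 0.03% on this small run
(sampling noise at 7×10⁴ aligned bases, plus the ~1–2% relative
end-censoring bias inherent to local alignment — see the vignette). Ten of
400 reads lost their barcode to injected errors and stay unassigned.
`summary(fit)` adds the per-amplicon table and the substitution matrix:

```
Substitution matrix (% per non-excluded reference base):
  A    C    G    T    Total
A .    1.00 0.34 0.25 1.59
C 0.97 .    0.22 0.41 1.60
G 0.37 0.21 .    0.86 1.44
T 0.23 0.37 0.94 .    1.54

Mean transition rate: 0.37%  mean transversion rate: 0.59%
```

which reproduces the transversion-heavy bias the preset injects.

For file-based runs, `run_pipeline(pipeline_config(reads = "reads.fastq",
refs = "panel.fasta", outdir = "out", barcodes = "bc.tsv",
construct = "miseq"))` writes `run_rates.tsv`, `amplicon_rates.tsv`,
`subst_matrix.tsv`, `report.json` and a stage-count `run.log` (percentages
rounded half-up to two decimals). A command-line wrapper with `profile`,
`simulate` and `demux` subcommands ships in `inst/cli/amperr.R`.

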