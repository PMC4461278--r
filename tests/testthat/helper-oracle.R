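# Independent brute-force oracle for local affine-gap alignment scores:
# memoized recursion over (read prefix, ref prefix, state), written and
# maintained separately from the package's dynamic-programming kernel.
# Conventions match the package contract: local alignment, a gap of length
# k costs gap_open + k * gap_extend, N mismatches everything.
sw_oracle_score <- function(read, ref, match = 2, mismatch = -4,
                            gap_open = -6, gap_extend = -1) {
  rd <- strsplit(read, "", fixed = TRUE)[[1]]
  rf <- strsplit(ref, "", fixed = TRUE)[[1]]
  n <- length(rd); m <- length(rf)
  NEG <- -1e9
  UNSET <- NA_real_
  memo <- array(UNSET, dim = c(n + 1, m + 1, 3)) # states: 1=H, 2=E(ins), 3=F(del)
  s <- function(a, b) if (a == b && a != "N" && b != "N") match else mismatch
  solve <- function(i, j, st) {
    v <- memo[i + 1, j + 1, st]
    if (!is.na(v)) return(v)
    v <- if (st == 1) {
      if (i == 0 || j == 0) 0
      else max(0,
               solve(i - 1, j - 1, 1) + s(rd[i], rf[j]),
               solve(i, j, 2),
               solve(i, j, 3))
    } else if (st == 2) {
      if (i == 0) NEG
      else max(solve(i - 1, j, 1) + gap_open + gap_extend,
               solve(i - 1, j, 2) + gap_extend)
    } else {
      if (j == 0) NEG
      else max(solve(i, j - 1, 1) + gap_open + gap_extend,
               solve(i, j - 1, 3) + gap_extend)
    }
    memo[i + 1, j + 1, st] <<- v
    v
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m))
    best <- max(best, solve(i, j, 1))
  best
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
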