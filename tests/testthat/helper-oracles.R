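# Independent oracles used by the property tests.  Each is deliberately
# brute-force and shares no code with the implementation it checks.

# Optimal global alignment score by exhaustive enumeration of every monotone
# alignment path (no dynamic-programming table).
brute_force_align_score <- function(a, b, match = 1, mismatch = -1,
                                    gap = -2) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  rec <- function(i, j) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1))
    }
    if (i <= length(av)) best <- max(best, gap + rec(i + 1, j))
    if (j <= length(bv)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# Exact two-sided binomial p by direct tail enumeration: sum the point
# probabilities of every outcome no more likely than the observed one.
enumerate_binom_p <- function(k, n, p = 0.5) {
  d <- dbinom(0:n, n, p)
  sum(d[d <= d[k + 1] * (1 + 1e-9)])
}

# Per-position scan of two equal-length sequences for differing bases,
# reported in signed coordinates of the first sequence.
scan_fixed_differences <- function(a, b, utr5_len = 0) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(av) == length(bv))
  idx <- which(av != bv)
  signed <- ifelse(idx > utr5_len, idx - utr5_len, idx - utr5_len - 1)
  data.frame(position = as.integer(signed), nile_allele = av[idx],
             blue_allele = bv[idx], stringsAsFactors = FALSE)
}

# Random DNA string helper for property tests.
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Truth-table oracle for the cis/trans category of one (A, B, eps) triple.
cistrans_category_oracle <- function(A, B, eps) {
  tr <- A - B
  if (abs(B) <= eps && abs(tr) <= eps) return("conserved")
  if (abs(tr) <= eps) return("cis_only")
  if (abs(B) <= eps) return("trans_only")
  if ((B > 0 && tr > 0) || (B < 0 && tr < 0)) return("enhancing")
  "compensating"
}
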