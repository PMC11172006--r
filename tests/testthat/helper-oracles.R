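# Independent brute-force oracles shared across test files. Each is coded
# from the definition, not from the implementation it checks.

# O(n^2) pairwise concordance with ties counted 1/2.
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Closed-form 2x2 Pearson chi-squared: N (ad - bc)^2 / product of margins.
chi2_closed_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Exhaustive fragility search: flip every subset of examples in the level,
# smallest subset first, until the test crosses alpha.
fragility_brute <- function(correct, group, level, alpha) {
  idx <- which(group == level)
  n <- length(idx)
  for (m in seq_len(n)) {
    combos <- utils::combn(idx, m, simplify = FALSE)
    for (cc in combos) {
      mod <- correct
      mod[cc] <- !mod[cc]
      p <- suppressWarnings(chi_squared_independence(mod, group)$p_value)
      if (p > alpha) return(m)
    }
  }
  NA_integer_
}
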