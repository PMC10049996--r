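# Independent oracles used across the suite. These deliberately avoid the
# package's own computation paths.

# Brute-force linear predictor: walk the coefficient table row by row and
# add each beta whose (factor, level) pair matches the profile.
oracle_logit <- function(profile, coeffs) {
  total <- coeffs$alpha
  for (i in seq_len(nrow(coeffs$betas))) {
    f <- coeffs$betas$factor_id[i]
    l <- coeffs$betas$level[i]
    if (!is.na(profile[f]) && profile[f] == l) {
      total <- total + coeffs$betas$beta[i]
    }
  }
  total
}

# Mann-Whitney concordance: over all case/control pairs, the fraction in
# which the case outscores the control, ties counted one half.
oracle_concordance <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# One random valid profile for a coefficient set.
random_profile <- function(coeffs) {
  levels <- split(coeffs$betas$level, coeffs$betas$factor_id)
  vapply(levels, function(lv) sample(lv, 1L), "")
}
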