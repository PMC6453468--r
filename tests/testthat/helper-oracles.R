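# Independent oracles used across the suite. Each is deliberately a
# different route than the package implementation it checks.

# HWE exact test via the heterozygote recurrence (the package enumerates
# log-probabilities directly)
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  rare <- min(nA, na)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  probs <- numeric(length(hets))
  probs[length(hets)] <- 1
  for (i in rev(seq_along(hets))[-1]) {
    h <- hets[i]                      # lower het count
    probs[i] <- probs[i + 1] * (h + 1) * (h + 2) /
      (4 * ((nA - h) / 2) * ((na - h) / 2))
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n_Aa, hets)]
  min(1, sum(probs[probs <= obs * (1 + 1e-9)]))
}

# Benjamini-Hochberg step-up by its textbook definition
bh_oracle <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- prev
  }
  q
}

# brute-force interval merge: expand and merge until fixpoint
merge_oracle <- function(pos, flank = 1e5) {
  iv <- cbind(start = pmax(1, pos - flank), end = pos + flank)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  repeat {
    merged <- FALSE
    i <- 1
    while (i < nrow(iv)) {
      if (iv[i + 1, 1] <= iv[i, 2]) {           # shared >= 1 bp
        iv[i, 2] <- max(iv[i, 2], iv[i + 1, 2])
        iv <- iv[-(i + 1), , drop = FALSE]
        merged <- TRUE
      } else i <- i + 1
    }
    if (!merged) break
  }
  iv
}

# full multiple-regression fit for one gene-variant pair (FWL oracle)
lm_oracle <- function(y, g, X) {
  fit <- summary(lm(y ~ g + X))$coefficients
  list(beta = fit["g", 1], t = fit["g", 3], p = fit["g", 4])
}
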