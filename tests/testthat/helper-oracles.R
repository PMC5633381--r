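# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Bisection solve of r = m (log m + 1.24) on the increasing branch
# m > exp(-1.24); 200 halvings give ~1e-12 relative precision.
bisectLeaCoulson <- function(r, iter = 200L) {
  f <- function(m) m * (log(m) + 1.24) - r
  lo <- exp(-1.24)
  hi <- max(2, r)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Two-sided Fisher p by full hypergeometric enumeration over all tables
# with the observed margins (point-probability ordering).
enumFisherP <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  pObs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Exact two-sided rank-sum p by enumeration of all group assignments.
enumRankSumP <- function(a, b) {
  pooled <- c(a, b)
  ranks <- rank(pooled)
  na <- length(a)
  combs <- utils::combn(length(pooled), na)
  sums <- apply(combs, 2, function(i) sum(ranks[i]))
  obs <- sum(ranks[seq_len(na)])
  mu <- na * (length(pooled) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# growth-call pattern helper: pattern like "+--+" for (foa, trp, hyg, nat)
callPattern <- function(pat) {
  v <- ifelse(strsplit(pat, "")[[1]] == "+", "yes", "no")
  colonyPhenotype(foa = v[1], trp = v[2], hyg = v[3], nat = v[4])
}
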