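# Independent oracles used to cross-check the package implementations.
# These are deliberately naive re-statements of the algorithms; the package
# code is never called from here.

# Naive PCIT: literal triple loop over trios, mean of signed partial/raw
# ratios, non-strict discard rule.
pcit_oracle <- function(r) {
  n <- nrow(r)
  sig <- matrix(TRUE, n, n)
  diag(sig) <- FALSE
  pc <- function(a, b, c) (a - b * c) / sqrt((1 - b^2) * (1 - c^2))
  for (x in 1:(n - 2)) for (y in (x + 1):(n - 1)) for (z in (y + 1):n) {
    rxy <- r[x, y]; rxz <- r[x, z]; ryz <- r[y, z]
    ratios <- c(
      if (rxy != 0) pc(rxy, rxz, ryz) / rxy,
      if (rxz != 0) pc(rxz, rxy, ryz) / rxz,
      if (ryz != 0) pc(ryz, rxy, rxz) / ryz
    )
    if (!length(ratios)) next
    eps <- mean(ratios)
    if (abs(rxy) <= abs(eps * rxz) && abs(rxy) <= abs(eps * ryz)) {
      sig[x, y] <- sig[y, x] <- FALSE
    }
    if (abs(rxz) <= abs(eps * rxy) && abs(rxz) <= abs(eps * ryz)) {
      sig[x, z] <- sig[z, x] <- FALSE
    }
    if (abs(ryz) <= abs(eps * rxy) && abs(ryz) <= abs(eps * rxz)) {
      sig[y, z] <- sig[z, y] <- FALSE
    }
  }
  sig
}

# Weir & Cockerham (1984) theta for two populations from per-SNP allele
# frequencies, heterozygote proportions and sample sizes (ratio of sums).
wc_fst <- function(p1, p2, h1, h2, n1, n2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  sum(a) / sum(a + b + cc)
}

# Exhaustive trio-coverage oracle on an igraph graph: enumerate all FE
# trios, score closed-neighbourhood node coverage directly with ego().
trio_oracle <- function(g, fe) {
  ids <- igraph::V(g)$name
  best <- -1; best_trio <- NULL
  for (tr in utils::combn(sort(fe), 3, simplify = FALSE)) {
    cov <- unique(unlist(lapply(tr, function(v)
      c(v, igraph::neighbors(g, v)$name))))
    if (length(cov) > best) { best <- length(cov); best_trio <- tr }
  }
  list(trio = best_trio, coverage = best / length(ids))
}

# Exhaustive permutation-percentile oracle: full enumeration of all
# size-k subsets of the background.
exhaustive_percentile <- function(taur, set_idx) {
  k <- length(set_idx)
  obs <- sum(taur[set_idx])
  counts <- utils::combn(length(taur), k, function(ix) sum(taur[ix]))
  100 * sum(counts < obs) / length(counts)
}
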