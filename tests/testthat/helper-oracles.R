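# Independent oracle implementations used to cross-check the package's
# estimators on toy inputs. Deliberately written in a direct, scalar style
# from the published formulas, separate from the package code paths.

# Weir & Cockerham (1984) theta for one biallelic site, r = 2 populations,
# diploid genotypes given as alt-allele dosages (NA = missing).
oracle_wc_fst_site <- function(ga, gb) {
  pops <- list(ga[!is.na(ga)], gb[!is.na(gb)])
  r <- 2
  n <- vapply(pops, length, 0)                   # individuals
  p <- vapply(pops, function(g) sum(g) / (2 * length(g)), 0)
  h <- vapply(pops, function(g) mean(g == 1), 0) # observed het freq
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, fst = a / (a + b + cc))
}

# Tajima (1989) D from a haplotype matrix (rows = haplotypes, 0/1 alleles).
oracle_tajima_d <- function(hap) {
  n <- nrow(hap)
  S <- 0
  pi_sum <- 0
  for (j in seq_len(ncol(hap))) {
    k <- sum(hap[, j])
    if (k > 0 && k < n) S <- S + 1
    # average pairwise difference at this site by explicit pair enumeration
    diffs <- 0
    for (u in seq_len(n - 1)) for (v in (u + 1):n)
      diffs <- diffs + (hap[u, j] != hap[v, j])
    pi_sum <- pi_sum + diffs / choose(n, 2)
  }
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Two-sided Fisher exact p for a 2x2 table by exhaustive hypergeometric
# tail summation.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) stats::dhyper(x, m, n2, k), 0)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up q-values written out directly.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}
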