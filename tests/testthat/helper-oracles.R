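# Independent oracles, written from first principles and kept separate from
# the package's code paths.

# Weir & Cockerham (1984) variance components for two populations at one
# biallelic site, scalar transliteration of the published formulas.
wc84_oracle <- function(dos_A, dos_B) {
  dos_A <- dos_A[!is.na(dos_A)]; dos_B <- dos_B[!is.na(dos_B)]
  r <- 2
  n <- c(length(dos_A), length(dos_B))
  p <- c(sum(dos_A) / (2 * n[1]), sum(dos_B) / (2 * n[2]))
  h <- c(mean(dos_A == 1), mean(dos_B == 1))
  nbar <- mean(n)
  CV2 <- sum((n - nbar)^2) / ((r) * nbar^2)  # unused; kept for clarity
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, abc = a + b + cc,
       fst = if ((a + b + cc) != 0) a / (a + b + cc) else NA_real_)
}

# Brute-force D_XY: average per-bp difference over every inter-species pair
# of haplotypes, haplotypes being the allele multisets implied by dosages.
dxy_bruteforce <- function(dos_A, dos_B, window_bp) {
  expand_alleles <- function(d) {
    unlist(lapply(d[!is.na(d)], function(x) c(rep(1, x), rep(0, 2 - x))))
  }
  total <- 0
  for (s in seq_len(nrow(dos_A))) {
    al_A <- expand_alleles(dos_A[s, ])
    al_B <- expand_alleles(dos_B[s, ])
    diffs <- outer(al_A, al_B, function(x, y) as.numeric(x != y))
    total <- total + mean(diffs)
  }
  total / window_bp
}

# Hudson F_ST (ratio of averages) from true per-species allele frequencies.
hudson_fst_truth <- function(p_A, p_B) {
  hw <- p_A * (1 - p_A) + p_B * (1 - p_B)
  hb <- p_A * (1 - p_B) + p_B * (1 - p_A)
  1 - mean(hw) / mean(hb)
}

# Textbook BH step-up q-values.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# All permutations of 1..n via lexicographic recursion (independent of the
# package's generator).
perms_oracle <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_oracle(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# Pearson chi-square from hand-computed expected counts.
chisq_oracle <- function(tab) {
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - expd)^2 / expd)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}
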