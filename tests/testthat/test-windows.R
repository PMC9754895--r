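# Per-site WC components, window statistics, rho, and correlations.

test_that("site components match an independent WC84 oracle", {
  cases <- list(
    list(A = c(0, 0), B = c(2, 2)),            # fixed difference
    list(A = c(0, 2), B = c(0, 2)),            # same split both species
    list(A = c(1, 1, 1), B = c(1, 1)),         # all hets
    list(A = c(0, 1, 2, 1), B = c(2, 2, 1)),   # unequal sizes
    list(A = c(0, 0, NA, 1), B = c(1, 2, NA))  # missing dropped per site
  )
  for (cs in cases) {
    got <- site_fst_components(cs$A, cs$B)
    want <- wc84_oracle(cs$A, cs$B)
    expect_equal(got$a, want$a, tolerance = 1e-12)
    expect_equal(got$abc, want$abc, tolerance = 1e-12)
  }
  # fixed difference gives ratio 1; all-het sites have non-positive a, kept
  expect_equal(site_fst_components(c(0, 0), c(2, 2))$fst, 1)
  expect_lte(site_fst_components(c(1, 1, 1), c(1, 1))$a, 0)
  expect_error(site_fst_components(c(0, NA), c(1, 1)), "non-missing")
})

test_that("one fixed difference in a 100-bp window gives dxy 0.01", {
  d <- rbind(c(0, 0, 2, 2))
  g <- toy_genotypes(d, n_A = 2, pos = 50L)
  w <- window_stats(g, window_bp = 100, step_bp = 100, min_snps = 1,
                    chrom_lengths = c(Chr01 = 100), rho = FALSE)
  expect_equal(w$dxy, 0.01)
  expect_equal(w$fst, 1)
  expect_equal(w$pi_A, 0)
  expect_equal(w$pi_B, 0)
})

test_that("monomorphic windows have zero diversity and divergence", {
  d <- rbind(rep(0, 6), rep(0, 6))
  g <- toy_genotypes(d, n_A = 3, pos = c(10L, 20L))
  w <- window_stats(g, window_bp = 100, step_bp = 100, min_snps = 1,
                    chrom_lengths = c(Chr01 = 100), rho = FALSE)
  expect_equal(w$pi_A, 0)
  expect_equal(w$pi_B, 0)
  expect_equal(w$dxy, 0)
  expect_true(is.na(w$fst))  # no variance components anywhere
})

test_that("window dxy equals brute-force inter-species pair averaging", {
  set.seed(8)
  for (rep in 1:5) {
    d <- matrix(sample(0:2, 5 * 9, replace = TRUE), nrow = 5)
    g <- toy_genotypes(d, n_A = 5, pos = c(11L, 25L, 40L, 61L, 90L))
    w <- window_stats(g, window_bp = 100, step_bp = 100, min_snps = 1,
                      chrom_lengths = c(Chr01 = 100), rho = FALSE)
    want <- dxy_bruteforce(d[, 1:5, drop = FALSE], d[, 6:9, drop = FALSE], 100)
    expect_equal(w$dxy, want, tolerance = 1e-12)
  }
})

test_that("dxy is invariant to sample order", {
  set.seed(21)
  d <- matrix(sample(0:2, 12 * 10, replace = TRUE), nrow = 12)
  g <- toy_genotypes(d, n_A = 6)
  w1 <- window_stats(g, 200, 200, min_snps = 1, rho = FALSE)
  perm <- c(sample(1:6), sample(7:10))
  g2 <- toy_genotypes(d[, perm], n_A = 6, pos = g$snps$pos)
  w2 <- window_stats(g2, 200, 200, min_snps = 1, rho = FALSE)
  expect_equal(w1$dxy, w2$dxy, tolerance = 1e-12)
})

test_that("windows below min_snps are emitted but flagged excluded", {
  d <- matrix(sample(0:2, 3 * 8, replace = TRUE), nrow = 3)
  g <- toy_genotypes(d, n_A = 4, pos = c(10L, 20L, 150L))
  w <- window_stats(g, window_bp = 100, step_bp = 100, min_snps = 3,
                    chrom_lengths = c(Chr01 = 200), rho = FALSE)
  expect_equal(nrow(w), 2)
  expect_equal(w$excluded, c(TRUE, TRUE))
  expect_equal(w$n_snps, c(2L, 1L))
  expect_error(window_stats(g, window_bp = 10, step_bp = 50), "positive")
})

test_that("window F_ST is 1 iff every polymorphic site is a fixed difference", {
  fixed <- rbind(c(0, 0, 2, 2), c(2, 2, 0, 0))
  g <- toy_genotypes(fixed, n_A = 2, pos = c(10L, 20L))
  w <- window_stats(g, 100, 100, min_snps = 1,
                    chrom_lengths = c(Chr01 = 100), rho = FALSE)
  expect_equal(w$fst, 1)
  mixed <- rbind(c(0, 0, 2, 2), c(0, 2, 0, 2))
  g2 <- toy_genotypes(mixed, n_A = 2, pos = c(10L, 20L))
  w2 <- window_stats(g2, 100, 100, min_snps = 1,
                     chrom_lengths = c(Chr01 = 100), rho = FALSE)
  expect_lt(w2$fst, 1)
})

test_that("rho inverts the corrected mean r-squared at the mean distance", {
  set.seed(4)
  n <- 30
  x <- rbinom(n, 2, 0.5)
  flip <- function(v, k) { i <- sample(n, k); v[i] <- 2 - v[i]; v }
  d <- rbind(x, flip(x, 4), flip(x, 7))
  pos <- c(100L, 600L, 1500L)
  g <- toy_genotypes(d, n_A = 15, pos = pos)
  got <- window_rho(g, "Chr01", 1, 2000)
  # oracle: plain formula on the same dosages
  r2 <- cor(t(d))^2
  r2bar <- mean(r2[lower.tri(r2)])
  dbar <- mean(dist(pos))
  r2c <- r2bar - 1 / (2 * n)
  want <- if (r2c >= 0.5) 0 else (1 / r2c - 2) / dbar
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("rho clamps to zero under near-perfect LD", {
  x <- c(rep(0, 10), rep(2, 10))
  d <- rbind(x, x, x)
  g <- toy_genotypes(d, n_A = 10, pos = c(100L, 500L, 900L))
  expect_equal(window_rho(g, "Chr01", 1, 1000), 0)
})

test_that("rho is missing with fewer than two common SNPs", {
  d <- rbind(c(rep(0, 19), 2), c(rep(0, 10), rep(2, 10)))
  g <- toy_genotypes(d, n_A = 10, pos = c(100L, 500L))
  # first site has MAF 0.05 < 0.1: only one qualifying SNP
  expect_true(is.na(window_rho(g, "Chr01", 1, 1000)))
})

test_that("islands have lower rho than background across seeds", {
  lower <- 0
  for (seed in 1:10) {
    cfg <- tiny_config(seed = seed)
    gen <- simulate_genotypes(cfg)
    w <- window_stats(gen$genotypes)
    isl <- w$chrom == "Chr01" & w$start >= 200001 & w$end <= 230000
    med_isl <- median(w$rho[isl & !w$excluded], na.rm = TRUE)
    med_bg <- median(w$rho[!isl & !w$excluded], na.rm = TRUE)
    lower <- lower + (med_isl < med_bg)
  }
  expect_gte(lower, 9)
})

test_that("stat correlations match a rank-then-Pearson oracle", {
  set.seed(12)
  w <- tibble::tibble(
    chrom = "Chr01", start = 1:10, end = 2:11, n_snps = 20L,
    fst = runif(10), dxy = runif(10), pi_all = runif(10),
    rho = runif(10), excluded = FALSE
  )
  w$dxy[3] <- w$dxy[4]  # tie: mid-ranked
  m <- stat_correlations(w)
  expect_equal(diag(m), setNames(rep(1, 4), colnames(m)))
  expect_equal(m, t(m))
  want <- cor(apply(as.matrix(w[, c("fst", "dxy", "pi_all", "rho")]), 2, rank))
  expect_equal(unname(m), unname(want), tolerance = 1e-12)
  # perfect monotone decrease
  w2 <- w
  w2$dxy <- -w2$fst
  expect_equal(stat_correlations(w2)["fst", "dxy"], -1)
})
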