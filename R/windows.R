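# Sliding-window landscapes: per-site Weir-Cockerham variance components,
# per-window pi / F_ST / D_XY / rho and the cross-window correlation matrix.

#' Per-site Weir-Cockerham (1984) variance components and frequencies
#'
#' For every biallelic site, computes the two-population Weir-Cockerham
#' variance components `a` (among populations) and `abc = a + b + c` (total)
#' from unphased diploid dosages, handling unequal sample sizes, observed
#' heterozygosity and per-site missingness. Sites where either species has
#' fewer than two non-missing diploids are flagged unusable (components `NA`);
#' sites monomorphic across both species get components `(0, 0)`. Negative
#' `a` values are retained, not clamped.
#'
#' @param g A [genotypes()] object (or an object with `dosage` + `samples`).
#' @return Tibble, one row per site: `snp_id, chrom, pos, n_A, n_B`
#'   (non-missing diploids), `p_A, p_B` (alternate-allele frequencies),
#'   `het_A, het_B` (observed heterozygote frequencies), `a, abc`,
#'   `fst_site = a/abc` (`NA` when `abc <= 0`), and `usable`.
#' @export
site_stats <- function(g) {
  sp <- species_index(g)
  d <- g$dosage
  dimnames(d) <- NULL
  dA <- d[, sp$A, drop = FALSE]
  dB <- d[, sp$B, drop = FALSE]
  nA <- rowSums(!is.na(dA))
  nB <- rowSums(!is.na(dB))
  pA <- rowSums(dA, na.rm = TRUE) / (2 * nA)
  pB <- rowSums(dB, na.rm = TRUE) / (2 * nB)
  hA <- rowSums(dA == 1L, na.rm = TRUE) / nA
  hB <- rowSums(dB == 1L, na.rm = TRUE) / nB
  comp <- wc_components(nA, pA, hA, nB, pB, hB)
  usable <- nA >= 2 & nB >= 2
  tibble::tibble(
    snp_id = g$snps$snp_id, chrom = g$snps$chrom, pos = g$snps$pos,
    n_A = nA, n_B = nB, p_A = pA, p_B = pB, het_A = hA, het_B = hB,
    a = ifelse(usable, comp$a, NA_real_),
    abc = ifelse(usable, comp$abc, NA_real_),
    fst_site = ifelse(usable & comp$abc > 0, comp$a / comp$abc, NA_real_),
    usable = usable
  )
}

# Weir & Cockerham 1984 components for r = 2 populations, vectorized over
# sites. n = diploid counts, p = allele frequencies, h = het frequencies.
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc, abc = a + b + cc)
}

#' Weir-Cockerham variance components for one site
#'
#' Convenience scalar wrapper around the vectorized machinery: takes the
#' dosage vectors of the two species at a single site and returns the WC84
#' components.
#'
#' @param dosages_A,dosages_B Integer dosages (0/1/2, `NA` missing).
#' @return List with `a`, `b`, `c`, `abc` and `fst = a/abc`.
#' @export
site_fst_components <- function(dosages_A, dosages_B) {
  nA <- sum(!is.na(dosages_A)); nB <- sum(!is.na(dosages_B))
  if (nA < 2 || nB < 2) abort("need >= 2 non-missing diploids per species")
  comp <- wc_components(nA, mean(dosages_A, na.rm = TRUE) / 2,
                        mean(dosages_A == 1L, na.rm = TRUE),
                        nB, mean(dosages_B, na.rm = TRUE) / 2,
                        mean(dosages_B == 1L, na.rm = TRUE))
  comp$fst <- if (comp$abc > 0) comp$a / comp$abc else NA_real_
  comp
}

# window grid: 1-based inclusive windows fully inside each chromosome
window_grid <- function(chrom_lengths, window_bp, step_bp) {
  purrr::imap_dfr(as.list(chrom_lengths), function(L, ch) {
    starts <- seq(1, L - window_bp + 1, by = step_bp)
    tibble::tibble(chrom = ch, start = starts, end = starts + window_bp - 1)
  })
}

#' Sliding-window population-genomic statistics
#'
#' Computes, per 1-based-inclusive window: SNP count, nucleotide diversity of
#' each species and pooled (`pi_* = sum_sites n/(n-1) * 2p(1-p) / window_bp`,
#' with `n` the non-missing allele count), the Weir-Cockerham weighted F_ST
#' (ratio of summed components `sum a / sum(a+b+c)`), D_XY
#' (`sum p_A(1-p_B) + p_B(1-p_A) / window_bp`, i.e. the mean per-bp pairwise
#' difference between inter-species sequences with monomorphic positions
#' counting zero), the moment-based population recombination rate rho per bp
#' (see [window_rho()]), and `rho_over_pi = rho / pi_all`. Windows with fewer
#' than `min_snps` usable SNPs are emitted but flagged `excluded`.
#'
#' @param g A [genotypes()] object.
#' @param window_bp,step_bp Window and step sizes in bp.
#' @param min_snps Minimum usable SNPs for a window to be analyzed.
#' @param chrom_lengths Optional named lengths; defaults to the last SNP
#'   position per chromosome rounded up to a full window.
#' @param rho Compute the rho column (set `FALSE` to skip the LD scan).
#' @return Tibble of per-window statistics; per-site components are attached
#'   as attribute `"sites"` for reuse by the island scan.
#' @export
window_stats <- function(g, window_bp = 20000, step_bp = 5000, min_snps = 10,
                         chrom_lengths = NULL, rho = TRUE) {
  if (window_bp <= 0 || step_bp <= 0 || window_bp < step_bp)
    abort("window_bp and step_bp must be positive with window_bp >= step_bp")
  st <- site_stats(g)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- st %>%
      dplyr::group_by(chrom) %>%
      dplyr::summarise(L = max(pos), .groups = "drop")
    chrom_lengths <- setNames(
      pmax(ceiling(chrom_lengths$L / window_bp) * window_bp, window_bp),
      chrom_lengths$chrom)
  }
  grid <- window_grid(chrom_lengths, window_bp, step_bp)

  # per-site accumulators (unusable sites contribute nothing)
  u <- st$usable
  aA <- 2 * st$n_A / (2 * st$n_A - 1)  # n/(n-1) on allele counts
  aB <- 2 * st$n_B / (2 * st$n_B - 1)
  nP <- st$n_A + st$n_B
  pP <- (st$n_A * st$p_A + st$n_B * st$p_B) / nP
  aP <- 2 * nP / (2 * nP - 1)
  acc <- cbind(
    n    = as.numeric(u),
    piA  = ifelse(u, aA * 2 * st$p_A * (1 - st$p_A), 0),
    piB  = ifelse(u, aB * 2 * st$p_B * (1 - st$p_B), 0),
    piP  = ifelse(u, aP * 2 * pP * (1 - pP), 0),
    dxy  = ifelse(u, st$p_A * (1 - st$p_B) + st$p_B * (1 - st$p_A), 0),
    a    = ifelse(u, st$a, 0),
    abc  = ifelse(u, st$abc, 0)
  )
  acc[is.na(acc)] <- 0

  out <- purrr::map_dfr(split(grid, grid$chrom), function(gr) {
    ch <- gr$chrom[1]
    on_ch <- which(st$chrom == ch)
    if (!length(on_ch)) {
      return(tibble::tibble(chrom = ch, start = gr$start, end = gr$end,
                            n_snps = 0L, pi_A = 0, pi_B = 0, pi_all = 0,
                            fst = NA_real_, dxy = 0, .lo = 1L, .hi = 0L))
    }
    pos <- st$pos[on_ch]
    cs <- rbind(0, apply(acc[on_ch, , drop = FALSE], 2, cumsum))
    lo <- findInterval(gr$start - 0.5, pos) + 1L
    hi <- findInterval(gr$end + 0.5, pos)
    sums <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
    tibble::tibble(
      chrom = ch, start = gr$start, end = gr$end,
      n_snps = as.integer(sums[, "n"]),
      pi_A = as.numeric(sums[, "piA"]) / window_bp,
      pi_B = as.numeric(sums[, "piB"]) / window_bp,
      pi_all = as.numeric(sums[, "piP"]) / window_bp,
      fst = as.numeric(ifelse(sums[, "abc"] > 0,
                              sums[, "a"] / sums[, "abc"], NA_real_)),
      dxy = as.numeric(sums[, "dxy"]) / window_bp,
      .lo = lo + min(on_ch) - 1L, .hi = hi + min(on_ch) - 1L
    )
  })
  out <- out %>% dplyr::mutate(excluded = n_snps < min_snps)
  if (rho) {
    out$rho <- purrr::map2_dbl(out$.lo, out$.hi, function(lo, hi) {
      if (hi < lo) return(NA_real_)
      window_rho_idx(g, st, seq(lo, hi))
    })
  } else {
    out$rho <- NA_real_
  }
  out <- out %>%
    dplyr::mutate(rho_over_pi = ifelse(pi_all > 0, rho / pi_all, NA_real_)) %>%
    dplyr::select(-".lo", -".hi")
  attr(out, "sites") <- st
  out
}

# rho for the sites indexed by idx (rows of st / g$dosage)
window_rho_idx <- function(g, st, idx, maf_min = 0.1) {
  nm <- st$n_A[idx] + st$n_B[idx]
  p <- (st$n_A[idx] * st$p_A[idx] + st$n_B[idx] * st$p_B[idx]) / nm
  qual <- !is.na(p) & pmin(p, 1 - p) >= maf_min & st$usable[idx]
  if (sum(qual) < 2) return(NA_real_)
  idx <- idx[qual]
  d <- t(g$dosage[idx, , drop = FALSE])
  r2 <- suppressWarnings(cor(d, use = "pairwise.complete.obs"))^2
  lt <- lower.tri(r2)
  dist <- abs(outer(st$pos[idx], st$pos[idx], "-"))
  ok <- lt & !is.na(r2)
  if (!any(ok)) return(NA_real_)
  r2bar <- mean(r2[ok])
  dbar <- mean(dist[ok])
  nbar <- mean(nm[qual])
  r2c <- r2bar - 1 / (2 * nbar)
  if (r2c >= 0.5) return(0)
  if (r2c <= 0) return(NA_real_)
  (1 / r2c - 2) / dbar
}

#' Moment-based window recombination-rate estimate
#'
#' Mean pairwise dosage r-squared (Rogers-Huff style) among SNPs with pooled
#' minor-allele frequency >= 0.1, corrected by subtracting `1/(2 n)` for
#' finite sample size; the per-bp population recombination rate solves
#' `r2 = 1 / (2 + rho * d)` at the mean pairwise distance `d`. Corrected
#' r-squared at or above 0.5 clamps rho to 0; non-positive corrected
#' r-squared (no detectable LD) and windows with fewer than two qualifying
#' SNPs return `NA`.
#'
#' @param g A [genotypes()] object.
#' @param chrom,start,end Window coordinates (1-based inclusive).
#' @return rho per bp (scalar).
#' @export
window_rho <- function(g, chrom, start, end) {
  st <- site_stats(g)
  idx <- which(st$chrom == chrom & st$pos >= start & st$pos <= end)
  if (length(idx) < 2) return(NA_real_)
  window_rho_idx(g, st, idx)
}

#' Spearman correlation matrix of window statistics
#'
#' Pairwise Spearman correlations (ties mid-ranked, pairwise-complete) among
#' window statistics over non-excluded windows.
#'
#' @param windows Output of [window_stats()].
#' @param stats Columns to correlate.
#' @return Symmetric correlation matrix with unit diagonal; pairs involving a
#'   constant statistic are `NA` (with a warning).
#' @export
stat_correlations <- function(windows,
                              stats = c("fst", "dxy", "pi_all", "rho")) {
  w <- windows %>% dplyr::filter(!excluded)
  m <- as.matrix(w[, stats])
  if (sum(complete.cases(m)) < 10)
    abort("need >= 10 non-excluded windows with all statistics present")
  const <- apply(m, 2, function(x) sd(x, na.rm = TRUE) == 0 || all(is.na(x)))
  if (any(const))
    warn(paste("constant statistic(s):", paste(stats[const], collapse = ", ")))
  suppressWarnings(cor(m, method = "spearman", use = "pairwise.complete.obs"))
}
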