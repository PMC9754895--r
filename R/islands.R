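# Genomic-island detection: permutation null over genome-wide per-site
# Weir-Cockerham components, BH FDR over top-F_ST candidate windows, merging
# of adjacent outlier windows, and island-vs-background comparisons.

#' Empirical permutation p-value for one window's F_ST
#'
#' Draws `n_snps` sites uniformly without replacement from the genome-wide
#' pool of usable per-site Weir-Cockerham components, recombines them as a
#' ratio of sums, and returns the add-one empirical tail probability
#' `p = (#\{null >= observed\} + 1) / (n_perm + 1)`.
#'
#' @param observed_fst Observed window F_ST (ratio of summed components).
#' @param n_snps Number of sites the window contributed.
#' @param pool Tibble with columns `a`, `abc` (usable sites genome-wide), as
#'   produced by [site_stats()].
#' @param n_perm Number of permutations.
#' @param unit Resampling unit: recombine variance components as a ratio of
#'   sums (`"components"`, default) or average raw per-site F_ST ratios
#'   (`"site_fst"`).
#' @return Empirical p-value in (0, 1].
#' @export
permutation_null <- function(observed_fst, n_snps, pool, n_perm = 10000,
                             unit = c("components", "site_fst")) {
  unit <- match.arg(unit)
  pool <- pool[!is.na(pool$a) & !is.na(pool$abc), , drop = FALSE]
  m <- nrow(pool)
  if (m < n_snps) abort("site pool smaller than the window's SNP count")
  null <- numeric(n_perm)
  if (unit == "components") {
    a <- pool$a; abc <- pool$abc
    for (i in seq_len(n_perm)) {
      idx <- sample.int(m, n_snps)
      null[i] <- sum(a[idx]) / sum(abc[idx])
    }
  } else {
    fs <- ifelse(pool$abc > 0, pool$a / pool$abc, NA_real_)
    for (i in seq_len(n_perm)) {
      null[i] <- mean(fs[sample.int(m, n_snps)], na.rm = TRUE)
    }
  }
  # small epsilon guards float jitter when a draw reproduces the observed set
  (sum(null >= observed_fst - 1e-12, na.rm = TRUE) + 1) / (n_perm + 1)
}

#' Call outlier windows by top-F_ST + permutation + BH FDR
#'
#' Candidates are the top `top_fraction` of non-excluded windows by F_ST
#' (ties at the cutoff all included). Each candidate receives a permutation
#' p-value against the genome-wide site pool ([permutation_null()]);
#' Benjamini-Hochberg q-values are computed over the candidate set only, and
#' a window is an outlier iff `q < fdr`.
#'
#' @param windows Output of [window_stats()] (the per-site pool is taken from
#'   its `"sites"` attribute unless `sites` is given).
#' @param sites Optional per-site tibble from [site_stats()].
#' @param top_fraction Fraction of windows taken as candidates.
#' @param n_perm Permutations per candidate window.
#' @param fdr FDR threshold on BH q-values.
#' @param seed Integer seed for the permutation draws.
#' @param unit Passed to [permutation_null()].
#' @return The windows tibble with `candidate`, `p`, `q` and `outlier`
#'   columns added.
#' @export
call_outliers <- function(windows, sites = NULL, top_fraction = 0.01,
                          n_perm = 10000, fdr = 0.01, seed = 1L,
                          unit = "components") {
  sites <- sites %||% attr(windows, "sites")
  if (is.null(sites)) abort("per-site components required (run window_stats)")
  if (n_perm < 1 / fdr)
    warn("n_perm below 1/fdr: permutation p resolution cannot reach the threshold")
  usable <- windows %>% dplyr::filter(!excluded, !is.na(fst))
  if (nrow(usable) < 100)
    warn("fewer than 100 analyzable windows; top-fraction cutoff is coarse")
  k <- max(1L, ceiling(top_fraction * nrow(usable)))
  cutoff <- sort(usable$fst, decreasing = TRUE)[min(k, nrow(usable))]
  pool <- sites %>% dplyr::filter(usable)
  out <- windows %>%
    dplyr::mutate(candidate = !excluded & !is.na(fst) & fst >= cutoff,
                  p = NA_real_, q = NA_real_, outlier = FALSE)
  set.seed(seed)
  ci <- which(out$candidate)
  out$p[ci] <- vapply(ci, function(i) {
    permutation_null(out$fst[i], out$n_snps[i], pool, n_perm, unit)
  }, numeric(1))
  out$q[ci] <- p.adjust(out$p[ci], method = "BH")
  out$outlier[ci] <- out$q[ci] < fdr
  attr(out, "sites") <- sites
  out
}

#' Merge adjacent outlier windows into island regions
#'
#' Outlier windows on the same chromosome that overlap or are book-ended
#' (next start = end + 1, which captures all step-offset neighbours) merge
#' into one region spanning their coordinate union.
#'
#' @param windows Tibble with an `outlier` column ([call_outliers()]) or any
#'   tibble of regions `chrom, start, end` to merge wholesale.
#' @return Tibble `region_id, chrom, start, end, n_windows, mean_fst`
#'   (mean F_ST is `NA` when no `fst` column is present).
#' @export
merge_islands <- function(windows) {
  w <- if ("outlier" %in% names(windows))
    dplyr::filter(windows, outlier) else windows
  if (!nrow(w)) {
    return(tibble::tibble(region_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          n_windows = integer(), mean_fst = numeric()))
  }
  if (!"fst" %in% names(w)) w$fst <- NA_real_
  w %>%
    dplyr::arrange(chrom, start) %>%
    dplyr::group_by(chrom) %>%
    dplyr::mutate(new_run = start > dplyr::lag(cummax(end), default = -Inf) + 1,
                  grp = cumsum(new_run)) %>%
    dplyr::group_by(chrom, grp) %>%
    dplyr::summarise(start = min(start), end = max(end),
                     n_windows = dplyr::n(), mean_fst = mean(fst),
                     .groups = "drop") %>%
    dplyr::arrange(chrom, start) %>%
    dplyr::mutate(region_id = sprintf("isl%03d", dplyr::row_number()),
                  .before = 1) %>%
    dplyr::select(-grp)
}

# windows overlapping any region
overlaps_regions <- function(windows, regions) {
  hit <- rep(FALSE, nrow(windows))
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (windows$chrom == regions$chrom[i] &
                    windows$start <= regions$end[i] &
                    windows$end >= regions$start[i])
  }
  hit
}

#' Island-vs-background comparisons
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) tests of each statistic between
#' island-member windows (non-excluded windows overlapping an island region)
#' and background windows, plus a chi-square goodness-of-fit test of
#' outlier-window counts per chromosome against expectation proportional to
#' the number of analyzed windows per chromosome.
#'
#' @param windows Output of [call_outliers()] (or [window_stats()]).
#' @param islands Regions from [merge_islands()].
#' @param stats Window statistics to compare.
#' @return List with `wilcoxon` (tibble `stat, n_island, n_background,
#'   median_island, median_background, p`) and `chrom_enrichment`
#'   (tibble `chi2, df, p`, or `NULL` when fewer than two chromosomes).
#' @export
island_background_tests <- function(windows, islands,
                                    stats = c("dxy", "pi_all", "rho",
                                              "rho_over_pi")) {
  if (!nrow(islands)) abort("no islands to test")
  w <- windows %>% dplyr::filter(!excluded)
  if (nrow(w) < 10) abort("need >= 10 analyzable windows")
  member <- overlaps_regions(w, islands)
  wil <- purrr::map_dfr(stats, function(s) {
    xi <- w[[s]][member]; xb <- w[[s]][!member]
    xi <- xi[!is.na(xi)]; xb <- xb[!is.na(xb)]
    p <- if (length(xi) && length(xb)) {
      if (sd(c(xi, xb)) == 0) 1  # identical constant samples: no evidence
      else suppressWarnings(wilcox.test(xi, xb)$p.value)
    } else NA_real_
    tibble::tibble(stat = s, n_island = length(xi), n_background = length(xb),
                   median_island = median(xi), median_background = median(xb),
                   p = p)
  })
  enrich <- NULL
  if (dplyr::n_distinct(w$chrom) >= 2 && "outlier" %in% names(w) &&
      sum(w$outlier) > 0) {
    tab <- w %>%
      dplyr::group_by(chrom) %>%
      dplyr::summarise(n_out = sum(outlier), n_win = dplyr::n(),
                       .groups = "drop")
    ct <- suppressWarnings(
      chisq.test(tab$n_out, p = tab$n_win / sum(tab$n_win)))
    enrich <- tibble::tibble(chi2 = unname(ct$statistic),
                             df = unname(ct$parameter),
                             p = ct$p.value)
  }
  list(wilcoxon = wil, chrom_enrichment = enrich)
}
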