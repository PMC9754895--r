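# Copy-number differentiation: gene copy numbers from CNV segments, the V_ST
# statistic, and CNDG calling by species-label permutation.

#' Gene copy numbers from per-individual CNV segments
#'
#' For each gene and individual, the copy number is the mean of overlapping
#' segment copy numbers weighted by overlap length, with uncovered gene bp
#' counting at the diploid baseline of 2; individuals (or genes) with no
#' overlapping segment sit at 2. Genes overlapped by at least one segment in
#' at least one individual are flagged copy-number genes (`cng`).
#'
#' @param segments Tibble `sample_id, chrom, start, end, copy_number`
#'   (1-based inclusive, non-overlapping per individual).
#' @param genes Tibble `gene_id, chrom, start, end` (1-based inclusive).
#' @param samples Sample metadata tibble (`sample_id, species`); defines the
#'   full individual set, including individuals without any segment.
#' @param baseline Copy number assumed outside segments.
#' @return Tibble `gene_id, sample_id, species, copy_number, cng`.
#' @export
gene_copy_numbers <- function(segments, genes, samples, baseline = 2) {
  if (any(segments$copy_number < 0)) abort("negative copy number in segments")
  glen <- genes$end - genes$start + 1
  ov <- dplyr::inner_join(
    genes, segments,
    by = dplyr::join_by(chrom, overlaps(start, end, start, end)),
    suffix = c("", ".seg")
  ) %>%
    dplyr::mutate(ov_len = pmin(end, end.seg) - pmax(start, start.seg) + 1) %>%
    dplyr::group_by(gene_id, sample_id) %>%
    dplyr::summarise(cn_cov = sum(copy_number * ov_len), cov = sum(ov_len),
                     .groups = "drop")
  grid <- tidyr::expand_grid(gene_id = genes$gene_id,
                             sample_id = samples$sample_id)
  grid %>%
    dplyr::left_join(ov, by = c("gene_id", "sample_id")) %>%
    dplyr::mutate(cov = dplyr::coalesce(cov, 0),
                  cn_cov = dplyr::coalesce(cn_cov, 0)) %>%
    dplyr::left_join(tibble::tibble(gene_id = genes$gene_id, glen = glen),
                     by = "gene_id") %>%
    dplyr::mutate(copy_number =
                    (cn_cov + baseline * (glen - cov)) / glen) %>%
    dplyr::group_by(gene_id) %>%
    dplyr::mutate(cng = any(cov > 0)) %>%
    dplyr::ungroup() %>%
    dplyr::left_join(dplyr::select(samples, sample_id, species),
                     by = "sample_id") %>%
    dplyr::select(gene_id, sample_id, species, copy_number, cng)
}

# population variance (divisor N)
pop_var <- function(x) mean((x - mean(x))^2)

#' V_ST copy-number differentiation statistic
#'
#' `V_ST = (V_total - (V_A N_A + V_B N_B) / N_total) / V_total`, with
#' population variances (divisor N; set `unbiased = TRUE` for N-1).
#' Undefined (`NA`) when the total variance is zero.
#'
#' @param cn_values_A,cn_values_B Copy-number vectors for the two species
#'   (each of length >= 2).
#' @param unbiased Use sample variances (divisor N-1) instead.
#' @return V_ST in (-Inf, 1], or `NA` when total variance is 0.
#' @export
vst <- function(cn_values_A, cn_values_B, unbiased = FALSE) {
  nA <- length(cn_values_A); nB <- length(cn_values_B)
  if (nA < 2 || nB < 2) abort("need >= 2 individuals per species")
  vf <- if (unbiased) var else pop_var
  vt <- vf(c(cn_values_A, cn_values_B))
  if (vt == 0) return(NA_real_)
  (vt - (vf(cn_values_A) * nA + vf(cn_values_B) * nB) / (nA + nB)) / vt
}

#' Call copy-number differentiated genes (CNDGs)
#'
#' Computes V_ST for every copy-number gene with defined total variance,
#' takes the top `top_fraction` as outliers (ties included), and for each
#' outlier permutes the species labels (preserving group sizes) `n_perm`
#' times to build a gene-specific null; the add-one permutation p uses a
#' greater-or-equal comparison. A gene is a CNDG iff it is an outlier and
#' `p <= alpha`.
#'
#' @param cn_tbl Output of [gene_copy_numbers()] (long tibble); genes never
#'   overlapped by a segment (`cng = FALSE`) are excluded from the ranking
#'   denominator.
#' @param top_fraction Outlier fraction of ranked genes.
#' @param n_perm Label permutations per outlier gene.
#' @param alpha Significance threshold on the permutation p.
#' @param seed Integer seed.
#' @param unbiased Passed to [vst()].
#' @return Tibble `gene_id, v_total, v_A, v_B, n_A, n_B, n_total, vst, top5,
#'   perm_p, cndg`, sorted by decreasing V_ST.
#' @export
call_cndg <- function(cn_tbl, top_fraction = 0.05, n_perm = 1000,
                      alpha = 0.01, seed = 1L, unbiased = FALSE) {
  if (n_perm < 1 / alpha)
    warn("n_perm below 1/alpha: permutation p resolution cannot reach alpha")
  vf <- if (unbiased) var else pop_var
  sp_levels <- unique(cn_tbl$species)
  wide <- cn_tbl %>%
    dplyr::filter(cng) %>%
    dplyr::select(gene_id, sample_id, species, copy_number)
  res <- wide %>%
    dplyr::group_by(gene_id) %>%
    dplyr::summarise(
      v_total = pop_var(copy_number),
      v_A = vf(copy_number[species == sp_levels[1]]),
      v_B = vf(copy_number[species == sp_levels[2]]),
      n_A = sum(species == sp_levels[1]),
      n_B = sum(species == sp_levels[2]),
      vst = tryCatch(vst(copy_number[species == sp_levels[1]],
                         copy_number[species == sp_levels[2]],
                         unbiased = unbiased),
                     error = function(e) NA_real_),
      .groups = "drop"
    ) %>%
    dplyr::mutate(n_total = n_A + n_B,
                  v_total = ifelse(unbiased,
                                   v_total * n_total / (n_total - 1), v_total))
  if (sum(!is.na(res$vst)) < 20)
    warn("fewer than 20 genes with defined V_ST; ranking is coarse")
  defined <- res %>% dplyr::filter(!is.na(vst))
  k <- max(1L, ceiling(top_fraction * nrow(defined)))
  cutoff <- sort(defined$vst, decreasing = TRUE)[min(k, nrow(defined))]
  res <- res %>%
    dplyr::mutate(top5 = !is.na(vst) & vst >= cutoff, perm_p = NA_real_)
  set.seed(seed)
  cn_by_gene <- split(cn_tbl$copy_number[cn_tbl$cng],
                      cn_tbl$gene_id[cn_tbl$cng])
  # permutations redraw the A-group membership; only group sizes are preserved
  for (i in which(res$top5)) {
    x <- cn_by_gene[[res$gene_id[i]]]
    nA <- res$n_A[i]; n <- res$n_total[i]
    obs <- res$vst[i]
    vt <- vf(x)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n, nA)
      grpA <- x[idx]; grpB <- x[-idx]
      v0 <- (vt - (vf(grpA) * nA + vf(grpB) * (n - nA)) / n) / vt
      if (!is.na(v0) && v0 >= obs - 1e-12) hits <- hits + 1L
    }
    res$perm_p[i] <- (hits + 1) / (n_perm + 1)
  }
  res %>%
    dplyr::mutate(cndg = top5 & !is.na(perm_p) & perm_p <= alpha) %>%
    dplyr::select(gene_id, v_total, v_A, v_B, n_A, n_B, n_total, vst, top5,
                  perm_p, cndg) %>%
    dplyr::arrange(dplyr::desc(vst))
}
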