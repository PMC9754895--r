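# HKA-style positive-selection scan: per-site classes (polymorphic within a
# species / fixed between species), Pearson 2x2 contingency test of each
# gene's polymorphism : fixed-difference ratio against the genome ratio, and
# island enrichment of the resulting selection candidates.

#' Classify sites as polymorphic-within-species and/or fixed-between
#'
#' A site is fixed-between iff its per-site Weir-Cockerham F_ST ratio is at
#' least `fst_fixed` (negative or undefined ratios count as below threshold);
#' it is polymorphic within a species iff its allele frequency among that
#' species' non-missing alleles is strictly between 0 and 1. A site can hold
#' both roles. Sites missing in an entire species are excluded for that
#' species.
#'
#' @param g A [genotypes()] object.
#' @param sites Optional precomputed [site_stats()] tibble.
#' @param fst_fixed Site F_ST threshold defining fixed loci.
#' @return Tibble `snp_id, chrom, pos, fst_site, fixed_between, poly_A,
#'   poly_B`.
#' @export
classify_sites <- function(g, sites = NULL, fst_fixed = 0.95) {
  st <- sites %||% site_stats(g)
  tibble::tibble(
    snp_id = st$snp_id, chrom = st$chrom, pos = st$pos,
    fst_site = st$fst_site,
    fixed_between = !is.na(st$fst_site) & st$fst_site >= fst_fixed,
    poly_A = st$n_A > 0 & st$p_A > 0 & st$p_A < 1,
    poly_B = st$n_B > 0 & st$p_B > 0 & st$p_B < 1
  )
}

#' Pearson chi-square HKA contingency test
#'
#' 2x2 table `[[n1_gene, n2_gene], [n1_genome, n2_genome]]` comparing a
#' gene's within-species polymorphism : fixed-difference ratio to the genome
#' ratio; 1 df, no continuity correction; upper-tail p. Warns when any
#' expected count falls below 5.
#'
#' @param n1_gene,n2_gene Gene counts of polymorphic-within and fixed loci.
#' @param n1_genome,n2_genome Genome-wide margin counts (positive total).
#' @return List `chi2, p` (`NA` when the gene has no sites).
#' @export
hka_test <- function(n1_gene, n2_gene, n1_genome, n2_genome) {
  if (n1_genome + n2_genome <= 0) abort("genome margins must be positive")
  if (n1_gene + n2_gene == 0) return(list(chi2 = NA_real_, p = NA_real_))
  tab <- matrix(c(n1_gene, n2_gene, n1_genome, n2_genome), 2, byrow = TRUE)
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expd < 5))
    warn("expected count below 5: chi-square approximation is rough")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = ct$p.value)
}

#' Call positively selected genes (HKA p plus nonsynonymous filter)
#'
#' For each focal species, a gene's `n1` counts SNPs polymorphic within that
#' species inside the gene, and `n2` counts fixed-between loci inside the
#' gene; genome-wide margins are the totals over all classified sites, by
#' default excluding the focal gene's own counts. The gene is a selection
#' candidate (`psg`) iff the HKA p-value is at most `alpha` and its
#' nonsynonymous fixed-site count exceeds 1.
#'
#' @param g A [genotypes()] object.
#' @param genes Gene models tibble `gene_id, chrom, start, end` (1-based
#'   inclusive, sorted).
#' @param nonsyn Tibble `gene_id, nonsyn`; genes absent from it count 0.
#' @param alpha HKA significance threshold.
#' @param focal `"each"` runs the test once per species (results stacked with
#'   a `focal_species` column); `"pooled"` counts polymorphism in either
#'   species as n1.
#' @param exclude_gene_margins Subtract the focal gene's counts from the
#'   genome margins (avoids self-comparison).
#' @param sites Optional precomputed [site_stats()] tibble.
#' @param fst_fixed Site F_ST threshold defining fixed loci.
#' @return Tibble `focal_species, gene_id, n1_gene, n2_gene, n1_genome,
#'   n2_genome, chi2, p, nonsyn, psg`; genes without SNPs are skipped.
#' @export
call_psg <- function(g, genes, nonsyn, alpha = 0.01,
                     focal = c("each", "pooled"),
                     exclude_gene_margins = TRUE, sites = NULL,
                     fst_fixed = 0.95) {
  focal <- match.arg(focal)
  cls <- classify_sites(g, sites = sites, fst_fixed = fst_fixed)
  sp <- species_levels(g)
  # assign sites to genes (position within gene extent)
  site_gene <- dplyr::inner_join(
    cls,
    dplyr::select(genes, gene_id, chrom, gstart = start, gend = end),
    by = dplyr::join_by(chrom, between(pos, gstart, gend))
  )
  runs <- if (focal == "each") {
    list(list(label = sp[1], poly = "poly_A"),
         list(label = sp[2], poly = "poly_B"))
  } else {
    list(list(label = "pooled", poly = "either"))
  }
  purrr::map_dfr(runs, function(run) {
    poly <- if (run$poly == "either") cls$poly_A | cls$poly_B else cls[[run$poly]]
    n1_tot <- sum(poly)
    n2_tot <- sum(cls$fixed_between)
    poly_g <- if (run$poly == "either")
      site_gene$poly_A | site_gene$poly_B else site_gene[[run$poly]]
    cnt <- site_gene %>%
      dplyr::mutate(polyf = poly_g) %>%
      dplyr::group_by(gene_id) %>%
      dplyr::summarise(n1_gene = sum(polyf), n2_gene = sum(fixed_between),
                       .groups = "drop") %>%
      dplyr::filter(n1_gene + n2_gene > 0) %>%
      dplyr::mutate(
        n1_genome = n1_tot - if (exclude_gene_margins) n1_gene else 0L,
        n2_genome = n2_tot - if (exclude_gene_margins) n2_gene else 0L
      )
    tests <- purrr::pmap(cnt[, c("n1_gene", "n2_gene", "n1_genome",
                                 "n2_genome")],
                         function(n1_gene, n2_gene, n1_genome, n2_genome) {
                           suppressWarnings(
                             hka_test(n1_gene, n2_gene, n1_genome, n2_genome))
                         })
    cnt %>%
      dplyr::mutate(
        focal_species = run$label, .before = 1) %>%
      dplyr::mutate(
        chi2 = purrr::map_dbl(tests, "chi2"),
        p = purrr::map_dbl(tests, "p")) %>%
      dplyr::left_join(nonsyn, by = "gene_id") %>%
      dplyr::mutate(nonsyn = dplyr::coalesce(nonsyn, 0L),
                    psg = !is.na(p) & p <= alpha & nonsyn > 1)
  })
}

#' Island enrichment of selection candidates
#'
#' 2x2 Pearson chi-square of selection-candidate status against island
#' membership (a gene is in an island iff its midpoint falls inside a merged
#' island region).
#'
#' @param psg_tbl Output of [call_psg()] (one focal species, or pass a
#'   pre-filtered subset); gene ids are deduplicated.
#' @param islands Regions from [merge_islands()].
#' @param genes Gene models tibble (defines the full gene universe).
#' @return Tibble `n_psg_island, n_psg_out, n_other_island, n_other_out,
#'   chi2, p`.
#' @export
island_enrichment <- function(psg_tbl, islands, genes) {
  if (!nrow(islands)) abort("no islands: enrichment test skipped")
  mid <- floor((genes$start + genes$end) / 2)
  in_isl <- in_regions(genes$chrom, mid, islands)
  if (!any(in_isl)) abort("no genes fall inside islands")
  psg_ids <- unique(psg_tbl$gene_id[psg_tbl$psg])
  is_psg <- genes$gene_id %in% psg_ids
  tab <- table(factor(is_psg, c(TRUE, FALSE)), factor(in_isl, c(TRUE, FALSE)))
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble::tibble(
    n_psg_island = tab[1, 1], n_psg_out = tab[1, 2],
    n_other_island = tab[2, 1], n_other_out = tab[2, 2],
    chi2 = unname(ct$statistic), p = ct$p.value
  )
}
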