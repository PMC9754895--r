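#' Configuration for the two-species synthetic dataset
#'
#' Builds and validates the configuration that drives [simulate_divergence_data()]
#' and the individual `simulate_*()` generators. Defaults emulate a two sister
#' species resequencing design: 26 + 14 diploids drawn from 12 + 4 natural
#' populations in two latitude bands, a heterogeneous differentiation landscape
#' with planted high-F_ST islands where linkage is strong (few founder
#' haplotypes), a fixed-difference site mass giving the site-F_ST distribution
#' its U shape, genes enriched for fixed differences (selection targets),
#' copy-number differentiated genes, and seven environmental predictors (plus
#' one deliberately collinear extra to exercise the predictor filter).
#'
#' @param seed Integer seed; every random substream is derived from it by a
#'   fixed offset, so identical configs give byte-identical outputs.
#' @param n_chromosomes,chrom_length_bp Genome layout. Chromosomes are named
#'   `Chr01`, `Chr02`, ...
#' @param n_samples_A,n_samples_B Diploid sample counts per species.
#' @param n_populations_A,n_populations_B Population counts per species.
#' @param snp_density Expected SNPs per bp before removal of sites monomorphic
#'   in the realized sample.
#' @param background_fst,island_fst Balding-Nichols differentiation parameters
#'   (both in (0,1), `island_fst > background_fst`).
#' @param island_regions Tibble `chrom,start,end` (1-based inclusive) of
#'   planted islands; must be non-overlapping and inside chromosome bounds.
#' @param founder_k_background,founder_k_island Founder-haplotype pool sizes
#'   per 20-kb linkage block; smaller pools give stronger LD (lower rho).
#'   `Inf` draws haplotype alleles independently (no LD).
#' @param island_snp_thinning Fraction of island SNP sites retained relative
#'   to the background density. Linked selection removes diversity, so
#'   islands carry fewer segregating sites; thinning reproduces the jointly
#'   reduced per-bp pi and D_XY inside islands.
#' @param fixed_diff_frac Fraction of background sites planted as fixed
#'   differences between the species (the study-scale site-F_ST distribution
#'   carries a fixed-difference mass of roughly 12.8%).
#' @param n_genes,gene_length_bp Number of gene models and their length range
#'   (uniform draw); at least `min_intergenic_frac` of each chromosome is left
#'   intergenic.
#' @param min_intergenic_frac Minimum intergenic fraction per chromosome.
#' @param n_psg Planted selection-target genes (elevated fixed-difference
#'   density, nonsynonymous fixed-site count >= 2).
#' @param psg_fixed_rate Probability that a SNP inside a planted selection
#'   target is a fixed difference.
#' @param n_cndg Planted copy-number differentiated genes (species copy-number
#'   means 2 vs 4).
#' @param cng_frac Fraction of genes that carry copy-number variation in at
#'   least one individual (the CNG universe over which V_ST is ranked).
#' @param cnv_noise_rate Per gene-by-individual probability of a background
#'   copy-number deviation (CN 1 or 3).
#' @param n_env_snps Planted environment-associated SNPs (dosage tracks annual
#'   precipitation with correlation around 0.8).
#' @param env_predictors Tibble `predictor, mean_A, mean_B, sd` for the seven
#'   predictors; see [default_env_predictors()].
#' @param missing_rate Fraction of genotypes masked as missing, in [0, 0.2].
#'
#' @return A validated list of class `divscan_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_chromosomes = 1, chrom_length_bp = 2e5,
#'                   island_regions = tibble::tibble(chrom = "Chr01",
#'                                                   start = 50001, end = 80000))
sim_config <- function(seed = 1L,
                       n_chromosomes = 4L,
                       chrom_length_bp = 1e6,
                       n_samples_A = 26L,
                       n_samples_B = 14L,
                       n_populations_A = 12L,
                       n_populations_B = 4L,
                       snp_density = 0.002,
                       background_fst = 0.2,
                       island_fst = 0.9,
                       island_regions = NULL,
                       founder_k_background = 100,
                       founder_k_island = 6,
                       island_snp_thinning = 0.5,
                       fixed_diff_frac = 0.128,
                       n_genes = 300L,
                       gene_length_bp = c(2000L, 6000L),
                       min_intergenic_frac = 0.1,
                       n_psg = 12L,
                       psg_fixed_rate = 0.8,
                       n_cndg = 5L,
                       cng_frac = 0.4,
                       cnv_noise_rate = 0.05,
                       n_env_snps = 15L,
                       env_predictors = default_env_predictors(),
                       missing_rate = 0.02) {
  if (is.null(island_regions)) {
    island_regions <- tibble::tibble(
      chrom = c("Chr01", "Chr03")[c(1, 2) <= n_chromosomes],
      start = c(500001, 200001)[c(1, 2) <= n_chromosomes],
      end   = c(540000, 230000)[c(1, 2) <= n_chromosomes]
    )
    island_regions <- dplyr::filter(island_regions, end <= chrom_length_bp)
  }
  cfg <- structure(list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    n_samples_A = as.integer(n_samples_A),
    n_samples_B = as.integer(n_samples_B),
    n_populations_A = as.integer(n_populations_A),
    n_populations_B = as.integer(n_populations_B),
    snp_density = snp_density,
    background_fst = background_fst,
    island_fst = island_fst,
    island_regions = tibble::as_tibble(island_regions),
    founder_k_background = founder_k_background,
    founder_k_island = founder_k_island,
    island_snp_thinning = island_snp_thinning,
    fixed_diff_frac = fixed_diff_frac,
    n_genes = as.integer(n_genes),
    gene_length_bp = as.integer(gene_length_bp),
    min_intergenic_frac = min_intergenic_frac,
    n_psg = as.integer(n_psg),
    psg_fixed_rate = psg_fixed_rate,
    n_cndg = as.integer(n_cndg),
    cng_frac = cng_frac,
    cnv_noise_rate = cnv_noise_rate,
    n_env_snps = as.integer(n_env_snps),
    env_predictors = tibble::as_tibble(env_predictors),
    missing_rate = missing_rate
  ), class = "divscan_sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Default environmental predictor specification
#'
#' Seven predictors in the style of bioclim/soil layers: subsoil sand fraction
#' (SSF), subsoil pH (Sp), solar radiation (SR), maximum temperature (MaT),
#' minimum temperature (MiT), mean diurnal range (MDR), annual precipitation
#' (AP). AP, MiT, MDR and Sp have species-separated means (AP by 3 within-
#' species SDs); an eighth collinear predictor (TS, built from MaT at r
#' about 0.9) is added by the generator to exercise the autocorrelation filter.
#'
#' @return Tibble with columns `predictor, mean_A, mean_B, sd`.
#' @export
default_env_predictors <- function() {
  tibble::tribble(
    ~predictor, ~mean_A, ~mean_B, ~sd,
    "SSF",      38,      38,      6,
    "Sp",       6.6,     7.0,     0.4,
    "SR",       15000,   15000,   1200,
    "MaT",      29,      29,      2,
    "MiT",      -6.5,    -4,      2,
    "MDR",      11,      9.7,     1,
    "AP",       800,     1400,    200
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(is.finite(cfg$seed))
  bad <- function(msg) abort(paste0("invalid sim_config: ", msg))
  counts <- c(cfg$n_chromosomes, cfg$chrom_length_bp, cfg$n_samples_A,
              cfg$n_samples_B, cfg$n_populations_A, cfg$n_populations_B,
              cfg$n_genes)
  if (any(counts <= 0)) bad("all counts must be positive")
  for (f in c(cfg$background_fst, cfg$island_fst)) {
    if (f <= 0 || f >= 1) bad("differentiation parameters must lie in (0, 1)")
  }
  if (cfg$island_fst <= cfg$background_fst)
    bad("island_fst must exceed background_fst")
  if (cfg$missing_rate < 0 || cfg$missing_rate > 0.2)
    bad("missing_rate must lie in [0, 0.2]")
  if (cfg$fixed_diff_frac < 0 || cfg$fixed_diff_frac >= 1)
    bad("fixed_diff_frac must lie in [0, 1)")
  if (cfg$island_snp_thinning <= 0 || cfg$island_snp_thinning > 1)
    bad("island_snp_thinning must lie in (0, 1]")
  isl <- cfg$island_regions
  if (nrow(isl)) {
    chroms <- chrom_names(cfg)
    if (!all(isl$chrom %in% chroms)) bad("island chromosome not in genome")
    if (any(isl$start < 1 | isl$end > cfg$chrom_length_bp | isl$start > isl$end))
      bad("island outside chromosome bounds")
    ov <- isl %>%
      dplyr::arrange(chrom, start) %>%
      dplyr::group_by(chrom) %>%
      dplyr::summarise(ov = any(start[-1] <= head(end, -1)), .groups = "drop")
    if (any(ov$ov)) bad("island regions overlap")
  }
  if (cfg$n_cndg > cfg$n_genes || cfg$n_psg > cfg$n_genes)
    bad("planted gene counts exceed n_genes")
  invisible(cfg)
}

chrom_names <- function(cfg) sprintf("Chr%02d", seq_len(cfg$n_chromosomes))

# deterministic substream seeds derived from the one global seed
substream <- function(cfg, offset) set.seed((cfg$seed + offset) %% .Machine$integer.max)

#' @export
print.divscan_sim_config <- function(x, ...) {
  cat("<divscan_sim_config>\n")
  cat(sprintf("  genome: %d x %s bp, snp_density %.4g\n",
              x$n_chromosomes, format(x$chrom_length_bp, big.mark = ","),
              x$snp_density))
  cat(sprintf("  samples: %d + %d diploids (%d + %d populations)\n",
              x$n_samples_A, x$n_samples_B, x$n_populations_A, x$n_populations_B))
  cat(sprintf("  F: background %.2f, island %.2f (%d island regions)\n",
              x$background_fst, x$island_fst, nrow(x$island_regions)))
  cat(sprintf("  planted: %d selection targets, %d CN-differentiated genes, %d env SNPs\n",
              x$n_psg, x$n_cndg, x$n_env_snps))
  invisible(x)
}
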