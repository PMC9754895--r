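# Seeded synthetic two-species dataset: Balding-Nichols differentiation with
# founder-haplotype linkage blocks, planted islands / selection targets /
# CN-differentiated genes / environment-associated SNPs.

rtruncbeta <- function(n, shape1 = 0.8, shape2 = 0.8, lo = 0.05, hi = 0.95) {
  qbeta(runif(n, pbeta(lo, shape1, shape2), pbeta(hi, shape1, shape2)),
        shape1, shape2)
}

#' Simulate sample metadata
#'
#' Diploid samples of two species assigned round-robin to populations; each
#' population gets coordinates in its species' latitude band (species A
#' northern, species B southern), emulating parapatric ranges.
#'
#' @param config A [sim_config()].
#' @return Tibble `sample_id, species, population, lat, lon`.
#' @export
simulate_samples <- function(config) {
  substream(config, 11L)
  pops_A <- sprintf("PA%02d", seq_len(config$n_populations_A))
  pops_B <- sprintf("PB%02d", seq_len(config$n_populations_B))
  coords <- tibble::tibble(
    population = c(pops_A, pops_B),
    lat = c(runif(length(pops_A), 32, 40), runif(length(pops_B), 24, 30)),
    lon = runif(length(pops_A) + length(pops_B), 100, 118)
  )
  tibble::tibble(
    sample_id = c(sprintf("A%02d", seq_len(config$n_samples_A)),
                  sprintf("B%02d", seq_len(config$n_samples_B))),
    species = rep(c("speciesA", "speciesB"),
                  c(config$n_samples_A, config$n_samples_B)),
    population = c(rep_len(pops_A, config$n_samples_A),
                   rep_len(pops_B, config$n_samples_B))
  ) %>%
    dplyr::left_join(coords, by = "population")
}

#' Simulate environmental predictors
#'
#' Seven predictors drawn per sample around species means (AP separated by 3
#' within-species SDs; MiT, MDR, Sp more mildly), plus one deliberately
#' collinear predictor `TS` built from `MaT` with correlation about 0.9 so the
#' autocorrelation filter has work to do.
#'
#' @param config A [sim_config()].
#' @param samples Optional tibble from [simulate_samples()].
#' @return Tibble with `sample_id` and one column per predictor.
#' @export
simulate_env <- function(config, samples = NULL) {
  samples <- samples %||% simulate_samples(config)
  substream(config, 13L)
  n <- nrow(samples)
  is_A <- samples$species == samples$species[1]
  env <- tibble::tibble(sample_id = samples$sample_id)
  for (i in seq_len(nrow(config$env_predictors))) {
    sp <- config$env_predictors[i, ]
    mu <- ifelse(is_A, sp$mean_A, sp$mean_B)
    env[[sp$predictor]] <- mu + sp$sd * rnorm(n)
  }
  z_mat <- as.numeric(scale(env$MaT))
  env$TS <- 25 + 3 * (0.9 * z_mat + sqrt(1 - 0.9^2) * rnorm(n))
  env
}

#' Simulate gene models and nonsynonymous fixed-site counts
#'
#' Non-overlapping, sorted gene models leaving at least
#' `min_intergenic_frac` of each chromosome intergenic; `n_psg` genes are
#' earmarked as selection targets and given nonsynonymous fixed-site counts
#' of at least 2, the rest draw from a Poisson background.
#'
#' @param config A [sim_config()].
#' @return List with `genes` (tibble `gene_id, chrom, start, end`, 1-based
#'   inclusive), `nonsyn` (tibble `gene_id, nonsyn`) and `psg_ids`.
#' @export
simulate_annotation <- function(config) {
  substream(config, 23L)
  chroms <- chrom_names(config)
  per_chrom <- diff(floor(seq(0, config$n_genes, length.out = length(chroms) + 1)))
  L <- config$chrom_length_bp
  genes <- purrr::map2_dfr(chroms, per_chrom, function(ch, ng) {
    if (ng == 0) return(NULL)
    len <- sample(seq(config$gene_length_bp[1], config$gene_length_bp[2]), ng,
                  replace = TRUE)
    budget <- floor((1 - config$min_intergenic_frac) * L)
    if (sum(len) > budget) len <- pmax(200L, floor(len * budget / sum(len)))
    gap_w <- runif(ng + 1)
    gaps <- floor((L - sum(len)) * gap_w / sum(gap_w))
    start <- cumsum(gaps[seq_len(ng)]) + cumsum(c(0L, len[-ng])) + 1
    tibble::tibble(chrom = ch, start = start, end = start + len - 1)
  })
  genes <- genes %>%
    dplyr::arrange(chrom, start) %>%
    dplyr::mutate(gene_id = sprintf("g%04d", dplyr::row_number()), .before = 1)
  psg_ids <- sort(sample(genes$gene_id, config$n_psg))
  nonsyn <- tibble::tibble(
    gene_id = genes$gene_id,
    nonsyn = rpois(nrow(genes), 0.8)
  )
  nonsyn$nonsyn[nonsyn$gene_id %in% psg_ids] <- 2L + rpois(length(psg_ids), 3)
  list(genes = genes, nonsyn = nonsyn, psg_ids = psg_ids)
}

# classify positions against regions (tibble chrom,start,end); returns logical
in_regions <- function(chrom, pos, regions) {
  hit <- rep(FALSE, length(pos))
  if (is.null(regions) || nrow(regions) == 0) return(hit)
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (chrom == regions$chrom[i] &
                    pos >= regions$start[i] & pos <= regions$end[i])
  }
  hit
}

#' Simulate two-species genotypes
#'
#' Sites get an ancestral frequency from a truncated Beta(0.8, 0.8) prior;
#' each species' frequency is drawn Balding-Nichols style from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = background_fst` outside islands
#' and `island_fst` inside. Haplotypes are built per 20-kb linkage block by
#' sampling from a pool of K founder haplotypes (small K inside islands gives
#' both high F_ST and strong LD / low rho). A `fixed_diff_frac` share of
#' background sites is planted as fixed inter-species differences (the
#' U-shaped site-F_ST mass); island SNP density is thinned by
#' `island_snp_thinning` (linked selection removes segregating sites, which
#' is what depresses per-bp pi and D_XY inside islands); sites inside
#' selection-target genes are enriched
#' for fixed differences; `n_env_snps` background SNPs have dosages tracking
#' annual precipitation. Genotypes are masked missing at `missing_rate`, and
#' sites monomorphic in the realized sample are dropped.
#'
#' @param config A [sim_config()].
#' @param samples,annotation,env Optional precomputed pieces (built from
#'   `config` when `NULL`). Annotation enables selection-target planting; env
#'   enables environment-associated SNP planting.
#' @return List with `genotypes` (a [genotypes()] object) and `truth`, a list
#'   holding the per-SNP truth tibble (`snp_id, chrom, pos, class, p_anc,
#'   p_A, p_B`), planted island regions and planted id vectors.
#' @export
simulate_genotypes <- function(config, samples = NULL, annotation = NULL,
                               env = NULL) {
  samples <- samples %||% simulate_samples(config)
  substream(config, 37L)
  n_A <- sum(samples$species == samples$species[1])
  n_B <- nrow(samples) - n_A
  block_bp <- 20000
  psg_genes <- NULL
  if (!is.null(annotation)) {
    psg_genes <- annotation$genes %>% dplyr::filter(gene_id %in% annotation$psg_ids)
  }

  all_sites <- list()
  for (ch in chrom_names(config)) {
    n_sites <- round(config$chrom_length_bp * config$snp_density)
    pos <- sort(sample.int(config$chrom_length_bp, n_sites))
    isl <- in_regions(ch, pos, config$island_regions)
    # linked selection strips diversity: thin island segregating sites
    if (config$island_snp_thinning < 1) {
      drop <- isl & runif(n_sites) > config$island_snp_thinning
      pos <- pos[!drop]; isl <- isl[!drop]
      n_sites <- length(pos)
    }
    psg <- if (is.null(psg_genes)) rep(FALSE, n_sites) else
      in_regions(ch, pos, psg_genes) & runif(n_sites) < config$psg_fixed_rate
    fixed <- !isl & !psg & runif(n_sites) < config$fixed_diff_frac
    class <- dplyr::case_when(psg ~ "psg_fixed", fixed ~ "fixed",
                              isl ~ "island", TRUE ~ "background")
    p_anc <- rtruncbeta(n_sites)
    Fpar <- ifelse(isl, config$island_fst, config$background_fst)
    pA <- rbeta(n_sites, p_anc * (1 - Fpar) / Fpar,
                (1 - p_anc) * (1 - Fpar) / Fpar)
    pB <- rbeta(n_sites, p_anc * (1 - Fpar) / Fpar,
                (1 - p_anc) * (1 - Fpar) / Fpar)
    flip <- runif(n_sites) < 0.5
    pA[fixed | psg] <- as.numeric(flip[fixed | psg])
    pB[fixed | psg] <- as.numeric(!flip[fixed | psg])
    all_sites[[ch]] <- tibble::tibble(chrom = ch, pos = pos, class = class,
                                      p_anc = p_anc, p_A = pA, p_B = pB)
  }
  sites <- dplyr::bind_rows(all_sites)

  # founder-haplotype sampling per 20-kb block and species
  dosage <- matrix(NA_integer_, nrow(sites), n_A + n_B)
  truth_A <- truth_B <- numeric(nrow(sites))
  draw_block <- function(p_s, n_dip, K) {
    m <- length(p_s)
    if (!is.finite(K)) {
      dos <- matrix(rbinom(n_dip * m, 2L, rep(p_s, each = n_dip)), n_dip, m)
      return(list(dos = dos, pool = p_s))
    }
    founders <- matrix(rbinom(K * m, 1L, rep(p_s, each = K)), K, m)
    i1 <- sample.int(K, n_dip, replace = TRUE)
    i2 <- sample.int(K, n_dip, replace = TRUE)
    list(dos = founders[i1, , drop = FALSE] + founders[i2, , drop = FALSE],
         pool = colMeans(founders))
  }
  for (ch in chrom_names(config)) {
    on_ch <- which(sites$chrom == ch)
    if (!length(on_ch)) next
    block <- (sites$pos[on_ch] - 1) %/% block_bp
    for (b in unique(block)) {
      idx <- on_ch[block == b]
      mid <- (b + 0.5) * block_bp
      K <- if (in_regions(ch, mid, config$island_regions))
        config$founder_k_island else config$founder_k_background
      ba <- draw_block(sites$p_A[idx], n_A, K)
      bb <- draw_block(sites$p_B[idx], n_B, K)
      dosage[idx, seq_len(n_A)] <- t(ba$dos)
      dosage[idx, n_A + seq_len(n_B)] <- t(bb$dos)
      truth_A[idx] <- ba$pool
      truth_B[idx] <- bb$pool
    }
  }

  # plant environment-associated SNPs: dosage is a discretized noisy copy of AP
  env_ids <- integer(0)
  if (!is.null(env) && config$n_env_snps > 0) {
    eligible <- which(sites$class == "background")
    env_ids <- sort(sample(eligible, min(config$n_env_snps, length(eligible))))
    z_ap <- as.numeric(scale(env$AP[match(samples$sample_id, env$sample_id)]))
    for (i in env_ids) {
      latent <- 0.95 * z_ap + sqrt(1 - 0.95^2) * rnorm(length(z_ap))
      dosage[i, ] <- findInterval(latent, c(-0.6, 0.6))
      truth_A[i] <- mean(dosage[i, seq_len(n_A)]) / 2
      truth_B[i] <- mean(dosage[i, n_A + seq_len(n_B)]) / 2
    }
    sites$class[env_ids] <- "env"
  }

  if (config$missing_rate > 0) {
    dosage[runif(length(dosage)) < config$missing_rate] <- NA_integer_
  }

  # drop sites monomorphic (or entirely missing) in the realized sample
  nm <- rowSums(!is.na(dosage))
  ac <- rowSums(dosage, na.rm = TRUE)
  keep <- nm > 0 & ac > 0 & ac < 2 * nm
  dosage <- dosage[keep, , drop = FALSE]
  sites <- sites[keep, , drop = FALSE]
  truth_A <- truth_A[keep]; truth_B <- truth_B[keep]

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nrow(sites), replace = TRUE)
  alt <- sample(bases[-1], nrow(sites), replace = TRUE)
  alt <- ifelse(alt == ref, "A", alt)
  sites$snp_id <- sprintf("%s_%d", sites$chrom, sites$pos)

  g <- genotypes(
    dosage,
    tibble::tibble(snp_id = sites$snp_id, chrom = sites$chrom, pos = sites$pos,
                   ref = ref, alt = alt),
    samples
  )
  truth <- list(
    snps = tibble::tibble(snp_id = sites$snp_id, chrom = sites$chrom,
                          pos = sites$pos, class = sites$class,
                          p_anc = sites$p_anc, p_A = truth_A, p_B = truth_B),
    islands = config$island_regions,
    psg_ids = if (is.null(annotation)) character(0) else annotation$psg_ids,
    env_snp_ids = sites$snp_id[sites$class == "env"]
  )
  list(genotypes = g, truth = truth)
}

#' Simulate per-individual CNV segments
#'
#' A `cng_frac` share of genes carries copy-number variation somewhere;
#' `n_cndg` of those are planted as copy-number differentiated (species means
#' 2 vs 4 with light integer noise), the rest get sporadic CN 1/3 deviations
#' at `cnv_noise_rate` per individual, species-blind. Segments cover the gene
#' exactly, so downstream overlap-weighted gene copy numbers reproduce the
#' intended values; individuals at baseline CN 2 emit no segment.
#'
#' @param config A [sim_config()].
#' @param annotation From [simulate_annotation()].
#' @param samples From [simulate_samples()].
#' @return List with `segments` (tibble `sample_id, chrom, start, end,
#'   copy_number`), `cndg_ids`, `cng_ids` and `cn_truth` (tibble
#'   `gene_id, sample_id, copy_number`).
#' @export
simulate_cnv <- function(config, annotation = NULL, samples = NULL) {
  annotation <- annotation %||% simulate_annotation(config)
  samples <- samples %||% simulate_samples(config)
  substream(config, 53L)
  genes <- annotation$genes
  n_cng <- max(config$n_cndg, round(config$cng_frac * nrow(genes)))
  cng_ids <- sort(sample(genes$gene_id, min(n_cng, nrow(genes))))
  cndg_ids <- sort(sample(cng_ids, config$n_cndg))
  is_A <- samples$species == samples$species[1]
  n <- nrow(samples)

  cn <- purrr::map_dfr(cng_ids, function(gid) {
    if (gid %in% cndg_ids) {
      base <- ifelse(is_A, 2L, 4L)
      noise <- sample(c(-1L, 0L, 1L), n, replace = TRUE, prob = c(.1, .8, .1))
      val <- pmax(0L, base + noise)
    } else {
      val <- rep(2L, n)
      hit <- runif(n) < config$cnv_noise_rate
      if (!any(hit)) hit[sample.int(n, 1)] <- TRUE
      val[hit] <- sample(c(1L, 3L), sum(hit), replace = TRUE)
    }
    tibble::tibble(gene_id = gid, sample_id = samples$sample_id,
                   copy_number = val)
  })
  segments <- cn %>%
    dplyr::filter(copy_number != 2L) %>%
    dplyr::left_join(genes, by = "gene_id") %>%
    dplyr::select(sample_id, chrom, start, end, copy_number) %>%
    dplyr::arrange(sample_id, chrom, start)
  list(segments = segments, cndg_ids = cndg_ids, cng_ids = cng_ids,
       cn_truth = cn)
}

#' Simulate a complete two-species dataset
#'
#' Orchestrates [simulate_samples()], [simulate_env()],
#' [simulate_annotation()], [simulate_genotypes()] and [simulate_cnv()] under
#' one seed, optionally writing the standard file bundle (VCF, samples.tsv,
#' env.tsv, genes.bed, nonsyn.tsv, cnv/<sample>.tsv, truth files) to `dir`.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; created if needed.
#' @return List with `genotypes`, `samples`, `env`, `annotation`, `cnv`,
#'   `truth` and the `config`, invisibly carrying `dir` when written.
#' @export
simulate_divergence_data <- function(config, dir = NULL) {
  samples <- simulate_samples(config)
  env <- simulate_env(config, samples)
  annotation <- simulate_annotation(config)
  gen <- simulate_genotypes(config, samples, annotation, env)
  cnv <- simulate_cnv(config, annotation, samples)
  truth <- gen$truth
  truth$cndg_ids <- cnv$cndg_ids
  truth$cng_ids <- cnv$cng_ids
  out <- list(genotypes = gen$genotypes, samples = samples, env = env,
              annotation = annotation, cnv = cnv, truth = truth,
              config = config)
  if (!is.null(dir)) write_dataset(out, dir)
  out
}
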