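# In-code fixtures: toy genotype tables and small simulation configs.

# build a genotypes object from a sites x samples dosage matrix
toy_genotypes <- function(dosage, n_A, pos = NULL, chrom = "Chr01",
                          populations = NULL) {
  n <- ncol(dosage)
  pos <- pos %||% (seq_len(nrow(dosage)) * 10L)
  samples <- tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n)),
    species = rep(c("spA", "spB"), c(n_A, n - n_A)),
    population = populations %||% rep(c("p1", "p2"), c(n_A, n - n_A)),
    lat = rep(c(35, 26), c(n_A, n - n_A)),
    lon = seq(100, 118, length.out = n)
  )
  snps <- tibble::tibble(
    snp_id = sprintf("%s_%d", chrom, pos), chrom = chrom, pos = pos,
    ref = "A", alt = "T"
  )
  genotypes(dosage, snps, samples)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# small fast config for module tests
tiny_config <- function(seed = 1, ...) {
  sim_config(
    seed = seed, n_chromosomes = 2, chrom_length_bp = 4e5,
    snp_density = 0.003,
    island_regions = tibble::tibble(chrom = "Chr01",
                                    start = 200001, end = 230000),
    n_genes = 80, n_psg = 6, n_cndg = 5, n_env_snps = 8,
    ...
  )
}
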