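# Synthetic-data generator: determinism, planted structure, validity.

test_that("identical config and seed give byte-identical outputs", {
  cfg <- tiny_config(seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_divergence_data(cfg, dir = d1)
  simulate_divergence_data(cfg, dir = d2)
  for (f in c("genotypes.vcf", "samples.tsv", "env.tsv", "genes.bed",
              "nonsyn.tsv", "truth_snps.tsv", "truth.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  segs <- sort(list.files(file.path(d1, "cnv")))
  expect_identical(segs, sort(list.files(file.path(d2, "cnv"))))
  for (f in segs) {
    expect_identical(unname(tools::md5sum(file.path(d1, "cnv", f))),
                     unname(tools::md5sum(file.path(d2, "cnv", f))))
  }
})

test_that("config validation rejects impossible designs", {
  expect_error(sim_config(background_fst = 0), "0, 1")
  expect_error(sim_config(island_fst = 1), "0, 1")
  expect_error(sim_config(background_fst = 0.5, island_fst = 0.3), "exceed")
  expect_error(sim_config(missing_rate = 0.5), "missing_rate")
  expect_error(
    sim_config(island_regions = tibble::tibble(chrom = "Chr01",
                                               start = 5e5, end = 2e6)),
    "bounds")
  expect_error(
    sim_config(n_chromosomes = 1,
               island_regions = tibble::tibble(chrom = "Chr09",
                                               start = 1, end = 100)),
    "not in genome")
})

test_that("missing_rate 0 yields a VCF without missing genotypes", {
  cfg <- tiny_config(seed = 3, missing_rate = 0)
  ds <- simulate_divergence_data(cfg)
  d <- withr::local_tempdir()
  write_vcf(ds$genotypes, file.path(d, "g.vcf"))
  expect_false(any(grepl("\\./\\.", readLines(file.path(d, "g.vcf")))))
})

test_that("every planted id exists in the emitted data", {
  ds <- simulate_divergence_data(tiny_config(seed = 7))
  expect_true(all(ds$truth$psg_ids %in% ds$annotation$genes$gene_id))
  expect_true(all(ds$truth$cndg_ids %in% ds$annotation$genes$gene_id))
  expect_true(all(ds$truth$env_snp_ids %in% ds$genotypes$snps$snp_id))
  expect_true(all(ds$truth$snps$snp_id == ds$genotypes$snps$snp_id))
})

test_that("gene models are sorted, non-overlapping, in bounds, with intergenic room", {
  cfg <- tiny_config(seed = 11)
  ann <- simulate_annotation(cfg)
  for (ch in unique(ann$genes$chrom)) {
    gch <- dplyr::filter(ann$genes, chrom == ch)
    expect_false(is.unsorted(gch$start))
    expect_true(all(gch$start[-1] > head(gch$end, -1)))
    expect_true(all(gch$start >= 1 & gch$end <= cfg$chrom_length_bp))
    intergenic <- 1 - sum(gch$end - gch$start + 1) / cfg$chrom_length_bp
    expect_gte(intergenic, cfg$min_intergenic_frac)
  }
  psg_nonsyn <- ann$nonsyn$nonsyn[ann$nonsyn$gene_id %in% ann$psg_ids]
  expect_true(all(psg_nonsyn >= 2))
})

test_that("realized island F_ST exceeds background on the truth frequencies", {
  # Hudson ratio-of-averages oracle computed directly from the emitted
  # per-species truth frequencies, over repeated seeds
  for (seed in 1:10) {
    cfg <- sim_config(seed = seed, n_chromosomes = 1, chrom_length_bp = 2.4e6,
                      snp_density = 0.005, island_snp_thinning = 1,
                      fixed_diff_frac = 0,
                      island_regions = tibble::tibble(chrom = "Chr01",
                                                      start = 1, end = 1.1e6))
    gen <- simulate_genotypes(cfg)
    tr <- gen$truth$snps
    isl <- tr$class == "island"
    expect_gte(sum(isl), 2000)
    expect_gte(sum(!isl), 2000)
    expect_gt(hudson_fst_truth(tr$p_A[isl], tr$p_B[isl]),
              hudson_fst_truth(tr$p_A[!isl], tr$p_B[!isl]))
  }
})

test_that("sample allele frequencies converge to the truth frequencies", {
  cfg <- sim_config(seed = 5, n_chromosomes = 1, chrom_length_bp = 1e6,
                    snp_density = 0.0025, n_samples_A = 500, n_samples_B = 4,
                    missing_rate = 0, fixed_diff_frac = 0,
                    island_regions = tibble::tibble(chrom = character(),
                                                    start = numeric(),
                                                    end = numeric()))
  gen <- simulate_genotypes(cfg)
  is_A <- gen$genotypes$samples$species == "speciesA"
  freq <- rowMeans(gen$genotypes$dosage[, is_A]) / 2
  err <- abs(freq - gen$truth$snps$p_A)
  expect_gte(mean(err <= 0.05), 0.99)
})

test_that("species-separated AP predictor is detectable by a t test", {
  hits <- 0
  for (seed in 1:20) {
    cfg <- tiny_config(seed = seed)
    samples <- simulate_samples(cfg)
    env <- simulate_env(cfg, samples)
    p <- t.test(env$AP[samples$species == "speciesA"],
                env$AP[samples$species == "speciesB"])$p.value
    hits <- hits + (p < 0.01)
  }
  expect_gte(hits, 19)  # separation of 3 SDs: essentially always detected
})

test_that("exactly one collinear predictor pair is planted and filtered", {
  cfg <- tiny_config(seed = 9)
  env <- simulate_env(cfg)
  cm <- abs(cor(as.matrix(env[, -1])))
  diag(cm) <- 0
  expect_equal(sum(cm >= 0.7) / 2, 1)  # one pair at |r| >= .7
  pair <- which(cm >= 0.7, arr.ind = TRUE)
  pair_names <- sort(unique(rownames(pair)))
  filtered <- filter_predictors(env)
  expect_equal(sum(pair_names %in% names(filtered)), 1)
  expect_setequal(setdiff(names(env), names(filtered)),
                  setdiff(pair_names, names(filtered)))
})

test_that("CNV generator plants species-differentiated copy numbers", {
  cfg <- tiny_config(seed = 13)
  samples <- simulate_samples(cfg)
  ann <- simulate_annotation(cfg)
  cnv <- simulate_cnv(cfg, ann, samples)
  is_A <- samples$species == "speciesA"
  for (gid in cnv$cndg_ids) {
    cn <- cnv$cn_truth[cnv$cn_truth$gene_id == gid, ]
    cn <- cn[match(samples$sample_id, cn$sample_id), ]
    expect_gte(abs(mean(cn$copy_number[is_A]) - mean(cn$copy_number[!is_A])),
               1.5)
  }
  # non-CNDG genes are species-blind by construction
  other <- setdiff(cnv$cng_ids, cnv$cndg_ids)
  cn <- cnv$cn_truth[cnv$cn_truth$gene_id %in% other, ]
  expect_lt(abs(mean(cn$copy_number) - 2), 0.3)
})
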