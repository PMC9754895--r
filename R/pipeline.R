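# One-call orchestration of the full scan with input validation and a
# reproducibility manifest.

#' Validate an input file bundle
#'
#' Checks that the VCF's samples are covered by the metadata (and vice
#' versa), that exactly two species labels are present, that coordinates are
#' sorted, and that the environmental table covers all samples. Collects all
#' violations rather than stopping at the first.
#'
#' @param dataset A list as returned by [simulate_divergence_data()], or a
#'   list of paths (`vcf, samples, env, genes, nonsyn, cnv_dir`) to load.
#' @return Tibble `check, ok, detail`; all-`ok` for a clean bundle.
#' @export
validate_inputs <- function(dataset) {
  if (!is.null(dataset$vcf) && is.character(dataset$vcf)) {
    samples <- read_samples_tsv(dataset$samples)
    g <- tryCatch(read_genotypes(dataset$vcf, samples), error = identity)
    env <- readr::read_tsv(dataset$env, show_col_types = FALSE)
    dataset <- list(genotypes = g, samples = samples, env = env)
  }
  g <- dataset$genotypes
  issues <- list()
  add <- function(check, ok, detail = "") {
    issues[[length(issues) + 1]] <<- tibble::tibble(check = check, ok = ok,
                                                    detail = detail)
  }
  if (inherits(g, "error")) {
    add("vcf_readable", FALSE, conditionMessage(g))
  } else {
    miss <- setdiff(g$samples$sample_id, dataset$samples$sample_id)
    add("vcf_samples_in_metadata", length(miss) == 0,
        paste(miss, collapse = ", "))
    nsp <- dplyr::n_distinct(dataset$samples$species)
    add("two_species_labels", nsp == 2, sprintf("%d labels found", nsp))
    sorted <- all(tapply(g$snps$pos, g$snps$chrom,
                         function(p) !is.unsorted(p, strictly = TRUE)))
    add("positions_sorted", sorted)
    if (!is.null(dataset$env)) {
      miss_env <- setdiff(g$samples$sample_id, dataset$env$sample_id)
      add("env_covers_samples", length(miss_env) == 0,
          paste(miss_env, collapse = ", "))
    }
  }
  dplyr::bind_rows(issues)
}

#' Run the full divergence scan
#'
#' Executes windows -> island scan -> CNV/V_ST -> HKA -> RDA -> Mantel on a
#' dataset bundle, writing result tables and a `manifest.json` (parameters,
#' seed, md5 of every output) when `out_dir` is given. Stage parameters
#' mirror the individual functions' defaults and can be overridden through
#' `params` (a named list, e.g. from [yaml::read_yaml()]).
#'
#' @param dataset Output of [simulate_divergence_data()] or a compatible
#'   list (`genotypes, samples, env, annotation, cnv`).
#' @param params Named list of overrides, or the path to a YAML file holding
#'   them: `window_bp, step_bp, min_snps,
#'   top_fraction, n_perm_islands, fdr, top_fraction_cnv, n_perm_cnv,
#'   alpha_cnv, alpha_hka, prune_r2, sd_mult, n_perm_rda, alpha_rda,
#'   n_perm_mantel, run_cnv, run_rda`.
#' @param seed Integer seed funnelled to every stochastic stage.
#' @param out_dir Optional output directory.
#' @return List with `windows, islands, island_tests, vst, psg,
#'   psg_island_enrichment, rda, rda_axes, rda_outliers, mantel, params`.
#' @export
run_pipeline <- function(dataset, params = list(), seed = 1L,
                         out_dir = NULL) {
  defaults <- list(window_bp = 20000, step_bp = 5000, min_snps = 10,
                   top_fraction = 0.01, n_perm_islands = 10000, fdr = 0.01,
                   top_fraction_cnv = 0.05, n_perm_cnv = 1000,
                   alpha_cnv = 0.01, alpha_hka = 0.01, prune_r2 = 0.4,
                   sd_mult = 3, n_perm_rda = 999, alpha_rda = 0.01,
                   n_perm_mantel = 999, run_cnv = TRUE, run_rda = TRUE)
  if (is.character(params)) params <- yaml::read_yaml(params)
  p <- utils::modifyList(defaults, params)
  val <- validate_inputs(dataset)
  if (!all(val$ok)) {
    abort(paste("invalid inputs:\n",
                paste(sprintf("%s: %s", val$check[!val$ok],
                              val$detail[!val$ok]), collapse = "\n ")))
  }
  g <- dataset$genotypes
  res <- list(params = p, seed = seed)

  win <- window_stats(g, p$window_bp, p$step_bp, p$min_snps)
  scored <- call_outliers(win, top_fraction = p$top_fraction,
                          n_perm = p$n_perm_islands, fdr = p$fdr, seed = seed)
  islands <- merge_islands(scored)
  res$windows <- scored
  res$islands <- islands
  res$island_tests <- if (nrow(islands))
    island_background_tests(scored, islands) else NULL

  if (isTRUE(p$run_cnv) && !is.null(dataset$cnv)) {
    cn_tbl <- gene_copy_numbers(dataset$cnv$segments,
                                dataset$annotation$genes, dataset$samples)
    res$cn_table <- cn_tbl
    res$vst <- suppressWarnings(
      call_cndg(cn_tbl, p$top_fraction_cnv, p$n_perm_cnv, p$alpha_cnv,
                seed = seed))
  }

  res$psg <- suppressWarnings(
    call_psg(g, dataset$annotation$genes, dataset$annotation$nonsyn,
             alpha = p$alpha_hka, sites = attr(win, "sites")))
  if (nrow(islands)) {
    res$psg_island_enrichment <- tryCatch(
      island_enrichment(res$psg, islands, dataset$annotation$genes),
      error = function(e) NULL)
  }

  if (isTRUE(p$run_rda) && !is.null(dataset$env)) {
    envf <- filter_predictors(dataset$env)
    kept <- ld_prune(g, r2_threshold = p$prune_r2)
    gp <- subset_genotypes(g, snp_ids = kept)
    resp <- impute_dosage(gp)
    fit <- fit_rda(resp, envf)
    ax <- test_axes(fit, n_perm = p$n_perm_rda, alpha = p$alpha_rda,
                    seed = seed)
    sig <- ax$axis[which(ax$significant)]
    if (!length(sig)) sig <- ax$axis[1]
    out <- suppressWarnings(
      call_outlier_variants(fit, sig, envf, sd_mult = p$sd_mult))
    res$rda <- fit
    res$rda_axes <- ax
    res$rda_outliers <- out
    # Mantel against a neutral intergenic set
    genic <- dplyr::inner_join(
      g$snps, dplyr::select(dataset$annotation$genes, chrom,
                            gstart = start, gend = end),
      by = dplyr::join_by(chrom, between(pos, gstart, gend)))
    neutral <- setdiff(g$snps$snp_id, genic$snp_id)
    sets <- list(neutral_intergenic = neutral)
    if (nrow(out)) sets$env_associated <- out$variant
    res$mantel <- tryCatch(
      suppressWarnings(mantel_ibd_ibe(g, envf, sets,
                                      n_perm = p$n_perm_mantel, seed = seed)),
      error = function(e) NULL)
  }

  if (!is.null(out_dir)) res$manifest <- write_run_outputs(res, out_dir)
  res
}

# write result tables + manifest.json; returns the manifest
write_run_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    if (is.null(x)) return(NULL)
    path <- file.path(out_dir, name)
    readr::write_tsv(x, path)
    path
  }
  paths <- c(
    wr(dplyr::select(res$windows, -dplyr::any_of("new_run")), "windows.tsv"),
    wr(res$islands, "islands.tsv"),
    wr(res$vst, "vst.tsv"),
    wr(res$psg, "psg.tsv"),
    wr(res$rda_outliers, "rda_outliers.tsv"),
    wr(res$mantel, "mantel.tsv")
  )
  if (!is.null(res$islands) && nrow(res$islands)) {
    bedpath <- file.path(out_dir, "islands.bed")
    readr::write_tsv(
      tibble::tibble(chrom = res$islands$chrom,
                     start = res$islands$start - 1,
                     end = res$islands$end,
                     name = res$islands$region_id),
      bedpath, col_names = FALSE)
    paths <- c(paths, bedpath)
  }
  manifest <- list(
    seed = res$seed,
    params = res$params,
    outputs = lapply(setNames(nm = basename(paths)), function(b)
      unname(tools::md5sum(file.path(out_dir, b))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
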