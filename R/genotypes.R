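#' Genotype table container
#'
#' Bundles biallelic SNP genotypes with sample metadata: a `samples` tibble
#' (`sample_id, species, population, lat, lon`), a `snps` tibble
#' (`snp_id, chrom, pos, ref, alt`; `pos` 1-based, strictly increasing within
#' chromosome), and an integer dosage matrix (`snps x samples`, values 0/1/2
#' counting alternate alleles, `NA` = missing).
#'
#' @param dosage Integer matrix, sites in rows, samples in columns.
#' @param snps Tibble of site records matching the rows of `dosage`.
#' @param samples Tibble of sample metadata matching the columns; `species`
#'   must take exactly two values.
#' @return An object of class `divscan_genotypes`.
#' @export
genotypes <- function(dosage, snps, samples) {
  snps <- tibble::as_tibble(snps)
  samples <- tibble::as_tibble(samples)
  stopifnot(nrow(snps) == nrow(dosage), nrow(samples) == ncol(dosage))
  if (!all(c("snp_id", "chrom", "pos") %in% names(snps)))
    abort("snps must have snp_id, chrom, pos")
  if (!all(c("sample_id", "species") %in% names(samples)))
    abort("samples must have sample_id, species")
  if (dplyr::n_distinct(samples$species) != 2L)
    abort("species labels must partition samples into exactly two groups")
  ok <- snps %>%
    dplyr::group_by(chrom) %>%
    dplyr::summarise(sorted = !is.unsorted(pos, strictly = TRUE), .groups = "drop")
  if (!all(ok$sorted))
    abort("positions must be strictly increasing within each chromosome")
  if (length(rle(snps$chrom)$values) != dplyr::n_distinct(snps$chrom))
    abort("rows of the same chromosome must be contiguous")
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) abort("dosages must be 0, 1, 2 or NA")
  dimnames(dosage) <- list(snps$snp_id, samples$sample_id)
  structure(list(dosage = dosage, snps = snps, samples = samples),
            class = "divscan_genotypes")
}

#' @export
print.divscan_genotypes <- function(x, ...) {
  sp <- table(x$samples$species)
  cat(sprintf("<divscan_genotypes> %s SNPs x %d samples (%s)\n",
              format(nrow(x$snps), big.mark = ","), nrow(x$samples),
              paste(sprintf("%s: %d", names(sp), sp), collapse = ", ")))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$snps$chrom), collapse = ", ")))
  invisible(x)
}

#' @export
dim.divscan_genotypes <- function(x) dim(x$dosage)

# species labels in stable order: first label in sample order = "A" side
species_levels <- function(g) {
  unique(g$samples$species)
}

# logical index of samples belonging to each of the two species
species_index <- function(g) {
  lv <- species_levels(g)
  list(A = g$samples$species == lv[1], B = g$samples$species == lv[2],
       labels = lv)
}

#' Subset a genotype table
#'
#' @param g A [genotypes()] object.
#' @param snp_ids Optional SNP ids to keep (order preserved as stored).
#' @param sample_ids Optional sample ids to keep.
#' @return A `divscan_genotypes` object.
#' @export
subset_genotypes <- function(g, snp_ids = NULL, sample_ids = NULL) {
  keep_r <- if (is.null(snp_ids)) rep(TRUE, nrow(g$snps)) else g$snps$snp_id %in% snp_ids
  keep_c <- if (is.null(sample_ids)) rep(TRUE, nrow(g$samples)) else g$samples$sample_id %in% sample_ids
  genotypes(g$dosage[keep_r, keep_c, drop = FALSE],
            g$snps[keep_r, , drop = FALSE],
            g$samples[keep_c, , drop = FALSE])
}
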