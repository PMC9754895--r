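# Readers/writers for the standard file bundle. In-memory coordinates are
# 1-based inclusive; BED exports are 0-based half-open.

#' Write genotypes to a VCF file
#'
#' Minimal VCFv4.2, one ALT per record, GT-only FORMAT, unphased genotypes,
#' missing written as `./.`. Output is deterministic for a fixed object.
#'
#' @param g A [genotypes()] object.
#' @param path Output path (plain text).
#' @param chrom_lengths Optional named vector for `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path, chrom_lengths = NULL) {
  gtmap <- c("0/0", "0/1", "1/1")
  d <- g$dosage
  gt <- matrix(ifelse(is.na(d), "./.", gtmap[d + 1L]), nrow(d), ncol(d))
  hdr <- c("##fileformat=VCFv4.2", "##source=divscan",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(chrom_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(chrom_lengths), as.integer(chrom_lengths)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", g$samples$sample_id),
                      collapse = "\t"))
  ref <- g$snps$ref %||% rep("A", nrow(g$snps))
  alt <- g$snps$alt %||% rep("T", nrow(g$snps))
  cols <- c(list(g$snps$chrom, g$snps$pos, g$snps$snp_id, ref, alt,
                 ".", "PASS", ".", "GT"),
            lapply(seq_len(ncol(gt)), function(j) gt[, j]))
  body <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genotypes from a VCF plus sample metadata
#'
#' Parses biallelic diploid GT fields into a 0/1/2 dosage matrix. Multiallelic
#' or non-SNP records are dropped with a message.
#'
#' @param vcf_path Path to a VCF (optionally gzipped).
#' @param samples Sample metadata: a tibble or a TSV path with columns
#'   `sample_id, species, population, lat, lon`.
#' @return A [genotypes()] object with samples ordered as in the VCF.
#' @export
read_genotypes <- function(vcf_path, samples) {
  if (is.character(samples)) samples <- read_samples_tsv(samples)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v),
                                         stringsAsFactors = FALSE))
  keep <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1 & nchar(fix$ALT) == 1
  if (!all(keep)) {
    inform(sprintf("dropping %d non-biallelic-SNP records", sum(!keep)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  alleles <- gsub("[|]", "/", gt)
  dos[alleles %in% c("0/0")] <- 0L
  dos[alleles %in% c("0/1", "1/0")] <- 1L
  dos[alleles %in% c("1/1")] <- 2L
  snps <- tibble::tibble(
    snp_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                    sprintf("%s_%s", fix$CHROM, fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT
  )
  samples <- samples[match(colnames(gt), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id))
    abort("VCF contains samples absent from the metadata table")
  genotypes(dos, snps, samples)
}

#' @rdname read_samples_tsv
#' @param samples Tibble to write.
#' @export
write_samples_tsv <- function(samples, path) {
  readr::write_tsv(samples, path)
  invisible(path)
}

#' Read or write the sample metadata TSV
#'
#' Columns: `sample_id, species, population, lat, lon`.
#'
#' @param path File path.
#' @return A tibble ([read_samples_tsv()]) or `path` invisibly.
#' @export
read_samples_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(sample_id = "c", species = "c",
                                          population = "c", .default = "d"))
}

#' Write/read gene models as BED (0-based half-open)
#'
#' In-memory gene tibbles use 1-based inclusive `start, end`; on disk the BED
#' convention applies (`start0 = start - 1`).
#'
#' @param genes Tibble `gene_id, chrom, start, end` (1-based inclusive).
#' @param path File path.
#' @return `path` invisibly, or the genes tibble.
#' @export
write_genes_bed <- function(genes, path) {
  readr::write_tsv(
    tibble::tibble(chrom = genes$chrom, start = genes$start - 1L,
                   end = genes$end, name = genes$gene_id),
    path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_genes_bed
#' @export
read_genes_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start0", "end", "name"),
                         show_col_types = FALSE,
                         col_types = readr::cols("c", "i", "i", "c"))
  tibble::tibble(gene_id = bed$name, chrom = bed$chrom,
                 start = bed$start0 + 1L, end = bed$end)
}

#' Write a simulated dataset bundle to disk
#'
#' Emits `genotypes.vcf`, `samples.tsv`, `env.tsv`, `genes.bed`,
#' `nonsyn.tsv`, `cnv/<sample>.tsv` (1-based inclusive segment coordinates)
#' and machine-readable truth (`truth.json` for planted ids and islands,
#' `truth_snps.tsv` for per-SNP frequencies).
#'
#' @param dataset Output of [simulate_divergence_data()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "cnv"), showWarnings = FALSE)
  cl <- setNames(rep(dataset$config$chrom_length_bp,
                     dataset$config$n_chromosomes),
                 chrom_names(dataset$config))
  write_vcf(dataset$genotypes, file.path(dir, "genotypes.vcf"), cl)
  write_samples_tsv(dataset$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(dataset$env, file.path(dir, "env.tsv"))
  write_genes_bed(dataset$annotation$genes, file.path(dir, "genes.bed"))
  readr::write_tsv(dataset$annotation$nonsyn, file.path(dir, "nonsyn.tsv"))
  for (s in unique(dataset$cnv$segments$sample_id)) {
    seg <- dataset$cnv$segments %>%
      dplyr::filter(sample_id == s) %>%
      dplyr::select(chrom, start, end, copy_number)
    readr::write_tsv(seg, file.path(dir, "cnv", paste0(s, ".tsv")))
  }
  readr::write_tsv(dataset$truth$snps, file.path(dir, "truth_snps.tsv"))
  jsonlite::write_json(
    list(islands = dataset$truth$islands, psg_ids = dataset$truth$psg_ids,
         cndg_ids = dataset$truth$cndg_ids, cng_ids = dataset$truth$cng_ids,
         env_snp_ids = dataset$truth$env_snp_ids,
         seed = dataset$config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read per-individual CNV segment files
#'
#' One TSV per sample (`chrom, start, end, copy_number`, 1-based inclusive)
#' named `<sample_id>.tsv`.
#'
#' @param dir Directory containing the per-sample TSVs.
#' @return Tibble `sample_id, chrom, start, end, copy_number`.
#' @export
read_cnv_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  purrr::map_dfr(files, function(f) {
    readr::read_tsv(f, show_col_types = FALSE,
                    col_types = readr::cols(chrom = "c", .default = "d")) %>%
      dplyr::mutate(sample_id = sub("\\.tsv$", "", basename(f)), .before = 1)
  })
}
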