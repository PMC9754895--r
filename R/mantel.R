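# Isolation by distance / environment: pairwise population F_ST, linearized
# F_ST/(1 - F_ST), haversine geographic and Euclidean environmental distance
# matrices, and the Mantel permutation test (exhaustive for small n).

#' Pairwise population F_ST matrix
#'
#' Weir-Cockerham ratio-of-sums F_ST between every pair of populations over a
#' SNP subset, treating each population as one group.
#'
#' @param g A [genotypes()] object (populations from `samples$population`).
#' @param snp_ids Optional SNP subset.
#' @param min_n Minimum non-missing diploids per population at a site.
#' @return Symmetric matrix of pairwise F_ST (zero diagonal); negative
#'   ratio-of-sums values are retained.
#' @export
pop_fst_matrix <- function(g, snp_ids = NULL, min_n = 2) {
  if (!is.null(snp_ids)) g <- subset_genotypes(g, snp_ids = snp_ids)
  pops <- sort(unique(g$samples$population))
  np <- length(pops)
  m <- matrix(0, np, np, dimnames = list(pops, pops))
  d <- g$dosage
  stats_by_pop <- lapply(pops, function(p) {
    dp <- d[, g$samples$population == p, drop = FALSE]
    n <- rowSums(!is.na(dp))
    list(n = n, p = rowSums(dp, na.rm = TRUE) / (2 * n),
         h = rowSums(dp == 1L, na.rm = TRUE) / n)
  })
  names(stats_by_pop) <- pops
  for (i in seq_len(np - 1)) {
    for (j in seq(i + 1, np)) {
      si <- stats_by_pop[[i]]; sj <- stats_by_pop[[j]]
      ok <- si$n >= min_n & sj$n >= min_n
      comp <- wc_components(si$n[ok], si$p[ok], si$h[ok],
                            sj$n[ok], sj$p[ok], sj$h[ok])
      denom <- sum(comp$abc, na.rm = TRUE)
      m[i, j] <- m[j, i] <-
        if (denom > 0) sum(comp$a, na.rm = TRUE) / denom else NA_real_
    }
  }
  m
}

#' Linearize an F_ST matrix
#'
#' `F_ST / (1 - F_ST)` elementwise; pairs at F_ST = 1 become `NA` with a
#' warning (infinite linearized distance) and are dropped from Mantel tests.
#'
#' @param fst_m Square F_ST matrix.
#' @return Matrix of linearized values.
#' @export
linearize_fst <- function(fst_m) {
  if (any(fst_m == 1, na.rm = TRUE))
    warn("F_ST = 1 pair(s): linearization infinite, excluded")
  out <- ifelse(fst_m == 1, NA_real_, fst_m / (1 - fst_m))
  diag(out) <- 0
  out
}

#' Haversine great-circle distance matrix (km)
#'
#' Great-circle distances on a sphere of radius 6371 km.
#'
#' @param coords Tibble with `lat, lon` (decimal degrees) and an id column
#'   (first non-coordinate column used for dimnames).
#' @return Symmetric distance matrix in km.
#' @export
geo_dist_km <- function(coords) {
  idcol <- setdiff(names(coords), c("lat", "lon"))[1]
  m <- geosphere::distm(cbind(coords$lon, coords$lat),
                        fun = function(x, y)
                          geosphere::distHaversine(x, y, r = 6371000)) / 1000
  dimnames(m) <- list(coords[[idcol]], coords[[idcol]])
  m
}

#' Euclidean environmental distance between populations
#'
#' Predictors are standardized over samples, averaged per population, and
#' compared by Euclidean distance.
#'
#' @param env Tibble `sample_id` + predictors.
#' @param samples Tibble `sample_id, population`.
#' @return Symmetric distance matrix over populations.
#' @export
env_dist_matrix <- function(env, samples) {
  preds <- setdiff(names(env), "sample_id")
  x <- as.matrix(env[, preds])
  x <- x[, apply(x, 2, sd) > 0, drop = FALSE]  # constants carry no distance
  z <- scale(x)
  pop <- samples$population[match(env$sample_id, samples$sample_id)]
  means <- rowsum(z, pop) / as.vector(table(pop)[sort(unique(pop))])
  as.matrix(stats::dist(means))
}

#' Mantel permutation test
#'
#' Pearson correlation of the lower triangles of two distance matrices;
#' significance by permuting the row/column order of the second matrix.
#' When `exact` (default for n <= 7) all `n!` permutations are enumerated
#' and `p` is the fraction with `r >= r_obs` (the identity included);
#' otherwise `n_perm` random permutations with the add-one convention.
#' `NA` entries (e.g. excluded F_ST = 1 pairs) are dropped pairwise.
#'
#' @param d1,d2 Square symmetric matrices with matching dimnames order.
#' @param n_perm Random permutations when not exhaustive.
#' @param seed Integer seed (random mode).
#' @param exact Force or forbid exhaustive enumeration.
#' @return List `r, p, n_perm, exact`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1L, exact = NULL) {
  n <- nrow(d1)
  stopifnot(all(dim(d1) == dim(d2)))
  if (n < 4) abort("need >= 4 populations")
  exact <- exact %||% (n <= 7)
  lt <- lower.tri(d1)
  r_obs <- cor(d1[lt], d2[lt], use = "pairwise.complete.obs")
  perm_r <- function(ord) {
    dp <- d2[ord, ord]
    cor(d1[lt], dp[lt], use = "pairwise.complete.obs")
  }
  if (exact) {
    perms <- all_permutations(n)
    rs <- vapply(perms, perm_r, numeric(1))
    p <- mean(rs >= r_obs - 1e-12)
    list(r = r_obs, p = p, n_perm = length(perms), exact = TRUE)
  } else {
    set.seed(seed)
    rs <- vapply(seq_len(n_perm), function(i) perm_r(sample.int(n)),
                 numeric(1))
    p <- (sum(rs >= r_obs - 1e-12, na.rm = TRUE) + 1) / (n_perm + 1)
    list(r = r_obs, p = p, n_perm = n_perm, exact = FALSE)
  }
}

# all n! permutations of 1..n, by inserting n into each slot of each (n-1)-perm
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) {
    for (i in 0:(n - 1)) {
      k <- k + 1L
      out[[k]] <- append(s, n, after = i)
    }
  }
  out
}

#' Mantel isolation-by-distance and isolation-by-environment tests
#'
#' For each supplied SNP set (typically environment-associated outliers and
#' a neutral intergenic set), computes pairwise population F_ST, linearizes
#' it to `F_ST/(1-F_ST)`, and Mantel-tests it against haversine geographic
#' distance and Euclidean environmental distance between populations.
#'
#' @param g A [genotypes()] object.
#' @param env Tibble `sample_id` + predictors.
#' @param snp_sets Named list of SNP-id vectors.
#' @param n_perm,seed,exact Passed to [mantel_test()].
#' @return Tibble `snp_set, comparison, mantel_r, p, n_pops`.
#' @export
mantel_ibd_ibe <- function(g, env, snp_sets, n_perm = 999, seed = 1L,
                           exact = NULL) {
  pops <- g$samples %>%
    dplyr::group_by(population) %>%
    dplyr::summarise(lat = mean(lat), lon = mean(lon), .groups = "drop") %>%
    dplyr::arrange(population)
  if (nrow(pops) < 4) abort("need >= 4 populations")
  dgeo <- geo_dist_km(dplyr::select(pops, population, lat, lon))
  denv <- env_dist_matrix(env, g$samples)[pops$population, pops$population]
  purrr::imap_dfr(snp_sets, function(ids, set_name) {
    fstm <- pop_fst_matrix(g, snp_ids = ids)[pops$population, pops$population]
    dgen <- suppressWarnings(linearize_fst(fstm))
    purrr::map_dfr(list(geographic = dgeo, environmental = denv),
                   function(dm) {
                     mt <- mantel_test(dgen, dm, n_perm = n_perm, seed = seed,
                                       exact = exact)
                     tibble::tibble(mantel_r = mt$r, p = mt$p,
                                    n_pops = nrow(pops))
                   }, .id = "comparison") %>%
      dplyr::mutate(snp_set = set_name, .before = 1)
  })
}
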