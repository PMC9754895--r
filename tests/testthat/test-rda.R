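# Predictor filtering, LD pruning, the RDA fit, axis tests, loading outliers.

test_that("predictor filter drops exactly one of a collinear pair", {
  set.seed(1)
  n <- 50
  a <- rnorm(n)
  env <- tibble::tibble(sample_id = sprintf("s%d", 1:n),
                        P1 = a, P2 = 0.97 * a + 0.2 * rnorm(n),
                        P3 = rnorm(n))
  out <- filter_predictors(env)
  expect_equal(ncol(out), 3)  # sample_id + 2 survivors
  expect_true("P3" %in% names(out))
  expect_equal(length(intersect(c("P1", "P2"), names(out))), 1)
})

test_that("uncorrelated predictors pass through unchanged", {
  set.seed(2)
  env <- tibble::tibble(sample_id = sprintf("s%d", 1:60),
                        A = rnorm(60), B = rnorm(60), C = rnorm(60))
  out <- filter_predictors(env)
  expect_identical(names(out), names(env))
  expect_warning(filter_predictors(dplyr::mutate(env, K = 1)), "constant")
})

test_that("greedy filtering of a correlated triple matches the optimal subset", {
  set.seed(3)
  n <- 80
  base <- rnorm(n)
  env <- tibble::tibble(
    sample_id = sprintf("s%d", 1:n),
    T1 = base + 0.1 * rnorm(n),
    T2 = base + 0.1 * rnorm(n),
    T3 = base + 0.1 * rnorm(n),
    D = rnorm(n)
  )
  out <- filter_predictors(env)
  kept <- setdiff(names(out), "sample_id")
  # exhaustive oracle: the largest subset with all pairwise |r| < 0.7
  preds <- setdiff(names(env), "sample_id")
  cm <- abs(cor(as.matrix(env[, preds])))
  best <- 0
  for (k in length(preds):1) {
    combos <- combn(preds, k, simplify = FALSE)
    ok <- purrr::keep(combos, function(s)
      all(cm[s, s][upper.tri(cm[s, s])] < 0.7))
    if (length(ok)) { best <- k; best_sets <- ok; break }
  }
  expect_equal(length(kept), best)
  expect_true(any(purrr::map_lgl(best_sets, ~setequal(.x, kept))))
})

test_that("LD pruning removes the later duplicate and keeps orthogonal SNPs", {
  set.seed(4)
  x <- rbinom(30, 2, 0.5)
  y <- rbinom(30, 2, 0.5)
  d <- rbind(x, x, y)  # sites 1-2 duplicated 1 kb apart, site 3 independent
  g <- toy_genotypes(d, n_A = 15, pos = c(1000L, 2000L, 3000L))
  kept <- ld_prune(g, r2_threshold = 0.4)
  expect_equal(kept, c("Chr01_1000", "Chr01_3000"))
})

test_that("windowed pruning matches the hand-rule greedy oracle", {
  set.seed(6)
  n <- 40
  base <- rbinom(n, 2, 0.5)
  jitter <- function(v, k) { i <- sample(n, k); v[i] <- sample(0:2, k, TRUE); v }
  d <- rbind(base, jitter(base, 3), jitter(base, 25),
             jitter(base, 2), jitter(base, 30), jitter(base, 4))
  pos <- c(100L, 2000L, 5000L, 8000L, 12000L, 15000L)
  g <- toy_genotypes(d, n_A = 20, pos = pos)
  kept <- ld_prune(g, r2_threshold = 0.4, window_bp = 20000, step_markers = 2)
  # oracle: single 20-kb window covers all six; scan ordered pairs, drop the
  # later member whenever r^2 of two still-kept SNPs exceeds the threshold
  dd <- t(d)
  alive <- rep(TRUE, 6)
  for (i in 1:5) {
    if (!alive[i]) next
    for (j in (i + 1):6) {
      if (!alive[j]) next
      if (cor(dd[, i], dd[, j])^2 > 0.4) alive[j] <- FALSE
    }
  }
  expect_equal(kept, g$snps$snp_id[alive])
})

test_that("noise-free rank-1 response is fully explained by one axis", {
  set.seed(7)
  n <- 30
  env <- tibble::tibble(sample_id = sprintf("s%d", 1:n),
                        E1 = rnorm(n), E2 = rnorm(n))
  load <- runif(12, -1, 1)
  resp <- outer(env$E1, load)
  rownames(resp) <- env$sample_id
  colnames(resp) <- sprintf("v%02d", 1:12)
  fit <- fit_rda(resp, env)
  expect_equal(fit$total_prop, 1, tolerance = 1e-8)
  expect_equal(unname(fit$prop_explained[1]), 1, tolerance = 1e-8)
  expect_lt(fit$eig[2] / fit$eig[1], 1e-8)
})

test_that("response orthogonal to the predictors explains nothing", {
  n <- 40
  env <- tibble::tibble(sample_id = sprintf("s%d", 1:n),
                        E1 = rep(c(-1, 1), n / 2))
  resp <- matrix(rep(c(1, 1, -1, -1), n / 4), ncol = 1) %*% t(rep(1, 5))
  rownames(resp) <- env$sample_id
  colnames(resp) <- sprintf("v%d", 1:5)
  fit <- fit_rda(resp, env)
  expect_lt(fit$total_prop, 1e-12)
})

test_that("eigenvalues match a normal-equations + eigendecomposition oracle", {
  set.seed(8)
  n <- 6
  Y <- matrix(rnorm(n * 4), n, 4)
  X <- matrix(rnorm(n * 2), n, 2)
  env <- tibble::tibble(sample_id = sprintf("s%d", 1:n),
                        E1 = X[, 1], E2 = X[, 2])
  rownames(Y) <- env$sample_id
  colnames(Y) <- sprintf("v%d", 1:4)
  fit <- fit_rda(Y, env)
  # oracle: explicit hat-matrix projection and eigen of the fitted crossprod
  Yc <- scale(Y, scale = FALSE)
  Xs <- scale(X)
  H <- Xs %*% solve(crossprod(Xs)) %*% t(Xs)
  F <- H %*% Yc
  ev <- eigen(crossprod(F) / (n - 1), symmetric = TRUE)$values
  expect_equal(unname(fit$eig), ev[seq_along(fit$eig)], tolerance = 1e-10)
  expect_equal(fit$total_prop, sum(ev) / (sum(Yc^2) / (n - 1)),
               tolerance = 1e-10)
})

test_that("eigenvalues agree with an independent RDA implementation", {
  skip_if_not_installed("vegan")
  set.seed(9)
  n <- 25
  Y <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(sprintf("s%d", 1:n), sprintf("v%d", 1:10)))
  env <- tibble::tibble(sample_id = rownames(Y),
                        E1 = rnorm(n), E2 = rnorm(n), E3 = rnorm(n))
  fit <- fit_rda(Y, env)
  vfit <- vegan::rda(Y ~ E1 + E2 + E3,
                     data = as.data.frame(env[, -1]), scale = FALSE)
  expect_equal(unname(fit$eig), unname(vfit$CCA$eig), tolerance = 1e-8)
  expect_equal(fit$total_prop,
               unname(vfit$CCA$tot.chi / vfit$tot.chi), tolerance = 1e-8)
})

test_that("proportion explained is invariant to scaling and env rotation", {
  set.seed(10)
  n <- 20
  Y <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(sprintf("s%d", 1:n), sprintf("v%d", 1:8)))
  env <- tibble::tibble(sample_id = rownames(Y), E1 = rnorm(n), E2 = rnorm(n))
  f1 <- fit_rda(Y, env)
  f2 <- fit_rda(Y * 7.3, env)
  expect_equal(f1$total_prop, f2$total_prop, tolerance = 1e-10)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  Xr <- scale(as.matrix(env[, -1])) %*% R
  env_r <- tibble::tibble(sample_id = env$sample_id,
                          E1 = Xr[, 1], E2 = Xr[, 2])
  f3 <- fit_rda(Y, env_r)
  expect_equal(f1$total_prop, f3$total_prop, tolerance = 1e-10)
})

test_that("a planted dominant signal drives the first axis to the floor p", {
  set.seed(11)
  n <- 30
  env <- tibble::tibble(sample_id = sprintf("s%d", 1:n),
                        E1 = rnorm(n), E2 = rnorm(n))
  resp <- outer(env$E1, runif(20, -2, 2)) + 0.01 * matrix(rnorm(n * 20), n)
  rownames(resp) <- env$sample_id
  colnames(resp) <- sprintf("v%d", 1:20)
  fit <- fit_rda(resp, env)
  ax <- test_axes(fit, n_perm = 199, seed = 3)
  expect_equal(ax$p[1], 1 / 200)
  expect_true(ax$significant[1])
})

test_that("rank-deficient env is rejected", {
  n <- 12
  env <- tibble::tibble(sample_id = sprintf("s%d", 1:n),
                        E1 = rnorm(n))
  env$E2 <- 2 * env$E1
  Y <- matrix(rnorm(n * 5), n, 5, dimnames = list(env$sample_id, NULL))
  expect_error(fit_rda(Y, env), "rank-deficient")
})

test_that("the 3-SD outlier boundary is strict", {
  set.seed(12)
  n <- 500
  v <- rnorm(n)
  scores <- matrix(v, ncol = 1,
                   dimnames = list(sprintf("v%03d", 1:n), "RDA1"))
  rda <- structure(list(eig = c(RDA1 = 1), variant_scores = scores,
                        Y = matrix(0, 4, n), n = 4,
                        sample_scores = matrix(0, 4, 1)),
                   class = "divscan_rda")
  out <- suppressWarnings(call_outlier_variants(rda, "RDA1", sd_mult = 3))
  z <- (v - mean(v)) / sd(v)
  expect_setequal(out$variant, sprintf("v%03d", which(abs(z) > 3)))
  # exact boundary: |z| equal to the cutoff is not an outlier
  out2 <- suppressWarnings(
    call_outlier_variants(rda, "RDA1", sd_mult = max(abs(z))))
  expect_equal(nrow(out2), 0)
})

test_that("outlier calls are invariant to axis sign flips", {
  set.seed(13)
  n <- 300
  scores <- matrix(rnorm(n), ncol = 1,
                   dimnames = list(sprintf("v%03d", 1:n), "RDA1"))
  base <- list(eig = c(RDA1 = 1), variant_scores = scores,
               Y = matrix(0, 4, n), n = 4, sample_scores = matrix(0, 4, 1))
  flipped <- base
  flipped$variant_scores <- -scores
  o1 <- suppressWarnings(
    call_outlier_variants(structure(base, class = "divscan_rda"), "RDA1"))
  o2 <- suppressWarnings(
    call_outlier_variants(structure(flipped, class = "divscan_rda"), "RDA1"))
  expect_setequal(o1$variant, o2$variant)
})

test_that("predictor assignment recovers a planted association", {
  set.seed(14)
  n <- 40
  ap <- c(rnorm(26, 0), rnorm(14, 3))
  env <- tibble::tibble(sample_id = sprintf("s%d", 1:n),
                        AP = ap, SR = rnorm(n), MDR = rnorm(n))
  z <- as.numeric(scale(ap))
  resp <- cbind(planted = findInterval(0.92 * z + 0.39 * rnorm(n),
                                       c(-0.6, 0.6)),
                noise = rbinom(n, 2, 0.5))
  rownames(resp) <- env$sample_id
  asg <- assign_predictors(resp, env)
  expect_equal(asg$predictor[asg$variant == "planted"], "AP")
  expect_true(asg$strong[asg$variant == "planted"])
})

test_that("tidy and glance expose the fit in broom shape", {
  set.seed(15)
  n <- 12
  Y <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(sprintf("s%d", 1:n), sprintf("v%d", 1:6)))
  env <- tibble::tibble(sample_id = rownames(Y), E1 = rnorm(n), E2 = rnorm(n))
  fit <- fit_rda(Y, env)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6 * length(fit$eig))
  expect_named(td, c("variant", "axis", "loading"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_variants, 6)
  expect_lte(gl$prop_explained, 1)
})
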