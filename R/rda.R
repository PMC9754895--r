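# Genotype/copy-number-environment association: predictor autocorrelation
# filter, LD pruning, redundancy analysis via least squares + SVD,
# permutation-tested constrained axes, 3-SD loading outliers with predictor
# assignment.

#' Filter collinear environmental predictors
#'
#' Greedy elimination: while any predictor pair has absolute Pearson
#' correlation at or above `threshold`, drop the predictor with the most such
#' partners (ties broken by larger mean absolute correlation to all others,
#' then lexicographically). Constant predictors are dropped first with a
#' warning. Deterministic.
#'
#' @param env Tibble with `sample_id` plus numeric predictor columns.
#' @param threshold Absolute-correlation cutoff.
#' @return The reduced env tibble; dropped names in attribute `"dropped"`.
#' @export
filter_predictors <- function(env, threshold = 0.7) {
  preds <- setdiff(names(env), "sample_id")
  if (length(preds) < 2) abort("need >= 2 predictors")
  x <- as.matrix(env[, preds])
  const <- apply(x, 2, function(v) sd(v) == 0)
  dropped <- character(0)
  if (any(const)) {
    warn(paste("dropping constant predictor(s):",
               paste(preds[const], collapse = ", ")))
    dropped <- preds[const]
    preds <- preds[!const]
    x <- x[, preds, drop = FALSE]
  }
  repeat {
    cm <- abs(cor(x))
    diag(cm) <- 0
    if (all(cm < threshold) || ncol(x) <= 1) break
    partners <- colSums(cm >= threshold)
    worst <- which(partners == max(partners))
    if (length(worst) > 1) {
      meanr <- colMeans(cm)[worst]
      worst <- worst[meanr == max(meanr)]
    }
    victim <- sort(colnames(x)[worst])[1]
    dropped <- c(dropped, victim)
    x <- x[, setdiff(colnames(x), victim), drop = FALSE]
  }
  out <- env[, c("sample_id", colnames(x))]
  attr(out, "dropped") <- dropped
  out
}

#' LD-prune SNPs by windowed dosage r-squared
#'
#' Slides a `window_bp` window advanced `step_markers` markers at a time
#' along each chromosome; within a window, ordered pairs of still-kept SNPs
#' with mean-imputed dosage r-squared above `r2_threshold` lose their
#' later-position member. The union of removals applies genome-wide.
#' Deterministic.
#'
#' @param g A [genotypes()] object.
#' @param r2_threshold Dosage r-squared above which the later SNP is removed.
#' @param window_bp Window span in bp.
#' @param step_markers Markers to advance between windows.
#' @return Character vector of kept SNP ids (in genome order).
#' @export
ld_prune <- function(g, r2_threshold = 0.4, window_bp = 20000,
                     step_markers = 2) {
  d <- impute_dosage(g)
  keep <- rep(TRUE, nrow(g$snps))
  for (ch in unique(g$snps$chrom)) {
    on_ch <- which(g$snps$chrom == ch)
    pos <- g$snps$pos[on_ch]
    i <- 1L
    while (i <= length(on_ch)) {
      win <- which(pos >= pos[i] & pos < pos[i] + window_bp)
      win <- win[win >= i]
      cand <- win[keep[on_ch[win]]]
      if (length(cand) > 1) {
        r2 <- suppressWarnings(cor(d[, on_ch[cand], drop = FALSE]))^2
        for (aa in seq_len(length(cand) - 1)) {
          if (!keep[on_ch[cand[aa]]]) next
          for (bb in seq((aa + 1), length(cand))) {
            if (!keep[on_ch[cand[bb]]]) next
            if (!is.na(r2[aa, bb]) && r2[aa, bb] > r2_threshold)
              keep[on_ch[cand[bb]]] <- FALSE
          }
        }
      }
      i <- i + step_markers
    }
  }
  g$snps$snp_id[keep]
}

# samples x snps dosage with missing values mean-imputed per site
impute_dosage <- function(g) {
  d <- t(g$dosage)
  mu <- colMeans(d, na.rm = TRUE)
  nas <- which(is.na(d), arr.ind = TRUE)
  if (nrow(nas)) d[nas] <- mu[nas[, 2]]
  d
}

#' Fit a redundancy analysis (RDA)
#'
#' Multivariate least squares of the column-centered response (samples x
#' variants; missing dosages mean-imputed) on the standardized environmental
#' predictors, followed by singular value decomposition of the fitted
#' values. Constrained eigenvalues are squared singular values divided by
#' n - 1; the proportion of response variance explained is their sum over
#' the total response variance; variant scores are right singular vectors
#' scaled by singular values.
#'
#' @param response Numeric matrix (samples x variants) or tibble with
#'   `sample_id` plus variant columns; dosages or gene copy numbers.
#' @param env Tibble with `sample_id` plus predictor columns (pre-filtered
#'   with [filter_predictors()]).
#' @param standardize_response Also scale response columns to unit variance.
#' @return Object of class `divscan_rda`: eigenvalues, per-axis and total
#'   proportion explained, variant/sample scores, and the matrices needed for
#'   permutation tests.
#' @export
fit_rda <- function(response, env, standardize_response = FALSE) {
  if (inherits(response, "data.frame")) {
    ids <- response$sample_id
    response <- as.matrix(response[, setdiff(names(response), "sample_id")])
    rownames(response) <- ids
  }
  ids <- rownames(response) %||% env$sample_id
  env_m <- as.matrix(env[match(ids, env$sample_id),
                         setdiff(names(env), "sample_id")])
  if (anyNA(env_m)) abort("env does not cover all samples")
  n <- nrow(response)
  # mean-impute then center (optionally scale) the response
  mu <- colMeans(response, na.rm = TRUE)
  nas <- which(is.na(response), arr.ind = TRUE)
  if (nrow(nas)) response[nas] <- mu[nas[, 2]]
  Y <- scale(response, center = TRUE, scale = standardize_response)
  Y[is.nan(Y)] <- 0
  X <- scale(env_m)
  if (any(!is.finite(X))) abort("constant predictor: filter predictors first")
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    abort("env is rank-deficient after filtering; remove collinear predictors")
  fitted <- qr.fitted(qrX, Y)
  sv <- svd(fitted)
  rank <- min(qrX$rank, n - 1, ncol(Y))
  d <- sv$d[seq_len(rank)]
  eig <- d^2 / (n - 1)
  total <- sum(Y^2) / (n - 1)
  variant_scores <- sv$v[, seq_len(rank), drop = FALSE] %*% diag(d, rank)
  sample_scores <- sv$u[, seq_len(rank), drop = FALSE]
  axes <- paste0("RDA", seq_len(rank))
  colnames(variant_scores) <- colnames(sample_scores) <- axes
  rownames(variant_scores) <- colnames(Y)
  rownames(sample_scores) <- ids
  structure(list(
    eig = setNames(eig, axes),
    prop_explained = setNames(eig / total, axes),
    total_prop = sum(eig) / total,
    variant_scores = variant_scores,
    sample_scores = sample_scores,
    Y = Y, X = X, n = n,
    predictors = colnames(env_m),
    standardize_response = standardize_response
  ), class = "divscan_rda")
}

#' @export
print.divscan_rda <- function(x, ...) {
  cat(sprintf("<divscan_rda> %d samples, %d variants, %d predictors\n",
              x$n, ncol(x$Y), length(x$predictors)))
  cat(sprintf("  constrained axes explain %.2f%% of response variance\n",
              100 * x$total_prop))
  print(round(rbind(eigenvalue = x$eig,
                    proportion = x$prop_explained), 4))
  invisible(x)
}

#' Permutation test of constrained RDA axes
#'
#' Permutes the rows of the predictor matrix, refits, and compares each
#' axis' eigenvalue with the observed one (add-one empirical upper tail).
#' Axes are tested in order and testing stops at the first non-significant
#' axis (later axes get `NA`).
#'
#' @param rda A fitted [fit_rda()] object.
#' @param n_perm Number of permutations.
#' @param alpha Per-axis significance threshold.
#' @param seed Integer seed.
#' @return Tibble `axis, eigenvalue, p, significant`.
#' @export
test_axes <- function(rda, n_perm = 999, alpha = 0.01, seed = 1L) {
  n <- rda$n
  if (n < length(rda$predictors) + 2)
    abort("too few samples for the permutation test")
  set.seed(seed)
  rank <- length(rda$eig)
  null_eig <- matrix(NA_real_, n_perm, rank)
  for (b in seq_len(n_perm)) {
    Xp <- rda$X[sample.int(n), , drop = FALSE]
    fit <- qr.fitted(qr(Xp), rda$Y)
    dd <- svd(fit, nu = 0, nv = 0)$d[seq_len(rank)]
    null_eig[b, ] <- dd^2 / (n - 1)
  }
  p <- rep(NA_real_, rank)
  sig <- rep(FALSE, rank)
  for (k in seq_len(rank)) {
    p[k] <- (sum(null_eig[, k] >= rda$eig[k]) + 1) / (n_perm + 1)
    sig[k] <- p[k] <= alpha
    if (!sig[k]) break
  }
  tibble::tibble(axis = names(rda$eig), eigenvalue = unname(rda$eig),
                 p = p, significant = sig)
}

#' Two-tailed normal tail probability of the loading-outlier cutoff
#'
#' The probability mass beyond `sd_mult` standard deviations on both sides
#' of a normal distribution (0.0027 at the conventional 3-SD cutoff).
#'
#' @param sd_mult Standard-deviation multiplier.
#' @return Two-tailed tail probability.
#' @export
rda_outlier_cutoff_p <- function(sd_mult = 3) 2 * pnorm(-sd_mult)

#' Call loading outliers on significant axes and assign predictors
#'
#' On each significant constrained axis, variant loadings are z-scored over
#' all variants; a variant is an outlier iff `|z|` strictly exceeds
#' `sd_mult` on any significant axis (axis sign flips are immaterial). Each
#' outlier is assigned the predictor with the largest absolute Pearson
#' correlation to its response column; the subset with `|r| > strong_r` is
#' flagged strongly associated.
#'
#' @param rda A fitted [fit_rda()] object.
#' @param axes Character vector of significant axes (e.g. from
#'   [test_axes()]); defaults to the first axis.
#' @param env The env tibble used in the fit (for predictor assignment).
#' @param sd_mult Z-score cutoff (strict inequality).
#' @param strong_r Threshold for the strong-association flag.
#' @return Tibble `variant, axis, z, predictor, r, strong` (one row per
#'   outlier; `axis`/`z` give the largest-|z| significant axis).
#' @export
call_outlier_variants <- function(rda, axes = NULL, env = NULL, sd_mult = 3,
                                  strong_r = 0.6) {
  axes <- axes %||% names(rda$eig)[1]
  axes <- intersect(axes, colnames(rda$variant_scores))
  if (!length(axes)) abort("no significant axes supplied")
  if (ncol(rda$Y) < 100)
    warn("fewer than 100 variants: loading SD is noisy")
  zm <- sapply(axes, function(ax) {
    v <- rda$variant_scores[, ax]
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  zm <- matrix(zm, ncol = length(axes),
               dimnames = list(rownames(rda$variant_scores), axes))
  zmax <- apply(abs(zm), 1, max)
  out_idx <- which(zmax > sd_mult)
  if (!length(out_idx)) {
    return(tibble::tibble(variant = character(), axis = character(),
                          z = numeric(), predictor = character(),
                          r = numeric(), strong = logical()))
  }
  best_axis <- axes[apply(abs(zm[out_idx, , drop = FALSE]), 1, which.max)]
  z <- zm[cbind(out_idx, match(best_axis, axes))]
  res <- tibble::tibble(variant = rownames(rda$variant_scores)[out_idx],
                        axis = best_axis, z = z,
                        predictor = NA_character_, r = NA_real_,
                        strong = NA)
  if (!is.null(env)) {
    asg <- assign_predictors(rda$Y[, out_idx, drop = FALSE], env,
                             ids = rownames(rda$sample_scores),
                             strong_r = strong_r)
    res$predictor <- asg$predictor
    res$r <- asg$r
    res$strong <- asg$strong
  }
  res
}

#' Assign each variant its best-correlated environmental predictor
#'
#' The predictor maximizing the absolute Pearson correlation with the
#' variant's dosage/copy-number column; correlations above `strong_r` in
#' absolute value are flagged strongly associated.
#'
#' @param response Samples x variants matrix (column names = variant ids) or
#'   tibble with `sample_id`.
#' @param env Tibble `sample_id` + predictors.
#' @param ids Sample ids ordering the response rows (defaults to rownames).
#' @param strong_r Strong-association threshold on `|r|`.
#' @return Tibble `variant, predictor, r, strong`.
#' @export
assign_predictors <- function(response, env, ids = NULL, strong_r = 0.6) {
  if (inherits(response, "data.frame")) {
    ids <- response$sample_id
    response <- as.matrix(response[, setdiff(names(response), "sample_id")])
  }
  ids <- ids %||% rownames(response)
  env_m <- as.matrix(env[match(ids, env$sample_id),
                         setdiff(names(env), "sample_id")])
  rc <- suppressWarnings(cor(response, env_m, use = "pairwise.complete.obs"))
  best <- apply(abs(rc), 1, which.max)
  tibble::tibble(
    variant = colnames(response) %||% as.character(seq_len(ncol(response))),
    predictor = colnames(env_m)[best],
    r = rc[cbind(seq_len(nrow(rc)), best)],
    strong = abs(rc[cbind(seq_len(nrow(rc)), best)]) > strong_r
  )
}
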