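# broom-style accessors for the RDA fit.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy variant loadings of an RDA fit
#'
#' @param x A [fit_rda()] object.
#' @param ... Unused.
#' @return Tibble `variant, axis, loading`, one row per variant-axis pair.
#' @method tidy divscan_rda
#' @export
tidy.divscan_rda <- function(x, ...) {
  tibble::as_tibble(x$variant_scores, rownames = "variant") %>%
    tidyr::pivot_longer(-variant, names_to = "axis", values_to = "loading")
}

#' One-row summary of an RDA fit
#'
#' @param x A [fit_rda()] object.
#' @param ... Unused.
#' @return Tibble with sample/variant/predictor counts, number of
#'   constrained axes, total proportion of response variance explained and
#'   the first-axis proportion.
#' @method glance divscan_rda
#' @export
glance.divscan_rda <- function(x, ...) {
  tibble::tibble(
    n_samples = x$n,
    n_variants = ncol(x$Y),
    n_predictors = length(x$predictors),
    n_axes = length(x$eig),
    prop_explained = x$total_prop,
    prop_axis1 = unname(x$prop_explained[1])
  )
}

utils::globalVariables("variant")
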