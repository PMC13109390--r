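#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a selection-signal test
#'
#' @param x A `ghat_test` object.
#' @param ... Unused.
#' @return One-row tibble: `ghat`, `cor`, `p_perm`, `n_perm`, `n_snp`,
#'   `significant`.
#' @export
tidy.ghat_test <- function(x, ...) {
  tibble::tibble(ghat = x$ghat, cor = x$cor, p_perm = x$p_perm,
                 n_perm = x$n_perm, n_snp = x$n_snp,
                 significant = x$significant)
}

#' @rdname tidy.ghat_test
#' @export
glance.ghat_test <- function(x, ...) {
  tibble::tibble(p_perm = x$p_perm, n_perm = x$n_perm, n_snp = x$n_snp,
                 alpha = x$alpha, significant = x$significant)
}

#' Tidy ridge-regression marker effects
#'
#' @param x A `ridge_blup` object.
#' @param ... Unused.
#' @return `tidy()`: tibble of per-SNP effects; `glance()`: one-row fit
#'   summary (`lambda`, `h2`, `n`, `m`, `mu`, `method`).
#' @export
tidy.ridge_blup <- function(x, ...) x$effects

#' @rdname tidy.ridge_blup
#' @export
glance.ridge_blup <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, h2 = x$h2, n = x$n, m = x$m,
                 mu = x$mu, method = x$method)
}
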