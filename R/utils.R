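#' @importFrom rlang abort warn inform .data
#' @importFrom stats coef lm lm.fit median pnorm pt qt quantile rbinom rnorm
#'   rpois runif sd setNames var vcov complete.cases cor
#' @importFrom utils head
NULL

# Run `code` under a temporary RNG state seeded with `seed`; the caller's RNG
# stream is untouched. `seed = NULL` leaves the global stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

check_columns <- function(df, cols, what = deparse(substitute(df))) {
  if (!is.data.frame(df)) abort(sprintf("`%s` must be a data frame.", what))
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_lower = TRUE, allow_upper = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (allow_lower) x >= lower else x > lower) &&
    (if (allow_upper) x <= upper else x < upper)
  if (!ok) {
    abort(sprintf("`%s` must be a single finite number in %s%s, %s%s.",
                  name, if (allow_lower) "[" else "(", format(lower),
                  format(upper), if (allow_upper) "]" else ")"))
  }
  invisible(x)
}

# Union-find over 1..n; used for genotype-block connectivity.
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[ri] <- rj
  parent
}

uf_components <- function(parent) {
  vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
}

# Stable hash of an R list: names sorted recursively, serialized as YAML,
# md5 of the text. Invariant to key ordering.
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x))) x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  txt <- yaml::as.yaml(canon(config))
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coefficient covariance without the "essentially perfect fit" noise:
# zero-residual fits are legitimate here (exact synthetic data)
quiet_vcov <- function(fit) {
  withCallingHandlers(vcov(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

# serialize doubles with 17 significant digits so values survive a
# write/parse round trip bit-exactly
fmt17 <- function(df) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.double),
                                  ~ ifelse(is.na(.x), NA_character_,
                                           sprintf("%.17g", .x))))
}
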