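#' Marker panel container
#'
#' Bundles a genotype-by-SNP dosage matrix (counts of the alternate allele,
#' 0/1/2, missing allowed) with cultivar release years, and records per-SNP
#' bookkeeping: missing rate and whether the locus is monomorphic among the
#' observed dosages.
#'
#' @param dosage Numeric matrix, genotypes in rows (rownames required), SNPs
#'   in columns (colnames required); entries in \{0, 1, 2\} or `NA`.
#' @param release_year Named numeric vector of release years, or a data
#'   frame with `genotype` and `release_year`; must cover all row names.
#' @return An object of class `marker_panel`: a list with elements
#'   `dosage`, `release_year` and `snp_info` (tibble with `snp`,
#'   `missing_rate`, `monomorphic`).
#' @export
marker_panel <- function(dosage, release_year) {
  if (!is.matrix(dosage) || is.null(rownames(dosage)) ||
      is.null(colnames(dosage))) {
    abort("`dosage` must be a matrix with genotype rownames and SNP colnames.")
  }
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) abort("Dosages must be 0, 1, 2 or NA.")
  if (is.data.frame(release_year)) {
    check_columns(release_year, c("genotype", "release_year"),
                  "release_year")
    release_year <- setNames(release_year$release_year,
                             release_year$genotype)
  }
  if (!all(rownames(dosage) %in% names(release_year))) {
    abort("`release_year` must cover every genotype in `dosage`.")
  }
  ry <- release_year[rownames(dosage)]
  rng <- apply(dosage, 2, function(x) {
    u <- unique(x[!is.na(x)])
    length(u) <= 1L
  })
  info <- tibble::tibble(
    snp = colnames(dosage),
    missing_rate = colMeans(is.na(dosage)),
    monomorphic = unname(rng)
  )
  structure(list(dosage = dosage, release_year = ry, snp_info = info),
            class = "marker_panel")
}

#' @method print marker_panel
#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("<marker_panel> %d genotypes x %d SNPs; release years %d-%d\n",
              nrow(x$dosage), ncol(x$dosage), min(x$release_year),
              max(x$release_year)))
  cat(sprintf("  monomorphic SNPs: %d; mean missing rate: %.3f\n",
              sum(x$snp_info$monomorphic), mean(x$snp_info$missing_rate)))
  invisible(x)
}

#' Allele-frequency change over release years
#'
#' Estimates, for each SNP, the change in alternate-allele frequency from
#' the first to the last year of cultivar release. The default regresses the
#' per-genotype frequency (dosage/2) on release year across all cultivars
#' and multiplies the slope by the year span, which uses every release year;
#' `method = "cohort"` instead takes the difference in mean frequency
#' between the last-year and first-year cohorts (the simple two-cohort
#' estimator, also useful as an independent cross-check). Missing dosages
#' are excluded SNP-wise.
#'
#' @param panel A [marker_panel()].
#' @param method `"regression"` (default) or `"cohort"`.
#' @return Tibble: `snp`, `dp` (the frequency change; `NA` when fewer than
#'   two informative genotypes or no year contrast), `n_informative`.
#' @export
allele_frequency_change <- function(panel,
                                    method = c("regression", "cohort")) {
  method <- match.arg(method)
  if (!inherits(panel, "marker_panel")) {
    abort("`panel` must be a marker_panel object.")
  }
  D <- panel$dosage
  ry <- panel$release_year
  if (length(unique(ry)) < 2L) abort("Need at least 2 distinct release years.")
  P <- D / 2
  M <- !is.na(P)
  n <- colSums(M)
  if (method == "regression") {
    P0 <- ifelse(M, P, 0)
    sx <- colSums(M * ry)
    sxx <- colSums(M * ry^2)
    sp <- colSums(P0)
    sxp <- colSums(P0 * ry)
    den <- n * sxx - sx^2
    slope <- ifelse(n >= 2 & den > 0, (n * sxp - sx * sp) / den, NA_real_)
    dp <- slope * (max(ry) - min(ry))
  } else {
    first <- ry == min(ry)
    last <- ry == max(ry)
    mean_first <- colSums(ifelse(M, P, 0)[first, , drop = FALSE]) /
      colSums(M[first, , drop = FALSE])
    mean_last <- colSums(ifelse(M, P, 0)[last, , drop = FALSE]) /
      colSums(M[last, , drop = FALSE])
    dp <- mean_last - mean_first
    dp[n < 2] <- NA_real_
  }
  tibble::tibble(snp = colnames(D), dp = unname(dp),
                 n_informative = unname(as.integer(n)))
}

#' Ridge-regression (rrBLUP-style) marker effects
#'
#' Estimates additive SNP effects by ridge regression with unpenalized
#' fixed covariates: minimise \eqn{\|y - Xb - Z\beta\|^2 +
#' \lambda\|\beta\|^2}, where Z holds the (mean-imputed) dosages. By
#' default X is just an intercept (the standard rrBLUP model).
#' `adjust_year = TRUE` adds the cultivar release year as an unpenalized
#' covariate, which matters when the effects are later paired with
#' allele-frequency changes over the same release years under the SNP-label
#' permutation null of [ghat_test()]: it makes the estimation noise of the
#' effects exactly orthogonal to the year contrast that defines the
#' frequency changes, removing the dominant shared-noise component that
#' otherwise inflates that null. The default year-shuffling null of
#' [ghat_test()] does not need this adjustment.
#'
#' With the default `lambda = NULL` the penalty is set to
#' \eqn{m (1 - h^2) / h^2} (m = number of markers), the value under which
#' ridge BLUP equals the kernel mixed model with genomic relationship
#' \eqn{ZZ'/m}; the heritability is estimated by a one-dimensional REML
#' grid search on that kernel model. Missing dosages are mean-imputed per
#' SNP; all-missing SNP columns are dropped with a warning.
#'
#' Two algebraically identical solvers are available: `"dual"` works in the
#' n-by-n genotype space (preferred when markers far outnumber genotypes)
#' and `"direct"` solves the m-by-m penalized normal equations; both act on
#' the covariate-residualized data (Henderson's mixed-model equations give
#' the same solution).
#'
#' @param panel A [marker_panel()].
#' @param phenotype Named numeric vector (names = genotypes) or data frame
#'   with `genotype` and `value`.
#' @param lambda Ridge penalty; `NULL` (default) uses the REML-based policy
#'   above.
#' @param method `"auto"` (dual when markers outnumber genotypes, direct
#'   otherwise), `"dual"` or `"direct"`.
#' @param adjust_year Include release year as an unpenalized fixed
#'   covariate (default `FALSE`; see Details).
#' @param min_genotypes Minimum phenotyped genotypes required, default 10.
#' @return Object of class `ridge_blup`: list with `effects` (tibble `snp`,
#'   `effect`), `lambda`, `h2`, `mu`, `n`, `m`, `method`. [generics::tidy()]
#'   returns the effects, [generics::glance()] the fit summary.
#' @export
ridge_marker_effects <- function(panel, phenotype, lambda = NULL,
                                 method = c("auto", "dual", "direct"),
                                 adjust_year = FALSE,
                                 min_genotypes = 10) {
  method <- match.arg(method)
  if (!inherits(panel, "marker_panel")) {
    abort("`panel` must be a marker_panel object.")
  }
  if (is.data.frame(phenotype)) {
    check_columns(phenotype, c("genotype", "value"), "phenotype")
    phenotype <- setNames(phenotype$value, phenotype$genotype)
  }
  common <- intersect(rownames(panel$dosage),
                      names(phenotype)[!is.na(phenotype)])
  if (length(common) < min_genotypes) {
    abort(sprintf("Phenotype available for %d genotypes; need at least %d.",
                  length(common), min_genotypes))
  }
  y <- phenotype[common]
  Z <- panel$dosage[common, , drop = FALSE]
  all_missing <- colSums(!is.na(Z)) == 0L
  if (any(all_missing)) {
    warn(sprintf("Dropping %d all-missing SNP column(s).",
                 sum(all_missing)))
    Z <- Z[, !all_missing, drop = FALSE]
  }
  # per-SNP mean imputation
  cm <- colMeans(Z, na.rm = TRUE)
  na_idx <- which(is.na(Z), arr.ind = TRUE)
  if (nrow(na_idx)) Z[na_idx] <- cm[na_idx[, 2]]
  n <- nrow(Z)
  m <- ncol(Z)

  # unpenalized fixed covariates, absorbed by residualizing y and Z
  ry <- panel$release_year[common]
  X <- if (adjust_year && length(unique(ry)) > 1L) {
    cbind(1, ry - mean(ry))
  } else {
    matrix(1, n, 1)
  }
  Q <- diag(n) - X %*% solve(crossprod(X), t(X))
  Zr <- Q %*% Z
  yr <- drop(Q %*% y)

  h2 <- NA_real_
  if (is.null(lambda)) {
    h2 <- reml_h2(yr, Zr, q = ncol(X))
    lambda <- m * (1 - h2) / h2
  }
  check_scalar(lambda, "lambda", lower = 0)
  if (method == "auto") method <- if (m > n) "dual" else "direct"
  if (method == "dual") {
    Kl <- tcrossprod(Zr) + diag(lambda, n)
    alpha <- tryCatch(solve(Kl, yr), error = function(e) {
      abort("Singular dual system; increase `lambda` or drop redundant genotypes.")
    })
    beta <- drop(crossprod(Zr, alpha))
  } else {
    A <- crossprod(Zr) + diag(lambda, m)
    beta <- tryCatch(drop(solve(A, crossprod(Zr, yr))),
                     error = function(e) {
      abort("Singular penalized normal equations; increase `lambda`.")
    })
  }
  b <- drop(solve(crossprod(X), crossprod(X, y - Z %*% beta)))
  structure(
    list(effects = tibble::tibble(snp = colnames(Z), effect = unname(beta)),
         lambda = lambda, h2 = h2, mu = b[1], n = n, m = m,
         method = method, adjust_year = adjust_year),
    class = "ridge_blup")
}

# REML grid search for h2 on the kernel model y = Xb + g + e,
# g ~ N(0, sigma_g^2 ZZ'/m), with y and Z already residualized on the q
# fixed covariates; delta = sigma_e^2 / sigma_g^2 = (1 - h2)/h2.
reml_h2 <- function(y, Z, q = 1, grid = seq(0.01, 0.99, by = 0.01)) {
  n <- length(y)
  K <- tcrossprod(Z) / ncol(Z)
  es <- eigen(K, symmetric = TRUE)
  keep <- seq_len(n - q)           # q dimensions absorbed by the covariates
  xi <- pmax(es$values[keep], 0)
  eta <- drop(crossprod(es$vectors[, keep, drop = FALSE], y))
  nq <- n - q
  ll <- vapply(grid, function(h2) {
    delta <- (1 - h2) / h2
    w <- xi + delta
    -0.5 * (nq * log(sum(eta^2 / w)) + sum(log(w)))
  }, double(1))
  grid[which.max(ll)]
}

#' @method print ridge_blup
#' @export
print.ridge_blup <- function(x, ...) {
  cat(sprintf(
    "<ridge_blup> %d genotypes, %d SNPs; lambda = %.4g%s (%s solver)\n",
    x$n, x$m, x$lambda,
    if (!is.na(x$h2)) sprintf(" (REML h2 = %.2f)", x$h2) else "",
    x$method))
  invisible(x)
}

#' Permutation test for a polygenic selection signal
#'
#' Combines estimated marker effects with allele-frequency changes into the
#' selection statistic \eqn{\hat G = \sum_i \beta_i \Delta p_i}: directional
#' selection on the trait drags trait-increasing alleles up in frequency, so
#' effects and frequency changes correlate and the sum drifts away from
#' zero. The two-sided p-value against the permutation null is
#' \eqn{(1 + \#\{|\hat G^*| \ge |\hat G|\}) / (n_{perm} + 1)}.
#'
#' Two permutation nulls are available. `perm = "years"` (default when a
#' panel is supplied) shuffles the cultivar release years and recomputes
#' every \eqn{\Delta p} from the shuffled years: because the year labels
#' are ancillary when neither frequencies nor the trait are associated with
#' release year, this null is exact, and it remains calibrated even though
#' effects and frequency changes are estimated from the same dosage matrix.
#' `perm = "dp_labels"` shuffles the \eqn{\Delta p} vector against the
#' effects (the classic label shuffle). The label shuffle is anti-
#' conservative when both statistics share estimation noise through the
#' dosages; if it is used, estimate the effects with
#' `ridge_marker_effects(..., adjust_year = TRUE)`, which removes the
#' dominant shared component (see that function's Details).
#'
#' The Pearson correlation between effects and frequency changes is
#' reported alongside (missing when either vector has zero variance). SNPs
#' with a missing effect or frequency change are dropped pairwise; fewer
#' than 10 complete SNPs is refused because the permutation null is then too
#' coarse to be meaningful.
#'
#' @param effects Numeric vector of marker effects, a `ridge_blup` object,
#'   or a data frame with `snp` and `effect`.
#' @param dp Frequency changes: the tibble from
#'   [allele_frequency_change()] (joined on `snp` when both sides carry SNP
#'   ids) or a numeric vector aligned with `effects`. May be omitted when a
#'   `panel` is given (it is then computed by regression).
#' @param panel A [marker_panel()]; required for `perm = "years"`.
#' @param n_perm Number of permutations, at least 100; default 1000.
#' @param seed Seed for the permutation stream (reproducible p-values).
#' @param alpha Significance level, default 0.1.
#' @param perm `"auto"` (years when a panel is available, labels
#'   otherwise), `"years"` or `"dp_labels"`.
#' @return Object of class `ghat_test`: `ghat`, `cor`, `p_perm`, `n_perm`,
#'   `n_snp`, `alpha`, `significant`, `perm`, `seed`, and the permuted
#'   statistics in `null`. `tidy()`/`glance()` return one-row tibbles.
#' @export
ghat_test <- function(effects, dp = NULL, panel = NULL, n_perm = 1000,
                      seed = NULL, alpha = 0.1,
                      perm = c("auto", "years", "dp_labels")) {
  check_scalar(n_perm, "n_perm", lower = 100)
  check_scalar(alpha, "alpha", lower = 0, upper = 1, allow_lower = FALSE)
  perm <- match.arg(perm)
  if (perm == "auto") perm <- if (is.null(panel)) "dp_labels" else "years"
  if (perm == "years" && !inherits(panel, "marker_panel")) {
    abort("`perm = \"years\"` requires a marker_panel.")
  }
  if (inherits(effects, "ridge_blup")) effects <- effects$effects
  if (is.null(dp)) {
    if (is.null(panel)) abort("Provide `dp` or a `panel`.")
    dp <- allele_frequency_change(panel)
  }
  if (is.data.frame(effects) && is.data.frame(dp) &&
      all(c("snp", "effect") %in% names(effects)) && "snp" %in% names(dp)) {
    j <- dplyr::inner_join(effects, dp, by = "snp")
    snp <- j$snp
    e <- j$effect
    d <- j$dp
  } else {
    e <- if (is.data.frame(effects)) effects$effect else as.numeric(effects)
    d <- if (is.data.frame(dp)) dp$dp else as.numeric(dp)
    snp <- if (is.data.frame(dp)) dp$snp else NULL
    if (length(e) != length(d)) {
      abort("`effects` and `dp` must align on the same SNPs.")
    }
  }
  keep <- is.finite(e) & is.finite(d)
  e <- e[keep]
  d <- d[keep]
  if (length(e) < 10L) {
    abort("Fewer than 10 SNPs with both an effect and a frequency change; permutation null too coarse.")
  }
  ghat <- sum(e * d)
  r <- if (sd(e) > 0 && sd(d) > 0) cor(e, d) else NA_real_
  null <- if (perm == "dp_labels") {
    with_seed(seed, vapply(seq_len(n_perm), function(i) {
      sum(e * d[sample.int(length(d))])
    }, double(1)))
  } else {
    snp_keep <- if (!is.null(snp)) snp[keep] else colnames(panel$dosage)
    P <- panel$dosage[, snp_keep, drop = FALSE] / 2
    ry <- panel$release_year
    M <- !is.na(P)
    P0 <- ifelse(M, P, 0)
    n_i <- colSums(M)
    span <- max(ry) - min(ry)
    sp <- colSums(P0)
    dp_of <- function(x) {
      sx <- drop(crossprod(M, x))
      sxx <- drop(crossprod(M, x^2))
      sxp <- drop(crossprod(P0, x))
      den <- n_i * sxx - sx^2
      ifelse(n_i >= 2 & den > 0,
             (n_i * sxp - sx * sp) / den * span, NA_real_)
    }
    with_seed(seed, vapply(seq_len(n_perm), function(i) {
      sum(e * dp_of(sample(ry)), na.rm = TRUE)
    }, double(1)))
  }
  p <- (1 + sum(abs(null) >= abs(ghat))) / (n_perm + 1)
  structure(
    list(ghat = ghat, cor = r, p_perm = p, n_perm = as.integer(n_perm),
         n_snp = length(e), alpha = alpha, significant = p < alpha,
         perm = perm, seed = seed, null = null),
    class = "ghat_test")
}

#' @method print ghat_test
#' @export
print.ghat_test <- function(x, ...) {
  cat(sprintf(
    "<ghat_test> Ghat = %.4g, cor = %s, p_perm = %.4g (%d perms, %d SNPs)%s\n",
    x$ghat, ifelse(is.na(x$cor), "NA", sprintf("%.3f", x$cor)), x$p_perm,
    x$n_perm, x$n_snp,
    if (x$significant) sprintf("  [significant at %.2g]", x$alpha) else ""))
  invisible(x)
}

#' Read a genotype-by-SNP dosage matrix from CSV
#'
#' First column = genotype ids, remaining columns = SNP dosages (0/1/2,
#' blanks allowed as missing).
#'
#' @param path CSV path.
#' @return Numeric matrix with genotype rownames and SNP colnames.
#' @export
read_dosage_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Read dosages from a VCF file
#'
#' Extracts GT fields and counts alternate alleles per genotype, yielding a
#' genotype-by-SNP dosage matrix (missing calls become `NA`). Sites are
#' labelled by their ID field, falling back to `chrom_pos`.
#'
#' @param path VCF path (plain or bgzipped).
#' @return Numeric matrix, genotypes in rows, SNPs in columns.
#' @export
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
  })
  ids <- vcfR::getID(v)
  fx <- is.na(ids) | ids == "."
  ids[fx] <- paste0(vcfR::getCHROM(v)[fx], "_", vcfR::getPOS(v)[fx])
  rownames(dos) <- ids
  t(dos)
}
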