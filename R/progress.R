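#' Breeding progress per trait and environment
#'
#' For each trait-environment group, regresses cultivar BLUEs on release
#' year by ordinary least squares. The slope is the absolute breeding
#' progress (ABP, trait units per year). Relative breeding progress (RBP) is
#' the predicted value at the 2010 release year divided by the predicted
#' value at 1970, a unitless ratio comparable across traits. Its confidence
#' interval comes from the delta method on the coefficient covariance (or a
#' genotype-resampling bootstrap via `ci = "bootstrap"`). Years are centered
#' at 1990 internally for numerical conditioning; all reported quantities
#' are on the calendar-year scale.
#'
#' Groups with fewer than `min_genotypes` genotypes, or without at least two
#' distinct release years, return missing estimates with an explanatory
#' `note`. When the predicted 1970 value is not positive the ratio is
#' meaningless; RBP is flagged undefined while ABP is still reported.
#'
#' @param blues Long tibble with columns `trait`, `environment`, `genotype`,
#'   `blue` (e.g. from [fit_blues()]).
#' @param meta Genotype metadata with columns `genotype`, `release_year`.
#' @param ref_years Length-2 vector of reference release years for the RBP
#'   ratio, default `c(1970, 2010)`.
#' @param min_genotypes Minimum genotypes per group, default 3.
#' @param level Confidence level for the RBP interval.
#' @param ci `"delta"` (default, deterministic) or `"bootstrap"`.
#' @param n_boot,seed Bootstrap replicates and seed (bootstrap CI only).
#' @return A tibble with one row per trait-environment: `n_genotypes`,
#'   `intercept` (predicted value at the first reference year), `abp`,
#'   `abp_se`, `rbp`, `rbp_lo`, `rbp_hi`, `note`.
#' @export
estimate_progress <- function(blues, meta, ref_years = c(1970, 2010),
                              min_genotypes = 3, level = 0.95,
                              ci = c("delta", "bootstrap"),
                              n_boot = 1000, seed = NULL) {
  check_columns(blues, c("trait", "environment", "genotype", "blue"),
                "blues")
  check_columns(meta, c("genotype", "release_year"), "meta")
  ci <- match.arg(ci)
  stopifnot(length(ref_years) == 2L, ref_years[1] < ref_years[2])
  df <- dplyr::inner_join(blues, meta[, c("genotype", "release_year")],
                          by = "genotype")
  df <- df[!is.na(df$blue) & !is.na(df$release_year), , drop = FALSE]
  df |>
    dplyr::group_by(.data$trait, .data$environment) |>
    dplyr::group_modify(~ progress_one(.x, ref_years, min_genotypes, level,
                                       ci, n_boot, seed)) |>
    dplyr::ungroup()
}

progress_one <- function(d, ref_years, min_genotypes, level, ci, n_boot,
                         seed) {
  empty <- tibble::tibble(
    n_genotypes = nrow(d), intercept = NA_real_, abp = NA_real_,
    abp_se = NA_real_, rbp = NA_real_, rbp_lo = NA_real_,
    rbp_hi = NA_real_, note = NA_character_
  )
  if (nrow(d) < min_genotypes) {
    empty$note <- "too_few_genotypes"
    return(empty)
  }
  if (length(unique(d$release_year)) < 2L) {
    empty$note <- "no_year_contrast"
    return(empty)
  }
  x <- d$release_year - 1990
  fit <- lm(d$blue ~ x)
  a <- coef(fit)[[1]]
  b <- coef(fit)[[2]]
  V <- quiet_vcov(fit)
  pred <- function(y) a + b * (y - 1990)
  v1 <- pred(ref_years[1])
  v2 <- pred(ref_years[2])
  se_b <- sqrt(V[2, 2])

  out <- empty
  out$intercept <- v1
  out$abp <- b
  out$abp_se <- if (nrow(d) >= 3) se_b else NA_real_
  if (v1 <= 0) {
    out$note <- "rbp_undefined_nonpositive_baseline"
    return(out)
  }
  r <- v2 / v1
  out$rbp <- r
  if (ci == "delta") {
    x1 <- ref_years[1] - 1990
    x2 <- ref_years[2] - 1990
    # gradient of (a + b x2)/(a + b x1) in (a, b)
    g <- c((v1 - v2) / v1^2, (x2 * v1 - x1 * v2) / v1^2)
    se_r <- sqrt(max(0, drop(t(g) %*% V %*% g)))
    tq <- qt(1 - (1 - level) / 2, df = fit$df.residual)
    out$rbp_lo <- r - tq * se_r
    out$rbp_hi <- r + tq * se_r
  } else {
    qs <- with_seed(seed, {
      reps <- vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(nrow(d), replace = TRUE)
        if (length(unique(d$release_year[idx])) < 2L) return(NA_real_)
        f <- lm.fit(cbind(1, x[idx]), d$blue[idx])
        cf <- f$coefficients
        lo <- cf[1] + cf[2] * (ref_years[1] - 1990)
        if (lo <= 0) return(NA_real_)
        (cf[1] + cf[2] * (ref_years[2] - 1990)) / lo
      }, double(1))
      quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
    })
    out$rbp_lo <- qs[[1]]
    out$rbp_hi <- qs[[2]]
  }
  out
}

#' Summarize breeding progress across environments
#'
#' Per trait, summarises the distribution of defined RBP values across
#' environments: mean, median, 10th and 90th percentiles (linear
#' interpolation between order statistics) and the environments whose RBP
#' falls outside a display axis range.
#'
#' @param estimates Output of [estimate_progress()].
#' @param axis_range Length-2 numeric; RBPs outside it are listed as
#'   outliers (display concern only).
#' @return A tibble of class `progress_summary` with columns `trait`,
#'   `n_environments`, `rbp_mean`, `rbp_median`, `rbp_p10`, `rbp_p90`,
#'   `outliers` (list-column of environment ids).
#' @export
summarize_progress <- function(estimates, axis_range = c(0.5, 2)) {
  check_columns(estimates, c("trait", "environment", "rbp"), "estimates")
  out <- estimates |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(
      n_environments = sum(!is.na(.data$rbp)),
      rbp_mean = mean(.data$rbp, na.rm = TRUE),
      rbp_median = median(.data$rbp, na.rm = TRUE),
      rbp_p10 = quantile(.data$rbp, 0.1, na.rm = TRUE, names = FALSE),
      rbp_p90 = quantile(.data$rbp, 0.9, na.rm = TRUE, names = FALSE),
      outliers = list(.data$environment[
        !is.na(.data$rbp) &
          (.data$rbp < axis_range[1] | .data$rbp > axis_range[2])]),
      .groups = "drop"
    )
  class(out) <- c("progress_summary", class(out))
  out
}

#' Classify the direction of breeding progress
#'
#' Applies the trend rule used for era-trial syntheses: a trait whose median
#' RBP lies within `delta` of 1 shows no change; otherwise the direction
#' follows the sign of (median - 1), and the trend is "clear" when the
#' p10-p90 interval of environment RBPs excludes 1 and "moderate" when it
#' straddles it.
#'
#' @param summary A [summarize_progress()] tibble (or any tibble with
#'   `rbp_median`, `rbp_p10`, `rbp_p90`).
#' @param delta Half-width of the no-change band around 1, default 0.02
#'   (i.e. less than 2 percent change between the reference years).
#' @return The input with a `trend_class` factor column: `increase`,
#'   `moderate_increase`, `no_change`, `moderate_decrease`, `decrease`, or
#'   `unclassifiable` when no RBP was defined.
#' @export
classify_trend <- function(summary, delta = 0.02) {
  check_columns(summary, c("rbp_median", "rbp_p10", "rbp_p90"), "summary")
  check_scalar(delta, "delta", lower = 0)
  lev <- c("increase", "moderate_increase", "no_change",
           "moderate_decrease", "decrease", "unclassifiable")
  cls <- purrr::pmap_chr(
    summary[, c("rbp_median", "rbp_p10", "rbp_p90")],
    function(rbp_median, rbp_p10, rbp_p90) {
      if (is.na(rbp_median)) return("unclassifiable")
      if (abs(rbp_median - 1) < delta) return("no_change")
      if (rbp_median > 1) {
        if (rbp_p10 > 1) "increase" else "moderate_increase"
      } else {
        if (rbp_p90 < 1) "decrease" else "moderate_decrease"
      }
    })
  summary$trend_class <- factor(cls, levels = lev)
  summary
}
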