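#' Range/mean phenotypic plasticity index
#'
#' For each cultivar and trait, plasticity is the range of its BLUEs across
#' environments (maximum minus minimum) divided by their mean: a unitless
#' measure of how strongly the cultivar responds to the environment, i.e. of
#' the extent of genotype-by-environment interaction it expresses. Because
#' the index is unitless, its breeding progress is directly comparable
#' across traits.
#'
#' When an environment-class map is supplied (e.g. field vs controlled
#' conditions), the index is computed separately within each class, so
#' cultivar sets that differ between data sources are never pooled.
#' Cultivar-trait combinations observed in fewer than `min_envs`
#' environments, or with a zero mean, return a missing index with a `note`.
#' Traits with a negative mean use the absolute mean (with a warning), so
#' the index stays non-negative and comparable.
#'
#' @param blues Long tibble `trait`, `environment`, `genotype`, `blue`.
#' @param min_envs Minimum environments required, default 2 (the
#'   mathematical minimum; 3 or more is recommended for stable ranges).
#' @param env_class Optional data frame `environment`, `env_class` mapping
#'   environments to classes; absent means a single pooled class.
#' @return Tibble: `trait`, `env_class`, `genotype`, `plasticity`,
#'   `n_envs`, `note`.
#' @export
#' @examples
#' blues <- data.frame(
#'   trait = "yield", environment = c("E1", "E2", "E3"),
#'   genotype = "g1", blue = c(8, 10, 12)
#' )
#' compute_plasticity(blues)  # (12 - 8) / 10 = 0.4
compute_plasticity <- function(blues, min_envs = 2, env_class = NULL) {
  check_columns(blues, c("trait", "environment", "genotype", "blue"),
                "blues")
  check_scalar(min_envs, "min_envs", lower = 2)
  if (is.null(env_class)) {
    blues$env_class <- "pooled"
  } else {
    check_columns(env_class, c("environment", "env_class"), "env_class")
    blues <- dplyr::inner_join(blues, env_class, by = "environment")
  }
  blues <- blues[!is.na(blues$blue), , drop = FALSE]
  neg_mean_seen <- FALSE
  out <- blues |>
    dplyr::group_by(.data$trait, .data$env_class, .data$genotype) |>
    dplyr::summarise(
      n_envs = dplyr::n_distinct(.data$environment),
      .range = max(.data$blue) - min(.data$blue),
      .mean = mean(.data$blue),
      .groups = "drop"
    )
  note <- rep(NA_character_, nrow(out))
  plast <- rep(NA_real_, nrow(out))
  ok <- out$n_envs >= min_envs
  note[!ok] <- "insufficient_environments"
  zero <- ok & out$.mean == 0
  note[zero] <- "undefined_zero_mean"
  good <- ok & !zero
  if (any(good & out$.mean < 0)) {
    warn("Negative trait means encountered; plasticity computed on |mean|.")
  }
  plast[good] <- out$.range[good] / abs(out$.mean[good])
  out$plasticity <- plast
  out$note <- note
  out[, c("trait", "env_class", "genotype", "plasticity", "n_envs", "note")]
}

#' Breeding progress in plasticity
#'
#' Regresses the plasticity index on cultivar release year, separately per
#' trait and environment class (classes are never pooled, so unbalanced
#' cultivar sets between e.g. field and controlled environments cannot bias
#' the slope). The slope is the absolute breeding progress of plasticity per
#' year, with a t-based confidence interval.
#'
#' @param plasticity Output of [compute_plasticity()].
#' @param meta Genotype metadata with `genotype`, `release_year`.
#' @param level Confidence level, default 0.95.
#' @param min_genotypes Minimum genotypes per group, default 3.
#' @return Tibble: `trait`, `env_class`, `n_genotypes`, `slope`,
#'   `slope_se`, `ci_lo`, `ci_hi`, `note`.
#' @export
plasticity_progress <- function(plasticity, meta, level = 0.95,
                                min_genotypes = 3) {
  check_columns(plasticity, c("trait", "env_class", "genotype",
                              "plasticity"), "plasticity")
  check_columns(meta, c("genotype", "release_year"), "meta")
  df <- dplyr::inner_join(plasticity, meta[, c("genotype", "release_year")],
                          by = "genotype")
  df <- df[!is.na(df$plasticity), , drop = FALSE]
  df |>
    dplyr::group_by(.data$trait, .data$env_class) |>
    dplyr::group_modify(function(d, key) {
      res <- tibble::tibble(n_genotypes = nrow(d), slope = NA_real_,
                            slope_se = NA_real_, ci_lo = NA_real_,
                            ci_hi = NA_real_, note = NA_character_)
      if (nrow(d) < min_genotypes) {
        res$note <- "too_few_genotypes"
        return(res)
      }
      if (length(unique(d$release_year)) < 2L) {
        res$note <- "no_year_contrast"
        return(res)
      }
      fit <- lm(plasticity ~ I(release_year - 1990), data = d)
      b <- coef(fit)[[2]]
      se <- sqrt(quiet_vcov(fit)[2, 2])
      tq <- qt(1 - (1 - level) / 2, df = fit$df.residual)
      res$slope <- b
      res$slope_se <- se
      res$ci_lo <- b - tq * se
      res$ci_hi <- b + tq * se
      res
    }) |>
    dplyr::ungroup()
}
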