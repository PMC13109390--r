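#' Cumulative thermal time
#'
#' Adds a cumulative thermal-time column (degree-days, degC d) to a daily
#' weather table: each day contributes `max(t_mean - base, 0)`. Thermal time
#' is the developmental clock used to align environments with different
#' calendars; the default base temperature for winter wheat development here
#' is 0 degC. If an `environment` column is present the accumulation runs
#' per environment. Dates must be contiguous; gaps are an error because a
#' missing day silently shifts every later window.
#'
#' @param weather Data frame with columns `date` (Date) and `t_mean`
#'   (daily mean temperature, degC); optional `environment`.
#' @param base Base temperature, degC. Default 0.
#' @return The input tibble with a `tt` column (cumulative degC d).
#' @export
thermal_time <- function(weather, base = 0) {
  check_columns(weather, c("date", "t_mean"), "weather")
  check_scalar(base, "base")
  one <- function(d) {
    d <- d[order(d$date), , drop = FALSE]
    gaps <- diff(as.integer(as.Date(d$date)))
    if (any(gaps != 1L)) {
      miss <- unlist(lapply(which(gaps > 1L), function(i) {
        format(seq(as.Date(d$date[i]) + 1, as.Date(d$date[i + 1]) - 1,
                   by = "day"))
      }))
      abort(paste0("Daily series has gaps; missing day(s): ",
                   paste(head(miss, 10), collapse = ", "),
                   if (length(miss) > 10) sprintf(" and %d more",
                                                  length(miss) - 10)))
    }
    d$tt <- cumsum(pmax(d$t_mean - base, 0))
    d
  }
  if ("environment" %in% names(weather)) {
    weather |>
      dplyr::group_by(.data$environment) |>
      dplyr::group_modify(~ one(.x)) |>
      dplyr::ungroup()
  } else {
    tibble::as_tibble(one(weather))
  }
}

#' Grid of thermal-time windows around heading
#'
#' Builds the set of overlapping developmental windows in which short-term
#' environmental effects are scanned: windows of `width` degC d whose
#' centers run from `-span` (before heading) to `+span` (after heading) in
#' increments of `step`. The defaults (span 900, width 100, step 20) give
#' the canonical 91-window grid covering double-ridge to grain desiccation.
#'
#' @param span Half-range of window centers, degC d. Default 900.
#' @param width Window width, degC d. Default 100.
#' @param step Spacing of consecutive centers, degC d; must divide `span`.
#'   Default 20.
#' @return Tibble of class `window_grid`: `index`, `center`, `lo`, `hi`
#'   (window = `[lo, hi)` in thermal time relative to heading).
#' @export
#' @examples
#' nrow(build_window_grid())  # 91
build_window_grid <- function(span = 900, width = 100, step = 20) {
  check_scalar(span, "span", lower = 0, allow_lower = FALSE)
  check_scalar(width, "width", lower = 0, allow_lower = FALSE)
  check_scalar(step, "step", lower = 0, allow_lower = FALSE)
  if (abs(span / step - round(span / step)) > 1e-9) {
    abort("`span` must be divisible by `step`.")
  }
  centers <- seq(-span, span, by = step)
  out <- tibble::tibble(
    index = seq_along(centers),
    center = centers,
    lo = centers - width / 2,
    hi = centers + width / 2
  )
  class(out) <- c("window_grid", class(out))
  out
}

#' Window means of environmental covariates
#'
#' For every genotype-environment pair, anchors the thermal-time axis at
#' that genotype's heading day (thermal time 0) and averages each weather
#' variable over the days whose relative thermal time falls in each window
#' `[lo, hi)`. Membership is decided on the thermal-time axis, never on
#' calendar distance, so environments with different temperature regimes
#' remain developmentally aligned. Windows containing no in-season day are
#' reported as missing, not zero.
#'
#' @param weather Daily weather, columns `environment`, `date` and the
#'   requested variables (defaults `gr`, `pr`, `t_max`, `t_mean`, `t_min`).
#' @param heading Data frame `genotype`, `environment`, and `heading_day`
#'   (1-based index into the environment's daily series) or `heading_date`.
#' @param grid A [build_window_grid()] table.
#' @param variables Character vector of weather columns to average.
#' @param base Base temperature passed to [thermal_time()].
#' @return Long tibble: `environment`, `genotype`, `index`, `center`,
#'   `variable`, `value` (NA for empty windows).
#' @export
window_covariates <- function(weather, heading, grid,
                              variables = c("gr", "pr", "t_max", "t_mean",
                                            "t_min"),
                              base = 0) {
  check_columns(weather, c("environment", "date", "t_mean"), "weather")
  check_columns(heading, c("genotype", "environment"), "heading")
  if (!all(variables %in% names(weather))) {
    abort(sprintf("Weather is missing variable(s): %s.",
                  paste(setdiff(variables, names(weather)), collapse = ", ")))
  }
  if (!all(c("heading_day", "heading_date") %in% names(heading)) &&
      !any(c("heading_day", "heading_date") %in% names(heading))) {
    abort("`heading` needs a heading_day or heading_date column.")
  }
  wtt <- thermal_time(weather, base = base)
  env_split <- split(wtt, wtt$environment)

  res <- purrr::pmap(
    heading[, intersect(c("genotype", "environment", "heading_day",
                          "heading_date"), names(heading))],
    function(genotype, environment, heading_day = NULL,
             heading_date = NULL) {
      w <- env_split[[environment]]
      if (is.null(w)) {
        abort(sprintf("No weather for environment '%s'.", environment))
      }
      if (is.null(heading_day)) {
        heading_day <- match(as.Date(heading_date), as.Date(w$date))
      }
      if (is.na(heading_day) || heading_day < 1 ||
          heading_day > nrow(w)) {
        abort(sprintf(
          "Heading for genotype '%s' lies outside the weather series of '%s'.",
          genotype, environment))
      }
      rel <- w$tt - w$tt[heading_day]
      # membership matrix days x windows on the relative thermal-time axis
      memb <- outer(rel, grid$lo, `>=`) & outer(rel, grid$hi, `<`)
      cnt <- colSums(memb)
      vals <- purrr::map(variables, function(v) {
        s <- colSums(memb * w[[v]])
        ifelse(cnt > 0, s / cnt, NA_real_)
      })
      tibble::tibble(
        environment = environment, genotype = genotype,
        index = rep(grid$index, length(variables)),
        center = rep(grid$center, length(variables)),
        variable = rep(variables, each = nrow(grid)),
        value = unlist(vals)
      )
    })
  dplyr::bind_rows(res)
}

#' Per-cultivar sensitivity to one window covariate
#'
#' Compares, across environments, a model of the cultivar's trait with and
#' without a given window covariate: `trait ~ 1 + covariate` against the
#' intercept-only reduction. The covariate coefficient carries the sign and
#' size of the environmental effect; its two-sided t-test supplies the
#' p-value. Sensitivity is reported as a normalized coefficient,
#' `100 * coefficient / mean(trait)`: the percent change in the trait per
#' unit of the variable.
#'
#' @param trait_values Numeric vector of the cultivar's per-environment
#'   trait values (e.g. BLUEs), aligned with `covariate`.
#' @param covariate Numeric vector of window means, same environments.
#' @param min_envs Minimum complete environments, default 4.
#' @return One-row tibble: `n_envs`, `coefficient`, `sensitivity_pct`,
#'   `p_value` (all NA when the covariate has no variance or too few
#'   environments are complete).
#' @export
cultivar_sensitivity <- function(trait_values, covariate, min_envs = 4) {
  if (length(trait_values) != length(covariate)) {
    abort("`trait_values` and `covariate` must have equal length.")
  }
  keep <- is.finite(trait_values) & is.finite(covariate)
  y <- trait_values[keep]
  x <- covariate[keep]
  n <- length(y)
  na <- tibble::tibble(n_envs = n, coefficient = NA_real_,
                       sensitivity_pct = NA_real_, p_value = NA_real_)
  if (n < min_envs) return(na)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(na)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  b <- sxy / sxx
  rss <- max(syy - b * sxy, 0)
  s2 <- rss / (n - 2)
  tstat <- if (s2 > 0) b / sqrt(s2 / sxx) else sign(b) * Inf
  p <- 2 * pt(-abs(tstat), df = n - 2)
  if (mean(y) == 0) return(na)
  tibble::tibble(n_envs = n, coefficient = b,
                 sensitivity_pct = 100 * b / mean(y), p_value = p)
}

#' Sensitivity scan over all windows, variables and cultivars
#'
#' Runs [cultivar_sensitivity()] for every cultivar at every window-variable
#' cell of the grid, using the cultivar's per-environment trait values and
#' the matching window covariates. Computation uses the closed-form
#' simple-regression algebra vectorised over the grid, so scanning the full
#' 91 x 5 grid for a panel stays fast.
#'
#' @param blues Long tibble `trait`, `environment`, `genotype`, `blue` for
#'   one trait (multiple traits are scanned independently).
#' @param covariates Output of [window_covariates()].
#' @param min_envs Minimum complete environments per regression, default 4.
#' @return Long tibble: `trait`, `genotype`, `index`, `center`, `variable`,
#'   `n_envs`, `coefficient`, `sensitivity_pct`, `p_value`.
#' @export
sensitivity_scan <- function(blues, covariates, min_envs = 4) {
  check_columns(blues, c("trait", "environment", "genotype", "blue"),
                "blues")
  check_columns(covariates, c("environment", "genotype", "index", "center",
                              "variable", "value"), "covariates")
  cells <- dplyr::distinct(covariates[, c("index", "center", "variable")])
  cells <- cells[order(cells$index, cells$variable), , drop = FALSE]
  cell_key <- paste(cells$index, cells$variable)
  cov_split <- split(covariates, covariates$genotype)

  blues |>
    dplyr::group_by(.data$trait, .data$genotype) |>
    dplyr::group_modify(function(d, key) {
      cov_g <- cov_split[[key$genotype]]
      if (is.null(cov_g)) return(tibble::tibble())
      envs <- intersect(unique(cov_g$environment), d$environment)
      y <- d$blue[match(envs, d$environment)]
      # env x cell covariate matrix; closed-form simple regression per
      # column (identical to lm(), property-tested against it)
      C <- matrix(NA_real_, length(envs), nrow(cells),
                  dimnames = list(envs, cell_key))
      C[cbind(match(cov_g$environment, envs),
              match(paste(cov_g$index, cov_g$variable), cell_key))] <-
        cov_g$value
      M <- is.finite(C) & is.finite(y)
      C0 <- ifelse(M, C, 0)
      y0 <- ifelse(is.finite(y), y, 0)
      n <- colSums(M)
      sx <- colSums(C0)
      sy <- colSums(M * y0)
      sxx <- colSums(C0^2)
      sxy <- colSums(C0 * y0)
      syy <- colSums(M * y0^2)
      Sxx <- sxx - sx^2 / n
      Sxy <- sxy - sx * sy / n
      Syy <- syy - sy^2 / n
      ok <- n >= max(min_envs, 3) & Sxx > 0
      b <- ifelse(ok, Sxy / Sxx, NA_real_)
      rss <- pmax(Syy - b * Sxy, 0)
      s2 <- rss / (n - 2)
      tstat <- ifelse(ok, ifelse(s2 > 0, b / sqrt(s2 / Sxx),
                                 sign(b) * Inf), NA_real_)
      p <- 2 * pt(-abs(tstat), df = n - 2)
      ym <- sy / n
      sens <- ifelse(ok & ym != 0, 100 * b / ym, NA_real_)
      tibble::tibble(index = cells$index, center = cells$center,
                     variable = cells$variable,
                     n_envs = as.integer(unname(n)),
                     coefficient = unname(b),
                     sensitivity_pct = unname(sens), p_value = unname(p))
    }) |>
    dplyr::ungroup()
}

#' Group-median sensitivity map (old vs modern cultivars)
#'
#' Aggregates per-cultivar scan results into the era contrast: cultivars
#' released before 1980 form the "old" group and those released after 2010
#' the "modern" group (intermediate releases are not assigned). Per trait,
#' group, window and variable the map holds the median sensitivity and the
#' median -ln(p); cells supported by fewer than `min_cultivars` informative
#' cultivars are missing. A `difference` layer (modern minus old medians) is
#' emitted alongside the two groups.
#'
#' @param scan Output of [sensitivity_scan()].
#' @param meta Genotype metadata with `genotype`, `release_year`.
#' @param min_cultivars Minimum informative cultivars per cell, default 5.
#' @param old_before,modern_after Era cut years (release year strictly
#'   below / above), defaults 1980 and 2010.
#' @return Tibble of class `sensitivity_map`: `trait`, `group`, `index`,
#'   `center`, `variable`, `n_cultivars`, `median_sensitivity`,
#'   `median_neglogp` (NA for the difference layer).
#' @export
group_sensitivity_map <- function(scan, meta, min_cultivars = 5,
                                  old_before = 1980, modern_after = 2010) {
  check_columns(scan, c("trait", "genotype", "index", "center", "variable",
                        "sensitivity_pct", "p_value"), "scan")
  check_columns(meta, c("genotype", "release_year"), "meta")
  meta$group <- dplyr::case_when(
    meta$release_year < old_before ~ "old",
    meta$release_year > modern_after ~ "modern",
    TRUE ~ NA_character_
  )
  df <- dplyr::inner_join(scan, meta[, c("genotype", "group")],
                          by = "genotype")
  df <- df[!is.na(df$group), , drop = FALSE]
  if (!nrow(df) || length(unique(df$group)) == 0L) {
    abort("No cultivars fall in the old/modern groups.")
  }
  agg <- df |>
    dplyr::group_by(.data$trait, .data$group, .data$index, .data$center,
                    .data$variable) |>
    dplyr::summarise(
      n_cultivars = sum(is.finite(.data$sensitivity_pct)),
      median_sensitivity = median(.data$sensitivity_pct, na.rm = TRUE),
      median_neglogp = median(-log(.data$p_value), na.rm = TRUE),
      .groups = "drop"
    )
  agg$median_sensitivity[agg$n_cultivars < min_cultivars] <- NA_real_
  agg$median_neglogp[agg$n_cultivars < min_cultivars] <- NA_real_
  out <- agg
  if (all(c("old", "modern") %in% agg$group)) {
    diff_layer <- agg |>
      tidyr::pivot_wider(id_cols = c("trait", "index", "center",
                                     "variable"),
                         names_from = "group",
                         values_from = c("median_sensitivity",
                                         "median_neglogp",
                                         "n_cultivars")) |>
      dplyr::mutate(
        group = "difference",
        n_cultivars = pmin(.data$n_cultivars_old,
                           .data$n_cultivars_modern),
        median_sensitivity = .data$median_sensitivity_modern -
          .data$median_sensitivity_old,
        median_neglogp = NA_real_
      ) |>
      dplyr::select(dplyr::all_of(c("trait", "group", "index", "center",
                                    "variable", "n_cultivars",
                                    "median_sensitivity",
                                    "median_neglogp")))
    out <- dplyr::bind_rows(agg, diff_layer)
  }
  class(out) <- c("sensitivity_map", class(out))
  out
}
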