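#' Simulate a cultivar panel spanning breeding eras
#'
#' Draws release years uniformly over `year_range` with both endpoints
#' forced, so downstream era-trend regressions always have support at the
#' extremes. Era labels follow the standard grouping: `old` for releases
#' before 1980, `modern` after 2010, `mid` otherwise.
#'
#' @param n_genotypes Number of cultivars (at least 2).
#' @param year_range Ordered length-2 integer vector of release years;
#'   default `c(1963, 2018)`.
#' @param seed Seed; fixed seed gives an identical panel.
#' @return Tibble: `genotype`, `release_year`, `era`.
#' @export
simulate_panel <- function(n_genotypes, year_range = c(1963, 2018),
                           seed = NULL) {
  check_scalar(n_genotypes, "n_genotypes", lower = 2)
  if (length(year_range) != 2L || year_range[1] > year_range[2]) {
    abort("`year_range` must be an ordered length-2 vector.")
  }
  years <- with_seed(seed, {
    mid <- if (n_genotypes > 2) {
      sample(seq(year_range[1], year_range[2]), n_genotypes - 2,
             replace = TRUE)
    } else integer()
    c(year_range[1], mid, year_range[2])
  })
  tibble::tibble(
    genotype = sprintf("G%04d", seq_len(n_genotypes)),
    release_year = as.integer(years),
    era = dplyr::case_when(years < 1980 ~ "old",
                           years > 2010 ~ "modern",
                           TRUE ~ "mid")
  )
}

#' Trait specification for trial simulation
#'
#' One row per simulated trait: the 1970 baseline value, the true absolute
#' breeding progress (units/year), the environment main-effect, GxE and
#' residual standard deviations, and the per-year trend in the range/mean
#' plasticity index.
#'
#' @param trait Trait name.
#' @param base_value_1970 Trait value of a 1970-release cultivar (> 0).
#' @param true_abp True change per release year, trait units.
#' @param env_sd SD of additive environment main effects.
#' @param gxe_sd Baseline genotype plasticity (range/mean at the 1990
#'   midpoint); controls the GxE magnitude.
#' @param residual_sd Plot residual (and block effect) SD.
#' @param plasticity_trend Change in the plasticity index per release year.
#' @return One-row tibble usable with [simulate_trials()] (bind rows for
#'   several traits).
#' @export
trait_spec <- function(trait = "yield", base_value_1970 = 2,
                       true_abp = 0.005, env_sd = 0, gxe_sd = 0,
                       residual_sd = 0, plasticity_trend = 0) {
  check_scalar(base_value_1970, "base_value_1970", lower = 0,
               allow_lower = FALSE)
  for (nm in c("env_sd", "gxe_sd", "residual_sd")) {
    check_scalar(get(nm), nm, lower = 0)
  }
  tibble::tibble(trait = trait, base_value_1970 = base_value_1970,
                 true_abp = true_abp, env_sd = env_sd, gxe_sd = gxe_sd,
                 residual_sd = residual_sd,
                 plasticity_trend = plasticity_trend)
}

#' Simulate multi-environment trial plots with known truth
#'
#' Generates plot-level observations for each trait in `specs` under the
#' generative model
#' `value = g_i * (1 + s_i * e_j) + E_j + B_jk + eps`, where
#' `g_i = base + ABP * (year_i - 1970)` is the genetic value, `e_j` a
#' latent environment index spaced over \[-0.5, 0.5\],
#' `s_i = max(0, gxe_sd + plasticity_trend * (year_i - 1990))` the
#' genotype's multiplicative environmental responsiveness (its true
#' range/mean plasticity), `E_j` an additive environment main effect,
#' `B_jk` a block effect and `eps` the plot residual. The
#' genotype-environment incidence is thinned at `missing_rate` to emulate
#' unbalanced era trials.
#'
#' @param panel Cultivar panel from [simulate_panel()].
#' @param specs Trait specification table ([trait_spec()] rows).
#' @param n_envs Number of environments (>= 1).
#' @param n_blocks Complete blocks per environment, default 2.
#' @param missing_rate Fraction of plots dropped at random, in \[0, 1).
#' @param seed Seed.
#' @return List with `plots` (tibble `genotype`, `environment`, `block`,
#'   `trait`, `value`) and `truth`: `trait_truth` (per trait: `true_abp`
#'   and the marginal `true_rbp`), `env_truth` (per environment: the
#'   realized additive environment effect and `true_rbp_env`, the RBP of
#'   the noise-free expected-value surface in that environment -- the
#'   estimand a per-environment regression targets), and
#'   `plasticity_truth` (per genotype: `true_plasticity`, the generating
#'   responsiveness, and `true_plasticity_index`, the range/mean index of
#'   the noise-free surface including environment main effects).
#' @export
simulate_trials <- function(panel, specs, n_envs, n_blocks = 2,
                            missing_rate = 0, seed = NULL) {
  check_columns(panel, c("genotype", "release_year"), "panel")
  check_columns(specs, c("trait", "base_value_1970", "true_abp", "env_sd",
                         "gxe_sd", "residual_sd", "plasticity_trend"),
                "specs")
  if (nrow(specs) == 0L) abort("`specs` must contain at least one trait.")
  check_scalar(n_envs, "n_envs", lower = 1)
  check_scalar(n_blocks, "n_blocks", lower = 1)
  check_scalar(missing_rate, "missing_rate", lower = 0, upper = 1,
               allow_upper = FALSE)
  envs <- sprintf("E%03d", seq_len(n_envs))
  e_idx <- if (n_envs == 1L) 0 else seq(-0.5, 0.5, length.out = n_envs)

  with_seed(seed, {
    plots <- list()
    plast <- list()
    env_truth <- list()
    for (k in seq_len(nrow(specs))) {
      sp <- specs[k, ]
      g <- sp$base_value_1970 + sp$true_abp * (panel$release_year - 1970)
      s <- pmax(0, sp$gxe_sd + sp$plasticity_trend *
                  (panel$release_year - 1990))
      E <- rnorm(n_envs, 0, sp$env_sd)
      B <- matrix(rnorm(n_envs * n_blocks, 0, sp$residual_sd),
                  n_envs, n_blocks)
      grid <- expand.grid(gi = seq_len(nrow(panel)), ej = seq_len(n_envs),
                          bk = seq_len(n_blocks))
      value <- g[grid$gi] * (1 + s[grid$gi] * e_idx[grid$ej]) +
        E[grid$ej] + B[cbind(grid$ej, grid$bk)] +
        rnorm(nrow(grid), 0, sp$residual_sd)
      df <- tibble::tibble(
        genotype = panel$genotype[grid$gi],
        environment = envs[grid$ej],
        block = grid$bk,
        trait = sp$trait,
        value = value
      )
      if (missing_rate > 0) {
        df <- df[runif(nrow(df)) >= missing_rate, , drop = FALSE]
      }
      plots[[k]] <- df
      # noise-free expected BLUE surface: the estimand of every downstream
      # regression, conditional on the realized environment effects
      surface <- outer(g, rep(1, n_envs)) *
        (1 + outer(s, e_idx)) + outer(rep(1, nrow(panel)), E)
      x <- panel$release_year - 1990
      sxx <- sum((x - mean(x))^2)
      env_truth[[k]] <- tibble::tibble(
        trait = sp$trait, environment = envs,
        env_effect = E,
        true_rbp_env = apply(surface, 2, function(v) {
          b <- sum((x - mean(x)) * (v - mean(v))) / sxx
          a <- mean(v) - b * mean(x)
          (a + b * 20) / (a - b * 20)
        })
      )
      plast[[k]] <- tibble::tibble(
        trait = sp$trait, genotype = panel$genotype,
        true_plasticity = s,
        true_plasticity_index = apply(surface, 1, function(v) {
          (max(v) - min(v)) / mean(v)
        })
      )
    }
    truth <- list(
      trait_truth = specs |>
        dplyr::mutate(true_rbp = (.data$base_value_1970 +
                                    40 * .data$true_abp) /
                        .data$base_value_1970) |>
        dplyr::select(dplyr::all_of(c("trait", "true_abp", "true_rbp"))),
      env_truth = dplyr::bind_rows(env_truth),
      plasticity_truth = dplyr::bind_rows(plast)
    )
    list(plots = dplyr::bind_rows(plots), truth = truth)
  })
}

#' Simulate a SNP panel under directional selection
#'
#' Selected loci have an expected alternate-allele frequency that rises
#' linearly with release year at `shift_per_year` (clamped to \[0.02,
#' 0.98\] so dosage variance never degenerates); neutral loci keep a
#' constant frequency. Dosages are binomial(2, p) draws. A phenotype is
#' generated as `dosages %*% effects` plus Gaussian noise scaled to the
#' requested heritability; selected loci carry positive effects so that
#' positive frequency shifts align with trait-increasing alleles, while
#' neutral loci carry none (a panel without selected loci therefore yields
#' a purely environmental phenotype, the null for test calibration).
#'
#' @param panel Cultivar panel from [simulate_panel()].
#' @param n_snp Total SNP count.
#' @param n_selected Number of selected loci (<= `n_snp`).
#' @param shift_per_year Expected frequency change per release year at
#'   selected loci.
#' @param h2 Heritability of the generated phenotype, in (0, 1].
#' @param seed Seed.
#' @return List: `panel` (a [marker_panel()]), `phenotype` (tibble
#'   `genotype`, `value`), `truth` (tibble `snp`, `effect`, `selected`).
#' @export
simulate_markers <- function(panel, n_snp, n_selected, shift_per_year,
                             h2 = 0.5, seed = NULL) {
  check_columns(panel, c("genotype", "release_year"), "panel")
  check_scalar(n_snp, "n_snp", lower = 1)
  check_scalar(n_selected, "n_selected", lower = 0, upper = n_snp)
  check_scalar(h2, "h2", lower = 0, upper = 1, allow_lower = FALSE)
  ry <- panel$release_year
  span <- max(ry) - min(ry)
  with_seed(seed, {
    n_g <- nrow(panel)
    snp_ids <- sprintf("S%05d", seq_len(n_snp))
    sel <- seq_len(n_snp) <= n_selected
    p0 <- ifelse(sel, runif(n_snp, 0.1, 0.3), runif(n_snp, 0.05, 0.95))
    # expected frequency per genotype x SNP
    P <- outer(rep(1, n_g), p0)
    if (n_selected > 0) {
      shift_mat <- outer(ry - min(ry), ifelse(sel, shift_per_year, 0))
      P <- P + shift_mat
      if (any(P < 0.02 | P > 0.98)) {
        warn("Expected allele frequencies clamped to [0.02, 0.98]; |shift_per_year| is large for the year span.")
      }
      P <- pmin(pmax(P, 0.02), 0.98)
    }
    D <- matrix(rbinom(n_g * n_snp, 2, P), n_g, n_snp,
                dimnames = list(panel$genotype, snp_ids))
    # selected loci are the causal ones: positive effects, so selection
    # drags their frequencies up; neutral loci carry no effect
    eff <- ifelse(sel, abs(rnorm(n_snp)), 0)
    gval <- drop(D %*% eff)
    vg <- var(gval)
    noise_sd <- if (vg > 0) {
      if (h2 < 1) sqrt(vg * (1 - h2) / h2) else 0
    } else 1   # pure-null panel: phenotype is environmental noise
    y <- gval + rnorm(n_g, 0, noise_sd)
    list(
      panel = marker_panel(D, setNames(ry, panel$genotype)),
      phenotype = tibble::tibble(genotype = panel$genotype,
                                 value = unname(y)),
      truth = tibble::tibble(snp = snp_ids, effect = eff, selected = sel,
                             shift_per_year = ifelse(sel, shift_per_year,
                                                     0))
    )
  })
}

#' Simulate daily weather, heading dates and a window-sensitive trait
#'
#' Builds, per environment, a daily season of weather (temperature from a
#' seasonal sinusoid with environment-specific level shifts and day-to-day
#' noise; radiation from a co-varying sinusoid; precipitation as
#' intermittent exponential draws), accumulates thermal time (base 0 degC)
#' and sets each genotype's heading day as the first day on which
#' cumulative thermal time reaches its target. Optionally injects a known
#' window effect: the trait value of each genotype-environment pair gains
#' `coefficient * mean(variable)` over the thermal window centered at
#' `inject$center` (width `inject$width`, default 100 degC d), so a
#' sensitivity scan should localise the signal there.
#'
#' @param panel Cultivar panel ([simulate_panel()]).
#' @param n_envs Number of environments.
#' @param season_days Days per season, default 250.
#' @param heading_thermal_target Thermal-time target (degC d) at heading;
#'   a single value (shared) or one per genotype. Default 1000.
#' @param inject `NULL` or a list with `center` (degC d relative to
#'   heading), `variable` (weather column), `coefficient`, and optional
#'   `width` (default 100).
#' @param base_trait Trait baseline, default 8.
#' @param residual_sd SD of the genotype-environment residual, default 0.2.
#' @param seed Seed.
#' @return List: `weather` (tibble `environment`, `date`, `t_min`,
#'   `t_mean`, `t_max`, `gr`, `pr`), `heading` (tibble `genotype`,
#'   `environment`, `heading_day`, `heading_date`), `plots` (one
#'   observation per genotype-environment, trait `"yield"`), `truth`
#'   (the injection settings).
#' @export
simulate_weather_and_heading <- function(panel, n_envs, season_days = 250,
                                         heading_thermal_target = 1000,
                                         inject = NULL, base_trait = 8,
                                         residual_sd = 0.2, seed = NULL) {
  check_columns(panel, c("genotype", "release_year"), "panel")
  check_scalar(n_envs, "n_envs", lower = 1)
  check_scalar(season_days, "season_days", lower = 30)
  targets <- rep_len(heading_thermal_target, nrow(panel))
  if (!is.null(inject)) {
    stopifnot(is.list(inject),
              all(c("center", "variable", "coefficient") %in%
                    names(inject)))
    inject$width <- inject$width %||% 100
  }
  with_seed(seed, {
    envs <- sprintf("E%03d", seq_len(n_envs))
    day <- seq_len(season_days)
    weather <- purrr::map(seq_len(n_envs), function(j) {
      level <- rnorm(1, 0, 1.5)           # environment temperature regime
      amp <- runif(1, 9, 12)
      tmean <- 8 + level + amp * sin(pi * day / season_days) + rnorm(
        season_days, 0, 1.5)
      spread_lo <- runif(season_days, 2, 6)
      spread_hi <- runif(season_days, 2, 6)
      gr <- pmax(0, 12 + 8 * sin(pi * day / season_days) +
                   rnorm(season_days, 0, 3) + rnorm(1, 0, 2))
      wet <- runif(season_days) < 0.35
      pr <- ifelse(wet, stats::rexp(season_days, rate = 1 / 5), 0)
      tibble::tibble(
        environment = envs[j],
        date = as.Date("2020-02-01") + day - 1,
        t_min = tmean - spread_lo,
        t_mean = tmean,
        t_max = tmean + spread_hi,
        gr = gr,
        pr = pr
      )
    }) |> dplyr::bind_rows()

    wtt <- thermal_time(weather)
    span_need_before <- 850   # leftmost window lower edge at -950 + margin
    span_need_after <- 950
    heading <- purrr::map(seq_len(n_envs), function(j) {
      w <- wtt[wtt$environment == envs[j], , drop = FALSE]
      hd <- vapply(targets, function(tg) {
        i <- which(w$tt >= tg)[1]
        if (is.na(i)) NA_integer_ else as.integer(i)
      }, integer(1))
      if (anyNA(hd)) {
        short <- max(targets) - max(w$tt)
        abort(sprintf(
          "Season too short in %s: %.0f degC d short of the heading target.",
          envs[j], short))
      }
      after <- max(w$tt) - w$tt[hd]
      before <- w$tt[hd]
      if (any(after < span_need_after) || any(before < span_need_before)) {
        abort(sprintf(
          "Season too short in %s: need %.0f degC d before and %.0f after heading; have %.0f / %.0f.",
          envs[j], span_need_before, span_need_after, min(before),
          min(after)))
      }
      tibble::tibble(genotype = panel$genotype, environment = envs[j],
                     heading_day = hd,
                     heading_date = w$date[hd])
    }) |> dplyr::bind_rows()

    gvalue <- rnorm(nrow(panel), 0, 0.3)  # small genotype main effect
    plots <- heading[, c("genotype", "environment")]
    plots$block <- 1L
    plots$trait <- "yield"
    value <- base_trait + gvalue[match(plots$genotype, panel$genotype)] +
      rnorm(nrow(plots), 0, residual_sd)
    if (!is.null(inject) && inject$coefficient != 0) {
      g1 <- tibble::tibble(index = 1L, center = inject$center,
                           lo = inject$center - inject$width / 2,
                           hi = inject$center + inject$width / 2)
      cov1 <- window_covariates(weather, heading, g1,
                                variables = inject$variable)
      key <- paste(cov1$genotype, cov1$environment)
      mkey <- match(paste(plots$genotype, plots$environment), key)
      addl <- inject$coefficient * cov1$value[mkey]
      value <- value + ifelse(is.na(addl), 0, addl)
    }
    plots$value <- value
    list(weather = weather, heading = heading, plots = plots,
         truth = list(inject = inject))
  })
}

#' Simulate stomatal image detections
#'
#' Per image, complete and incomplete stomata counts are Poisson draws
#' whose effective weighted sum (complete + 0.5 incomplete) has expectation
#' `density_mean * image_area`; blurry and trichome detections are added as
#' nuisance classes proportional to the density. Guard-cell lengths are
#' lognormal around `sl_mean` and widths a sub-unity fraction of length, so
#' width never exceeds length.
#'
#' @param panel Cultivar panel ([simulate_panel()]).
#' @param density_mean True stomatal density, mm^-2.
#' @param sl_mean Mean stomatal length, micrometres.
#' @param n_images Images per genotype, default 8.
#' @param image_area_mm2 Image area, default 0.806 mm^2.
#' @param seed Seed.
#' @return List: `counts` (tibble `genotype`, `image_id`, `n_complete`,
#'   `n_incomplete`, `n_blurry_complete`, `n_blurry_incomplete`,
#'   `n_trichome`, `image_area_mm2`) and `dimensions` (per-stoma tibble
#'   `genotype`, `image_id`, `sl_um`, `sw_um`).
#' @export
simulate_stomata <- function(panel, density_mean = 60, sl_mean = 50,
                             n_images = 8, image_area_mm2 = 0.806,
                             seed = NULL) {
  check_columns(panel, c("genotype"), "panel")
  check_scalar(density_mean, "density_mean", lower = 0)
  check_scalar(sl_mean, "sl_mean", lower = 0, allow_lower = FALSE)
  check_scalar(n_images, "n_images", lower = 1)
  with_seed(seed, {
    n <- nrow(panel) * n_images
    lam <- density_mean * image_area_mm2
    counts <- tibble::tibble(
      genotype = rep(panel$genotype, each = n_images),
      image_id = sprintf("%s_img%02d", rep(panel$genotype,
                                           each = n_images),
                         rep(seq_len(n_images), nrow(panel))),
      n_complete = rpois(n, 0.7 * lam),
      n_incomplete = rpois(n, 0.6 * lam),   # weighted 0.5 => 0.3 * lam
      n_blurry_complete = rpois(n, 0.05 * lam),
      n_blurry_incomplete = rpois(n, 0.05 * lam),
      n_trichome = rpois(n, 0.02 * lam),
      image_area_mm2 = image_area_mm2
    )
    dims <- counts |>
      dplyr::reframe(
        sl_um = stats::rlnorm(.data$n_complete, log(sl_mean), 0.08),
        .by = c("genotype", "image_id")
      )
    dims$sw_um <- dims$sl_um * runif(nrow(dims), 0.4, 0.6)
    list(counts = counts, dimensions = dims)
  })
}

#' Write every pipeline input format
#'
#' Serialises a full synthetic dataset to the plain-text formats the
#' pipeline reads: plots TSV, genotype metadata TSV, dosage CSV and a
#' minimal GT-only VCF, weather CSV, heading TSV, and stomatal counts and
#' dimensions CSVs.
#'
#' @param dir Output directory (created if needed).
#' @param panel,trials,markers,weather,stomata Outputs of the respective
#'   `simulate_*()` generators; any may be `NULL` to skip.
#' @return Invisibly, the named vector of written file paths.
#' @export
write_pipeline_inputs <- function(dir, panel = NULL, trials = NULL,
                                  markers = NULL, weather = NULL,
                                  stomata = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c()
  w <- function(obj, file, writer) {
    p <- file.path(dir, file)
    writer(obj, p)
    paths[[file]] <<- p
  }
  if (!is.null(panel)) w(panel, "genotype_meta.tsv", readr::write_tsv)
  if (!is.null(trials)) w(trials$plots, "plots.tsv", readr::write_tsv)
  if (!is.null(markers)) {
    dos <- markers$panel$dosage
    w(tibble::as_tibble(dos, rownames = "genotype"), "dosages.csv",
      readr::write_csv)
    write_minimal_vcf(dos, file.path(dir, "markers.vcf"))
    paths[["markers.vcf"]] <- file.path(dir, "markers.vcf")
    w(markers$phenotype, "marker_phenotype.tsv", readr::write_tsv)
  }
  if (!is.null(weather)) {
    w(weather$weather, "weather.csv", readr::write_csv)
    w(weather$heading, "heading.tsv", readr::write_tsv)
    w(weather$plots, "weather_plots.tsv", readr::write_tsv)
  }
  if (!is.null(stomata)) {
    w(stomata$counts, "stomata_counts.csv", readr::write_csv)
    w(stomata$dimensions, "stomata_dims.csv", readr::write_csv)
  }
  invisible(unlist(paths))
}

# Minimal GT-only VCF: one pseudo-chromosome, positions 1..m, REF/ALT A/B,
# unphased genotypes reconstructed from dosages (NA -> ./.).
write_minimal_vcf <- function(dosage, path) {
  m <- ncol(dosage)
  gt_of <- function(d) {
    if (is.na(d)) "./." else c("0/0", "0/1", "1/1")[d + 1]
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dosage)), collapse = "\t")
  )
  body <- vapply(seq_len(m), function(j) {
    paste(c("1", j, colnames(dosage)[j], "A", "T", ".", ".", ".", "GT",
            vapply(dosage[, j], gt_of, character(1))), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
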