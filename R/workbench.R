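#' Default pipeline configuration
#'
#' A complete, validated configuration for a synthetic end-to-end run.
#' Every threshold the pipeline consumes lives here: the no-change band
#' `delta` for trend classification, the selection-test level `alpha`, the
#' plasticity floor `min_envs`, permutation count `n_perm`, and the
#' thermal-window geometry. All stochastic stages derive their streams
#' from the single `seed`.
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return Nested named list (class `run_config`).
#' @export
default_config <- function(seed = 1, out_dir = tempfile("eratrend_run_")) {
  structure(list(
    seed = seed,
    out_dir = out_dir,
    synth = list(
      n_genotypes = 80, year_range = c(1963, 2018),
      n_envs = 8, n_blocks = 2, missing_rate = 0.05,
      trait = list(base_value_1970 = 2, true_abp = 0.005, env_sd = 0.15,
                   gxe_sd = 0.25, residual_sd = 0.15,
                   plasticity_trend = -0.002),
      markers = list(n_snp = 500, n_selected = 100,
                     shift_per_year = 0.005, h2 = 0.5),
      weather = list(n_envs = 12, season_days = 250,
                     heading_thermal_target = 1000,
                     inject = list(center = -600, variable = "t_mean",
                                   coefficient = 0.4)),
      stomata = list(density_mean = 60, sl_mean = 50, n_images = 8)
    ),
    thresholds = list(delta = 0.02, alpha = 0.1, min_envs = 2,
                      n_perm = 200, window_span = 900, window_width = 100,
                      window_step = 20, min_cultivars = 5,
                      sens_min_envs = 4)
  ), class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Checks every threshold against its documented bounds before any stage
#' runs, so a bad configuration fails fast rather than mid-pipeline.
#'
#' @param config A configuration list (e.g. [default_config()] or a YAML
#'   file read with [read_config()]).
#' @return The config, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(config) {
  if (!is.list(config)) abort("`config` must be a list.")
  for (f in c("seed", "out_dir", "synth", "thresholds")) {
    if (is.null(config[[f]])) abort(sprintf("Config is missing `%s`.", f))
  }
  th <- config$thresholds
  check_scalar(th$alpha, "thresholds$alpha", lower = 0, upper = 1,
               allow_lower = FALSE)
  check_scalar(th$delta, "thresholds$delta", lower = 0, upper = 1)
  check_scalar(th$min_envs, "thresholds$min_envs", lower = 2)
  check_scalar(th$n_perm, "thresholds$n_perm", lower = 100)
  check_scalar(th$window_span, "thresholds$window_span", lower = 0,
               allow_lower = FALSE)
  check_scalar(th$window_width, "thresholds$window_width", lower = 0,
               allow_lower = FALSE)
  check_scalar(th$window_step, "thresholds$window_step", lower = 0,
               allow_lower = FALSE)
  check_scalar(config$seed, "seed")
  invisible(config)
}

#' Read a YAML configuration
#'
#' @param path YAML file with the same structure as [default_config()].
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

round12 <- function(df) {
  plain_double <- function(x) is.double(x) && is.null(attributes(x))
  dplyr::mutate(df, dplyr::across(dplyr::where(plain_double),
                                  ~ signif(.x, 12)))
}

#' Run the full pipeline on synthetic data
#'
#' Executes every stage in dependency order from a single configuration:
#' synthetic-data generation, per-environment BLUEs, breeding progress with
#' trend classification, plasticity and its progress, the selection-signal
#' test, the thermal-window sensitivity scan with the old/modern contrast,
#' and stomatal traits. All stage outputs are written as TSV (numeric
#' columns serialised at 12 significant digits, so reruns and machines
#' agree bit-for-bit) and listed in a manifest with md5 checksums. Rerunning
#' with the same configuration and seed reproduces every output exactly.
#'
#' @param config A configuration list or a path to a YAML file.
#' @return A `run_report`: list with `manifest` (tibble `stage`, `file`,
#'   `md5`), `config_hash`, `version`, `timings` and `warnings`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  sy <- config$synth
  manifest <- list()
  timings <- list()
  warn_log <- character()
  emit <- function(stage, name, df) {
    p <- file.path(config$out_dir, name)
    readr::write_tsv(round12(df), p)
    manifest[[length(manifest) + 1L]] <<- tibble::tibble(
      stage = stage, file = name, md5 = unname(tools::md5sum(p)))
  }
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    withCallingHandlers(force(code), warning = function(w) {
      warn_log <<- c(warn_log, sprintf("[%s] %s", name,
                                       conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
  }

  # -- synth ---------------------------------------------------------------
  panel <- NULL; trials <- NULL; markers <- NULL; wx <- NULL; stom <- NULL
  stage("synth", {
    panel <- simulate_panel(sy$n_genotypes, unlist(sy$year_range),
                             seed = config$seed)
    spec <- do.call(trait_spec, sy$trait)
    trials <- simulate_trials(panel, spec, n_envs = sy$n_envs,
                               n_blocks = sy$n_blocks,
                               missing_rate = sy$missing_rate,
                               seed = config$seed + 1)
    markers <- do.call(simulate_markers,
                        c(list(panel = panel, seed = config$seed + 2),
                          sy$markers))
    wx <- do.call(simulate_weather_and_heading,
                   c(list(panel = panel, seed = config$seed + 3),
                     sy$weather))
    stom <- do.call(simulate_stomata,
                     c(list(panel = panel, seed = config$seed + 4),
                       sy$stomata))
    emit("synth", "genotype_meta.tsv", panel)
    emit("synth", "plots.tsv", trials$plots)
    emit("synth", "weather.tsv", wx$weather)
    emit("synth", "heading.tsv", wx$heading)
  })

  # -- blues ---------------------------------------------------------------
  blues <- NULL
  stage("blues", {
    blues <- fit_blues(trials$plots)
    emit("blues", "blues.tsv", blues)
  })

  # -- progress ------------------------------------------------------------
  summary_cls <- NULL
  stage("progress", {
    est <- estimate_progress(blues, panel)
    summ <- summarize_progress(est)
    summary_cls <- classify_trend(summ, delta = th$delta)
    emit("progress", "progress_estimates.tsv", est)
    emit("progress", "progress_summary.tsv",
         dplyr::select(summary_cls, -dplyr::any_of("outliers")))
  })

  # -- plasticity ----------------------------------------------------------
  stage("plasticity", {
    plast <- compute_plasticity(blues, min_envs = th$min_envs)
    pp <- plasticity_progress(plast, panel)
    emit("plasticity", "plasticity.tsv", plast)
    emit("plasticity", "plasticity_progress.tsv", pp)
  })

  # -- selection -----------------------------------------------------------
  stage("selection", {
    afc <- allele_frequency_change(markers$panel)
    eff <- ridge_marker_effects(markers$panel, markers$phenotype)
    gt <- ghat_test(eff, afc, panel = markers$panel, n_perm = th$n_perm,
                    seed = config$seed + 5, alpha = th$alpha)
    emit("selection", "allele_frequency_change.tsv", afc)
    emit("selection", "marker_effects.tsv", eff$effects)
    emit("selection", "selection_result.tsv", tidy(gt))
  })

  # -- sensitivity ---------------------------------------------------------
  stage("sensitivity", {
    grid <- build_window_grid(th$window_span, th$window_width,
                              th$window_step)
    cov <- window_covariates(wx$weather, wx$heading, grid)
    wblues <- fit_blues(wx$plots)
    scan <- sensitivity_scan(wblues, cov, min_envs = th$sens_min_envs)
    map <- group_sensitivity_map(scan, panel,
                                 min_cultivars = th$min_cultivars)
    emit("sensitivity", "sensitivity_scan.tsv", scan)
    emit("sensitivity", "sensitivity_map.tsv", map)
  })

  # -- stomata -------------------------------------------------------------
  stage("stomata", {
    per_img <- stom$dimensions |>
      dplyr::group_by(.data$genotype, .data$image_id) |>
      dplyr::summarise(sl_um = mean(.data$sl_um), sw_um = mean(.data$sw_um),
                       .groups = "drop") |>
      dplyr::inner_join(stom$counts, by = c("genotype", "image_id"))
    traits <- stomatal_traits(per_img)
    traits$genotype <- per_img$genotype
    emit("stomata", "stomatal_traits.tsv", traits)
  })

  cfg_for_hash <- unclass(config)
  report <- structure(list(
    manifest = dplyr::bind_rows(manifest),
    config = config,
    config_hash = config_hash(cfg_for_hash),
    version = as.character(utils::packageVersion("eratrend")),
    timings = timings,
    warnings = warn_log
  ), class = "run_report")
  yaml::write_yaml(cfg_for_hash, file.path(config$out_dir, "config.yaml"))
  report
}

#' @method print run_report
#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d files, config %s (v%s)\n",
              nrow(x$manifest), substr(x$config_hash, 1, 8), x$version))
  print(x$manifest, n = nrow(x$manifest))
  if (length(x$warnings)) {
    cat("warnings:\n")
    cat(paste0("  - ", x$warnings, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Export figures from a pipeline run
#'
#' Renders the standard figure set from the stage TSVs alone (no
#' recomputation): the relative-breeding-progress summary, the
#' selection-test null distribution, the plasticity-progress intervals and
#' the sensitivity heatmaps. Stages whose output files are absent are
#' skipped with a warning.
#'
#' @param report A `run_report` from [run_pipeline()], or the output
#'   directory of one.
#' @param dir Directory for the figure files; defaults to
#'   `<out_dir>/figures`.
#' @param device File extension, default `"pdf"`.
#' @return Invisibly, the written figure paths.
#' @export
export_figures <- function(report, dir = NULL, device = "pdf") {
  out_dir <- if (inherits(report, "run_report")) report$config$out_dir
             else report
  dir <- dir %||% file.path(out_dir, "figures")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  render <- function(file, plot_fn) {
    src <- file.path(out_dir, file)
    if (!file.exists(src)) {
      warn(sprintf("Skipping figure: %s not found.", file))
      return()
    }
    df <- readr::read_tsv(src, show_col_types = FALSE)
    if (nrow(df) == 0L) {
      warn(sprintf("Skipping figure: %s is empty.", file))
      return()
    }
    p <- plot_fn(df)
    f <- file.path(dir, paste0(sub("\\.tsv$", "", file), ".", device))
    ggplot2::ggsave(f, p, width = 8, height = 6)
    written <<- c(written, f)
  }
  render("progress_summary.tsv", function(df) {
    class(df) <- c("progress_summary", class(df))
    autoplot(df)
  })
  render("plasticity_progress.tsv", plot_plasticity_progress)
  render("sensitivity_map.tsv", function(df) {
    class(df) <- c("sensitivity_map", class(df))
    autoplot(df)
  })
  render("selection_result.tsv", plot_selection_results)
  invisible(written)
}
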