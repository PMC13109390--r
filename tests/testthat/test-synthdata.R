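test_that("panels force the era endpoints and are seed-deterministic", {
  p <- simulate_panel(2, c(1970, 2010), seed = 1)
  expect_setequal(p$release_year, c(1970, 2010))
  expect_identical(simulate_panel(50, seed = 3), simulate_panel(50, seed = 3))
  p2 <- simulate_panel(200, c(1963, 2018), seed = 4)
  expect_true(min(p2$release_year) == 1963 && max(p2$release_year) == 2018)
  expect_error(simulate_panel(1), "n_genotypes")
})

test_that("era labels split at 1980 and 2010", {
  p <- simulate_panel(100, seed = 5)
  expect_true(all(p$era[p$release_year < 1980] == "old"))
  expect_true(all(p$era[p$release_year > 2010] == "modern"))
  expect_true(all(p$era[p$release_year >= 1980 &
                          p$release_year <= 2010] == "mid"))
})

test_that("release-year means concentrate near the range midpoint", {
  means <- vapply(1:100, function(s) {
    mean(simulate_panel(200, c(1963, 2018), seed = s)$release_year)
  }, double(1))
  mid <- (1963 + 2018) / 2
  # uniform draw: sd of the mean is (range/sqrt(12))/sqrt(n)
  sd_mean <- (2018 - 1963) / sqrt(12) / sqrt(200)
  expect_lt(abs(mean(means) - mid), 3 * sd_mean)
})

test_that("zero-noise trials reproduce genetic values exactly", {
  panel <- simulate_panel(10, seed = 6)
  sim <- simulate_trials(panel, trait_spec(base_value_1970 = 2,
                                           true_abp = 0.005),
                         n_envs = 3, n_blocks = 2, seed = 7)
  g <- 2 + 0.005 * (panel$release_year - 1970)
  want <- g[match(sim$plots$genotype, panel$genotype)]
  expect_equal(sim$plots$value, want, tolerance = 1e-12)
  # truth table closed form
  expect_equal(sim$truth$trait_truth$true_rbp,
               (2 + 40 * 0.005) / 2, tolerance = 1e-12)
})

test_that("missingness thins the incidence at the requested rate", {
  panel <- simulate_panel(40, seed = 8)
  sim <- simulate_trials(panel, trait_spec(), n_envs = 10, n_blocks = 2,
                         missing_rate = 0.3, seed = 9)
  n_full <- 40 * 10 * 2
  expect_lt(nrow(sim$plots), n_full)
  expect_equal(nrow(sim$plots) / n_full, 0.7, tolerance = 0.05)
  expect_error(simulate_trials(panel, trait_spec()[0, ], n_envs = 2),
               "at least one trait")
})

test_that("null marker panels have flat frequency trajectories", {
  panel <- simulate_panel(60, seed = 10)
  sim <- simulate_markers(panel, n_snp = 300, n_selected = 0,
                          shift_per_year = 0, seed = 11)
  afc <- allele_frequency_change(sim$panel)
  expect_lt(abs(mean(afc$dp, na.rm = TRUE)), 0.02)
  expect_true(all(sim$truth$effect == 0))
})

test_that("noise-free phenotypes are exactly linear in dosages", {
  panel <- simulate_panel(30, seed = 12)
  sim <- simulate_markers(panel, n_snp = 50, n_selected = 10,
                          shift_per_year = 0.004, h2 = 1, seed = 13)
  want <- drop(sim$panel$dosage %*% sim$truth$effect)
  expect_equal(sim$phenotype$value, unname(want), tolerance = 1e-12)
})

test_that("excessive frequency shifts warn and clamp", {
  panel <- simulate_panel(30, seed = 14)
  expect_warning(
    sim <- simulate_markers(panel, n_snp = 20, n_selected = 20,
                            shift_per_year = 0.05, seed = 15),
    "clamped")
  expect_true(all(sim$panel$dosage %in% 0:2))
})

test_that("weather respects ordering invariants and heading arithmetic", {
  panel <- simulate_panel(6, seed = 16)
  sim <- simulate_weather_and_heading(panel, n_envs = 3, seed = 17)
  w <- sim$weather
  expect_true(all(w$t_min <= w$t_mean & w$t_mean <= w$t_max))
  expect_true(all(w$gr >= 0))
  expect_true(all(w$pr >= 0))
  # dates contiguous per environment
  for (e in unique(w$environment)) {
    expect_true(all(diff(as.integer(w$date[w$environment == e])) == 1))
  }
  # heading day is the first day reaching the thermal target
  wtt <- thermal_time(w)
  h1 <- sim$heading[1, ]
  tt_env <- wtt$tt[wtt$environment == h1$environment]
  expect_gte(tt_env[h1$heading_day], 1000)
  if (h1$heading_day > 1) expect_lt(tt_env[h1$heading_day - 1], 1000)
})

test_that("constant 10-degree days put heading at ceil(target/10)", {
  # deterministic check through the same accumulation rule the generator
  # uses, on a hand-built series
  w <- tibble::tibble(date = as.Date("2020-03-01") + 0:149,
                      t_mean = rep(10, 150))
  tt <- thermal_time(w)$tt
  expect_equal(which(tt >= 995)[1], ceiling(995 / 10))
})

test_that("a too-short season fails with the thermal shortfall named", {
  panel <- simulate_panel(4, seed = 18)
  expect_error(
    simulate_weather_and_heading(panel, n_envs = 1, season_days = 60,
                                 seed = 19),
    "degC d")
})

test_that("zero injection leaves the trait independent of window covariates", {
  panel <- simulate_panel(20, seed = 20)
  sim <- simulate_weather_and_heading(panel, n_envs = 8, seed = 21,
                                      inject = NULL, residual_sd = 0.1)
  grid <- build_window_grid(span = 300, width = 100, step = 100)
  cov <- window_covariates(sim$weather, sim$heading, grid,
                           variables = "t_mean")
  blues <- fit_blues(sim$plots)
  scan <- sensitivity_scan(blues, cov)
  # p-values roughly uniform: no excess of small ones
  expect_lt(mean(scan$p_value < 0.05, na.rm = TRUE), 0.2)
})

test_that("generators are bit-reproducible under a fixed seed", {
  panel <- simulate_panel(10, seed = 22)
  expect_identical(
    simulate_trials(panel, trait_spec(residual_sd = 0.2), 4, seed = 23),
    simulate_trials(panel, trait_spec(residual_sd = 0.2), 4, seed = 23))
  expect_identical(
    simulate_markers(panel, 40, 10, 0.004, seed = 24),
    simulate_markers(panel, 40, 10, 0.004, seed = 24))
  expect_identical(
    simulate_weather_and_heading(panel, 2, seed = 25),
    simulate_weather_and_heading(panel, 2, seed = 25))
})

test_that("generator seeds do not disturb the global RNG stream", {
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(simulate_panel(10, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("pipeline input writers emit every declared format", {
  panel <- simulate_panel(8, seed = 26)
  trials <- simulate_trials(panel, trait_spec(residual_sd = 0.1), 3,
                            seed = 27)
  markers <- simulate_markers(panel, 20, 5, 0.004, seed = 28)
  wx <- simulate_weather_and_heading(panel, 2, seed = 29)
  stom <- simulate_stomata(panel, seed = 30)
  dir <- tempfile()
  paths <- write_pipeline_inputs(dir, panel = panel, trials = trials,
                                 markers = markers, weather = wx,
                                 stomata = stom)
  expect_true(all(file.exists(paths)))
  expect_true(all(c("genotype_meta.tsv", "plots.tsv", "dosages.csv",
                    "markers.vcf", "weather.csv", "heading.tsv",
                    "stomata_counts.csv") %in% names(paths)))
})
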