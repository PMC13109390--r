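mk_weather <- function(t_mean, start = "2020-03-01", env = NULL) {
  w <- tibble::tibble(date = as.Date(start) + seq_along(t_mean) - 1,
                      t_mean = t_mean)
  if (!is.null(env)) w$environment <- env
  w
}

test_that("thermal time accumulates clamped daily means", {
  w <- thermal_time(mk_weather(rep(10, 10)))
  expect_equal(w$tt, seq(10, 100, by = 10))
  # frost days contribute nothing
  w2 <- thermal_time(mk_weather(c(5, -5, 8)))
  expect_equal(w2$tt, c(5, 5, 13))
  # nonzero base shifts the clamp
  w3 <- thermal_time(mk_weather(c(5, 3, 8)), base = 4)
  expect_equal(w3$tt, c(1, 1, 5))
})

test_that("thermal time matches a day-by-day loop oracle on random series", {
  set.seed(30)
  tm <- rnorm(60, 8, 6)
  got <- thermal_time(mk_weather(tm))$tt
  acc <- 0
  want <- vapply(tm, function(x) {
    acc <<- acc + max(x - 0, 0)
    acc
  }, double(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("date gaps are refused with the missing days named", {
  w <- mk_weather(rep(10, 5))
  w <- w[-3, ]
  expect_error(thermal_time(w), "2020-03-03")
})

test_that("the default grid has 91 uniformly spaced windows spanning +-900", {
  g <- build_window_grid()
  expect_equal(nrow(g), 91L)
  expect_equal(g$center[1], -900)
  expect_equal(g$center[91], 900)
  expect_true(all(diff(g$center) == 20))
  expect_equal(g$hi - g$lo, rep(100, 91))
})

test_that("grid size follows 2*span/step + 1 for arbitrary geometries", {
  g3 <- build_window_grid(span = 100, width = 100, step = 100)
  expect_equal(g3$center, c(-100, 0, 100))
  set.seed(31)
  for (i in 1:50) {
    step <- sample(c(5, 10, 20, 25, 50), 1)
    span <- step * sample(1:40, 1)
    g <- build_window_grid(span = span, width = 100, step = step)
    expect_equal(nrow(g), length(seq(-span, span, by = step)))
    expect_equal(nrow(g), 2 * span / step + 1)
  }
  expect_error(build_window_grid(span = 900, step = 24), "divisible")
})

test_that("window covariates equal the constant for constant weather", {
  w <- mk_weather(rep(10, 200), env = "E1")
  w$gr <- 15
  heading <- data.frame(genotype = "g1", environment = "E1",
                        heading_day = 100)
  grid <- build_window_grid(span = 300, width = 100, step = 100)
  cov <- window_covariates(w, heading, grid, variables = "gr")
  expect_true(all(cov$value == 15))
})

test_that("windows outside the season are missing, not zero", {
  w <- mk_weather(rep(10, 60), env = "E1")
  w$gr <- 5
  heading <- data.frame(genotype = "g1", environment = "E1",
                        heading_day = 30)
  # season spans only +-300 degC d around heading
  grid <- build_window_grid(span = 900, width = 100, step = 300)
  cov <- window_covariates(w, heading, grid, variables = "gr")
  expect_true(anyNA(cov$value))
  expect_true(all(is.na(cov$value[abs(cov$center) == 900])))
  expect_false(anyNA(cov$value[cov$center == 0]))
})

test_that("member days match a brute-force day scan on random weather", {
  set.seed(32)
  tm <- pmax(rnorm(150, 12, 5), 0.1)
  w <- mk_weather(tm, env = "E1")
  w$gr <- runif(150, 0, 30)
  heading <- data.frame(genotype = "g1", environment = "E1",
                        heading_day = 75)
  grid <- build_window_grid(span = 400, width = 100, step = 50)
  cov <- window_covariates(w, heading, grid, variables = "gr")
  tt <- cumsum(pmax(tm, 0))
  rel <- tt - tt[75]
  for (k in seq_len(nrow(grid))) {
    days <- which(rel >= grid$lo[k] & rel < grid$hi[k])
    want <- if (length(days)) mean(w$gr[days]) else NA_real_
    expect_equal(cov$value[cov$index == grid$index[k]], want,
                 tolerance = 1e-12)
  }
})

test_that("every in-season day is covered by width/step consecutive windows", {
  set.seed(33)
  tm <- pmax(rnorm(250, 12, 4), 0.1)
  tt <- cumsum(tm)
  hd <- 120
  rel <- tt - tt[hd]
  grid <- build_window_grid()          # width/step = 5
  memb <- outer(rel, grid$lo, `>=`) & outer(rel, grid$hi, `<`)
  counts <- rowSums(memb)
  interior <- rel >= -850 & rel < 850  # away from the grid edges
  expect_true(all(counts[interior] == 5))
})

test_that("heading outside the weather series is an error", {
  w <- mk_weather(rep(10, 50), env = "E1")
  w$gr <- 1
  heading <- data.frame(genotype = "g1", environment = "E1",
                        heading_day = 60)
  expect_error(window_covariates(w, heading, build_window_grid(span = 100),
                                 variables = "gr"), "outside")
})

test_that("an exact linear covariate effect yields the normalized coefficient", {
  cov <- c(1, 3, 5, 9, 11)
  y <- 10 + 0.5 * cov
  res <- cultivar_sensitivity(y, cov)
  expect_equal(res$coefficient, 0.5, tolerance = 1e-10)
  expect_equal(res$sensitivity_pct, 100 * 0.5 / mean(y), tolerance = 1e-10)
  expect_lt(res$p_value, 1e-10)
})

test_that("sensitivity regression matches the lm oracle on noisy data", {
  set.seed(34)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    x <- rnorm(n, 10, 3)
    y <- 5 + rnorm(n)
    res <- cultivar_sensitivity(y, x)
    want <- slope_oracle(y, x)
    expect_equal(res$coefficient, unname(want["coef"]), tolerance = 1e-10)
    expect_equal(res$p_value, unname(want["p"]), tolerance = 1e-10)
  }
})

test_that("sensitivity guards zero-variance covariates and short series", {
  expect_true(is.na(cultivar_sensitivity(rnorm(6), rep(3, 6))$coefficient))
  expect_true(is.na(cultivar_sensitivity(rnorm(3), rnorm(3))$coefficient))
})

test_that("shifting the covariate leaves slope, p and sensitivity unchanged", {
  set.seed(35)
  x <- rnorm(10, 5)
  y <- 8 + 0.3 * x + rnorm(10, 0, 0.2)
  r1 <- cultivar_sensitivity(y, x)
  r2 <- cultivar_sensitivity(y, x + 100)
  expect_equal(r2$coefficient, r1$coefficient, tolerance = 1e-10)
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-10)
  expect_equal(r2$sensitivity_pct, r1$sensitivity_pct, tolerance = 1e-10)
  # trait rescaling moves sensitivity only through the trait mean
  r3 <- cultivar_sensitivity(2 * y, x)
  expect_equal(r3$coefficient, 2 * r1$coefficient, tolerance = 1e-10)
  expect_equal(r3$sensitivity_pct, r1$sensitivity_pct, tolerance = 1e-10)
  expect_equal(r3$p_value, r1$p_value, tolerance = 1e-10)
})

test_that("group medians match a sort-based oracle and respect the floor", {
  set.seed(36)
  scan <- expand.grid(genotype = paste0("g", 1:9), index = 1L,
                      center = 0, variable = "gr",
                      stringsAsFactors = FALSE)
  scan$trait <- "yield"
  scan$n_envs <- 10
  scan$sensitivity_pct <- rnorm(9)
  scan$p_value <- runif(9)
  meta <- data.frame(genotype = paste0("g", 1:9),
                     release_year = c(rep(1970, 5), rep(2015, 4)))
  m <- group_sensitivity_map(scan, meta, min_cultivars = 2)
  old_vals <- scan$sensitivity_pct[1:5]
  expect_equal(m$median_sensitivity[m$group == "old"],
               sort(old_vals)[3])
  expect_equal(m$median_neglogp[m$group == "old"],
               percentile_oracle(-log(scan$p_value[1:5]), 0.5))
  expect_equal(m$median_sensitivity[m$group == "difference"],
               m$median_sensitivity[m$group == "modern"] -
                 m$median_sensitivity[m$group == "old"])
  # raising the floor blanks the cells
  m2 <- group_sensitivity_map(scan, meta, min_cultivars = 6)
  expect_true(all(is.na(m2$median_sensitivity[m2$group != "difference"])))
})

test_that("a single cultivar per group reports that cultivar's values", {
  scan <- data.frame(genotype = c("a", "b"), trait = "yield", index = 1L,
                     center = 0, variable = "gr", n_envs = 8,
                     sensitivity_pct = c(2.5, -1), p_value = c(0.01, 0.4))
  meta <- data.frame(genotype = c("a", "b"),
                     release_year = c(1975, 2012))
  m <- group_sensitivity_map(scan, meta, min_cultivars = 1)
  expect_equal(m$median_sensitivity[m$group == "old"], 2.5)
  expect_equal(m$median_neglogp[m$group == "modern"], -log(0.4))
})

test_that("the vectorised scan agrees with per-cell regressions", {
  set.seed(37)
  panel <- simulate_panel(6, seed = 38)
  sim <- simulate_weather_and_heading(panel, n_envs = 8, seed = 39,
                                      inject = list(center = -200,
                                                    variable = "gr",
                                                    coefficient = 0.1),
                                      residual_sd = 0.3)
  grid <- build_window_grid(span = 400, width = 100, step = 200)
  cov <- window_covariates(sim$weather, sim$heading, grid,
                           variables = c("gr", "t_mean"))
  blues <- fit_blues(sim$plots)
  scan <- sensitivity_scan(blues, cov)
  for (r in sample(nrow(scan), 25)) {
    row <- scan[r, ]
    cg <- cov[cov$genotype == row$genotype & cov$index == row$index &
                cov$variable == row$variable, ]
    bg <- blues[blues$genotype == row$genotype, ]
    merged <- merge(cg, bg, by = "environment")
    want <- cultivar_sensitivity(merged$blue, merged$value)
    expect_equal(row$coefficient, want$coefficient, tolerance = 1e-10)
    expect_equal(row$p_value, want$p_value, tolerance = 1e-10)
    expect_equal(row$sensitivity_pct, want$sensitivity_pct,
                 tolerance = 1e-10)
  }
})
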