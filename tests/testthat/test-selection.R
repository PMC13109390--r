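two_point_panel <- function() {
  dos <- matrix(c(0, 2), 2, 1,
                dimnames = list(c("A", "B"), "snp1"))
  marker_panel(dos, c(A = 1970, B = 2010))
}

test_that("two genotypes spanning the era give a unit frequency change", {
  afc <- allele_frequency_change(two_point_panel())
  expect_equal(afc$dp, 1)
})

test_that("constant dosages give zero frequency change", {
  dos <- matrix(2, 4, 2, dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  p <- marker_panel(dos, setNames(c(1970, 1985, 2000, 2010),
                                  paste0("g", 1:4)))
  expect_equal(allele_frequency_change(p)$dp, c(0, 0))
})

test_that("regression and cohort estimators agree on two-cohort designs", {
  set.seed(12)
  n_half <- 15
  dos <- rbind(
    matrix(rbinom(n_half * 40, 2, 0.3), n_half, 40),
    matrix(rbinom(n_half * 40, 2, 0.6), n_half, 40)
  )
  rownames(dos) <- paste0("g", 1:(2 * n_half))
  colnames(dos) <- paste0("s", 1:40)
  ry <- setNames(rep(c(1970, 2010), each = n_half), rownames(dos))
  p <- marker_panel(dos, ry)
  reg <- allele_frequency_change(p, method = "regression")
  coh <- allele_frequency_change(p, method = "cohort")
  # with only two year levels the regression line passes through the two
  # cohort means, so slope * span = cohort difference
  expect_equal(reg$dp, coh$dp, tolerance = 1e-12)
})

test_that("missing dosages are excluded pairwise and sparse SNPs flagged", {
  dos <- matrix(c(0, 1, 2, NA, NA, NA, NA, 1), 4, 2,
                dimnames = list(paste0("g", 1:4), c("ok", "sparse")))
  p <- marker_panel(dos, setNames(c(1970, 1980, 2000, 2010),
                                  paste0("g", 1:4)))
  afc <- allele_frequency_change(p)
  expect_false(is.na(afc$dp[afc$snp == "ok"]))
  expect_true(is.na(afc$dp[afc$snp == "sparse"]))
  expect_equal(afc$n_informative, c(3L, 1L))
})

sim_ridge_fixture <- function(n = 20, m = 50, seed = 13) {
  set.seed(seed)
  dos <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.8)[rep(1:m, each = n)]),
                n, m, dimnames = list(paste0("g", 1:n), paste0("s", 1:m)))
  ry <- setNames(sample(1963:2018, n, replace = TRUE), rownames(dos))
  y <- setNames(rnorm(n, 10), rownames(dos))
  list(panel = marker_panel(dos, ry), y = y)
}

test_that("dual and direct ridge solvers agree to 1e-8", {
  for (seed in 14:18) {
    fx <- sim_ridge_fixture(seed = seed)
    d1 <- ridge_marker_effects(fx$panel, fx$y, lambda = 25,
                               method = "dual")
    d2 <- ridge_marker_effects(fx$panel, fx$y, lambda = 25,
                               method = "direct")
    expect_equal(d1$effects$effect, d2$effects$effect, tolerance = 1e-8)
  }
})

test_that("ridge effects vanish as the penalty grows", {
  fx <- sim_ridge_fixture()
  big <- ridge_marker_effects(fx$panel, fx$y, lambda = 1e10)
  expect_lt(max(abs(big$effects$effect)), 1e-6)
})

test_that("a single SNP with zero penalty reduces to the OLS slope", {
  set.seed(15)
  dos <- matrix(rbinom(30, 2, 0.5), 30, 1,
                dimnames = list(paste0("g", 1:30), "s1"))
  z <- dos[, 1]
  y <- setNames(1.5 * z + rnorm(30, 0, 0.5), rownames(dos))
  p <- marker_panel(dos, setNames(rep(c(1970, 2010), 15), rownames(dos)))
  r <- ridge_marker_effects(p, y, lambda = 0, adjust_year = FALSE)
  ols <- coef(lm(y ~ z))[[2]]
  expect_equal(r$effects$effect, ols, tolerance = 1e-10)
})

test_that("REML lambda policy tracks heritability", {
  panel <- simulate_panel(60, seed = 16)
  high <- simulate_markers(panel, n_snp = 200, n_selected = 50,
                           shift_per_year = 0.004, h2 = 0.9, seed = 17)
  low <- simulate_markers(panel, n_snp = 200, n_selected = 50,
                          shift_per_year = 0.004, h2 = 0.2, seed = 17)
  r_high <- ridge_marker_effects(high$panel, high$phenotype)
  r_low <- ridge_marker_effects(low$panel, low$phenotype)
  expect_gt(r_high$h2, r_low$h2)
  expect_lt(r_high$lambda, r_low$lambda)
})

test_that("ghat test handles degenerate inputs per contract", {
  set.seed(18)
  e <- rnorm(50)
  # zero frequency change: statistic 0, p-value 1
  g0 <- ghat_test(e, rep(0, 50), n_perm = 100, seed = 1)
  expect_equal(g0$ghat, 0)
  expect_equal(g0$p_perm, 1)
  # constant effects: correlation undefined but statistic defined
  dpv <- rnorm(50, 0, 0.1)
  gc <- ghat_test(rep(2, 50), dpv, n_perm = 100, seed = 1)
  expect_equal(gc$ghat, 2 * sum(dpv), tolerance = 1e-12)
  expect_true(is.na(gc$cor))
  expect_error(ghat_test(e[1:5], dpv[1:5], n_perm = 100), "Fewer than 10")
  expect_error(ghat_test(e, dpv, n_perm = 50), "n_perm")
})

test_that("ghat is bilinear and its p-value sign-flip invariant and bounded", {
  set.seed(19)
  e <- rnorm(80)
  dpv <- rnorm(80, 0.05, 0.1)
  g1 <- ghat_test(e, dpv, n_perm = 200, seed = 5)
  g2 <- ghat_test(3 * e, dpv, n_perm = 200, seed = 5)
  expect_equal(g2$ghat, 3 * g1$ghat, tolerance = 1e-12)
  expect_identical(g2$p_perm, g1$p_perm)
  g3 <- ghat_test(-e, -dpv, n_perm = 200, seed = 5)
  expect_identical(g3$p_perm, g1$p_perm)
  expect_gte(g1$p_perm, 1 / 201)
  # fixed seed reproduces the permutation p exactly
  expect_identical(ghat_test(e, dpv, n_perm = 200, seed = 5)$p_perm,
                   g1$p_perm)
})

test_that("selection simulated at high shift is detected with positive cor", {
  panel <- simulate_panel(50, seed = 20)
  sim <- simulate_markers(panel, n_snp = 300, n_selected = 60,
                          shift_per_year = 0.006, h2 = 0.6, seed = 21)
  eff <- ridge_marker_effects(sim$panel, sim$phenotype)
  afc <- allele_frequency_change(sim$panel)
  gt <- ghat_test(eff, afc, n_perm = 200, seed = 22)
  expect_gt(gt$cor, 0)
  expect_true(gt$significant)
  td <- tidy(gt)
  expect_equal(td$p_perm, gt$p_perm)
})

test_that("marker panel validates dosages and records monomorphism", {
  dos <- matrix(c(0, 0, 0, 1, 2, 1), 3, 2,
                dimnames = list(paste0("g", 1:3), c("mono", "poly")))
  p <- marker_panel(dos, setNames(c(1970, 1990, 2010), paste0("g", 1:3)))
  expect_true(p$snp_info$monomorphic[1])
  expect_false(p$snp_info$monomorphic[2])
  dos_bad <- dos
  dos_bad[1, 1] <- 3
  expect_error(marker_panel(dos_bad, setNames(c(1970, 1990, 2010),
                                              paste0("g", 1:3))),
               "Dosages")
})

test_that("dosage CSV and minimal VCF readers agree with the source matrix", {
  panel <- simulate_panel(12, seed = 23)
  sim <- simulate_markers(panel, n_snp = 25, n_selected = 5,
                          shift_per_year = 0.004, seed = 24)
  dir <- tempfile()
  write_pipeline_inputs(dir, markers = sim)
  csv <- read_dosage_csv(file.path(dir, "dosages.csv"))
  expect_equal(csv, sim$panel$dosage)
  vcf <- read_vcf_dosages(file.path(dir, "markers.vcf"))
  expect_equal(vcf[rownames(csv), colnames(csv)], csv)
})
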