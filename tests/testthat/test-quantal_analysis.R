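test_that("single-Gaussian histogram fits recover their parameters", {
  set.seed(41)
  x <- rnorm(10000, 0, 212)
  f <- fit_noise_gaussian(x)
  expect_lt(abs(f$mean), 10)
  expect_lt(abs(f$sd - 212), 10)
  expect_gt(f$chi2_p, 1e-4)
  # symmetric input fits a centred Gaussian
  set.seed(42)
  y <- rnorm(3000, 50, 7)
  fs <- fit_noise_gaussian(c(y, -y))
  expect_lt(abs(fs$mean), 3)
  # quantal-scale parameters
  set.seed(43)
  q <- rnorm(1178, 623, 122)
  fq <- fit_noise_gaussian(q)
  expect_equal(fq$mean, 623, tolerance = 0.05)
  expect_equal(fq$sd, 122, tolerance = 0.05)
  expect_error(fit_noise_gaussian(rep(1, 100)), "degenerate")
  expect_error(fit_noise_gaussian(rnorm(10)), "30")
})

test_that("D'Agostino-Pearson matches the reference implementation", {
  # frozen values computed with an independent implementation of the
  # omnibus test (skewtest + kurtosistest) on these reproducible samples
  set.seed(99)
  x <- round(rnorm(200, 5, 2) + 0.3 * rnorm(200)^2, 6)
  dp <- dagostino_pearson(x)
  expect_equal(dp$k2, 1.6075587110, tolerance = 1e-8)
  expect_equal(dp$p, 0.4476339952, tolerance = 1e-8)
  expect_equal(dp$z_skew, -1.26778406, tolerance = 1e-6)
  expect_equal(dp$z_kurt, -0.01680179, tolerance = 1e-6)
  set.seed(77)
  y <- round(rnorm(150), 6)
  dp2 <- dagostino_pearson(y)
  expect_equal(dp2$k2, 3.4593062271, tolerance = 1e-8)
  expect_equal(dp2$p, 0.1773459182, tolerance = 1e-8)
  expect_error(dagostino_pearson(rnorm(5)), "8")
  expect_error(dagostino_pearson(rep(2, 50)), "variance")
})

test_that("a single quantal Gaussian stays a one-component model", {
  set.seed(51)
  x <- rnorm(1200, 623, 122)
  f <- fit_quantal_mixture(x)
  expect_equal(f$n_components, 1L)
  expect_equal(f$q, 623, tolerance = 0.03)
  expect_equal(multivesicular_fraction(f), 0)
})

test_that("calibrated mixture fits recover weights and constraints", {
  set.seed(52)
  # 2 mM-like: 17% of events at c*q
  x2 <- rquantal_mix(1200, c(0.83, 0.17), c(1, 1.34))
  f2 <- fit_quantal_mixture(x2, q_init = 623, sigma_init = 122,
                            fix_quantal = TRUE)
  expect_equal(f2$n_components, 2L)
  expect_lt(abs(unname(f2$weights[2]) - 0.17), 0.06)
  expect_gt(f2$c, 1.1); expect_lt(f2$c, 1.6)
  expect_equal(f2$multipliers, c(1, f2$c))
  # 8 mM-like: 70% multivesicular over three components
  x8 <- rquantal_mix(1100, c(0.30, 0.40, 0.30), c(1, 1.34, 2))
  f8 <- fit_quantal_mixture(x8, q_init = 623, sigma_init = 122,
                            fix_quantal = TRUE)
  expect_equal(f8$n_components, 3L)
  # third component hard-constrained to exactly 2q
  expect_identical(f8$multipliers[3] * f8$q, 2 * f8$q)
  expect_equal(f8$multipliers[3] * f8$q, 1246)
  expect_lt(abs(multivesicular_fraction(f8) - 0.70), 0.06)
  # weights live on the simplex
  expect_equal(sum(f2$weights), 1, tolerance = 1e-9)
  expect_equal(sum(f8$weights), 1, tolerance = 1e-9)
  expect_true(all(f8$weights >= 0))
  expect_error(fit_quantal_mixture(rnorm(50, 623, 122)), "100")
  expect_error(fit_quantal_mixture(x2, fix_quantal = TRUE), "q_init")
})

test_that("mixture fits are invariant to data ordering", {
  set.seed(53)
  x <- rquantal_mix(1200, c(0.7, 0.3), c(1, 1.34))
  f1 <- fit_quantal_mixture(x, q_init = 623, sigma_init = 122,
                            fix_quantal = TRUE)
  f2 <- fit_quantal_mixture(sample(x), q_init = 623, sigma_init = 122,
                            fix_quantal = TRUE)
  expect_equal(f1$weights, f2$weights, tolerance = 1e-6)
  expect_equal(f1$c, f2$c, tolerance = 1e-6)
})

test_that("component count is selected correctly in most replicates", {
  set.seed(54)
  scen <- list(list(w = 1, m = 1, k = 1L),
               list(w = c(0.83, 0.17), m = c(1, 1.34), k = 2L),
               list(w = c(0.30, 0.40, 0.30), m = c(1, 1.34, 2), k = 3L))
  for (s in scen) {
    ks <- replicate(8, {
      x <- rquantal_mix(1200, s$w, s$m)
      fit_quantal_mixture(x, q_init = 623, sigma_init = 122,
                          fix_quantal = TRUE)$n_components
    })
    expect_gte(mean(ks == s$k), 0.8)
  }
})

test_that("multivesicular fraction sums weights above 1q", {
  set.seed(56)
  x <- rquantal_mix(1100, c(0.30, 0.40, 0.30), c(1, 1.34, 2))
  f <- fit_quantal_mixture(x, q_init = 623, sigma_init = 122,
                           fix_quantal = TRUE)
  expect_equal(multivesicular_fraction(f), sum(f$weights[-1]))
})

test_that("Beta fits to decay times recover shapes, mean and median", {
  set.seed(61)
  u <- runif(1000)
  fu <- fit_beta_decay(u, scale = 1.0000001)
  expect_equal(fu$alpha, 1, tolerance = 0.15)
  expect_equal(fu$beta, 1, tolerance = 0.15)
  x <- 0.8 * rbeta(1000, 2, 5)
  f <- fit_beta_decay(x, scale = 0.8)
  expect_equal(f$alpha, 2, tolerance = 0.15)
  expect_equal(f$beta, 5, tolerance = 0.15)
  # reported mean and median are exact functionals of the fit
  expect_identical(f$mean, 0.8 * f$alpha / (f$alpha + f$beta))
  expect_identical(f$median, 0.8 * qbeta(0.5, f$alpha, f$beta))
  expect_equal(f$mean, 0.8 * 2 / 7, tolerance = 0.05)
  # default scale sits just above the largest observation
  fd <- fit_beta_decay(x)
  expect_equal(fd$scale, max(x) * 1.05)
  # explicit support interval rescales before fitting
  fs <- fit_beta_decay(x + 1, support = c(1, 1.81))
  expect_equal(fs$shift, 1)
  expect_equal(fs$mean, 1 + 0.81 * fs$alpha / (fs$alpha + fs$beta))
  expect_error(fit_beta_decay(c(x, -0.1)), "positive")
  expect_error(fit_beta_decay(x[1:10]), "50")
})

test_that("distribution comparisons report Dmax and its location", {
  set.seed(71)
  a <- rnorm(500)
  ident <- compare_distributions(a, a, test = "KS")
  expect_equal(ident$ks_stat, 0)
  expect_equal(ident$p, 1)
  b <- rnorm(500, 3)
  sep <- compare_distributions(a, b, test = "KS")
  expect_lt(sep$p, 1e-6)
  # Dmax location against a brute-force ECDF scan
  grid <- sort(c(a, b))
  gap <- abs(ecdf(a)(grid) - ecdf(b)(grid))
  expect_equal(sep$ks_stat, max(gap), tolerance = 1e-12)
  expect_equal(sep$dmax_location, grid[which.max(gap)])
  # other configured tests dispatch
  expect_lt(compare_distributions(a, b, test = "t_test")$p, 1e-6)
  expect_lt(compare_distributions(a, b, test = "chi2_gof")$p, 1e-6)
  dpn <- compare_distributions(a, test = "dagostino_pearson")
  expect_gt(dpn$p, 1e-3)
  expect_error(compare_distributions(a, b, test = "anova"))
  expect_error(compare_distributions(1:3, 1:10, test = "KS"), ">= 5")
})
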