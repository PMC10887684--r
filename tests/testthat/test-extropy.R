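test_that("true extropy matches closed forms and quadrature", {
  expect_equal(true_extropy(dist_spec("uniform")), -0.5)
  expect_equal(true_extropy(dist_spec("exponential", rate = 1)), -0.25)
  expect_equal(true_extropy(dist_spec("exponential", rate = 2)), -0.5)
  for (fam in c("exponential", "lognormal", "uniform", "power2x",
                "rayleigh")) {
    d <- dist_spec(fam)
    expect_equal(true_extropy(d, method = "quadrature"),
                 true_extropy(d, method = "closed_form"),
                 tolerance = 1e-7, label = fam)
  }
})

test_that("true weighted extropy: closed forms agree with quadrature", {
  # exponential: -1/8 for every rate
  for (l in c(0.25, 0.5, 1, 2, 4)) {
    d <- dist_spec("exponential", rate = l)
    expect_equal(true_weighted_extropy(d), -0.125)
    expect_equal(true_weighted_extropy(d, method = "quadrature"), -0.125,
                 tolerance = 1e-8, label = sprintf("rate %g", l))
  }
  # lognormal: -1/(4 sigma sqrt(pi)), independent of meanlog
  for (s in c(0.5, 1, 1.066, 2)) {
    d <- dist_spec("lognormal", meanlog = 0.3, sdlog = s)
    expect_equal(true_weighted_extropy(d, method = "quadrature"),
                 -1 / (4 * s * sqrt(pi)), tolerance = 1e-8,
                 label = sprintf("sdlog %g", s))
  }
  expect_equal(true_weighted_extropy(dist_spec("lognormal")), -0.1410474,
               tolerance = 1e-6)
  expect_equal(true_weighted_extropy(dist_spec("uniform")), -0.25)
  expect_equal(true_weighted_extropy(dist_spec("power2x")), -0.5)
  expect_equal(true_weighted_extropy(dist_spec("power2x"),
                                     method = "quadrature"), -0.5,
               tolerance = 1e-8)
  expect_equal(true_weighted_extropy(dist_spec("rayleigh"),
                                     method = "quadrature"), -0.25,
               tolerance = 1e-8)
})

test_that("estimators equal dense brute-force integrals of their formulas", {
  s <- fixed_sample_50()
  h_log <- plugin_bandwidth(s, "log")$h
  h_raw <- plugin_bandwidth(s, "raw")$h
  expect_equal(we_lkde(s, h = h_log)$value,
               oracle_we_lkde(s$values, h_log), tolerance = 1e-6)
  expect_equal(we_kde(s, h = h_raw)$value,
               oracle_we_kde(s$values, h_raw), tolerance = 1e-6)
  expect_equal(we_empirical(s, h = h_raw)$value,
               oracle_we_empirical(s$values, h_raw), tolerance = 1e-10)
  # small-sample kde check on a hand-specified sample
  expect_equal(we_kde(c(1, 2, 3), h = 0.5)$value,
               oracle_we_kde(c(1, 2, 3), 0.5), tolerance = 1e-6)
})

test_that("weighted and Fubini double-integral forms of the lkde agree", {
  s <- fixed_sample_50()
  direct <- we_lkde(s, h = 0.35)$value
  fubini <- we_lkde(s, h = 0.35, form = "fubini")$value
  expect_equal(direct, fubini, tolerance = 1e-6)
})

test_that("empirical estimator spacing arithmetic is exact", {
  # single spacing {1, 2}: -(1/4)(4 - 1) fhat(1)^2
  h <- 0.7
  fhat1 <- kde_fit(c(1, 2), h = h)$evaluate(1)
  expect_equal(we_empirical(c(1, 2), h = h)$value, -0.75 * fhat1^2,
               tolerance = 1e-12)
  # tied sample: all spacings zero
  expect_equal(we_empirical(c(2, 2, 2), h = 1)$value, 0)
})

test_that("every estimator is nonpositive on positive samples", {
  for (fam in c("exponential", "lognormal", "uniform", "power2x",
                "rayleigh")) {
    s <- sample_distribution(dist_spec(fam), 60, seed = 100 + match(fam,
           c("exponential", "lognormal", "uniform", "power2x", "rayleigh")))
    expect_lte(we_lkde(s)$value, 0, label = paste("lkde", fam))
    expect_lte(we_kde(s)$value, 0, label = paste("kde", fam))
    expect_lte(we_empirical(s)$value, 0, label = paste("empirical", fam))
  }
})

test_that("order invariance of the estimators", {
  set.seed(77)
  x <- rexp(40)
  expect_identical(we_empirical(x, h = 0.3)$value,
                   we_empirical(rev(x), h = 0.3)$value)
  expect_identical(we_kde(x, h = 0.3)$value,
                   we_kde(rev(x), h = 0.3)$value)
})

test_that("lkde estimator is consistent for the exponential", {
  set.seed(2024)
  means <- replicate(200, we_lkde(rexp(2000))$value)
  expect_lt(abs(mean(means) + 0.125), 0.01)
})

test_that("lkde RMSE decreases with sample size (exponential)", {
  rmse <- vapply(c(50, 200, 800), function(n) {
    v <- vapply(1:200, function(r) {
      set.seed(n * 1000 + r)
      we_lkde(rexp(n))$value
    }, numeric(1))
    sqrt(mean((v + 0.125)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("parametric plug-in estimates", {
  set.seed(12)
  x <- rexp(40, rate = 3.2)
  est <- we_parametric(x, "exponential")
  expect_identical(est$value, -0.125) # rate-free
  # lognormal at the injected parameters of the heavy-tailed fit
  d <- dist_spec("lognormal", meanlog = 1.756, sdlog = 1.066)
  expect_lt(abs(true_weighted_extropy(d) - (-0.1323)), 1e-4)
  expect_lt(abs(true_weighted_extropy(d, method = "quadrature") - (-0.1323)),
            1e-4)
  # fitted lognormal recovers the closed form at the ML estimates
  set.seed(13)
  y <- rlnorm(200, 1.7, 1.1)
  est2 <- we_parametric(y, "lognormal")
  sd_hat <- sqrt(mean((log(y) - mean(log(y)))^2))
  expect_equal(est2$value, -1 / (4 * sd_hat * sqrt(pi)), tolerance = 1e-8)
  # nonpositive data cannot form a lifetime sample at all
  expect_error(we_parametric(c(0, 1, 2), "lognormal"), "positive")
})

test_that("theory terms scale exactly and match the Fubini oracle", {
  d <- dist_spec("exponential")
  expect_equal(we_lkde_bias_theory(d, 0.2) / we_lkde_bias_theory(d, 0.1),
               4, tolerance = 1e-9)
  v <- we_lkde_var_theory(d, n = 100, h = 0.1)
  expect_equal(we_lkde_var_theory(d, n = 200, h = 0.1), v / 2,
               tolerance = 1e-9)
  expect_equal(we_lkde_var_theory(d, n = 100, h = 0.2), v / 2,
               tolerance = 1e-9)
  # nested double integrals vs single-integral oracles
  expect_equal(we_lkde_bias_theory(d, 0.1),
               -0.01 / 2 * oracle_bias_functional(d), tolerance = 1e-4)
  expect_equal(v, 1 / (2 * sqrt(pi)) / 10 * oracle_var_functional(d),
               tolerance = 1e-4)
  # exponential closed form: bias = +h^2/16
  expect_equal(we_lkde_bias_theory(d, 0.1), 0.1^2 / 16, tolerance = 1e-6)
})

test_that("AMISE is minimised at the closed-form optimal bandwidth", {
  d <- dist_spec("exponential")
  th <- we_lkde_amise(d, n = 100)
  h0 <- th$h_opt
  amise_at <- function(h) we_lkde_amise(d, n = 100, h = h)$amise
  # central difference derivative vanishes at h_opt
  eps <- 1e-4 * h0
  deriv <- (amise_at(h0 + eps) - amise_at(h0 - eps)) / (2 * eps)
  expect_lt(abs(deriv), 1e-6 * th$amise / h0)
  expect_lte(th$amise, amise_at(h0 / 2))
  expect_lte(th$amise, amise_at(2 * h0))
  # h_opt scaling through the theory object
  expect_equal(we_lkde_amise(d, n = 3200)$h_opt / h0, 0.5,
               tolerance = 1e-9)
})
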