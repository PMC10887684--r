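test_that("kde and lkde reproduce closed-form evaluations", {
  s <- lifetime_sample(c(1, 1))
  expect_equal(kde_fit(s, h = 1)$evaluate(1), dnorm(0), tolerance = 1e-7)
  expect_equal(lkde_fit(s, h = 1)$evaluate(1), dnorm(0), tolerance = 1e-7)
  # two distinct points, hand-computed mixture value
  s2 <- lifetime_sample(c(1, 3))
  expect_equal(kde_fit(s2, h = 0.5)$evaluate(2),
               mean(dnorm((2 - c(1, 3)) / 0.5)) / 0.5, tolerance = 1e-12)
})

test_that("fitted densities integrate to one", {
  set.seed(5)
  s <- lifetime_sample(rlnorm(40))
  kde <- kde_fit(s)
  lkde <- lkde_fit(s)
  expect_equal(integrate(kde$evaluate, -Inf, Inf, rel.tol = 1e-9)$value,
               1, tolerance = 1e-6)
  expect_equal(integrate(lkde$evaluate, 1e-12,
                         max(s$values) * exp(12 * lkde$h),
                         rel.tol = 1e-9, subdivisions = 400L)$value,
               1, tolerance = 1e-6)
})

test_that("lkde equals the log-space kde after change of variables", {
  set.seed(6)
  x <- rexp(30)
  h <- 0.4
  lk <- lkde_fit(x, h = h)
  y <- log(x)
  at <- c(0.2, 0.7, 1.5, 4)
  log_space <- vapply(log(at),
                      function(t) mean(dnorm((t - y) / h)) / h, numeric(1))
  expect_equal(lk$evaluate(at), log_space / at, tolerance = 1e-12)
})

test_that("estimators are order-invariant and scale-equivariant", {
  set.seed(8)
  x <- rlnorm(25)
  h <- 0.3
  f1 <- lkde_fit(x, h = h)$evaluate(1.3)
  f2 <- lkde_fit(rev(sort(x)), h = h)$evaluate(1.3)
  expect_identical(f1, f2)
  # Y = cX: lkde_Y(c x) = lkde_X(x) / c exactly (log-space shift)
  cc <- 3.7
  fX <- lkde_fit(x, h = h)$evaluate(c(0.5, 1, 2))
  fY <- lkde_fit(cc * x, h = h)$evaluate(cc * c(0.5, 1, 2))
  expect_equal(fY, fX / cc, tolerance = 1e-12)
})

test_that("densities are nonnegative on their grids", {
  set.seed(9)
  s <- lifetime_sample(rexp(40))
  expect_true(all(kde_fit(s)$grid$fx >= 0))
  expect_true(all(lkde_fit(s)$grid$fx >= 0))
})

test_that("lkde pointwise bias and variance leading terms are correct", {
  d <- dist_spec("exponential")
  # (h^2/2)[f + 3xf' + x^2 f''] at x = 1 collapses to -(h^2/2) e^{-1}
  expect_equal(lkde_bias(d, x = 1, h = 0.1), -0.005 * exp(-1),
               tolerance = 1e-9)
  expect_lt(abs(lkde_bias(d, x = 1, h = 0.1) - (-0.0018394)), 1e-7)
  expect_identical(lkde_bias(d, x = 2, h = 0), 0)
  expect_error(lkde_bias(d, x = -1, h = 0.1), "support")

  expect_equal(lkde_variance(d, x = 1, n = 100, h = 0.2),
               (1 / (2 * sqrt(pi)) / 20) * exp(-1), tolerance = 1e-9)
  expect_lt(abs(lkde_variance(d, x = 1, n = 100, h = 0.2) - 0.0051889),
            1e-7)
  # exact 1/(nh) scaling
  expect_equal(lkde_variance(d, 1, n = 200, h = 0.2) * 2,
               lkde_variance(d, 1, n = 100, h = 0.2), tolerance = 1e-12)
  expect_error(lkde_variance(d, x = 0, n = 10, h = 0.1), "positive")
})

test_that("simulated lkde moments match the leading-term theory", {
  d <- dist_spec("exponential")
  x0 <- 1
  n <- 5000
  reps <- 2000
  draw <- function(h) {
    replicate(reps, {
      x <- rexp(n)
      mean(dnorm((log(x0) - log(x)) / h)) / (x0 * h)
    })
  }
  # bias check at a moderate bandwidth where the h^2 term is visible
  set.seed(314)
  h <- 0.15
  fhat <- draw(h)
  mc_se <- sqrt(lkde_variance(d, x0, n, h) / reps)
  expect_lt(abs(mean(fhat) - d$pdf(x0) - lkde_bias(d, x0, h)), 3 * mc_se)
  # variance check at a smaller bandwidth so the leading 1/(nh) term
  # dominates; the bound allows 3 Monte Carlo s.e. of a sample variance
  # plus the known next-order correction of magnitude f(x)^2/n
  set.seed(315)
  h2 <- 0.05
  fhat2 <- draw(h2)
  theo_var <- lkde_variance(d, x0, n, h2)
  expect_lt(abs(var(fhat2) - theo_var),
            3 * sqrt(2 / reps) * theo_var + d$pdf(x0)^2 / n)
})

test_that("kde integrated squared error decreases with sample size", {
  d <- dist_spec("exponential")
  grid <- seq(0.01, 8, length.out = 200)
  ise <- function(n, seed) {
    set.seed(seed)
    f <- kde_fit(rexp(n))
    mean((f$evaluate(grid) - d$pdf(grid))^2) * diff(range(grid))
  }
  mise_100 <- mean(vapply(1:50, function(s) ise(100, s), numeric(1)))
  mise_1000 <- mean(vapply(1:50, function(s) ise(1000, 1000 + s), numeric(1)))
  expect_lt(mise_1000, mise_100)
})

test_that("degenerate inputs raise domain errors", {
  expect_error(kde_fit(numeric(0)), "non-empty")
  expect_error(kde_fit(lifetime_sample(1.5)), "n >= 2")
  expect_error(lifetime_sample(c(1, -2)), "positive")
  expect_error(lifetime_sample(c(1, NA)), "finite")
  expect_error(lkde_fit(c(1, 2), h = 0.5)$evaluate(-1), "x > 0")
})
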