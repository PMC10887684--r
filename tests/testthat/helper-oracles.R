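# Independent brute-force oracles for the weighted-extropy estimators.
# These integrate the defining formulas with stats::integrate() and share
# no code with the package's Simpson-grid implementations.

oracle_we_lkde <- function(x, h) {
  f <- function(t) {
    vapply(t, function(ti) mean(dnorm((log(ti) - log(x)) / h)) / (ti * h),
           numeric(1))
  }
  -0.5 * stats::integrate(function(t) t * f(t)^2,
                          lower = 1e-12, upper = max(x) * exp(10 * h),
                          rel.tol = 1e-10, subdivisions = 500L)$value
}

oracle_we_kde <- function(x, h) {
  f <- function(t) {
    vapply(t, function(ti) mean(dnorm((ti - x) / h)) / h, numeric(1))
  }
  -0.5 * stats::integrate(function(t) t * f(t)^2,
                          lower = 0, upper = max(x) + 10 * h,
                          rel.tol = 1e-10, subdivisions = 500L)$value
}

oracle_we_empirical <- function(x, h) {
  xs <- sort(x)
  n <- length(x)
  total <- 0
  for (i in seq_len(n - 1L)) {
    fi <- mean(dnorm((xs[i] - x) / h)) / h
    total <- total - 0.25 * (xs[i + 1L]^2 - xs[i]^2) * fi^2
  }
  total
}

# Single-integral (Fubini-collapsed) forms of the theory functionals, used
# as independent oracles for the nested double-integral implementation:
# Int_0^inf dy Int_y^inf g = Int_0^inf x g(x) dx.
oracle_bias_functional <- function(dist) {
  stats::integrate(function(x)
    x * (dist$pdf(x) + 3 * x * dist$pdf_d1(x) + x^2 * dist$pdf_d2(x)) *
      dist$pdf(x),
    0, dist$quantile(1 - 1e-12), rel.tol = 1e-10)$value
}

oracle_var_functional <- function(dist) {
  stats::integrate(function(x) dist$pdf(x)^3,
                   0, dist$quantile(1 - 1e-12), rel.tol = 1e-10)$value
}

# Fixed exponential sample shared by the oracle-equality tests.
fixed_sample_50 <- function() {
  set.seed(421)
  lifetime_sample(rexp(50))
}
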