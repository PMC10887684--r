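# Internal numerical helpers.

# Composite Simpson rule on an equally spaced grid with an even number of
# intervals. `fx` holds the integrand values, `dx` the spacing.
simpson <- function(fx, dx) {
  m <- length(fx) - 1L
  stopifnot(m >= 2L, m %% 2L == 0L)
  dx / 3 * (fx[1L] + fx[m + 1L] +
            4 * sum(fx[seq(2L, m, by = 2L)]) +
            2 * sum(fx[seq(3L, m - 1L, by = 2L)]))
}

# Simpson integration of `f` over [lower, upper] on a grid of `m` intervals,
# with one refinement pass: the integrand is evaluated once on the refined
# grid (4m intervals) and the coarse value is recovered by striding, so a
# converged integral costs a single fine evaluation. If coarse and fine
# disagree by more than `tol` the grid is refined once more (16m intervals).
simpson_refined <- function(f, lower, upper, m = 1024L, tol = 1e-6) {
  value_pair <- function(m_fine) {
    g <- seq(lower, upper, length.out = m_fine + 1L)
    fx <- f(g)
    dx <- (upper - lower) / m_fine
    coarse <- simpson(fx[seq(1L, m_fine + 1L, by = 4L)], 4 * dx)
    c(coarse, simpson(fx, dx))
  }
  v <- value_pair(4L * m)
  if (abs(v[2L] - v[1L]) > tol) v <- value_pair(16L * m)
  v[2L]
}

# Adaptive quadrature wrapper with a uniform error message.
quad <- function(f, lower, upper, rel.tol = 1e-8, ...) {
  res <- tryCatch(
    stats::integrate(f, lower, upper, rel.tol = rel.tol,
                     subdivisions = 500L, ...),
    error = function(e) stop("quadrature failed on [", signif(lower, 4), ", ",
                             signif(upper, 4), "]: ", conditionMessage(e),
                             call. = FALSE)
  )
  res$value
}

stop_domain <- function(...) stop(..., call. = FALSE)

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_domain("`", name, "` must be a single finite positive number")
  invisible(x)
}
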