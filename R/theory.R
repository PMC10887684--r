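#' Asymptotic theory of the log-kernel weighted-extropy estimator
#'
#' Leading bias and variance terms of \eqn{\hat J_n^w(X)} and the resulting
#' AMISE and optimal bandwidth. The two density functionals are
#' \deqn{I_b = \int_0^\infty\!dy\int_y^\infty
#'   \big[f_X(x) + 3x f_X'(x) + x^2 f_X''(x)\big] f_X(x)\,dx, \qquad
#'   I_v = \int_0^\infty\!dy\int_y^\infty \frac{f_X^3(x)}{x}\,dx,}
#' giving
#' \deqn{Bias(\hat J_n^w) \approx -\frac{h^2}{2} I_b, \qquad
#'   Var(\hat J_n^w) \approx \frac{C_K}{nh} I_v, \qquad
#'   AMISE(h) = \frac{h^4}{4} I_b^2 + \frac{C_K}{nh} I_v,}
#' minimised at \eqn{h_{opt} = (C_K I_v / I_b^2)^{1/5} n^{-1/5}}.
#'
#' Both functionals are computed by nested adaptive quadrature of the
#' double integrals (inner integral at each outer node; relative tolerance
#' `1e-8`), truncated at the distribution's \eqn{1-10^{-9}} quantile.
#' Divergent functionals (for example a variance integrand
#' \eqn{f^3/x} that is not integrable near 0) surface as a quadrature
#' error with a diagnostic.
#'
#' @param dist A [dist_spec()] with analytic derivatives.
#' @param h Bandwidth, positive.
#' @param n Sample size, positive.
#' @param kernel A [kernel_spec()] (supplies \eqn{C_K}).
#' @return `we_lkde_bias_theory()`: the signed leading bias term,
#'   proportional to \eqn{h^2}. `we_lkde_var_theory()`: the nonnegative
#'   leading variance term, proportional to \eqn{1/(nh)}.
#'   `we_lkde_amise()`: a list of class `we_theory` with `amise`, `h_opt`,
#'   `bias_term`, `variance_term`, `n`, `h`, and the functionals `I_b`,
#'   `I_v`.
#' @examples
#' d <- dist_spec("exponential")
#' we_lkde_bias_theory(d, h = 0.1)
#' th <- we_lkde_amise(d, n = 100)
#' th$h_opt
#' @export
we_lkde_bias_theory <- function(dist, h) {
  stopifnot(inherits(dist, "dist_spec"))
  if (!is.numeric(h) || length(h) != 1L || h < 0)
    stop_domain("`h` must be nonnegative")
  -h^2 / 2 * double_integral(dist, function(x)
    (dist$pdf(x) + 3 * x * dist$pdf_d1(x) + x^2 * dist$pdf_d2(x)) *
      dist$pdf(x))
}

#' @rdname we_lkde_bias_theory
#' @export
we_lkde_var_theory <- function(dist, n, h, kernel = kernel_gaussian()) {
  stopifnot(inherits(dist, "dist_spec"))
  check_positive_scalar(n, "n")
  check_positive_scalar(h, "h")
  v <- kernel$roughness / (n * h) *
    double_integral(dist, function(x) dist$pdf(x)^3 / x)
  if (v < 0) stop("internal error: negative variance functional",
                  call. = FALSE)
  v
}

#' @rdname we_lkde_bias_theory
#' @export
we_lkde_amise <- function(dist, n, h = NULL, kernel = kernel_gaussian()) {
  stopifnot(inherits(dist, "dist_spec"))
  check_positive_scalar(n, "n")
  fun <- we_functionals(dist, kernel)
  if (fun$A <= 0 || fun$B <= 0)
    stop_domain("degenerate AMISE functionals (A = ", signif(fun$A, 6),
                ", B = ", signif(fun$B, 6), ")")
  h_opt <- (fun$B / fun$A)^(1 / 5) * n^(-1 / 5)
  if (is.null(h)) h <- h_opt
  check_positive_scalar(h, "h")
  structure(list(
    amise = h^4 / 4 * fun$A + fun$B / (n * h),
    h_opt = h_opt,
    bias_term = -h^2 / 2 * fun$I_b,
    variance_term = fun$B / (n * h),
    I_b = fun$I_b, I_v = fun$I_v,
    n = n, h = h), class = "we_theory")
}

#' @export
print.we_theory <- function(x, ...) {
  cat("<we_theory> n =", x$n, " h =", format(x$h),
      "\n  AMISE =", format(x$amise), " h_opt =", format(x$h_opt),
      "\n  bias term =", format(x$bias_term),
      " variance term =", format(x$variance_term), "\n")
  invisible(x)
}

# Shared functionals: A = I_b^2 (squared bias functional), B = C_K * I_v.
we_functionals <- function(dist, kernel = kernel_gaussian()) {
  I_b <- double_integral(dist, function(x)
    (dist$pdf(x) + 3 * x * dist$pdf_d1(x) + x^2 * dist$pdf_d2(x)) *
      dist$pdf(x))
  I_v <- double_integral(dist, function(x) dist$pdf(x)^3 / x)
  list(I_b = I_b, I_v = I_v, A = I_b^2, B = kernel$roughness * I_v)
}

# Nested quadrature of Int_0^U dy Int_y^U g(x) dx with U the 1 - 1e-9
# quantile (or the finite support endpoint). The inner integral is computed
# by adaptive quadrature at every node the outer rule requests.
double_integral <- function(dist, g) {
  upper <- dist_upper(dist)
  inner <- function(y) quad(g, y, upper, rel.tol = 1e-8)
  quad(Vectorize(inner), 0, upper, rel.tol = 1e-8)
}
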