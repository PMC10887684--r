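#' Kernel specifications
#'
#' A kernel specification bundles a symmetric probability kernel \eqn{K} with
#' its roughness \eqn{C_K = \int K^2(z)\,dz}, the constant entering every
#' variance expression of the kernel and log-kernel estimators. On
#' construction the kernel conditions are verified by quadrature:
#' \eqn{\int K = 1}, \eqn{\int zK = 0}, \eqn{\int z^2 K = 1}, and
#' \eqn{C_K < \infty}.
#'
#' @param name Identifier for the kernel.
#' @param fn Vectorised kernel function, a density on the real line.
#' @param roughness Optional known value of \eqn{\int K^2}; computed by
#'   quadrature when omitted.
#' @param check Verify the kernel conditions (relative tolerance `1e-6`)?
#'
#' @return An object of class `kernel_spec` with elements `name`, `fn`,
#'   `roughness`.
#' @examples
#' k <- kernel_gaussian()
#' k$roughness # 1 / (2 sqrt(pi))
#' @export
kernel_spec <- function(name, fn, roughness = NULL, check = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  if (check) {
    mass <- quad(fn, -Inf, Inf)
    mu1  <- quad(function(z) z * fn(z), -Inf, Inf)
    mu2  <- quad(function(z) z^2 * fn(z), -Inf, Inf)
    if (abs(mass - 1) > 1e-6)
      stop_domain("kernel does not integrate to 1 (got ", signif(mass, 8), ")")
    if (abs(mu1) > 1e-6)
      stop_domain("kernel first moment is not 0 (got ", signif(mu1, 8), ")")
    if (abs(mu2 - 1) > 1e-6)
      stop_domain("kernel second moment is not 1 (got ", signif(mu2, 8), ")")
  }
  if (is.null(roughness)) roughness <- quad(function(z) fn(z)^2, -Inf, Inf)
  if (!is.finite(roughness) || roughness <= 0)
    stop_domain("kernel roughness must be finite and positive")
  structure(list(name = name, fn = fn, roughness = roughness),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("<kernel_spec>", x$name, " roughness C_K =", format(x$roughness), "\n")
  invisible(x)
}

#' The Gaussian kernel
#'
#' `gaussian_kernel()` evaluates the standard normal density; it is the
#' kernel used throughout the simulation study (both on the raw scale and
#' inside the log kernel). `kernel_gaussian()` wraps it as a [kernel_spec()]
#' with the exact roughness \eqn{C_K = 1/(2\sqrt{\pi})}.
#'
#' @param u Numeric vector of evaluation points; must be finite.
#' @return `gaussian_kernel()`: the kernel values; `kernel_gaussian()`: a
#'   `kernel_spec`.
#' @examples
#' gaussian_kernel(0) # 1/sqrt(2*pi)
#' @export
gaussian_kernel <- function(u) {
  if (!is.numeric(u) || any(!is.finite(u)))
    stop_domain("kernel argument must be finite numeric")
  stats::dnorm(u)
}

#' @rdname gaussian_kernel
#' @export
kernel_gaussian <- function() {
  kernel_spec("gaussian", stats::dnorm, roughness = 1 / (2 * sqrt(pi)),
              check = FALSE)
}

#' The log kernel
#'
#' The log kernel \eqn{L(x, z, h) = \frac{1}{xh} K\!\big(\log(x/z)/h\big)}
#' is the building block of the log-transformed kernel density estimator: an
#' ordinary kernel placed in log space and mapped back to \eqn{(0,\infty)}.
#' For every location \eqn{z > 0} and bandwidth \eqn{h > 0} it is a density
#' on \eqn{(0, \infty)}.
#'
#' @param x Evaluation points, strictly positive.
#' @param z Location parameter, strictly positive scalar.
#' @param h Bandwidth on the log scale, strictly positive scalar.
#' @param kernel A [kernel_spec()]; Gaussian by default.
#' @return Nonnegative density values at `x`.
#' @examples
#' log_kernel(1, z = 1, h = 1) # K(0)
#' @export
log_kernel <- function(x, z, h, kernel = kernel_gaussian()) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop_domain("`x` must be finite and > 0")
  check_positive_scalar(z, "z")
  check_positive_scalar(h, "h")
  kernel$fn(log(x / z) / h) / (x * h)
}
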