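#' Lifetime samples
#'
#' A validated univariate sample of strictly positive lifetimes, carrying a
#' sorted view (the order statistics \eqn{X_{1:n} \le \dots \le X_{n:n}})
#' used by the empirical weighted-extropy estimator.
#'
#' @param x Numeric vector of lifetimes; every value must be finite and
#'   strictly positive.
#' @return An object of class `lifetime_sample` with elements `values`,
#'   `n` and `sorted` (the order statistics).
#' @examples
#' s <- lifetime_sample(c(2.3, 0.7, 1.1))
#' s$sorted
#' @export
lifetime_sample <- function(x) {
  if (inherits(x, "lifetime_sample")) return(x)
  if (!is.numeric(x) || length(x) == 0L)
    stop_domain("a lifetime sample must be a non-empty numeric vector")
  x <- as.numeric(x)
  if (any(!is.finite(x)))
    stop_domain("lifetime sample contains non-finite values")
  if (any(x <= 0))
    stop_domain("lifetimes must be strictly positive; found ",
                sum(x <= 0), " nonpositive value(s)")
  structure(list(values = x, n = length(x), sorted = sort(x)),
            class = "lifetime_sample")
}

#' @rdname lifetime_sample
#' @param object Object to test or coerce.
#' @export
is_lifetime_sample <- function(object) inherits(object, "lifetime_sample")

#' @export
print.lifetime_sample <- function(x, ...) {
  cat("<lifetime_sample> n =", x$n,
      " range = [", format(min(x$values)), ",", format(max(x$values)), "]\n")
  invisible(x)
}
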