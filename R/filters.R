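#' Homophilic spectral filter families
#'
#' A spectral filter is a scalar function \eqn{g(\omega)} on \eqn{[-1, 1]},
#' the spectral range of the self-loop-normalized adjacency. All three
#' families implemented here are low-pass on the adjacency (monotonically
#' non-decreasing in \eqn{\omega}), matching the homophily assumption of
#' cell-type clustering:
#'
#' * `rwr` — random walk with restart, \eqn{g(\omega) = (1-\alpha)/(1-\alpha\omega)},
#'   the spectral response of \eqn{(1-\alpha)(I-\alpha \hat A)^{-1}};
#' * `heat` — heat-kernel diffusion for time `T`,
#'   \eqn{g(\omega) = e^{T(\omega - 1)}}, the response of \eqn{e^{-T(I-\hat A)}};
#' * `beta` — the zeroth-order beta kernel of order `K`,
#'   \eqn{g(\omega) = (K+1)\,((1+\omega)/2)^K}, a polynomial by construction.
#'
#' @param family `"rwr"`, `"heat"` or `"beta"`.
#' @param alpha restart/damping parameter in (0, 1) (rwr only).
#' @param t diffusion time, positive (heat only).
#' @param k polynomial order, non-negative integer (beta only).
#' @return An object of class `spectral_filter`; call it on \eqn{\omega}
#'   values with [filter_value()].
#' @export
spectral_filter <- function(family = c("rwr", "heat", "beta"),
                            alpha = NULL, t = NULL, k = NULL) {
  family <- match.arg(family)
  params <- switch(family,
    rwr = {
      stop_if_not_scalar_number(alpha %||% rlang::abort("rwr needs `alpha`"),
                                "alpha", lo = 0, hi = 1, open = TRUE)
      list(alpha = alpha)
    },
    heat = {
      stop_if_not_scalar_number(t %||% rlang::abort("heat needs `t`"),
                                "t", lo = 0, open = TRUE)
      list(t = t)
    },
    beta = {
      stop_if_not_scalar_number(k %||% rlang::abort("beta needs `k`"),
                                "k", lo = 0, integer = TRUE)
      list(k = as.integer(k))
    }
  )
  structure(list(family = family, params = params), class = "spectral_filter")
}

#' @export
print.spectral_filter <- function(x, ...) {
  cat(sprintf("<spectral_filter> %s(%s)\n", x$family,
              paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Evaluate a spectral filter
#'
#' @param filter a [spectral_filter()].
#' @param omega numeric vector in \eqn{[-1, 1]}.
#' @return numeric vector \eqn{g(\omega)}.
#' @export
filter_value <- function(filter, omega) {
  stopifnot(inherits(filter, "spectral_filter"))
  if (any(abs(omega) > 1 + 1e-12)) {
    rlang::abort("`omega` must lie in [-1, 1]")
  }
  switch(filter$family,
    rwr = rwr_filter_value(omega, filter$params$alpha),
    heat = heat_filter_value(omega, filter$params$t),
    beta = (filter$params$k + 1) * ((1 + omega) / 2)^filter$params$k
  )
}

#' @rdname filter_value
#' @param omega numeric vector in \eqn{[-1,1]}.
#' @param alpha restart parameter in (0, 1).
#' @export
rwr_filter_value <- function(omega, alpha) {
  stop_if_not_scalar_number(alpha, "alpha", lo = 0, hi = 1, open = TRUE)
  (1 - alpha) / (1 - alpha * omega)
}

#' @rdname filter_value
#' @param t diffusion time, positive.
#' @export
heat_filter_value <- function(omega, t) {
  stop_if_not_scalar_number(t, "t", lo = 0, open = TRUE)
  exp(t * (omega - 1))
}

#' Polynomial coefficient vectors
#'
#' Monomial coefficients \eqn{\theta_0 \dots \theta_K} of the degree-K
#' propagation polynomial \eqn{\sum_k \theta_k \hat A^k}, tagged with the
#' scheme that produced them.
#'
#' @param coeffs numeric vector of length K+1, all finite.
#' @param scheme one of `"rwr_truncated"`, `"rwr_interpolated"`,
#'   `"heat_taylor"`, `"heat_interpolated"`, `"beta_direct"`,
#'   `"beta_interpolated"`, `"random"`, `"custom"`.
#' @param source_filter the [spectral_filter()] the coefficients derive from,
#'   or `NULL`.
#' @return An object of class `coef_vector`.
#' @export
coefficient_vector <- function(coeffs,
                               scheme = "custom",
                               source_filter = NULL) {
  if (!is.numeric(coeffs) || length(coeffs) < 1L || any(!is.finite(coeffs))) {
    rlang::abort("`coeffs` must be a non-empty finite numeric vector")
  }
  scheme <- match.arg(scheme, c(
    "rwr_truncated", "rwr_interpolated", "heat_taylor", "heat_interpolated",
    "beta_direct", "beta_interpolated", "random", "custom"
  ))
  structure(
    list(coeffs = as.numeric(coeffs), scheme = scheme,
         source_filter = source_filter),
    class = "coef_vector"
  )
}

#' @export
print.coef_vector <- function(x, ...) {
  cat(sprintf("<coef_vector> K=%d scheme=%s\n", length(x$coeffs) - 1L, x$scheme))
  print(signif(x$coeffs, 5))
  invisible(x)
}

#' Degree of a coefficient vector
#' @param x a `coef_vector`.
#' @export
poly_degree <- function(x) length(x$coeffs) - 1L

#' Evaluate the polynomial of a coefficient vector
#'
#' Horner evaluation of \eqn{P(\omega) = \sum_k \theta_k \omega^k}.
#'
#' @param x a `coef_vector` (or bare numeric vector of coefficients).
#' @param omega numeric vector.
#' @export
poly_value <- function(x, omega) {
  cf <- if (inherits(x, "coef_vector")) x$coeffs else as.numeric(x)
  out <- rep(cf[length(cf)], length(omega))
  for (k in rev(seq_len(length(cf) - 1L))) {
    out <- out * omega + cf[k]
  }
  out
}

#' Closed-form coefficient schemes
#'
#' Non-interpolated polynomial coefficients for each filter family:
#' truncation of the RWR Neumann series (\eqn{\theta_k = (1-\alpha)\alpha^k}),
#' the degree-K Taylor/Maclaurin expansion of the heat kernel
#' (\eqn{\theta_k = e^{-T} T^k / k!}), and the exact binomial expansion of the
#' zeroth-order beta kernel (\eqn{\theta_k = (K+1)\binom{K}{k}/2^K}).
#'
#' @param alpha restart parameter in (0, 1).
#' @param K polynomial degree, non-negative integer.
#' @return A `coef_vector` of length K+1.
#' @export
rwr_truncated_coefficients <- function(alpha, K) {
  stop_if_not_scalar_number(alpha, "alpha", lo = 0, hi = 1, open = TRUE)
  stop_if_not_scalar_number(K, "K", lo = 0, integer = TRUE)
  coefficient_vector((1 - alpha) * alpha^(0:K), "rwr_truncated",
                     spectral_filter("rwr", alpha = alpha))
}

#' @rdname rwr_truncated_coefficients
#' @param t diffusion time, positive.
#' @export
heat_taylor_coefficients <- function(t, K) {
  stop_if_not_scalar_number(t, "t", lo = 0, open = TRUE)
  stop_if_not_scalar_number(K, "K", lo = 0, integer = TRUE)
  k <- 0:K
  coefficient_vector(exp(-t) * t^k / factorial(k), "heat_taylor",
                     spectral_filter("heat", t = t))
}

#' @rdname rwr_truncated_coefficients
#' @export
beta_coefficients <- function(K) {
  stop_if_not_scalar_number(K, "K", lo = 0, integer = TRUE)
  coefficient_vector((K + 1) * choose(K, 0:K) / 2^K, "beta_direct",
                     spectral_filter("beta", k = K))
}

#' Random coefficient initialization
#'
#' The no-filter-guidance control: K+1 coefficients drawn i.i.d. uniformly
#' on \eqn{[-1, 1]} (configurable), reproducible by seed.
#'
#' @param K polynomial degree.
#' @param seed integer seed.
#' @param dist `"uniform"` on \eqn{[-1,1]} or `"normal"` (sd 1).
#' @return A `coef_vector` with scheme `"random"`.
#' @export
random_coefficients <- function(K, seed, dist = c("uniform", "normal")) {
  stop_if_not_scalar_number(K, "K", lo = 0, integer = TRUE)
  dist <- match.arg(dist)
  cf <- with_seed(seed, switch(dist,
    uniform = stats::runif(K + 1L, -1, 1),
    normal = stats::rnorm(K + 1L)
  ))
  coefficient_vector(cf, "random")
}
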