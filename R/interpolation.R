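#' Chebyshev sample points on an interval
#'
#' The r Chebyshev nodes \eqn{\cos((2k-1)\pi/(2r))}, \eqn{k = 1..r}, mapped
#' affinely from \eqn{[-1,1]} onto \eqn{[l,u]}. Chebyshev spacing keeps
#' polynomial interpolation well behaved (no Runge oscillation) and, combined
#' with Arnoldi orthonormalization, yields a near-unit-condition basis.
#'
#' @param r number of nodes, at least 1.
#' @param l,u interval bounds, `l < u`. The default \eqn{[-0.9, 0.9]} is the
#'   interval the encoder interpolates on: it covers the bulk of the spectrum
#'   of the normalized adjacency while staying clear of the RWR filter's pole
#'   beyond \eqn{\omega = 1}.
#' @return An object of class `cheb_nodes` with fields `nodes`, `r`, `l`, `u`.
#' @export
chebyshev_nodes <- function(r, l = -0.9, u = 0.9) {
  stop_if_not_scalar_number(r, "r", lo = 1, integer = TRUE)
  if (!is.numeric(l) || !is.numeric(u) || l >= u) {
    rlang::abort("need interval bounds with l < u")
  }
  k <- seq_len(r)
  base <- cos((2 * k - 1) * pi / (2 * r))
  structure(
    list(nodes = (l + u) / 2 + (u - l) / 2 * base, r = as.integer(r),
         l = l, u = u),
    class = "cheb_nodes"
  )
}

#' Arnoldi orthonormalization of the node-power basis
#'
#' Builds an orthonormal basis Q for the Krylov space
#' \eqn{\{1, \omega, \dots, \omega^K\}} evaluated at the sample nodes, under
#' the discrete inner product \eqn{\langle u,v\rangle = u^\top v / r}. The
#' recurrence starts from the all-ones vector; each new column is
#' \eqn{\Omega q_m} (\eqn{\Omega} the diagonal of nodes) orthogonalized
#' against all previous columns, with the recurrence weights collected in an
#' upper-Hessenberg matrix `H` ((K+1) x K). With real nodes the recurrence is
#' tridiagonal up to rounding (Lanczos), but full Gram-Schmidt is kept for
#' numerical hygiene.
#'
#' This replaces the notoriously ill-conditioned Vandermonde solve: the Gram
#' matrix of Q has condition number ~1 where the raw Vandermonde Gram blows
#' up exponentially in K.
#'
#' @param nodes a [chebyshev_nodes()] object (or any list with a numeric
#'   `nodes` field of distinct values).
#' @param K polynomial degree; requires at least K+1 distinct nodes.
#' @return An object of class `arnoldi_basis` with fields `Q`
#'   (r x (K+1), orthonormal under `crossprod(Q)/r`), `H` ((K+1) x K
#'   Hessenberg recurrence), and `nodes`.
#' @export
arnoldi_orthonormalize <- function(nodes, K) {
  stop_if_not_scalar_number(K, "K", lo = 1, integer = TRUE)
  om <- nodes$nodes
  r <- length(om)
  if (r < K + 1L) {
    rlang::abort(sprintf("need at least K+1 = %d nodes, got %d", K + 1L, r))
  }
  Q <- matrix(0, r, K + 1L)
  Q[, 1L] <- 1
  H <- matrix(0, K + 1L, K)
  for (m in seq_len(K)) {
    q <- om * Q[, m]
    for (j in seq_len(m)) {
      H[j, m] <- sum(Q[, j] * q) / r
      q <- q - H[j, m] * Q[, j]
    }
    # norm under <u,v> = u'v/r
    H[m + 1L, m] <- sqrt(sum(q^2)) / sqrt(r)
    if (H[m + 1L, m] <= 1e-13) {
      rlang::abort(sprintf(
        "Arnoldi breakdown at degree %d: fewer than %d distinct nodes", m, K + 1L
      ))
    }
    Q[, m + 1L] <- q / H[m + 1L, m]
  }
  structure(list(Q = Q, H = H, nodes = nodes), class = "arnoldi_basis")
}

#' @export
print.arnoldi_basis <- function(x, ...) {
  cat(sprintf("<arnoldi_basis> r=%d nodes, degree K=%d\n",
              nrow(x$Q), ncol(x$Q) - 1L))
  invisible(x)
}

# monomial coefficients of each Arnoldi basis polynomial: column m of the
# returned (K+1) x (K+1) matrix C holds the monomial coefficients of q_m,
# recovered by back-substituting the Hessenberg recurrence
#   omega * q_m = sum_{j<=m} H[j,m] q_j + H[m+1,m] q_{m+1}
monomial_basis_matrix <- function(basis) {
  K <- ncol(basis$Q) - 1L
  C <- matrix(0, K + 1L, K + 1L)
  C[1L, 1L] <- 1
  for (m in seq_len(K)) {
    shifted <- c(0, C[seq_len(K), m])   # multiply polynomial by omega
    acc <- shifted
    for (j in seq_len(m)) {
      acc <- acc - basis$H[j, m] * C[, j]
    }
    C[, m + 1L] <- acc / basis$H[m + 1L, m]
  }
  C
}

#' Interpolate a spectral filter with a monomial polynomial
#'
#' Computes monomial coefficients \eqn{a_0 \dots a_K} of the degree-K
#' polynomial matching \eqn{g} at Chebyshev nodes: the filter is projected
#' onto the Arnoldi-orthonormal basis (\eqn{a_A = Q^\dagger g(\omega)}, a
#' plain inner product thanks to orthonormality), then the monomial
#' coefficients are recovered through the Hessenberg change of basis. With
#' `r = K+1` (the default) the interpolation is exact at the nodes; `r > K+1`
#' gives the least-squares fit.
#'
#' @param filter a [spectral_filter()], or any function of one argument.
#' @param K polynomial degree.
#' @param l,u interpolation interval (default \eqn{[-0.9, 0.9]}).
#' @param r number of Chebyshev sample nodes, at least K+1 (default K+1).
#' @return A `coef_vector` with an `*_interpolated` scheme tag.
#' @export
interpolate_coefficients <- function(filter, K, l = -0.9, u = 0.9, r = K + 1L) {
  stop_if_not_scalar_number(K, "K", lo = 1, integer = TRUE)
  if (r < K + 1L) rlang::abort("need r >= K + 1 sample nodes")
  nodes <- chebyshev_nodes(r, l, u)
  basis <- arnoldi_orthonormalize(nodes, K)
  gfun <- filter_as_function(filter)
  gv <- gfun(nodes$nodes)
  a_basis <- drop(crossprod(basis$Q, gv)) / nodes$r
  a <- drop(monomial_basis_matrix(basis) %*% a_basis)
  scheme <- if (inherits(filter, "spectral_filter")) {
    paste0(filter$family, "_interpolated")
  } else {
    "custom"
  }
  coefficient_vector(a, scheme,
                     if (inherits(filter, "spectral_filter")) filter else NULL)
}

filter_as_function <- function(filter) {
  if (inherits(filter, "spectral_filter")) {
    function(om) filter_value(filter, om)
  } else if (is.function(filter)) {
    filter
  } else {
    rlang::abort("`filter` must be a spectral_filter or a function")
  }
}

#' Dense Vandermonde least-squares oracle
#'
#' Solves the monomial interpolation system \eqn{V a = g(\omega)} directly
#' with a dense QR least-squares solver. Restricted to small degrees where
#' the Vandermonde matrix is still tolerably conditioned; used as an
#' independent cross-check of the Arnoldi path.
#'
#' @param nodes a [chebyshev_nodes()] object.
#' @param filter a [spectral_filter()] or function.
#' @param K polynomial degree, at most 8.
#' @return A `coef_vector` (scheme `"custom"`).
#' @export
vandermonde_oracle <- function(nodes, filter, K) {
  stop_if_not_scalar_number(K, "K", lo = 0, hi = 8, integer = TRUE)
  V <- vandermonde_matrix(nodes$nodes, K)
  gv <- filter_as_function(filter)(nodes$nodes)
  coefficient_vector(drop(qr.solve(qr(V), gv)), "custom")
}

vandermonde_matrix <- function(om, K) {
  outer(om, 0:K, "^")
}

#' Condition number of the basis Gram matrix
#'
#' 2-norm condition number (ratio of extreme singular values) of
#' \eqn{Q^\top Q}. Near 1 for the Arnoldi basis; compare with the Gram matrix
#' of the raw Vandermonde basis, which is exponentially ill-conditioned.
#'
#' @param basis an `arnoldi_basis`, or any matrix whose columns form the
#'   basis.
#' @return a single number, at least 1.
#' @export
basis_condition_number <- function(basis) {
  Q <- if (inherits(basis, "arnoldi_basis")) basis$Q else as.matrix(basis)
  sv <- svd(crossprod(Q), nu = 0, nv = 0)$d
  max(sv) / min(sv)
}

#' Sup-norm fidelity of a polynomial to its filter
#'
#' \eqn{\max_\omega |P(\omega) - g(\omega)|} over a 1001-point uniform grid
#' of \eqn{[l, u]}; the figure of merit showing that interpolated
#' coefficients track a filter better than truncated/Taylor ones.
#'
#' @param coeffs a `coef_vector` (or bare numeric coefficients).
#' @param filter a [spectral_filter()] or function.
#' @param l,u evaluation interval (default \eqn{[-0.9, 0.9]}).
#' @param n_grid grid resolution.
#' @return a single non-negative number.
#' @export
filter_fidelity <- function(coeffs, filter, l = -0.9, u = 0.9, n_grid = 1001L) {
  grid <- seq(l, u, length.out = n_grid)
  max(abs(poly_value(coeffs, grid) - filter_as_function(filter)(grid)))
}

#' Coefficient/fidelity diagnostic table
#'
#' For a filter family and degree, tabulates the closed-form and interpolated
#' coefficient schemes with their sup-norm fidelity; the data behind
#' filter-landscape plots.
#'
#' @param filter a [spectral_filter()].
#' @param K polynomial degree.
#' @param l,u interpolation/evaluation interval.
#' @return A tibble with one row per (scheme, order) and columns `scheme`,
#'   `order`, `coefficient`, `fidelity`.
#' @export
interpolation_report <- function(filter, K, l = -0.9, u = 0.9) {
  schemes <- list(interpolated = interpolate_coefficients(filter, K, l, u))
  closed <- switch(filter$family,
    rwr = rwr_truncated_coefficients(filter$params$alpha, K),
    heat = heat_taylor_coefficients(filter$params$t, K),
    beta = beta_coefficients(filter$params$k)
  )
  schemes[[closed$scheme]] <- closed
  purrr::map_dfr(names(schemes), function(nm) {
    cv <- schemes[[nm]]
    tibble::tibble(
      scheme = cv$scheme,
      order = seq_along(cv$coeffs) - 1L,
      coefficient = cv$coeffs,
      fidelity = filter_fidelity(cv, filter, l, u)
    )
  })
}
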