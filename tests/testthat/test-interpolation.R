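test_that("Chebyshev nodes match closed forms and scale affinely", {
  expect_equal(chebyshev_nodes(1, -1, 1)$nodes, 0)
  n2 <- chebyshev_nodes(2, -1, 1)$nodes
  expect_equal(n2, c(cos(pi / 4), cos(3 * pi / 4)))
  expect_equal(chebyshev_nodes(2, -0.9, 0.9)$nodes, 0.9 * n2)
  expect_error(chebyshev_nodes(3, 1, -1), "l < u")
  # nodes stay strictly inside and are symmetric about the midpoint
  nd <- chebyshev_nodes(9, 0.1, 0.7)
  expect_true(all(nd$nodes > 0.1 & nd$nodes < 0.7))
  expect_equal(nd$nodes + rev(nd$nodes), rep(0.8, 9))
})

test_that("Arnoldi basis is orthonormal under the discrete inner product", {
  basis <- arnoldi_orthonormalize(chebyshev_nodes(2, -1, 1), 1)
  expect_equal(abs(basis$Q), rbind(c(1, 1), c(1, 1)))  # columns 1 and omega
  for (K in c(3, 6, 12, 24)) {
    b <- arnoldi_orthonormalize(chebyshev_nodes(64), K)
    gram <- crossprod(b$Q) / 64
    expect_lt(max(abs(gram - diag(K + 1L))), 1e-10)
  }
})

test_that("the three-term recurrence is honoured by the Hessenberg matrix", {
  b <- arnoldi_orthonormalize(chebyshev_nodes(32), 8)
  om <- b$nodes$nodes
  # omega * q_m = sum_j H[j,m] q_j + H[m+1,m] q_{m+1} at every node
  for (m in 1:8) {
    lhs <- om * b$Q[, m]
    rhs <- b$Q[, 1:(m + 1L)] %*% b$H[1:(m + 1L), m]
    expect_lt(max(abs(lhs - rhs)), 1e-12)
  }
  # with real nodes the recurrence is tridiagonal up to rounding
  upper <- b$H[upper.tri(b$H, diag = FALSE) & row(b$H) < col(b$H) - 0]
  far <- b$H[row(b$H) < col(b$H) - 1]
  expect_lt(max(abs(far)), 1e-13)
})

test_that("degenerate nodes break down with an informative error", {
  fake <- list(nodes = rep(0.5, 5))
  expect_error(arnoldi_orthonormalize(fake, 2), "breakdown")
  expect_error(arnoldi_orthonormalize(chebyshev_nodes(3), 5), "K\\+1")
})

test_that("interpolation reproduces polynomials exactly", {
  const <- interpolate_coefficients(function(om) rep(1, length(om)), 4)
  expect_equal(const$coeffs, c(1, 0, 0, 0, 0), tolerance = 1e-12)
  ident <- interpolate_coefficients(function(om) om, 3)
  expect_equal(ident$coeffs, c(0, 1, 0, 0), tolerance = 1e-12)
  sq <- vandermonde_oracle(chebyshev_nodes(3), function(om) om^2, 2)
  expect_equal(sq$coeffs, c(0, 0, 1), tolerance = 1e-10)
})

test_that("square interpolation is exact at the nodes for every grid filter", {
  for (flt in grid_filters()) {
    for (K in c(2:6, 12, 24)) {
      cv <- interpolate_coefficients(flt, K)
      nd <- chebyshev_nodes(K + 1L)
      resid <- max(abs(poly_value(cv, nd$nodes) - filter_value(flt, nd$nodes)))
      expect_lt(resid, 1e-8, label = sprintf("%s K=%d", flt$family, K))
    }
  }
})

test_that("Arnoldi path agrees with the dense Vandermonde oracle", {
  for (flt in list(spectral_filter("heat", t = 2),
                   spectral_filter("rwr", alpha = 0.5))) {
    for (K in 2:5) {
      a <- interpolate_coefficients(flt, K)$coeffs
      v <- vandermonde_oracle(chebyshev_nodes(K + 1L), flt, K)$coeffs
      expect_lt(max(abs(a - v)), 1e-6)
    }
  }
})

test_that("the Arnoldi basis is near-perfectly conditioned where Vandermonde is not", {
  for (K in c(2, 6, 12, 24)) {
    b <- arnoldi_orthonormalize(chebyshev_nodes(max(64, K + 1L)), K)
    expect_lte(basis_condition_number(b), 1.01)
  }
  expect_equal(basis_condition_number(diag(4)), 1.0)
  # raw Vandermonde Gram matrix at K = 12: catastrophically worse
  V <- outer(chebyshev_nodes(13)$nodes, 0:12, "^")
  kV <- max(svd(crossprod(V))$d) / min(svd(crossprod(V))$d)
  expect_gt(kV, 1e6)
  kA <- basis_condition_number(arnoldi_orthonormalize(chebyshev_nodes(13), 12))
  expect_gt(kV / kA, 1e3)
})

test_that("interpolated coefficients track the filter better than closed forms", {
  for (tt in 2:3) {
    flt <- spectral_filter("heat", t = tt)
    expect_lte(filter_fidelity(interpolate_coefficients(flt, 6), flt),
               filter_fidelity(heat_taylor_coefficients(tt, 6), flt))
  }
  rwr <- spectral_filter("rwr", alpha = 0.9)
  expect_lte(filter_fidelity(interpolate_coefficients(rwr, 6), rwr),
             filter_fidelity(rwr_truncated_coefficients(0.9, 6), rwr))
  # a polynomial filter is matched to rounding by its own expansion
  beta <- spectral_filter("beta", k = 4)
  expect_lt(filter_fidelity(beta_coefficients(4), beta), 1e-12)
})

test_that("least-squares mode (r > K+1) still fits well", {
  flt <- spectral_filter("heat", t = 2)
  cv <- interpolate_coefficients(flt, 6, r = 64)
  expect_lt(filter_fidelity(cv, flt), 5e-4)
})

test_that("interpolation report tabulates both schemes", {
  rep <- interpolation_report(spectral_filter("heat", t = 2), 4)
  expect_setequal(unique(rep$scheme), c("heat_interpolated", "heat_taylor"))
  expect_equal(nrow(rep), 10L)
  fid <- unique(rep[, c("scheme", "fidelity")])
  expect_lte(fid$fidelity[fid$scheme == "heat_interpolated"],
             fid$fidelity[fid$scheme == "heat_taylor"])
})
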