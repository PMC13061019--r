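# internal helpers shared across modules

# run `code` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched, so pipelines are reproducible piecewise
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stop_if_not_scalar_number <- function(x, name, lo = -Inf, hi = Inf,
                                      integer = FALSE, open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    rlang::abort(sprintf("`%s` must be a single finite number", name))
  }
  ok <- if (open) (x > lo && x < hi) else (x >= lo && x <= hi)
  if (!ok) {
    rlang::abort(sprintf(
      "`%s` = %g is outside %s%g, %g%s", name, x,
      if (open) "(" else "[", lo, hi, if (open) ")" else "]"
    ))
  }
  if (integer && x != round(x)) {
    rlang::abort(sprintf("`%s` must be an integer", name))
  }
  invisible(x)
}

# mean +/- 95% t-based confidence interval over a vector of per-seed values
t_ci <- function(x, level = 0.95) {
  n <- length(x)
  m <- mean(x)
  if (n < 2L || stats::sd(x) == 0) {
    return(c(mean = m, ci_lo = m, ci_hi = m))
  }
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1L) * stats::sd(x) / sqrt(n)
  c(mean = m, ci_lo = m - half, ci_hi = m + half)
}

relu <- function(x) pmax(x, 0)

prelu <- function(x, slope) ifelse(x > 0, x, slope * x)

# numerically safe row L2 normalization; errors on zero rows
row_normalize <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) {
    rlang::abort("cannot L2-normalize: zero-norm embedding row encountered")
  }
  m / nrm
}

mean_pairwise_cosine <- function(H) {
  U <- row_normalize(H)
  S <- U %*% t(U)
  n <- nrow(S)
  (sum(S) - n) / (n * (n - 1))
}
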