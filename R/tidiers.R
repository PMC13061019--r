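#' Tidy a contrastive fit
#'
#' One row per propagation order with the initial and learned coefficient —
#' the tabular form of the "initial vs learned filter" comparison.
#'
#' @param x a `gcl_fit`.
#' @param ... unused.
#' @return A tibble with columns `order`, `initial`, `learned`.
#' @export
tidy.gcl_fit <- function(x, ...) {
  if (x$model != "spectral") {
    rlang::abort("the adjacency-gcn baseline has no coefficient vector to tidy")
  }
  tibble::tibble(
    order = seq_along(x$state$c) - 1L,
    initial = x$init_coeffs$coeffs,
    learned = x$state$c
  )
}

#' @rdname tidy.gcl_fit
#' @export
glance.gcl_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    scheme = if (x$model == "spectral") x$init_coeffs$scheme else "adjacency",
    n_cells = nrow(x$embedding),
    dim = ncol(x$embedding),
    epochs = nrow(x$log),
    final_loss = if (nrow(x$log)) x$log$loss[nrow(x$log)] else NA_real_
  )
}

#' @rdname tidy.gcl_fit
#' @export
tidy.metrics_report <- function(x, ...) x$summary

#' @rdname tidy.gcl_fit
#' @export
glance.metrics_report <- function(x, ...) {
  tidyr::pivot_wider(dplyr::select(x$summary, "metric", "mean"),
                     names_from = "metric", values_from = "mean")
}

#' @rdname tidy.gcl_fit
#' @export
tidy.coef_vector <- function(x, ...) {
  tibble::tibble(order = seq_along(x$coeffs) - 1L, coefficient = x$coeffs,
                 scheme = x$scheme)
}

#' Plot a spectral filter against its polynomial schemes
#'
#' Draws \eqn{g(\omega)} with the interpolated and closed-form polynomial
#' approximations over the interpolation interval.
#'
#' @param object a `spectral_filter`.
#' @param K polynomial degree (default 6).
#' @param l,u interval.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.spectral_filter <- function(object, K = 6L, l = -0.9, u = 0.9, ...) {
  grid <- seq(l, u, length.out = 401L)
  rep_tbl <- interpolation_report(object, K, l, u)
  schemes <- unique(rep_tbl$scheme)
  curves <- purrr::map_dfr(schemes, function(sc) {
    cf <- rep_tbl$coefficient[rep_tbl$scheme == sc]
    tibble::tibble(omega = grid, value = poly_value(cf, grid), curve = sc)
  })
  exact <- tibble::tibble(omega = grid,
                          value = filter_value(object, grid),
                          curve = "filter")
  ggplot2::ggplot(dplyr::bind_rows(exact, curves),
                  ggplot2::aes(x = .data$omega, y = .data$value,
                               colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(omega), y = expression(g(omega)),
                  title = sprintf("%s filter and degree-%d polynomials",
                                  object$family, K)) +
    ggplot2::theme_minimal()
}

#' Plot the training trajectory of a contrastive fit
#'
#' Loss per epoch and, for spectral encoders, the coefficient trajectories.
#'
#' @param object a `gcl_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gcl_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$log, -"epoch",
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = "Contrastive training trajectory")
}

#' Plot a multi-seed metrics report
#'
#' Mean with 95% confidence interval per metric.
#'
#' @param object a `metrics_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.metrics_report <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$metric, y = .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.2) +
    ggplot2::theme_minimal() +
    ggplot2::labs(y = "mean ± 95% CI", x = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
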