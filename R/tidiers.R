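#' Tidy a market equilibrium
#'
#' @param x A `market_equilibrium`.
#' @param ... Unused.
#' @return The per-agent decision tibble.
#' @export
tidy.market_equilibrium <- function(x, ...) {
  dplyr::select(
    as_tibble(x$decisions),
    dplyr::any_of(c("pixel_id", "option", "plant_id", "profit",
                    "profit_src", "profit_annual", "profit_fallow",
                    "forced"))
  )
}

#' Glance at a market equilibrium
#'
#' @inheritParams tidy.market_equilibrium
#' @return One-row tibble of prices, supplies and convergence diagnostics.
#' @export
glance.market_equilibrium <- function(x, ...) {
  s <- x$supplies
  tibble(
    price_src = x$price_src,
    price_annual = x$price_annual,
    supply_src = s$supply_t[s$commodity == "src"],
    demand_src = s$demand_t[s$commodity == "src"],
    supply_annual = s$supply_t[s$commodity == "annual"],
    demand_annual = s$demand_t[s$commodity == "annual"],
    converged = x$converged,
    at_corner = x$at_corner,
    iterations = x$iterations,
    method = x$method
  )
}

#' Tidy a bundle result
#'
#' @param x A `bundle_result`.
#' @param ... Unused.
#' @return Long tibble of per-bundle service means on the original scale.
#' @export
tidy.bundle_result <- function(x, ...) x$raw_centroids

#' Glance at a bundle result
#'
#' @inheritParams tidy.bundle_result
#' @return One-row tibble with `k`, fit statistics and pixel count.
#' @export
glance.bundle_result <- function(x, ...) {
  tibble(
    k = x$k, n = nrow(x$labels),
    tot_withinss = x$tot_withinss, betweenss = x$betweenss
  )
}

#' Tidy a stepwise logit model
#'
#' @param x A `logit_model`.
#' @param ... Unused.
#' @return Tibble of standardized coefficients with SE, z and p values.
#' @export
tidy.logit_model <- function(x, ...) x$coefficients

#' Glance at a stepwise logit model
#'
#' @inheritParams tidy.logit_model
#' @return One-row tibble with AIC, log-likelihood and the null-model LR
#'   test.
#' @export
glance.logit_model <- function(x, ...) {
  null_fit <- stats::glm(.y ~ 1, data = x$data_std,
                         family = stats::binomial())
  lr <- lr_test(null_fit, x)
  tibble(
    aic = x$aic, aic_full = x$aic_full, log_lik = x$log_lik, n = x$n,
    n_retained = length(x$retained),
    null_chisq = lr$chisq, null_df = lr$df, null_p_value = lr$p_value
  )
}

#' Tidy a scenario result
#'
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return The service/production totals tibble.
#' @export
tidy.scenario_result <- function(x, ...) x$totals

#' Glance at a scenario result
#'
#' @inheritParams tidy.scenario_result
#' @return One-row summary (SRC share, prices, convergence).
#' @export
glance.scenario_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble(scenario = x$name, src_share = x$src_share),
    glance(x$equilibrium)
  )
}

#' Map a landscape layer
#'
#' @param landscape A `landscape`.
#' @param layer Column of the pixel table to map.
#' @return A ggplot raster map.
#' @export
plot_landscape <- function(landscape, layer = "lulc") {
  stopifnot(inherits(landscape, "landscape"))
  px <- landscape$pixels
  if (!layer %in% names(px)) {
    abort(sprintf("Layer `%s` not found in the pixel table.", layer))
  }
  p <- ggplot2::ggplot(px, ggplot2::aes(.data$x, .data$y,
                                        fill = .data[[layer]])) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = layer) +
    ggplot2::theme_minimal()
  if (nrow(landscape$plants)) {
    p <- p + ggplot2::geom_point(
      data = landscape$plants,
      ggplot2::aes(.data$x, .data$y), inherit.aes = FALSE,
      shape = 17, size = 2
    )
  }
  p
}

#' Radar-style plot of bundle centroids
#'
#' @param object A `bundle_result`.
#' @param ... Unused.
#' @return A ggplot (polar service profile per bundle).
#' @export
autoplot.bundle_result <- function(object, ...) {
  cent <- object$centroids
  ggplot2::ggplot(cent, ggplot2::aes(.data$service, .data$center,
                                     group = .data$bundle)) +
    ggplot2::geom_polygon(fill = NA, colour = "steelblue") +
    ggplot2::coord_polar() +
    ggplot2::facet_wrap(~bundle) +
    ggplot2::labs(x = NULL, y = "standardized service level") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 7))
}

#' Bar chart of the cross-scenario comparison
#'
#' @param object A `scenario_comparison` from [compare_scenarios()].
#' @param ... Unused.
#' @return A ggplot of normalised service levels per scenario.
#' @export
autoplot.scenario_comparison <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$service, .data$pct_of_max,
                                       fill = .data$scenario)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(y = "% of cross-scenario maximum", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Price trajectory of a market clearing
#'
#' @param object A `market_equilibrium`.
#' @param ... Unused.
#' @return A ggplot of prices over solver iterations (empty for runs that
#'   converge immediately).
#' @export
autoplot.market_equilibrium <- function(object, ...) {
  tr <- object$trajectory
  long <- tidyr::pivot_longer(
    tr, c("price_src", "price_annual"),
    names_to = "commodity", values_to = "price"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$iter, .data$price,
                                     colour = .data$commodity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "price (EUR/t)") +
    ggplot2::theme_minimal()
}
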