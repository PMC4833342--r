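default_service_cols <- function(data) {
  setdiff(
    names(data)[vapply(data, is.numeric, TRUE)],
    c("pixel_id", "row", "col", "x", "y")
  )
}

#' Normalise a pixels-by-services matrix
#'
#' `mode = "z"` centres and scales each service to zero mean and unit
#' variance (the metric used for clustering); `mode = "max"` expresses each
#' service as a percentage of its maximum, optionally of the maximum over a
#' set of scenarios supplied via `reference`, so the largest value maps to
#' exactly 100 (the radar-chart / cross-scenario reporting scale).
#' [denormalize_services()] inverts either transform.
#'
#' @param data Data frame of per-pixel service values.
#' @param mode `"z"` or `"max"`.
#' @param service_cols Columns to normalise; defaults to all numeric columns
#'   except identifiers/coordinates.
#' @param reference For `"max"`: named vector of maxima, or a list of data
#'   frames (e.g. the same services under every scenario) whose combined
#'   maxima define 100%.
#' @return Tibble with normalised columns and a `srcscape_norm` attribute.
#' @export
normalize_services <- function(data, mode = c("z", "max"),
                               service_cols = NULL, reference = NULL) {
  mode <- match.arg(mode)
  cols <- service_cols %||% default_service_cols(data)
  out <- as_tibble(data)
  if (mode == "z") {
    center <- vapply(out[cols], mean, 0)
    scale <- vapply(out[cols], stats::sd, 0)
    flat <- cols[scale < .Machine$double.eps]
    if (length(flat)) {
      abort(sprintf(
        "Cannot z-scale constant service column(s): %s.", toString(flat)
      ))
    }
    for (j in cols) out[[j]] <- (out[[j]] - center[j]) / scale[j]
    attr(out, "srcscape_norm") <- list(mode = "z", center = center,
                                       scale = scale, cols = cols)
  } else {
    maxima <- if (is.null(reference)) {
      vapply(out[cols], max, 0)
    } else if (is.list(reference) && !is.data.frame(reference) &&
                 !is.numeric(reference)) {
      apply(do.call(rbind, lapply(reference, function(d) {
        vapply(as_tibble(d)[cols], max, 0)
      })), 2, max)
    } else {
      reference[cols]
    }
    if (any(maxima == 0)) {
      abort("Max-normalisation needs a non-zero maximum per service.")
    }
    for (j in cols) out[[j]] <- 100 * out[[j]] / maxima[j]
    attr(out, "srcscape_norm") <- list(mode = "max", maxima = maxima,
                                       cols = cols)
  }
  out
}

#' @rdname normalize_services
#' @export
denormalize_services <- function(data) {
  norm <- attr(data, "srcscape_norm")
  if (is.null(norm)) abort("`data` carries no normalisation metadata.")
  out <- as_tibble(data)
  for (j in norm$cols) {
    out[[j]] <- if (norm$mode == "z") {
      out[[j]] * norm$scale[j] + norm$center[j]
    } else {
      out[[j]] * norm$maxima[j] / 100
    }
  }
  attr(out, "srcscape_norm") <- NULL
  out
}

#' Identify ecosystem-service bundles by k-means
#'
#' Clusters pixels with similar service profiles (Lloyd's algorithm, best of
#' `n_init` seeded starts by total within-cluster sum of squares).
#' Clustering is run on z-scaled services unless `data` is already
#' normalised. The default `k = 6` matches the bundle count used for
#' reporting.
#'
#' @param data Per-pixel service data frame.
#' @param k Number of bundles (1..n pixels).
#' @param seed Seed making the start set reproducible.
#' @param n_init Number of random starts.
#' @param service_cols Service columns (default: numeric non-identifier).
#' @return A `bundle_result`: labels, centroids (on the clustering scale and
#'   raw), frequencies and fit statistics.
#' @export
kmeans_bundles <- function(data, k = 6, seed = 1, n_init = 10,
                           service_cols = NULL) {
  cols <- service_cols %||% default_service_cols(data)
  norm <- attr(data, "srcscape_norm")
  work <- if (is.null(norm)) {
    normalize_services(data, "z", service_cols = cols)
  } else {
    as_tibble(data)
  }
  X <- as.matrix(work[cols])
  if (k < 1 || k > nrow(X)) abort("`k` must lie in 1..number of pixels.")
  fit <- withr::with_seed(seed, {
    stats::kmeans(X, centers = k, nstart = n_init, iter.max = 200)
  })
  labels <- tibble(
    pixel_id = data$pixel_id %||% seq_len(nrow(X)),
    bundle = as.integer(fit$cluster)
  )
  centroids <- as_tibble(fit$centers) |>
    dplyr::mutate(bundle = dplyr::row_number()) |>
    tidyr::pivot_longer(-"bundle", names_to = "service",
                        values_to = "center")
  raw_centroids <- as_tibble(data)[cols] |>
    dplyr::mutate(bundle = labels$bundle) |>
    dplyr::group_by(.data$bundle) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean),
                     .groups = "drop") |>
    tidyr::pivot_longer(-"bundle", names_to = "service", values_to = "mean")
  structure(
    list(
      k = as.integer(k),
      labels = labels,
      centroids = centroids,
      raw_centroids = raw_centroids,
      frequencies = dplyr::count(labels, .data$bundle, name = "n"),
      tot_withinss = fit$tot.withinss,
      betweenss = fit$betweenss,
      service_cols = cols,
      seed = seed
    ),
    class = "bundle_result"
  )
}

#' @export
print.bundle_result <- function(x, ...) {
  cat(sprintf("<bundle_result> k = %d over %d pixels (within-SS %.1f)\n",
              x$k, nrow(x$labels), x$tot_withinss))
  print(x$frequencies)
  invisible(x)
}

#' Moving-window landscape composition
#'
#' For every pixel, the percentage of each land-cover class within a
#' circular buffer (default radius 5 km, ten cells on the 500 m grid).
#' Pixels near the edge use their truncated buffer, so the percentages of an
#' exhaustive class set always sum to 100.
#'
#' @param data Pixel data frame in column-major grid order.
#' @param grid The [grid_spec()].
#' @param radius_km Buffer radius in km.
#' @param classes Classes to report (default: all levels present).
#' @param class_col Name of the class column.
#' @return `data` with one `pct_<class>` column per class.
#' @export
moving_window_composition <- function(data, grid, radius_km = 5,
                                      classes = NULL,
                                      class_col = "landuse") {
  out <- as_tibble(data)
  if (nrow(out) != n_cells(grid)) {
    abort("`data` rows must cover the grid in column-major order.")
  }
  cls <- as.character(out[[class_col]])
  classes <- classes %||% lulc_levels()
  r_cells <- radius_km * 1000 / grid$cell_size
  span <- floor(r_cells)
  kernel <- 1 * (outer((-span:span)^2, (-span:span)^2, "+") <= r_cells^2)
  total <- conv2d_same(matrix(1, grid$n_rows, grid$n_cols), kernel)
  for (k in classes) {
    ind <- as_grid_matrix(as.numeric(cls == k), grid)
    cnt <- conv2d_same(ind, kernel)
    out[[paste0("pct_", k)]] <- as.vector(100 * cnt / total)
  }
  out
}

#' Screen predictors by variance inflation factor
#'
#' Iteratively removes the predictor with the largest VIF
#' (`1 / (1 - R^2)` of its regression on the remaining predictors) until
#' all VIFs are at or below the threshold (default 10, the usual
#' multicollinearity screen before regression modelling).
#'
#' @param data Data frame of candidate predictors.
#' @param threshold VIF threshold.
#' @param cols Columns to screen (default: all numeric).
#' @return List with `data` (reduced tibble), `removed` (removal log with
#'   the VIF at removal) and `vif` (final VIFs).
#' @export
vif_filter <- function(data, threshold = 10, cols = NULL) {
  cols <- cols %||% names(data)[vapply(data, is.numeric, TRUE)]
  keep <- cols
  removed <- list()
  vifs_of <- function(vars) {
    vapply(vars, function(v) {
      others <- setdiff(vars, v)
      if (!length(others)) return(1)
      # a perfect fit here just means VIF = Inf, not a modelling problem
      r2 <- suppressWarnings(summary(stats::lm(
        stats::reformulate(sprintf("`%s`", others), response = sprintf("`%s`", v)),
        data = data
      ))$r.squared)
      if (!is.finite(r2) || r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, 0)
  }
  step <- 0L
  repeat {
    v <- vifs_of(keep)
    if (all(v <= threshold) || length(keep) == 1L) break
    step <- step + 1L
    worst <- names(which.max(v))
    removed[[step]] <- tibble(step = step, variable = worst,
                              vif = unname(v[worst]))
    keep <- setdiff(keep, worst)
  }
  list(
    data = as_tibble(data)[keep],
    removed = dplyr::bind_rows(removed),
    vif = vifs_of(keep)
  )
}

#' Backward-stepwise binomial logistic regression
#'
#' Standardises the predictors (zero mean, unit SD, so coefficients are
#' directly comparable standardized betas), fits the full binomial logit,
#' then repeatedly drops the variable whose removal most improves the
#' Akaike information criterion until no removal improves it.
#'
#' @param data Data frame holding predictors (and optionally the response).
#' @param response Either the name of a 0/1 column in `data` or a 0/1
#'   vector.
#' @param predictors Predictor column names (default: all numeric columns
#'   except the response).
#' @return A `logit_model` with standardized coefficients, SE, z and
#'   two-sided p values, AIC/log-likelihood, and the retained/removed sets.
#' @export
backward_stepwise_logit <- function(data, response, predictors = NULL) {
  data <- as_tibble(data)
  if (is.character(response) && length(response) == 1L) {
    y <- data[[response]]
    predictors <- predictors %||%
      setdiff(names(data)[vapply(data, is.numeric, TRUE)], response)
  } else {
    y <- response
    predictors <- predictors %||%
      names(data)[vapply(data, is.numeric, TRUE)]
  }
  if (!all(y %in% c(0, 1))) abort("The response must be binary 0/1.")
  X <- data[predictors]
  sds <- vapply(X, stats::sd, 0)
  flat <- predictors[sds < .Machine$double.eps]
  if (length(flat)) {
    abort(sprintf("Constant predictor(s) cannot be standardized: %s.",
                  toString(flat)))
  }
  Xs <- as_tibble(lapply(X, function(v) (v - mean(v)) / stats::sd(v)))
  df <- dplyr::bind_cols(tibble(.y = as.numeric(y)), Xs)
  full <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  if (full$deviance / stats::nobs(full) < 1e-8) {
    cf <- stats::coef(full)[-1]
    abort(sprintf(
      "Perfect separation: variable `%s` separates the response.",
      names(which.max(abs(cf)))
    ), class = "srcscape_separation_error")
  }
  final <- stats::step(full, direction = "backward", trace = 0)
  sm <- summary(final)$coefficients
  coefs <- tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    statistic = sm[, "z value"],
    p_value = sm[, "Pr(>|z|)"]
  )
  retained <- setdiff(rownames(sm), "(Intercept)")
  structure(
    list(
      fit = final,
      full_fit = full,
      coefficients = coefs,
      retained = retained,
      removed = setdiff(predictors, retained),
      aic = stats::AIC(final),
      aic_full = stats::AIC(full),
      log_lik = as.numeric(stats::logLik(final)),
      n = stats::nobs(final),
      data_std = df,
      scaling = list(center = vapply(X, mean, 0), scale = sds)
    ),
    class = "logit_model"
  )
}

#' @export
print.logit_model <- function(x, ...) {
  cat(sprintf(
    "<logit_model> %d of %d predictors retained (AIC %.1f, n = %d)\n",
    length(x$retained), length(x$retained) + length(x$removed), x$aic, x$n
  ))
  print(x$coefficients)
  invisible(x)
}

loglik_df <- function(model) {
  ll <- stats::logLik(if (inherits(model, "logit_model")) model$fit else model)
  c(ll = as.numeric(ll), df = attr(ll, "df"))
}

#' Likelihood-ratio test between nested models
#'
#' `chi^2 = 2 (ll_full - ll_nested)` with degrees of freedom equal to the
#' parameter-count difference; the p value comes from the chi-squared upper
#' tail. Identical models give `chi^2 = 0`, `p = 1`.
#'
#' @param model_nested,model_full Fitted models (`logit_model` or any object
#'   with a [stats::logLik()] method); the full model must nest the other.
#' @return One-row tibble with `chisq`, `df`, `p_value`.
#' @export
lr_test <- function(model_nested, model_full) {
  a <- loglik_df(model_nested)
  b <- loglik_df(model_full)
  chisq <- max(0, 2 * (b["ll"] - a["ll"]))
  df <- b["df"] - a["df"]
  if (df < 0) abort("`model_full` must have at least as many parameters.")
  p <- if (df == 0) {
    if (chisq <= 1e-12) 1 else 0
  } else {
    stats::pchisq(chisq, df, lower.tail = FALSE)
  }
  tibble(chisq = unname(chisq), df = unname(as.integer(df)),
         p_value = unname(p))
}

#' Spatial-autocorrelation check of a final logit model
#'
#' Refits the final model with (standardized) geographic coordinates added
#' and compares the two by likelihood-ratio test: a significant improvement
#' flags residual spatial structure the covariates miss. Adding `x` and `y`
#' gives 2 df; `include_interaction = TRUE` also adds `x:y` (3 df).
#'
#' @param model A `logit_model` from [backward_stepwise_logit()].
#' @param coords Data frame with `x` and `y` for the same rows.
#' @param include_interaction Add the `x:y` term.
#' @return List with the `lr` tibble and the refitted `model_xy` glm.
#' @export
spatial_autocorrelation_check <- function(model, coords,
                                          include_interaction = FALSE) {
  stopifnot(inherits(model, "logit_model"))
  if (nrow(coords) != nrow(model$data_std)) {
    abort("`coords` must have one row per model observation.")
  }
  zx <- as.numeric(scale(coords$x))
  zy <- as.numeric(scale(coords$y))
  zx[is.na(zx)] <- 0  # constant coordinate: no spatial axis to test
  zy[is.na(zy)] <- 0
  df <- model$data_std
  df$.coord_x <- zx
  df$.coord_y <- zy
  rhs <- c(sprintf("`%s`", model$retained), ".coord_x", ".coord_y")
  if (include_interaction) rhs <- c(rhs, ".coord_x:.coord_y")
  if (!length(model$retained)) rhs <- c("1", rhs)
  fit_xy <- stats::glm(
    stats::reformulate(rhs, response = ".y"),
    data = df, family = stats::binomial()
  )
  list(lr = lr_test(model, fit_xy), model_xy = fit_xy)
}
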