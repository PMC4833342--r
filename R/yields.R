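#' Density-dependent coefficients of the poplar yield regression
#'
#' The two outer coefficients of the short-rotation-coppice yield regression
#' are quadratic polynomials in planting density `N` (stems per hectare):
#' `a4 = -1.13e-9 N^2 + 2.54e-5 N + 0.028` and
#' `a5 = 3.41e-9 N^2 - 5.01e-5 N + 2.614`.
#'
#' @param N Planting density (stems per hectare, >= 0).
#' @return Named numeric vector `c(a4, a5)`.
#' @export
#' @examples
#' src_coefficients(9446)
src_coefficients <- function(N) {
  assert_number(N, "N", lower = 0)
  c(
    a4 = -1.13e-9 * N^2 + 2.54e-5 * N + 0.028,
    a5 = 3.41e-9 * N^2 - 5.01e-5 * N + 2.614
  )
}

#' Parameters of the poplar SRC yield model
#'
#' Species parameters for the commercial poplar clone Max: the regression
#' `yield = a4 * (a1*C + a2*P*SQI + a3*T/AWC)^a5` with rotation cycle `C`
#' (years), May--June precipitation sum `P` (mm), soil quality index `SQI`,
#' April--July mean temperature `T` (degrees C) and available water holding
#' capacity `AWC` (mm). The third term is `a3 * T / AWC` by default; the
#' typographically ambiguous alternative product form `a3 * T * AWC` is
#' available via `t_over_awc = FALSE` but produces negative inner terms for
#' realistic sites.
#'
#' @param a1,a2,a3 Species parameters.
#' @param N Planting density (stems/ha); determines `a4`, `a5` via
#'   [src_coefficients()].
#' @param C Rotation cycle length (years).
#' @param t_over_awc Logical; `TRUE` (default) reads the third regression
#'   term as `a3 * T / AWC`.
#' @return List of class `src_yield_params` including the derived `a4`, `a5`.
#' @export
src_yield_params <- function(a1 = 1.569, a2 = 0.0004, a3 = -23.198,
                             N = 9446, C = 5.5, t_over_awc = TRUE) {
  assert_number(N, "N", lower = 0, strict = TRUE)
  assert_number(C, "C", lower = 0, strict = TRUE)
  a45 <- src_coefficients(N)
  structure(
    list(
      a1 = a1, a2 = a2, a3 = a3, N = N, C = C,
      a4 = unname(a45["a4"]), a5 = unname(a45["a5"]),
      t_over_awc = isTRUE(t_over_awc)
    ),
    class = "src_yield_params"
  )
}

src_yield_vec <- function(P, SQI, T, AWC, params = src_yield_params(),
                          output = c("annual", "rotation"),
                          warn_clip = TRUE) {
  output <- match.arg(output)
  if (any(!is.finite(AWC)) || any(AWC <= 0)) {
    abort("`AWC` must be positive (the regression divides by it).")
  }
  if (any(P < 0)) abort("`P` (May-June precipitation) must be >= 0.")
  third <- if (params$t_over_awc) params$a3 * T / AWC else params$a3 * T * AWC
  inner <- params$a1 * params$C + params$a2 * P * SQI + third
  y <- ifelse(inner > 0, params$a4 * inner^params$a5, 0)
  if (warn_clip && any(inner <= 0)) {
    warn(sprintf(
      "%d site(s) had a non-positive inner regression term; yield clipped to 0.",
      sum(inner <= 0)
    ))
  }
  if (output == "annual") y / params$C else y
}

#' Site-specific poplar SRC yield
#'
#' Evaluates the density-calibrated yield regression for every row of
#' `data`. With `output = "annual"` (default) the per-rotation regression
#' value is divided by the rotation cycle `C`, giving a mean annual
#' dry-matter increment (t/ha/a); `output = "rotation"` returns the raw
#' regression value (the rotation total). Sites whose inner regression term
#' is non-positive get yield 0 with a warning.
#'
#' @param data Data frame with columns `precip_mayjun` (mm), `sqi`,
#'   `temp_aprjul` (degrees C) and `awc_mm` (mm).
#' @param params [src_yield_params()].
#' @param output `"annual"` or `"rotation"`.
#' @param warn_clip Warn when the inner term is clipped at 0.
#' @return `data` as a tibble with a `yield_src` column (t dry matter/ha).
#' @export
#' @examples
#' src_yield(tibble::tibble(
#'   precip_mayjun = 150, sqi = 40, temp_aprjul = 13, awc_mm = 150
#' ))
src_yield <- function(data, params = src_yield_params(),
                      output = c("annual", "rotation"), warn_clip = TRUE) {
  need <- c("precip_mayjun", "sqi", "temp_aprjul", "awc_mm")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    abort(sprintf("`data` lacks column(s): %s.", toString(missing)))
  }
  out <- as_tibble(data)
  out$yield_src <- src_yield_vec(
    data$precip_mayjun, data$sqi, data$temp_aprjul, data$awc_mm,
    params = params, output = match.arg(output), warn_clip = warn_clip
  )
  out
}

#' Downscale a district-level crop yield to pixels
#'
#' Each pixel receives the district yield scaled by its own yield potential
#' relative to the district's arithmetic-mean potential:
#' `pixel yield = district_yield * pixel_potential / district_mean_potential`.
#'
#' @param district_yield District average yield (t/ha/a).
#' @param pixel_potential Pixel yield potential (any consistent index).
#' @param district_mean_potential District arithmetic-mean potential (> 0).
#' @return Pixel yield (t/ha/a), vectorised.
#' @export
crop_yield_pixel <- function(district_yield, pixel_potential,
                             district_mean_potential) {
  if (any(!is.finite(district_mean_potential)) ||
      any(district_mean_potential <= 0)) {
    abort("`district_mean_potential` must be positive.")
  }
  district_yield * pixel_potential / district_mean_potential
}

#' Attach downscaled crop yields to pixels
#'
#' Joins the district table and applies [crop_yield_pixel()], using the soil
#' quality index as the pixel yield-potential proxy.
#'
#' @param data Pixel data frame with `district_id` and `sqi`.
#' @param districts District table with `district_id`, `yield_t_ha`,
#'   `mean_potential`.
#' @return `data` with a `yield_annual` column (t/ha/a).
#' @export
add_crop_yield <- function(data, districts) {
  out <- dplyr::left_join(
    as_tibble(data),
    dplyr::select(districts, "district_id", "yield_t_ha", "mean_potential"),
    by = "district_id"
  )
  if (any(is.na(out$yield_t_ha))) {
    abort("Some pixels have a district_id without a district-table row.")
  }
  out$yield_annual <- crop_yield_pixel(out$yield_t_ha, out$sqi,
                                       out$mean_potential)
  dplyr::select(out, -"yield_t_ha", -"mean_potential")
}

#' Regional production totals by land-use class
#'
#' @param data Data frame with a land-use column and a per-hectare yield
#'   column.
#' @param cell_area Cell area in hectares.
#' @param class_col,yield_col Column names.
#' @return Tibble with `landuse` and `production_t` (t/a).
#' @export
regional_production <- function(data, cell_area, class_col = "landuse",
                                yield_col = "yield_t_ha") {
  as_tibble(data) |>
    dplyr::group_by(landuse = .data[[class_col]]) |>
    dplyr::summarise(
      production_t = sum(.data[[yield_col]] * cell_area),
      .groups = "drop"
    )
}
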