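#' Synthesis parameters for the landscape generator
#'
#' Defaults emulate a Central-European low-mountain watershed: elevation from
#' ~70 to ~1200 m, annual precipitation increasing and April--July
#' temperature decreasing with elevation, spatially autocorrelated soil
#' quality (SQI) and available water holding capacity (AWC), and a
#' cropland-dominated land-cover mosaic. Marginal distributions of SQI/AWC
#' are uniform over the stated ranges after Gaussian-random-field ranking;
#' the generator is a statistical stand-in, not a reconstruction of any real
#' region.
#'
#' @param autocorr_range_cells Autocorrelation range of the random fields, in
#'   cells (Gaussian smoothing scale; Moran's I of SQI is positive at this
#'   range).
#' @param elevation_range Min/max elevation (m).
#' @param precip_base Annual precipitation at elevation 0 (mm/a).
#' @param precip_lapse Increase of annual precipitation per metre of
#'   elevation (mm/m). Set to 0 for an elevation-independent field.
#' @param precip_noise_sd Standard deviation of the autocorrelated residual
#'   field added to precipitation (mm).
#' @param mayjun_frac Fraction of annual precipitation falling in May--June.
#' @param temp_base Mean April--July temperature at elevation 0 (degrees C).
#' @param temp_lapse Decrease of temperature per metre of elevation (K/m).
#' @param temp_noise_sd Residual temperature field SD (K).
#' @param et0_base,et0_lapse Reference evapotranspiration at elevation 0
#'   (mm/a) and its decrease per metre.
#' @param sqi_range Range of the soil quality index (0--100 scale).
#' @param awc_mm_range Range of profile available water capacity (mm).
#' @param rooting_depth_range Range of effective rooting depth (mm).
#' @param erodibility_range Range of the USLE K factor
#'   (t ha h / (ha MJ mm)).
#' @param erosivity_per_mm USLE R factor per mm of annual precipitation
#'   (MJ mm / (ha h a) per mm); the default is a common German
#'   regression slope.
#' @param ndep_range Range of atmospheric N deposition (kg N/ha/a).
#' @param critical_n_load Critical N load used for the MSA exceedance
#'   pressure (kg N/ha/a).
#' @param pop_density_max Maximum population density (n/km^2).
#' @param lulc_proportions Named proportions (summing to 1) for the baseline
#'   mosaic over `cropland, forest, grassland, urban, water`. Classes are
#'   assigned from low to high terrain position in the order given, so the
#'   default puts cropland and settlements in the lowlands and forest on the
#'   mountain ridges, as in the emulated watershed.
#' @param lulc_elevation_weight Weight (0--1) of elevation in the mosaic
#'   field; the remainder is an independent autocorrelated field, so class
#'   boundaries are noisy rather than pure contour lines.
#' @param n_districts Number of rectangular administrative districts.
#' @param district_yield_base,district_yield_sd Mean and between-district SD
#'   of the district-level crop yield (t/ha/a, one aggregate commodity).
#' @return A named list of class `synthesis_params`.
#' @export
synthesis_params <- function(autocorr_range_cells = 8,
                             elevation_range = c(70, 1214),
                             precip_base = 550,
                             precip_lapse = 0.65,
                             precip_noise_sd = 30,
                             mayjun_frac = 0.18,
                             temp_base = 14.5,
                             temp_lapse = 0.0065,
                             temp_noise_sd = 0.3,
                             et0_base = 620,
                             et0_lapse = 0.15,
                             sqi_range = c(30, 90),
                             awc_mm_range = c(140, 220),
                             rooting_depth_range = c(300, 1500),
                             erodibility_range = c(0.1, 0.5),
                             erosivity_per_mm = 0.0788,
                             ndep_range = c(5, 35),
                             critical_n_load = 15,
                             pop_density_max = 1500,
                             lulc_proportions = c(
                               cropland = 0.45, urban = 0.06, water = 0.04,
                               grassland = 0.15, forest = 0.30
                             ),
                             lulc_elevation_weight = 0.6,
                             n_districts = 6,
                             district_yield_base = 7.2,
                             district_yield_sd = 0.5) {
  p <- as.list(environment())
  class(p) <- "synthesis_params"
  p
}

check_proportions <- function(props) {
  if (is.null(names(props)) || any(!nzchar(names(props)))) {
    abort("`lulc_proportions` must be a named numeric vector.")
  }
  bad <- setdiff(names(props), lulc_levels())
  if (length(bad)) {
    abort(sprintf("Unknown land-cover class(es): %s.", toString(bad)))
  }
  if (any(props < 0)) abort("`lulc_proportions` must be non-negative.")
  if (abs(sum(props) - 1) > 1e-8) {
    abort(sprintf(
      "`lulc_proportions` must sum to 1 (got %.6f).", sum(props)
    ))
  }
  invisible(props)
}

#' Generate a seeded synthetic landscape
#'
#' Builds a complete, mutually aligned layer stack on one grid: elevation and
#' terrain derivatives, autocorrelated soil quality and water-capacity
#' fields, elevation-driven climate, a baseline land-cover mosaic drawn from
#' an autocorrelated field so classes form patches, rectangular districts
#' with district-level crop yields, and population density. Deterministic
#' for a fixed seed.
#'
#' @param grid A [grid_spec()]; needs at least 2 rows and columns so terrain
#'   derivatives are defined.
#' @param params A [synthesis_params()] list.
#' @param seed Integer seed; the same seed reproduces the stack bit for bit.
#' @return A `landscape` object: list with `grid`, `pixels` (one row per
#'   cell), `districts`, `params`, `seed` and (after
#'   [place_chp_plants()]) `plants`.
#' @export
#' @examples
#' ls <- generate_landscape(grid_spec(20, 20), seed = 1)
#' dplyr::count(ls$pixels, lulc)
generate_landscape <- function(grid, params = synthesis_params(), seed = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  if (grid$n_rows < 2 || grid$n_cols < 2) {
    abort("`grid` must have at least 2 rows and 2 columns.")
  }
  props <- check_proportions(params$lulc_proportions)
  nr <- grid$n_rows
  nc <- grid$n_cols
  rng <- params$autocorr_range_cells

  withr::with_seed(seed, {
    elev_f <- gaussian_random_field(nr, nc, rng * 2)
    sqi_f <- gaussian_random_field(nr, nc, rng)
    awc_f <- gaussian_random_field(nr, nc, rng)
    root_f <- gaussian_random_field(nr, nc, rng)
    erod_f <- gaussian_random_field(nr, nc, rng)
    ndep_f <- gaussian_random_field(nr, nc, rng)
    prec_f <- gaussian_random_field(nr, nc, rng)
    temp_f <- gaussian_random_field(nr, nc, rng)
    lulc_f <- gaussian_random_field(nr, nc, rng)
    pop_f <- gaussian_random_field(nr, nc, rng)
    yield_noise <- stats::rnorm(params$n_districts, 0, params$district_yield_sd)
  })

  elevation <- rescale_range(elev_f, params$elevation_range[1],
                             params$elevation_range[2])
  terrain <- derive_terrain(elevation, cell_size = grid$cell_size)

  px <- grid_coords(grid)
  px$elevation <- as.vector(elevation)
  px$slope <- as.vector(terrain$slope)
  px$aspect <- as.vector(terrain$aspect)
  px$curvature <- as.vector(terrain$curvature)
  px$sqi <- as.vector(rescale_range(sqi_f, params$sqi_range[1],
                                    params$sqi_range[2]))
  px$awc_mm <- as.vector(rescale_range(awc_f, params$awc_mm_range[1],
                                       params$awc_mm_range[2]))
  px$rooting_depth <- as.vector(rescale_range(root_f,
                                              params$rooting_depth_range[1],
                                              params$rooting_depth_range[2]))
  # volumetric AWC (cm water per cm soil) from profile AWC and rooting depth
  px$awc <- pmin(pmax(px$awc_mm / px$rooting_depth, 0.02), 0.45)
  px$erodibility_k <- as.vector(rescale_range(erod_f,
                                              params$erodibility_range[1],
                                              params$erodibility_range[2]))
  px$precip_annual <- pmax(
    params$precip_base + params$precip_lapse * px$elevation +
      params$precip_noise_sd * as.vector(prec_f),
    50
  )
  px$precip_mayjun <- params$mayjun_frac * px$precip_annual
  px$temp_aprjul <- params$temp_base - params$temp_lapse * px$elevation +
    params$temp_noise_sd * as.vector(temp_f)
  px$et0 <- pmax(params$et0_base - params$et0_lapse * px$elevation, 100)
  px$erosivity_r <- params$erosivity_per_mm * px$precip_annual
  px$n_deposition <- as.vector(rescale_range(ndep_f, params$ndep_range[1],
                                             params$ndep_range[2]))

  # mosaic: rank an elevation-coupled autocorrelated field and slice it at
  # the cumulative class proportions, so counts hit the request exactly (up
  # to rounding), classes form contiguous patches, and the class sequence
  # follows the terrain position (cropland in the lowlands first)
  w <- params$lulc_elevation_weight
  mix <- w * as.vector(elev_f) + (1 - w) * as.vector(lulc_f)
  ord <- rank(mix, ties.method = "first")
  cuts <- round(cumsum(props) * n_cells(grid))
  cls <- character(n_cells(grid))
  lo <- 0L
  for (k in seq_along(props)) {
    cls[ord > lo & ord <= cuts[k]] <- names(props)[k]
    lo <- cuts[k]
  }
  cls[ord > lo] <- names(props)[length(props)]
  px$lulc <- factor(cls, levels = lulc_levels())

  pop <- rescale_range(exp(1.2 * as.vector(pop_f)), 0, params$pop_density_max)
  px$pop_density <- ifelse(px$lulc == "urban", pmax(pop, 200), pop)

  px$district_id <- assign_districts(grid, params$n_districts)

  districts <- build_district_table(px, params, yield_noise)

  structure(
    list(
      grid = grid, pixels = px, districts = districts,
      plants = empty_plants(), params = params, seed = seed
    ),
    class = "landscape"
  )
}

# k rectangular blocks: factor k into the most square r x c layout
assign_districts <- function(grid, k) {
  k <- max(1L, as.integer(k))
  r <- floor(sqrt(k))
  while (k %% r != 0L) r <- r - 1L
  cc <- k %/% r
  row_band <- pmin(ceiling(rep(seq_len(grid$n_rows), grid$n_cols) /
                             (grid$n_rows / r)), r)
  col_band <- pmin(ceiling(rep(seq_len(grid$n_cols), each = grid$n_rows) /
                             (grid$n_cols / cc)), cc)
  as.integer((row_band - 1L) * cc + col_band)
}

# district-level aggregate crop yield and mean yield potential (the yield
# potential proxy is the soil quality index, over cropland where present).
# District yields scale with district soil quality — good-soil districts
# report higher average yields — plus independent noise, so downscaling by
# relative potential reproduces an approximately proportional yield-quality
# relation across the whole landscape
build_district_table <- function(px, params, yield_noise) {
  ids <- sort(unique(px$district_id))
  crop_all <- px[px$lulc == "cropland", ]
  sqi_ref <- if (nrow(crop_all)) mean(crop_all$sqi) else mean(px$sqi)
  purrr::map_dfr(seq_along(ids), function(i) {
    d <- px[px$district_id == ids[i], ]
    crop <- d[d$lulc == "cropland", ]
    pot <- if (nrow(crop)) mean(crop$sqi) else mean(d$sqi)
    tibble(
      district_id = ids[i],
      crop = "cereal",
      yield_t_ha = pmax(
        params$district_yield_base * pot / sqi_ref + yield_noise[i], 1
      ),
      mean_potential = pot
    )
  })
}

empty_plants <- function() {
  tibble(
    id = integer(), row = integer(), col = integer(),
    x = numeric(), y = numeric(), capacity = numeric()
  )
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf(
    "<landscape> %d x %d cells (%g m), %d CHP plant(s), seed %s\n",
    x$grid$n_rows, x$grid$n_cols, x$grid$cell_size, nrow(x$plants),
    format(x$seed)
  ))
  print(dplyr::count(x$pixels, .data$lulc, .drop = FALSE), n = Inf)
  invisible(x)
}

#' @export
as_tibble.landscape <- function(x, ...) x$pixels

#' Terrain derivatives from an elevation raster
#'
#' Slope and aspect use Horn's 3x3 finite-difference stencil on an
#' edge-replicated grid; curvature is the negated Laplacian (convex-up
#' positive), scaled by 100 to a dimensionless score.
#'
#' @param elevation Numeric matrix of elevations (m), at least 2 x 2.
#' @param cell_size Cell side length in metres.
#' @return List of matrices `slope` (percent, >= 0), `aspect` (degrees in
#'   `[0, 360)`, downslope azimuth clockwise from grid north; 0 on flats)
#'   and `curvature` (score).
#' @export
derive_terrain <- function(elevation, cell_size = 500) {
  if (!is.matrix(elevation) || !is.numeric(elevation)) {
    abort("`elevation` must be a numeric matrix.")
  }
  if (any(!is.finite(elevation))) abort("`elevation` must be finite.")
  if (length(elevation) < 2L) {
    abort("Cannot derive terrain from a single-pixel raster (no neighbors).")
  }
  z <- elevation
  nb <- function(dr, dc) shift_mat(z, -dr, -dc)  # value at (r + dr, c + dc)
  a <- nb(-1, -1); b <- nb(-1, 0); c2 <- nb(-1, 1)
  d <- nb(0, -1); f <- nb(0, 1)
  g <- nb(1, -1); h <- nb(1, 0); i <- nb(1, 1)
  p <- ((c2 + 2 * f + i) - (a + 2 * d + g)) / (8 * cell_size)  # dz/dx (east)
  q <- ((a + 2 * b + c2) - (g + 2 * h + i)) / (8 * cell_size)  # dz/dy (north)
  slope <- 100 * sqrt(p^2 + q^2)
  aspect <- (atan2(-p, -q) * 180 / pi) %% 360
  aspect[slope == 0] <- 0
  lap <- (b + h + d + f - 4 * z) / cell_size^2
  curvature <- -lap * 100
  list(slope = slope, aspect = aspect, curvature = curvature)
}

#' Place combined heat and power (CHP) plants
#'
#' Samples `n` distinct non-water pixels as plant locations (wood-chip
#' consumers). The regional default of 15 plants matches the number of CHP
#' plants in the watershed the model emulates.
#'
#' @param landscape A `landscape`.
#' @param n Number of plants (>= 0).
#' @param capacity_rule Either a single capacity (t dry matter per year,
#'   applied to every plant) or a function `function(n)` returning `n`
#'   capacities.
#' @param seed Integer seed for the placement.
#' @return The landscape with a `plants` tibble
#'   (`id, row, col, x, y, capacity`) attached.
#' @export
place_chp_plants <- function(landscape, n = 15, capacity_rule = 2000,
                             seed = 1) {
  stopifnot(inherits(landscape, "landscape"))
  assert_number(n, "n", lower = 0)
  n <- as.integer(n)
  # plants sit where wood-chip consumers do: in settlements and the
  # agricultural lowlands, not in the forested uplands
  eligible <- landscape$pixels[landscape$pixels$lulc %in%
                                 c("urban", "cropland"), ]
  if (nrow(eligible) == 0L) {
    eligible <- landscape$pixels[landscape$pixels$lulc != "water", ]
  }
  if (n > nrow(eligible)) {
    abort(sprintf(
      "Cannot place %d plants on %d eligible (non-water) pixels.",
      n, nrow(eligible)
    ))
  }
  if (n == 0L) {
    landscape$plants <- empty_plants()
    return(landscape)
  }
  idx <- withr::with_seed(seed, sample(nrow(eligible), n))
  caps <- if (is.function(capacity_rule)) capacity_rule(n) else {
    rep(as.numeric(capacity_rule), n)
  }
  if (length(caps) != n || any(!is.finite(caps)) || any(caps <= 0)) {
    abort("`capacity_rule` must yield one positive capacity per plant.")
  }
  landscape$plants <- tibble(
    id = seq_len(n),
    row = eligible$row[idx], col = eligible$col[idx],
    x = eligible$x[idx], y = eligible$y[idx],
    capacity = caps
  )
  landscape
}
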