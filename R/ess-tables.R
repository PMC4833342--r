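#' Carbon densities per land-use class
#'
#' Carbon stock split into the four standard pools (aboveground,
#' belowground, soil organic, dead organic matter), in t C per hectare.
#' Defaults are documented plausible values for temperate Central-European
#' classes; SRC plantations store more carbon than the cropland they
#' replace, mostly through woody biomass and reduced tillage.
#'
#' @param densities Optional tibble overriding the default
#'   (`landuse, aboveground, belowground, soil, dead`).
#' @return Tibble of class densities.
#' @export
carbon_pool_table <- function(densities = NULL) {
  tab <- densities %||% tibble(
    landuse = lulc_levels(),
    aboveground = c(5, 110, 7, 3, 0, 22, 4),
    belowground = c(1, 25, 14, 1, 0, 8, 1),
    soil = c(80, 85, 86, 40, 0, 84, 82),
    dead = c(0, 8, 0, 0, 0, 2, 1)
  )
  if (any(tab$aboveground < 0 | tab$belowground < 0 | tab$soil < 0 |
            tab$dead < 0)) {
    abort("Carbon pool densities must be >= 0.")
  }
  tab$total <- tab$aboveground + tab$belowground + tab$soil + tab$dead
  tab
}

#' Phosphorus export coefficients and filtering efficiencies
#'
#' Per land-use class: the P load a pixel emits (kg/ha/a) and the fraction
#' of a load passing through the pixel that its vegetation retains.
#' Perennial woody cover (forest, SRC) emits little and filters much;
#' tilled cropland is the main source.
#'
#' @param params Optional overriding tibble
#'   (`landuse, export_coeff, filter_eff`).
#' @return Tibble of nutrient parameters.
#' @export
nutrient_param_table <- function(params = NULL) {
  tab <- params %||% tibble(
    landuse = lulc_levels(),
    export_coeff = c(2.0, 0.1, 0.4, 1.2, 0.0, 0.3, 0.6),
    filter_eff = c(0.25, 0.80, 0.50, 0.05, 0.00, 0.60, 0.40)
  )
  if (any(tab$filter_eff < 0 | tab$filter_eff > 1)) {
    abort("Filtering efficiencies must lie in [0, 1].")
  }
  if (any(tab$export_coeff < 0)) abort("Export coefficients must be >= 0.")
  tab
}

#' USLE cover/practice factors and sediment trap efficiencies
#'
#' Per land-use class: cover-management factor `c_factor`, support-practice
#' factor `p_factor` (both dimensionless in `[0, 1]`) and the fraction of
#' sediment arriving from upslope that the class traps.
#'
#' @param params Optional overriding tibble.
#' @return Tibble of USLE parameters.
#' @export
usle_param_table <- function(params = NULL) {
  tab <- params %||% tibble(
    landuse = lulc_levels(),
    c_factor = c(0.15, 0.002, 0.01, 0.005, 0, 0.02, 0.05),
    p_factor = c(1, 1, 1, 1, 1, 1, 1),
    trap_eff = c(0.10, 0.80, 0.50, 0.05, 0.90, 0.60, 0.30)
  )
  rng <- c(tab$c_factor, tab$p_factor, tab$trap_eff)
  if (any(rng < 0 | rng > 1)) {
    abort("USLE factors and trap efficiencies must lie in [0, 1].")
  }
  tab
}

#' Pressure-response tables of the mean-species-abundance model
#'
#' The biodiversity model multiplies five pressure factors, each in
#' `[0, 1]`: land use (`msa_lu`; an undisturbed ecosystem scores 1, SRC
#' scores 0.2, intensive cropland 0.1), habitat fragmentation (patch area),
#' infrastructure proximity, population density and N-deposition exceedance
#' of the critical load. Each non-land-use pressure is a piecewise-constant
#' lookup: `breaks` are the left edges of the classes of the driver value
#' and `values` the corresponding factors, with the no-impact class mapping
#' to 1.
#'
#' @param msa_lu Named numeric vector of land-use factors.
#' @param fragmentation,infrastructure,population,n_deposition Lists with
#'   `breaks` (ascending driver-class edges) and `values`.
#' @param natural_classes Classes whose patches count as habitat for the
#'   fragmentation pressure.
#' @return List of class `msa_pressure_tables`.
#' @export
msa_pressure_tables <- function(msa_lu = c(
                                  cropland = 0.1, forest = 1.0,
                                  grassland = 0.4, urban = 0.05,
                                  water = 1.0, SRC = 0.2, fallow = 0.3
                                ),
                                fragmentation = list(
                                  breaks = c(0, 100, 1000, 10000, 1e5),
                                  values = c(0.45, 0.60, 0.70, 0.90, 1.0)
                                ),
                                infrastructure = list(
                                  breaks = c(0, 0.5, 1.5, 5),
                                  values = c(0.70, 0.85, 0.95, 1.0)
                                ),
                                population = list(
                                  breaks = c(0, 10, 100, 1000),
                                  values = c(1.0, 0.90, 0.75, 0.60)
                                ),
                                n_deposition = list(
                                  # impact starts once exceedance is positive
                                  breaks = c(-Inf, 1e-9, 5, 10, 20),
                                  values = c(1.0, 0.90, 0.80, 0.70, 0.60)
                                ),
                                natural_classes = c("forest", "grassland")) {
  check_lookup <- function(tab, name) {
    if (length(tab$breaks) != length(tab$values)) {
      abort(sprintf("`%s` needs one value per break.", name))
    }
    if (is.unsorted(tab$breaks, strictly = TRUE)) {
      abort(sprintf("`%s` breaks must be strictly increasing.", name))
    }
    if (any(tab$values < 0 | tab$values > 1)) {
      abort(sprintf("`%s` factors must lie in [0, 1].", name))
    }
  }
  if (any(msa_lu < 0 | msa_lu > 1)) abort("msa_lu values must lie in [0, 1].")
  check_lookup(fragmentation, "fragmentation")
  check_lookup(infrastructure, "infrastructure")
  check_lookup(population, "population")
  check_lookup(n_deposition, "n_deposition")
  structure(
    list(
      msa_lu = msa_lu, fragmentation = fragmentation,
      infrastructure = infrastructure, population = population,
      n_deposition = n_deposition, natural_classes = natural_classes
    ),
    class = "msa_pressure_tables"
  )
}

lookup_factor <- function(x, tab) {
  idx <- findInterval(x, tab$breaks)
  # below the first break (only possible for drivers with a finite floor)
  # means no measurable pressure
  out <- ifelse(idx == 0, 1, tab$values[pmax(idx, 1)])
  out[is.na(x)] <- 1
  out
}

join_class_param <- function(landuse, table, column) {
  idx <- match(as.character(landuse), table$landuse)
  if (any(is.na(idx))) {
    abort(sprintf(
      "Land-use class(es) missing from the parameter table: %s.",
      toString(unique(as.character(landuse)[is.na(idx)]))
    ))
  }
  table[[column]][idx]
}
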