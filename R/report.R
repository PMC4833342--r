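#' Ecosystem-service parameter bundle
#'
#' Collects the per-model parameter tables used by [compute_ess_stack()].
#'
#' @param carbon [carbon_pool_table()].
#' @param nutrients [nutrient_param_table()].
#' @param usle [usle_param_table()].
#' @param msa [msa_pressure_tables()].
#' @param slope_length USLE slope length (m).
#' @return List of class `ess_params`.
#' @export
ess_params <- function(carbon = carbon_pool_table(),
                       nutrients = nutrient_param_table(),
                       usle = usle_param_table(),
                       msa = msa_pressure_tables(),
                       slope_length = 22.13) {
  structure(
    list(carbon = carbon, nutrients = nutrients, usle = usle, msa = msa,
         slope_length = slope_length),
    class = "ess_params"
  )
}

#' Compute the full per-pixel service stack for one land-use map
#'
#' Runs carbon storage, routed P export/retention, routed USLE sediment
#' export/retention and the multiplicative MSA model on a landscape under a
#' (possibly scenario-modified) land-use vector, and aggregates watershed
#' totals.
#'
#' @param landscape A `landscape`.
#' @param landuse Land-use factor vector (one value per pixel, column-major
#'   order); defaults to the baseline mosaic.
#' @param params An [ess_params()] bundle.
#' @param flow Optional precomputed [build_flow_graph()] (it only depends on
#'   elevation, so it can be shared across scenarios).
#' @return An `ess_stack`: list with `per_pixel` (tibble of service columns)
#'   and `totals` (tibble `service`, `value`, `unit`).
#' @export
compute_ess_stack <- function(landscape, landuse = NULL,
                              params = ess_params(), flow = NULL) {
  stopifnot(inherits(landscape, "landscape"))
  grid <- landscape$grid
  area <- cell_area_ha(grid)
  px <- landscape$pixels
  px$landuse <- factor(landuse %||% px$lulc, levels = lulc_levels())
  flow <- flow %||% build_flow_graph(
    as_grid_matrix(px$elevation, grid), cell_size = grid$cell_size
  )
  px$ndep_exceedance <- px$n_deposition -
    (landscape$params$critical_n_load %||% 15)
  px <- carbon_storage(px, params$carbon, cell_area = area)
  px <- p_export(px, flow, params$nutrients, cell_area = area)
  px <- sediment_export(px, flow, params$usle, cell_area = area,
                        slope_length = params$slope_length)
  px <- patch_sizes(px, grid, natural_classes = params$msa$natural_classes)
  px <- infrastructure_distance(px)
  px <- msa(px, params$msa)
  totals <- tibble(
    service = c("carbon", "p_export", "p_retention", "sediment_export",
                "sediment_retention", "msa"),
    value = c(
      sum(px$carbon_t),
      sum(px$p_exported_kg),
      sum(px$p_retained_kg),
      sum(px$sed_exported_t),
      sum(px$sed_retained_t),
      mean(px$msa)
    ),
    unit = c("t C", "kg P/a", "kg P/a", "t/a", "t/a", "MSA")
  )
  structure(
    list(per_pixel = as_tibble(px), totals = totals, flow = flow),
    class = "ess_stack"
  )
}

#' Per-pixel service matrix for bundle analysis
#'
#' Extracts the six services used for clustering (carbon, P retention and
#' export, sediment retention and export, MSA) plus coordinates.
#'
#' @param stack An `ess_stack`.
#' @return Tibble with `pixel_id`, `x`, `y` and the service columns.
#' @export
ess_matrix <- function(stack) {
  stopifnot(inherits(stack, "ess_stack"))
  dplyr::transmute(
    stack$per_pixel,
    pixel_id = .data$pixel_id, x = .data$x, y = .data$y,
    carbon = .data$carbon_t,
    p_retention = .data$p_retained_kg,
    p_export = .data$p_exported_kg,
    sediment_retention = .data$sed_retained_t,
    sediment_export = .data$sed_exported_t,
    msa = .data$msa
  )
}

#' The scenario registry
#'
#' The six study scenarios: four economic demand levels (wood-chip demand at
#' 1x, 2x, 4x and 8x the summed CHP plant capacities) and two EFA policy
#' variants placing 16.67% of cropland into SRC on the worst or best soils,
#' plus the no-SRC baseline.
#'
#' @return Tibble with `name`, `demand_multiplier`, `policy`.
#' @export
scenario_registry <- function() {
  tibble(
    name = c("baseline", "standard", "medium", "high", "very_high",
             "efa_bad_soils", "efa_good_soils"),
    demand_multiplier = c(0, 1, 2, 4, 8, 1, 1),
    policy = c("none", "none", "none", "none", "none",
               "efa_bad_soils", "efa_good_soils")
  )
}

#' Run one scenario end to end
#'
#' Builds agents, calibrates the annual demand if not supplied, clears the
#' markets (with EFA pre-allocation under a policy scenario), applies the
#' decisions to the land-use map, and evaluates services and production.
#'
#' @param landscape A `landscape` with plants placed.
#' @param scenario A [scenario_config()].
#' @param costs A [cost_table()].
#' @param agents Optional prebuilt agent table.
#' @param params An [ess_params()] bundle.
#' @param flow Optional precomputed flow graph.
#' @param yield_params [src_yield_params()].
#' @return A `scenario_result`: equilibrium, land-use vector, SRC area share
#'   (percent of total area), ESS stack, production totals.
#' @export
run_scenario <- function(landscape, scenario = scenario_config(),
                         costs = cost_table(), agents = NULL,
                         params = ess_params(), flow = NULL,
                         yield_params = src_yield_params()) {
  stopifnot(inherits(landscape, "landscape"))
  agents <- agents %||% build_agents(landscape, yield_params)
  if (is.null(scenario$demand_annual)) {
    cal <- calibrate_annual_demand(
      agents, costs, target_shares = scenario$target_shares,
      scenario = scenario
    )
    scenario$demand_annual <- cal$demand_annual
  }
  eq <- if (scenario$policy == "none") {
    clear_market(agents, scenario, costs, plants = landscape$plants)
  } else {
    allocate_efa(agents, scenario, costs, plants = landscape$plants)
  }
  landuse <- apply_decisions(landscape, eq$decisions)
  stack <- compute_ess_stack(landscape, landuse, params, flow)
  area <- cell_area_ha(landscape$grid)
  production <- tibble(
    commodity = c("src", "annual"),
    production_t = c(
      sum(eq$decisions$yield_src[eq$decisions$option == "SRC"] * area),
      sum(eq$decisions$yield_annual[eq$decisions$option == "ANNUAL"] * area)
    )
  )
  structure(
    list(
      name = scenario$name, scenario = scenario, equilibrium = eq,
      landuse = landuse,
      src_share = 100 * sum(landuse == "SRC") / length(landuse),
      ess = stack, production = production,
      totals = scenario_totals(stack, production)
    ),
    class = "scenario_result"
  )
}

# land-use map after the simulated decisions: cropland pixels take their
# agent's option, everything else keeps the baseline class
apply_decisions <- function(landscape, decisions) {
  lu <- as.character(landscape$pixels$lulc)
  idx <- match(decisions$pixel_id, landscape$pixels$pixel_id)
  lu[idx] <- c(SRC = "SRC", ANNUAL = "cropland",
               FALLOW = "fallow")[decisions$option]
  factor(lu, levels = lulc_levels())
}

scenario_totals <- function(stack, production) {
  dplyr::bind_rows(
    stack$totals[, c("service", "value")],
    tibble(
      service = c("crop_production", "src_production"),
      value = c(
        production$production_t[production$commodity == "annual"],
        production$production_t[production$commodity == "src"]
      )
    )
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf(
    "<scenario_result> '%s': SRC share %.1f%% of total area, prices src %.1f / annual %.1f EUR/t\n",
    x$name, x$src_share, x$equilibrium$price_src, x$equilibrium$price_annual
  ))
  print(x$totals)
  invisible(x)
}

#' Run several scenarios on one landscape
#'
#' Shares the agent table, the calibrated annual demand and the flow graph
#' across scenarios so cross-scenario differences come from the scenario
#' settings alone.
#'
#' @param landscape A `landscape` with plants.
#' @param scenarios Tibble like [scenario_registry()] (columns `name`,
#'   `demand_multiplier`, `policy`), or a list of [scenario_config()]s.
#' @param costs,params,yield_params Shared model parameters.
#' @param ... Extra arguments passed to every [scenario_config()] built from
#'   a registry row.
#' @return Named list of `scenario_result`s.
#' @export
run_scenarios <- function(landscape, scenarios = scenario_registry(),
                          costs = cost_table(), params = ess_params(),
                          yield_params = src_yield_params(), ...) {
  agents <- build_agents(landscape, yield_params)
  flow <- build_flow_graph(
    as_grid_matrix(landscape$pixels$elevation, landscape$grid),
    cell_size = landscape$grid$cell_size
  )
  configs <- if (is.data.frame(scenarios)) {
    purrr::pmap(
      scenarios[, c("name", "demand_multiplier", "policy")],
      function(name, demand_multiplier, policy) {
        scenario_config(name = name, demand_multiplier = demand_multiplier,
                        policy = policy, ...)
      }
    )
  } else {
    scenarios
  }
  cal <- calibrate_annual_demand(
    agents, costs, target_shares = configs[[1]]$target_shares,
    scenario = configs[[1]]
  )
  results <- purrr::map(configs, function(cfg) {
    cfg$demand_annual <- cfg$demand_annual %||% cal$demand_annual
    run_scenario(landscape, cfg, costs, agents = agents, params = params,
                 flow = flow, yield_params = yield_params)
  })
  stats::setNames(results, purrr::map_chr(configs, "name"))
}

#' Cross-scenario comparison table
#'
#' For every service, scales scenario values so the maximum over all
#' scenarios is exactly 100% and adds the signed percent change against the
#' baseline. P export and sediment export are flagged `lower_better`; for
#' every other service larger values mean better performance.
#'
#' @param results Named list of `scenario_result`s (or a list of `totals`
#'   tibbles).
#' @param baseline Name of the baseline scenario.
#' @return A tibble of class `scenario_comparison` with `scenario`,
#'   `service`, `value`, `pct_of_max`, `change_vs_baseline_pct`,
#'   `orientation`.
#' @export
compare_scenarios <- function(results, baseline = "baseline") {
  totals <- purrr::imap_dfr(results, function(res, nm) {
    tt <- if (inherits(res, "scenario_result")) res$totals else as_tibble(res)
    dplyr::mutate(tt, scenario = nm, .before = 1)
  })
  if (!baseline %in% totals$scenario) {
    abort(sprintf("Baseline scenario '%s' not among the results.", baseline))
  }
  lower_better <- c("p_export", "sediment_export")
  out <- totals |>
    dplyr::group_by(.data$service) |>
    dplyr::mutate(
      pct_of_max = 100 * .data$value / max(.data$value),
      change_vs_baseline_pct = {
        base <- .data$value[.data$scenario == baseline][1]
        if (base == 0) {
          ifelse(.data$value == 0, 0, NA_real_)
        } else {
          100 * (.data$value - base) / base
        }
      },
      orientation = ifelse(.data$service %in% lower_better,
                           "lower_better", "higher_better")
    ) |>
    dplyr::ungroup()
  class(out) <- c("scenario_comparison", class(out))
  out
}

#' Write the interface files of a scenario result
#'
#' `equilibrium.csv` (prices, supplies, iterations), `decisions.csv`,
#' `ess_totals.csv` and the scenario land-use map as an ASCII grid with a
#' legend.
#'
#' @param result A `scenario_result`.
#' @param dir Output directory.
#' @param landscape The landscape the scenario ran on (for the grid).
#' @return `dir`, invisibly.
#' @export
write_scenario_result <- function(result, dir, landscape) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  eq <- result$equilibrium
  readr::write_csv(
    dplyr::mutate(eq$supplies, iterations = eq$iterations,
                  method = eq$method),
    file.path(dir, "equilibrium.csv")
  )
  readr::write_csv(
    dplyr::select(eq$decisions, -dplyr::any_of(c("dist_matrix"))),
    file.path(dir, "decisions.csv")
  )
  readr::write_csv(result$totals, file.path(dir, "ess_totals.csv"))
  write_ascii_grid(as.integer(result$landuse), landscape$grid,
                   file.path(dir, "landuse.asc"))
  readr::write_csv(
    tibble(code = seq_along(lulc_levels()), class = lulc_levels()),
    file.path(dir, "lulc_legend.csv")
  )
  invisible(dir)
}

#' Read/write scenario configurations as YAML
#'
#' @param path YAML file path.
#' @return A [scenario_config()] for `read_scenario_config()`.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort(sprintf("Unknown scenario config field(s): %s.", toString(unknown)))
  }
  if (!is.null(vals$target_shares)) {
    vals$target_shares <- unlist(vals$target_shares)
  }
  if (!is.null(vals$price_bounds)) {
    vals$price_bounds <- unlist(vals$price_bounds)
  }
  do.call(scenario_config, vals)
}

#' @rdname read_scenario_config
#' @param config A [scenario_config()].
#' @export
write_scenario_config <- function(config, path) {
  vals <- unclass(config)
  vals$target_shares <- as.list(vals$target_shares)
  vals$price_bounds <- as.numeric(vals$price_bounds)
  yaml::write_yaml(vals, path)
  invisible(path)
}
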