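#' Production, transport and fallow-payment parameters
#'
#' Per-hectare production costs by land-use option, a per-tonne-kilometre
#' transport rate for wood chips (annual crops are marketed locally and
#' carry no explicit transport term), and the area payment received for
#' fallow land. Values are documented plausible defaults for a German
#' commercial setting; the comparative behaviour of the model (who switches
#' first, where) does not depend on their absolute levels.
#'
#' @param production_src SRC production cost (EUR/ha/a, annualised over the
#'   plantation life).
#' @param production_annual Annual-crop production cost (EUR/ha/a).
#' @param production_fallow Fallow upkeep cost (EUR/ha/a).
#' @param transport_rate Wood-chip transport cost (EUR per t per km); the
#'   default reflects farm tractor-and-trailer haulage of fresh chips over
#'   the few-kilometre distances that dominate deliveries here.
#' @param fallow_payment Area payment on fallow land (EUR/ha/a).
#' @return List of class `cost_table`.
#' @export
cost_table <- function(production_src = 300, production_annual = 1100,
                       production_fallow = 0, transport_rate = 1.0,
                       fallow_payment = 100) {
  vals <- c(production_src, production_annual, production_fallow,
            transport_rate, fallow_payment)
  if (any(!is.finite(vals)) || any(vals[1:4] < 0)) {
    abort("Costs must be finite and production/transport costs >= 0.")
  }
  structure(
    list(
      production_src = production_src,
      production_annual = production_annual,
      production_fallow = production_fallow,
      transport_rate = transport_rate,
      fallow_payment = fallow_payment
    ),
    class = "cost_table"
  )
}

#' Market prices and exogenous demands
#'
#' @param price_src Wood-chip price (EUR/t); in local mode the scalar is the
#'   initial value of every plant price.
#' @param price_annual Annual-crop price (EUR/t).
#' @param demand_src Exogenous wood-chip demand (t/a, regional total).
#' @param demand_annual Exogenous annual-crop demand (t/a).
#' @param price_mode `"regional"` (one wood-chip price) or `"local"` (one
#'   price per CHP plant).
#' @param plant_prices,plant_demands Per-plant price and demand vectors
#'   (local mode).
#' @return List of class `market_state`.
#' @export
market_state <- function(price_src = 100, price_annual = 180,
                         demand_src = 0, demand_annual = 0,
                         price_mode = c("regional", "local"),
                         plant_prices = NULL, plant_demands = NULL) {
  price_mode <- match.arg(price_mode)
  if (any(c(price_src, price_annual, demand_src, demand_annual) < 0)) {
    abort("Prices and demands must be >= 0.")
  }
  structure(
    list(
      price_src = price_src, price_annual = price_annual,
      demand_src = demand_src, demand_annual = demand_annual,
      price_mode = price_mode,
      plant_prices = plant_prices, plant_demands = plant_demands
    ),
    class = "market_state"
  )
}

#' EFA fraction implied by the CAP greening rule
#'
#' Farmers must reserve `efa_share` (5%) of arable land as ecological focus
#' area; SRC counts with weighting factor `src_weight` (0.3), so the land
#' share actually planted is `efa_share / src_weight` = 16.67%.
#'
#' @param efa_share Required EFA share of arable land.
#' @param src_weight EFA weighting factor of SRC.
#' @return The SRC land fraction.
#' @export
#' @examples
#' efa_fraction_cap() # 0.1667
efa_fraction_cap <- function(efa_share = 0.05, src_weight = 0.3) {
  efa_share / src_weight
}

#' Scenario configuration
#'
#' A scenario fixes the wood-chip demand level (as a multiplier on the base
#' demand, by default the summed CHP plant capacities), the price-formation
#' mode, and an optional EFA policy that pre-allocates a fixed share of
#' cropland to SRC by soil quality.
#'
#' @param name Scenario name.
#' @param demand_multiplier Multiplier on the base wood-chip demand
#'   (standard/medium/high/very-high default to 1/2/4/8).
#' @param price_mode `"regional"` or `"local"`.
#' @param policy `"none"`, `"efa_bad_soils"` or `"efa_good_soils"`.
#' @param efa_fraction Cropland share converted under an EFA policy; default
#'   [efa_fraction_cap()].
#' @param demand_src_base Base wood-chip demand (t/a); `NULL` = sum of plant
#'   capacities.
#' @param demand_annual Annual-crop demand (t/a); `NULL` = calibrate against
#'   `target_shares` (see [calibrate_annual_demand()]).
#' @param target_shares Named baseline shares of cropland under `ANNUAL` and
#'   `FALLOW` used for calibration.
#' @param tol Relative market-clearing tolerance.
#' @param max_iter Price-iteration cap.
#' @param lambda Initial damping of the multiplicative price update.
#' @param price_bounds Price bounds (EUR/t).
#' @param seed Scenario seed.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(name = "standard",
                            demand_multiplier = 1,
                            price_mode = c("regional", "local"),
                            policy = c("none", "efa_bad_soils",
                                       "efa_good_soils"),
                            efa_fraction = efa_fraction_cap(),
                            demand_src_base = NULL,
                            demand_annual = NULL,
                            target_shares = c(annual = 0.85, fallow = 0.15),
                            tol = 0.01,
                            max_iter = 400,
                            lambda = 0.25,
                            price_bounds = c(0, 2000),
                            seed = 1) {
  price_mode <- match.arg(price_mode)
  policy <- match.arg(policy)
  if (efa_fraction < 0 || efa_fraction > 1) {
    abort("`efa_fraction` must lie in [0, 1].")
  }
  assert_number(demand_multiplier, "demand_multiplier", lower = 0)
  structure(
    list(
      name = name, demand_multiplier = demand_multiplier,
      price_mode = price_mode, policy = policy, efa_fraction = efa_fraction,
      demand_src_base = demand_src_base, demand_annual = demand_annual,
      target_shares = target_shares, tol = tol, max_iter = max_iter,
      lambda = lambda, price_bounds = price_bounds, seed = seed
    ),
    class = "scenario_config"
  )
}

#' Build the agent table from a landscape
#'
#' One agent per cropland pixel, carrying the site covariates both yield
#' models need, the site-specific SRC and annual-crop yields, and transport
#' distances to every CHP plant (Euclidean, km). The full distance matrix is
#' kept as an attribute (`dist_matrix`, agents x plants) for local price
#' formation; `dist_km`/`nearest_plant` describe the nearest plant (ties to
#' the lowest plant id).
#'
#' @param landscape A `landscape` with plants placed (possibly zero).
#' @param yield_params [src_yield_params()].
#' @return Tibble of agents with attribute `dist_matrix`.
#' @export
build_agents <- function(landscape, yield_params = src_yield_params()) {
  stopifnot(inherits(landscape, "landscape"))
  crop <- landscape$pixels[landscape$pixels$lulc == "cropland", ]
  crop <- src_yield(crop, params = yield_params, warn_clip = FALSE)
  crop <- add_crop_yield(crop, landscape$districts)
  agents <- dplyr::select(
    crop, "pixel_id", "row", "col", "x", "y", "sqi",
    "yield_src", "yield_annual", "district_id"
  )
  plants <- landscape$plants
  if (nrow(plants) == 0L) {
    dm <- matrix(Inf, nrow(agents), 0)
    agents$dist_km <- rep(Inf, nrow(agents))
    agents$nearest_plant <- rep(NA_integer_, nrow(agents))
  } else {
    dm <- outer(agents$x, plants$x, "-")^2 + outer(agents$y, plants$y, "-")^2
    dm <- sqrt(dm) / 1000
    nearest <- max.col(-dm, ties.method = "first")
    agents$dist_km <- dm[cbind(seq_len(nrow(agents)), nearest)]
    agents$nearest_plant <- plants$id[nearest]
  }
  attr(agents, "dist_matrix") <- dm
  attr(agents, "cell_area_ha") <- cell_area_ha(landscape$grid)
  agents
}

#' Choose the CHP plant an agent would deliver to
#'
#' Under one regional price the nearest plant minimises transport cost and
#' wins; under local prices the plant maximising the per-tonne margin
#' (local price minus transport cost) wins. Ties go to the lowest plant id.
#'
#' @param agents Agent tibble from [build_agents()].
#' @param market A [market_state()].
#' @param costs A [cost_table()] (supplies the transport rate).
#' @return Integer vector of plant ids (`NA` if there are no plants).
#' @export
choose_plant <- function(agents, market, costs = cost_table()) {
  dm <- attr(agents, "dist_matrix")
  if (is.null(dm) || ncol(dm) == 0L) return(rep(NA_integer_, nrow(agents)))
  if (market$price_mode == "regional") {
    return(agents$nearest_plant)
  }
  prices <- market$plant_prices %||%
    rep(market$price_src, ncol(dm))
  margin <- matrix(prices, nrow(agents), ncol(dm), byrow = TRUE) -
    costs$transport_rate * dm
  as.integer(max.col(margin, ties.method = "first"))
}

#' Net profit of a land-use option
#'
#' Net profit is revenue minus cost, per hectare and year. For SRC, revenue
#' is the wood-chip price times the site yield, and costs include production
#' and transport (rate x yield x distance to the chosen plant); annual crops
#' carry production cost only; fallow earns the area payment minus upkeep.
#' With no reachable plant the SRC profit is `-Inf`.
#'
#' @param agents Agent tibble.
#' @param option One of `"SRC"`, `"ANNUAL"`, `"FALLOW"`.
#' @param market A [market_state()].
#' @param costs A [cost_table()].
#' @return Numeric vector (EUR/ha/a).
#' @export
net_profit <- function(agents, option, market, costs = cost_table()) {
  option <- match.arg(option, land_use_options())
  n <- nrow(agents)
  switch(option,
    SRC = {
      pl <- choose_plant(agents, market, costs)
      if (all(is.na(pl))) return(rep(-Inf, n))
      dm <- attr(agents, "dist_matrix")
      d <- dm[cbind(seq_len(n), pl)]
      price <- if (market$price_mode == "local") {
        (market$plant_prices %||% rep(market$price_src, ncol(dm)))[pl]
      } else {
        market$price_src
      }
      price * agents$yield_src - costs$production_src -
        costs$transport_rate * agents$yield_src * d
    },
    ANNUAL = market$price_annual * agents$yield_annual -
      costs$production_annual,
    FALLOW = rep(costs$fallow_payment - costs$production_fallow, n)
  )
}

#' Profit-maximising land-use choice of every agent
#'
#' Evaluates [net_profit()] for all three options and picks the argmax.
#' Exact ties are broken deterministically in favour of `ANNUAL`, then
#' `SRC`, then `FALLOW` (the cultivation status quo wins a tie, SRC wins a
#' tie against idling land).
#'
#' @inheritParams net_profit
#' @return Agent tibble with `profit_src`, `profit_annual`, `profit_fallow`,
#'   chosen `option`, its `profit`, and `plant_id` for SRC deliveries.
#' @export
best_response <- function(agents, market, costs = cost_table()) {
  out <- as_tibble(agents)
  out$profit_src <- net_profit(agents, "SRC", market, costs)
  out$profit_annual <- net_profit(agents, "ANNUAL", market, costs)
  out$profit_fallow <- net_profit(agents, "FALLOW", market, costs)
  m <- pmax(out$profit_src, out$profit_annual, out$profit_fallow)
  out$option <- ifelse(out$profit_annual == m, "ANNUAL",
                       ifelse(out$profit_src == m, "SRC", "FALLOW"))
  out$profit <- m
  pl <- choose_plant(agents, market, costs)
  out$plant_id <- ifelse(out$option == "SRC", pl, NA_integer_)
  attr(out, "dist_matrix") <- attr(agents, "dist_matrix")
  attr(out, "cell_area_ha") <- attr(agents, "cell_area_ha")
  out
}

#' Aggregate commodity supply implied by agent decisions
#'
#' Supply is the sum of yield times cell area over the pixels holding each
#' option.
#'
#' @param decisions Tibble from [best_response()] (columns `option`,
#'   `yield_src`, `yield_annual`, `plant_id`).
#' @param cell_area Cell area in ha; taken from the decisions attribute when
#'   omitted.
#' @param by_plant Also break SRC supply down by receiving plant.
#' @return Tibble with `commodity` and `supply_t`; with `by_plant = TRUE`
#'   an additional tibble attribute `plant_supply`.
#' @export
aggregate_supply <- function(decisions, cell_area = NULL, by_plant = FALSE) {
  cell_area <- cell_area %||% attr(decisions, "cell_area_ha") %||%
    abort("`cell_area` is required.")
  src <- decisions$option == "SRC"
  ann <- decisions$option == "ANNUAL"
  out <- tibble(
    commodity = c("src", "annual"),
    supply_t = c(
      sum(decisions$yield_src[src] * cell_area),
      sum(decisions$yield_annual[ann] * cell_area)
    )
  )
  if (by_plant) {
    ps <- decisions[src, ] |>
      dplyr::group_by(plant_id = .data$plant_id) |>
      dplyr::summarise(supply_t = sum(.data$yield_src * cell_area),
                       .groups = "drop")
    attr(out, "plant_supply") <- ps
  }
  out
}
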