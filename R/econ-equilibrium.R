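# market clearing: damped multiplicative tatonnement with a
# reservation-price fallback on the monotone step supply curve

subset_agents <- function(agents, keep) {
  out <- agents[keep, , drop = FALSE]
  dm <- attr(agents, "dist_matrix")
  if (!is.null(dm)) attr(out, "dist_matrix") <- dm[keep, , drop = FALSE]
  attr(out, "cell_area_ha") <- attr(agents, "cell_area_ha")
  out
}

market_cleared <- function(supply, demand, price, tol, bounds) {
  eps <- 1e-9 * max(1, bounds[2])
  (demand == 0 && supply == 0) ||
    (demand > 0 && abs(supply - demand) <= tol * demand) ||
    (supply < demand && price >= bounds[2] - eps) ||
    (supply > demand && price <= bounds[1] + eps)
}

at_corner <- function(supply, demand, price, tol, bounds) {
  eps <- 1e-9 * max(1, bounds[2])
  cleared_interior <- (demand == 0 && supply == 0) ||
    (demand > 0 && abs(supply - demand) <= tol * demand)
  !cleared_interior &&
    ((supply < demand && price >= bounds[2] - eps) ||
       (supply > demand && price <= bounds[1] + eps))
}

# price at which cumulative supply along sorted reservation prices comes
# closest to the demand (the step just below or just above the crossing);
# q = per-agent output (t/a)
pick_clearing_price <- function(r, q, demand, tol, bounds) {
  if (demand <= 0) return(bounds[1])
  o <- order(r)
  fin <- is.finite(r[o])
  cum <- cumsum(q[o])
  m <- which(cum >= demand & fin)[1]
  if (is.na(m)) return(bounds[2])
  if (m > 1 && abs(cum[m - 1] - demand) <= abs(cum[m] - demand)) {
    m <- m - 1
  }
  min(max(r[o][m] * (1 + 1e-9) + 1e-12, bounds[1]), bounds[2])
}

#' Clear the SRC and annual-crop markets
#'
#' Finds prices at which every agent plays a profit-maximising best response
#' and each commodity's endogenous supply matches its exogenous demand
#' within `scenario$tol` (or sits at a corner: demand unmeetable at the
#' price cap, or excess supply at the price floor). The solver runs a damped
#' multiplicative tatonnement `p <- p * (D/S)^lambda` with decaying damping
#' and price bounds; if the step structure of supply defeats it, a
#' reservation-price pass solves each market exactly on the sorted step
#' supply curve (Gauss--Seidel across the two commodities). Returned
#' decisions are best responses to the returned prices, so no agent can gain
#' by unilateral deviation.
#'
#' @param agents Agent tibble from [build_agents()].
#' @param scenario A [scenario_config()].
#' @param costs A [cost_table()].
#' @param demand_src,demand_annual Commodity demands (t/a); defaults come
#'   from the scenario (`demand_src_base * demand_multiplier` and
#'   `demand_annual`).
#' @param plants Plant table; required in local price mode (per-plant
#'   demands default to capacity times the multiplier).
#' @return A `market_equilibrium`: final prices, per-agent `decisions`,
#'   `supplies` (supply, demand, cleared and corner flags per commodity),
#'   convergence diagnostics and the price `trajectory`.
#' @export
clear_market <- function(agents, scenario = scenario_config(),
                         costs = cost_table(),
                         demand_src = NULL, demand_annual = NULL,
                         plants = NULL) {
  if (nrow(agents) == 0L) {
    abort("No agents: the landscape has no cropland pixels.")
  }
  d_src <- demand_src %||%
    ((scenario$demand_src_base %||% sum(plants$capacity %||% 0)) *
       scenario$demand_multiplier)
  d_ann <- demand_annual %||% scenario$demand_annual %||% 0
  if (d_src < 0 || d_ann < 0) abort("Demands must be >= 0.")
  if (scenario$price_mode == "local") {
    return(clear_market_local(agents, scenario, costs, d_ann, plants))
  }
  area <- attr(agents, "cell_area_ha")
  bounds <- scenario$price_bounds
  tol <- scenario$tol

  eval_at <- function(p_src, p_ann) {
    mkt <- market_state(p_src, p_ann, d_src, d_ann)
    dec <- best_response(agents, mkt, costs)
    s <- aggregate_supply(dec, area)
    list(mkt = mkt, dec = dec,
         s_src = s$supply_t[s$commodity == "src"],
         s_ann = s$supply_t[s$commodity == "annual"])
  }

  p_src <- if (d_src == 0) 0 else min(max(100, bounds[1]), bounds[2])
  p_ann <- if (d_ann == 0) 0 else min(max(180, bounds[1]), bounds[2])
  traj <- vector("list", scenario$max_iter)
  st <- eval_at(p_src, p_ann)
  iter <- 0L
  repeat {
    ok_src <- market_cleared(st$s_src, d_src, p_src, tol, bounds)
    ok_ann <- market_cleared(st$s_ann, d_ann, p_ann, tol, bounds)
    if ((ok_src && ok_ann) || iter >= scenario$max_iter) break
    iter <- iter + 1L
    lam <- scenario$lambda / (1 + iter / 50)
    if (d_src > 0) {
      delta <- 1e-9 + 1e-6 * d_src
      p_src <- min(max(p_src * ((d_src + delta) / (st$s_src + delta))^lam,
                       bounds[1] + 1e-9), bounds[2])
    }
    if (d_ann > 0) {
      delta <- 1e-9 + 1e-6 * d_ann
      p_ann <- min(max(p_ann * ((d_ann + delta) / (st$s_ann + delta))^lam,
                       bounds[1] + 1e-9), bounds[2])
    }
    st <- eval_at(p_src, p_ann)
    traj[[iter]] <- tibble(
      iter = iter, price_src = p_src, price_annual = p_ann,
      supply_src = st$s_src, supply_annual = st$s_ann, method = "tatonnement"
    )
  }
  method <- "tatonnement"

  # max_iter = 0 requests the exact solver directly (used by calibration,
  # where the share-demand relation must be free of tolerance noise)
  if (scenario$max_iter == 0L ||
      !(market_cleared(st$s_src, d_src, p_src, tol, bounds) &&
        market_cleared(st$s_ann, d_ann, p_ann, tol, bounds))) {
    # exact solve on the step supply curves: for any annual price the SRC
    # market is cleared exactly by sorting reservation prices (the price at
    # which SRC profit equals an agent's best alternative); the annual price
    # is then bracketed by bisection on its monotone excess demand
    method <- "reservation"
    solve_src <- function(p_ann) {
      if (d_src <= 0) return(0)
      mkt0 <- market_state(0, p_ann, d_src, d_ann)
      alt <- pmax(net_profit(agents, "ANNUAL", mkt0, costs),
                  net_profit(agents, "FALLOW", mkt0, costs))
      r <- (alt + costs$production_src) / agents$yield_src +
        costs$transport_rate * agents$dist_km
      r[agents$yield_src <= 0 | !is.finite(agents$dist_km)] <- Inf
      pick_clearing_price(r, agents$yield_src * area, d_src, tol, bounds)
    }
    eval_ann <- function(p_ann) {
      ps <- solve_src(p_ann)
      list(p_src = ps, st = eval_at(ps, p_ann))
    }
    take <- function(res, p_ann) {
      p_src <<- res$p_src
      p_ann <<- p_ann
      st <<- res$st
    }
    if (d_ann <= 0) {
      take(eval_ann(0), 0)
    } else if (d_src <= 0) {
      # annual-only market: solve it exactly on its own step supply curve
      mkt0 <- market_state(0, 0, d_src, d_ann)
      alt <- pmax(net_profit(agents, "SRC", mkt0, costs),
                  net_profit(agents, "FALLOW", mkt0, costs))
      r <- (alt + costs$production_annual) / agents$yield_annual
      r[agents$yield_annual <= 0] <- Inf
      pa <- pick_clearing_price(r, agents$yield_annual * area, d_ann,
                                tol, bounds)
      take(eval_ann(pa), pa)
    } else {
      lo <- bounds[1]
      hi <- bounds[2]
      res_hi <- eval_ann(hi)
      res_lo <- eval_ann(lo)
      if (res_hi$st$s_ann < d_ann * (1 - tol)) {
        take(res_hi, hi)   # demand unmeetable even at the price cap
      } else if (res_lo$st$s_ann > d_ann * (1 + tol)) {
        take(res_lo, lo)   # excess supply even at the price floor
      } else {
        take(res_lo, lo)
        for (b in seq_len(80L)) {
          iter <- iter + 1L
          mid <- (lo + hi) / 2
          res <- eval_ann(mid)
          take(res, mid)
          if (market_cleared(st$s_ann, d_ann, p_ann, tol, bounds) &&
              market_cleared(st$s_src, d_src, p_src, tol, bounds)) break
          if (st$s_ann < d_ann) lo <- mid else hi <- mid
          if ((hi - lo) < 1e-10 * max(1, hi)) break
        }
      }
    }
  }

  trajectory <- dplyr::bind_rows(traj[!vapply(traj, is.null, TRUE)])
  supplies <- tibble(
    commodity = c("src", "annual"),
    supply_t = c(st$s_src, st$s_ann),
    demand_t = c(d_src, d_ann),
    price = c(p_src, p_ann),
    cleared = c(market_cleared(st$s_src, d_src, p_src, tol, bounds),
                market_cleared(st$s_ann, d_ann, p_ann, tol, bounds)),
    at_corner = c(at_corner(st$s_src, d_src, p_src, tol, bounds),
                  at_corner(st$s_ann, d_ann, p_ann, tol, bounds))
  )
  if (!all(supplies$cleared)) {
    abort(
      c(
        "Market clearing failed to converge.",
        sprintf("src: supply %.1f vs demand %.1f at price %.2f",
                st$s_src, d_src, p_src),
        sprintf("annual: supply %.1f vs demand %.1f at price %.2f",
                st$s_ann, d_ann, p_ann)
      ),
      class = "srcscape_market_error",
      trajectory = trajectory
    )
  }
  structure(
    list(
      price_src = p_src, price_annual = p_ann,
      market = st$mkt, decisions = st$dec, supplies = supplies,
      converged = TRUE, at_corner = any(supplies$at_corner),
      iterations = iter, method = method, trajectory = trajectory,
      price_mode = "regional", costs = costs, tol = tol
    ),
    class = "market_equilibrium"
  )
}

# local price formation: one price and one demand per plant
clear_market_local <- function(agents, scenario, costs, d_ann, plants) {
  if (is.null(plants) || nrow(plants) == 0L) {
    abort("Local price mode needs a plant table.")
  }
  area <- attr(agents, "cell_area_ha")
  bounds <- scenario$price_bounds
  tol <- scenario$tol
  d_plant <- plants$capacity * scenario$demand_multiplier
  p_plant <- rep(min(max(100, bounds[1]), bounds[2]), nrow(plants))
  p_ann <- if (d_ann == 0) 0 else min(max(180, bounds[1]), bounds[2])

  eval_at <- function(p_plant, p_ann) {
    mkt <- market_state(
      price_src = mean(p_plant), price_annual = p_ann,
      demand_src = sum(d_plant), demand_annual = d_ann,
      price_mode = "local", plant_prices = p_plant, plant_demands = d_plant
    )
    dec <- best_response(agents, mkt, costs)
    s <- aggregate_supply(dec, area, by_plant = TRUE)
    ps <- attr(s, "plant_supply")
    s_plant <- rep(0, nrow(plants))
    if (nrow(ps)) s_plant[ps$plant_id] <- ps$supply_t
    list(mkt = mkt, dec = dec, s_plant = s_plant,
         s_ann = s$supply_t[s$commodity == "annual"])
  }

  st <- eval_at(p_plant, p_ann)
  traj <- vector("list", scenario$max_iter)
  iter <- 0L
  repeat {
    ok_p <- vapply(seq_along(d_plant), function(j) {
      market_cleared(st$s_plant[j], d_plant[j], p_plant[j], tol, bounds)
    }, TRUE)
    ok_a <- market_cleared(st$s_ann, d_ann, p_ann, tol, bounds)
    if ((all(ok_p) && ok_a) || iter >= scenario$max_iter) break
    iter <- iter + 1L
    lam <- scenario$lambda / (1 + iter / 50)
    delta <- 1e-9 + 1e-6 * pmax(d_plant, 1)
    p_plant <- pmin(pmax(
      p_plant * ((d_plant + delta) / (st$s_plant + delta))^lam,
      bounds[1] + 1e-9
    ), bounds[2])
    if (d_ann > 0) {
      da <- 1e-9 + 1e-6 * d_ann
      p_ann <- min(max(p_ann * ((d_ann + da) / (st$s_ann + da))^lam,
                       bounds[1] + 1e-9), bounds[2])
    }
    st <- eval_at(p_plant, p_ann)
    traj[[iter]] <- tibble(
      iter = iter, price_src = mean(p_plant), price_annual = p_ann,
      supply_src = sum(st$s_plant), supply_annual = st$s_ann,
      method = "tatonnement"
    )
  }
  all_ok <- function(st, p_plant, p_ann) {
    all(vapply(seq_along(d_plant), function(j) {
      market_cleared(st$s_plant[j], d_plant[j], p_plant[j], tol, bounds)
    }, TRUE)) && market_cleared(st$s_ann, d_ann, p_ann, tol, bounds)
  }
  method <- "tatonnement"
  if (!all_ok(st, p_plant, p_ann)) {
    # Gauss-Seidel sweeps of exact reservation-price clearing: each plant's
    # price is solved on the sorted step supply curve given every other
    # price, as is the annual price
    method <- "reservation"
    dm <- attr(agents, "dist_matrix")
    area_q_src <- agents$yield_src * area
    # restart from moderate prices: the sweeps converge from a neutral
    # start, not necessarily from wherever the tatonnement diverged to
    p_plant <- rep(min(max(100, bounds[1]), bounds[2]), nrow(plants))
    p_ann <- if (d_ann == 0) 0 else min(max(180, bounds[1]), bounds[2])
    for (sweep in seq_len(400L)) {
      iter <- iter + 1L
      # per-tonne margin p_k - tau * d_ik, as profit per ha
      marg <- t(t(-costs$transport_rate * dm) + p_plant)
      prof_plant <- marg * agents$yield_src - costs$production_src
      prof_ann <- if (d_ann > 0) {
        p_ann * agents$yield_annual - costs$production_annual
      } else {
        -costs$production_annual
      }
      prof_fal <- costs$fallow_payment - costs$production_fallow
      if (d_ann > 0) {
        alt <- pmax(apply(prof_plant, 1, max), prof_fal)
        r_ann <- (alt + costs$production_annual) / agents$yield_annual
        r_ann[agents$yield_annual <= 0] <- Inf
        p_ann <- pick_clearing_price(r_ann, agents$yield_annual * area,
                                     d_ann, tol, bounds)
        prof_ann <- p_ann * agents$yield_annual - costs$production_annual
      }
      for (j in seq_along(d_plant)) {
        marg <- t(t(-costs$transport_rate * dm) + p_plant)
        prof_plant <- marg * agents$yield_src - costs$production_src
        others <- prof_plant[, -j, drop = FALSE]
        alt <- pmax(
          if (ncol(others)) apply(others, 1, max) else -Inf,
          prof_ann, prof_fal
        )
        r_j <- (alt + costs$production_src) / agents$yield_src +
          costs$transport_rate * dm[, j]
        r_j[agents$yield_src <= 0] <- Inf
        p_plant[j] <- pick_clearing_price(r_j, area_q_src, d_plant[j],
                                          tol, bounds)
      }
      st <- eval_at(p_plant, p_ann)
      if (all_ok(st, p_plant, p_ann)) break
      # Gauss-Seidel can creep when plants compete for the same margin;
      # rescale all plant prices jointly when the aggregate is far off
      if (sweep %% 20L == 0L) {
        tot_s <- sum(st$s_plant)
        tot_d <- sum(d_plant)
        if (tot_d > 0 && abs(tot_s - tot_d) > 2 * tol * tot_d) {
          p_plant <- pmin(pmax(
            p_plant * ((tot_d + 1e-9) / (tot_s + 1e-9))^0.5,
            bounds[1] + 1e-9
          ), bounds[2])
          st <- eval_at(p_plant, p_ann)
        }
      }
    }
  }
  trajectory <- dplyr::bind_rows(traj[!vapply(traj, is.null, TRUE)])
  if (!all_ok(st, p_plant, p_ann)) {
    abort("Local market clearing failed to converge.",
          class = "srcscape_market_error", trajectory = trajectory)
  }
  supplies <- tibble(
    commodity = c("src", "annual"),
    supply_t = c(sum(st$s_plant), st$s_ann),
    demand_t = c(sum(d_plant), d_ann),
    price = c(mean(p_plant), p_ann),
    cleared = TRUE,
    at_corner = c(
      any(vapply(seq_along(d_plant), function(j) {
        at_corner(st$s_plant[j], d_plant[j], p_plant[j], tol, bounds)
      }, TRUE)),
      at_corner(st$s_ann, d_ann, p_ann, tol, bounds)
    )
  )
  structure(
    list(
      price_src = mean(p_plant), price_annual = p_ann,
      plant_prices = tibble(plant_id = plants$id, price = p_plant,
                            demand_t = d_plant, supply_t = st$s_plant),
      market = st$mkt, decisions = st$dec, supplies = supplies,
      converged = TRUE, at_corner = any(supplies$at_corner),
      iterations = iter, method = method, trajectory = trajectory,
      price_mode = "local", costs = costs, tol = tol
    ),
    class = "market_equilibrium"
  )
}

#' @export
print.market_equilibrium <- function(x, ...) {
  cat(sprintf(
    "<market_equilibrium> %s prices after %d iteration(s) [%s]%s\n",
    x$price_mode, x$iterations, x$method,
    if (x$at_corner) " (corner)" else ""
  ))
  print(x$supplies)
  invisible(x)
}

#' Largest unilateral deviation gain at an equilibrium
#'
#' Recomputes every agent's option profits at the equilibrium prices and
#' returns the maximum profit an agent could add by switching away from its
#' recorded decision. At a valid equilibrium this is <= 0 (up to floating
#' point): the epsilon-stability check.
#'
#' @param eq A `market_equilibrium`.
#' @return Maximum deviation gain (EUR/ha/a).
#' @export
equilibrium_stability <- function(eq) {
  br <- best_response(eq$decisions, eq$market, eq$costs)
  prof <- cbind(br$profit_src, br$profit_annual, br$profit_fallow)
  chosen <- prof[cbind(
    seq_len(nrow(prof)),
    match(eq$decisions$option, land_use_options())
  )]
  max(br$profit - chosen)
}

#' Calibrate the annual-crop demand against baseline land-use shares
#'
#' With zero SRC demand, searches (by bisection on the monotone share-demand
#' relation) for the annual-crop demand under which the simulated baseline
#' shares of cultivated vs fallow cropland match the empirical targets, then
#' returns the cleared supply at that point as the canonical demand.
#'
#' @param agents Agent tibble.
#' @param costs A [cost_table()].
#' @param target_shares Named vector with the target `annual` share of
#'   cropland (the `fallow` share is its complement).
#' @param tol Absolute tolerance on the achieved share; it cannot be tighter
#'   than the one-agent step `1/n` of the share-demand relation.
#' @param scenario Scenario template supplying solver settings.
#' @return List of class `demand_calibration` with `demand_annual`,
#'   `achieved_share`, `target_share`, `iterations`.
#' @export
calibrate_annual_demand <- function(agents, costs = cost_table(),
                                    target_shares = c(annual = 0.85,
                                                      fallow = 0.15),
                                    tol = 0.01,
                                    scenario = scenario_config()) {
  target <- unname(target_shares[["annual"]])
  if (target < 0 || target > 1) abort("Target annual share must be in [0,1].")
  if (sum(target_shares) > 1 + 1e-9) {
    abort("Target shares over cropland must sum to <= 1.")
  }
  area <- attr(agents, "cell_area_ha")
  # with zero SRC demand the reservation-price solve is exact and cheap, so
  # skip the tatonnement phase inside the bisection
  scenario$max_iter <- 0L
  eval_share <- function(D) {
    eq <- clear_market(agents, scenario, costs,
                       demand_src = 0, demand_annual = D)
    list(
      share = mean(eq$decisions$option == "ANNUAL"),
      supply = eq$supplies$supply_t[eq$supplies$commodity == "annual"]
    )
  }
  if (target == 0) {
    return(structure(
      list(demand_annual = 0, achieved_share = 0, target_share = 0,
           iterations = 0L),
      class = "demand_calibration"
    ))
  }
  hi <- 1.05 * sum(agents$yield_annual * area)
  lo <- 0
  top <- eval_share(hi)
  if (target > top$share + tol) {
    abort(sprintf(
      "Target annual share %.3f unreachable; achievable range is [0, %.3f].",
      target, top$share
    ))
  }
  res <- top
  best <- res
  iter <- 0L
  while (abs(best$share - target) > tol && iter < 60L) {
    iter <- iter + 1L
    mid <- (lo + hi) / 2
    res <- eval_share(mid)
    if (abs(res$share - target) < abs(best$share - target)) best <- res
    if (res$share < target) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-9 * max(1, hi)) break
  }
  res <- best
  if (abs(res$share - target) > tol) {
    abort(sprintf(
      "Calibration could not reach share %.3f within tol %.3f (best %.3f); the share-demand relation steps by 1/%d.",
      target, tol, res$share, nrow(agents)
    ))
  }
  structure(
    list(
      demand_annual = res$supply, achieved_share = res$share,
      target_share = target, iterations = iter
    ),
    class = "demand_calibration"
  )
}

#' Pixels selected under an EFA policy
#'
#' @param agents Agent tibble.
#' @param fraction Cropland fraction to convert.
#' @param mode `"bad_soils"` (ascending soil quality) or `"good_soils"`
#'   (descending); ties break on pixel id.
#' @return Integer vector of selected `pixel_id`s
#'   (`ceiling(fraction * n)` of them).
#' @export
efa_selection <- function(agents, fraction, mode = c("bad_soils",
                                                     "good_soils")) {
  mode <- match.arg(mode)
  if (fraction < 0 || fraction > 1) abort("`fraction` must be in [0, 1].")
  n_efa <- ceiling(fraction * nrow(agents))
  if (n_efa == 0L) return(integer())
  o <- if (mode == "bad_soils") {
    order(agents$sqi, agents$pixel_id)
  } else {
    order(-agents$sqi, agents$pixel_id)
  }
  agents$pixel_id[o[seq_len(n_efa)]]
}

#' Clear the markets under an EFA greening policy
#'
#' Converts `scenario$efa_fraction` of cropland to SRC by ascending
#' (`efa_bad_soils`) or descending (`efa_good_soils`) soil quality, feeds
#' the mandated SRC output into the wood-chip market (reducing the demand
#' the remaining agents face; EFA output is sold at the resulting
#' equilibrium price), and clears the remaining agents' markets.
#'
#' @inheritParams clear_market
#' @return A `market_equilibrium` whose decisions include the forced EFA
#'   pixels (`forced = TRUE`) and an `efa` diagnostic list.
#' @export
allocate_efa <- function(agents, scenario, costs = cost_table(),
                         demand_src = NULL, demand_annual = NULL,
                         plants = NULL) {
  mode <- switch(scenario$policy,
    efa_bad_soils = "bad_soils",
    efa_good_soils = "good_soils",
    abort("`scenario$policy` must be an EFA policy for allocate_efa().")
  )
  d_src <- demand_src %||%
    ((scenario$demand_src_base %||% sum(plants$capacity %||% 0)) *
       scenario$demand_multiplier)
  area <- attr(agents, "cell_area_ha")
  efa_ids <- efa_selection(agents, scenario$efa_fraction, mode)
  efa_mask <- agents$pixel_id %in% efa_ids
  efa_supply <- sum(agents$yield_src[efa_mask] * area)
  rest <- subset_agents(agents, !efa_mask)
  free_scenario <- scenario
  free_scenario$policy <- "none"
  eq <- clear_market(rest, free_scenario, costs,
                     demand_src = max(0, d_src - efa_supply),
                     demand_annual = demand_annual, plants = plants)
  eq$decisions$forced <- FALSE
  if (any(efa_mask)) {
    efa_dec <- best_response(subset_agents(agents, efa_mask), eq$market,
                             costs)
    efa_dec$option <- "SRC"
    efa_dec$profit <- efa_dec$profit_src
    efa_dec$plant_id <- choose_plant(subset_agents(agents, efa_mask),
                                     eq$market, costs)
    efa_dec$forced <- TRUE
    eq$decisions <- dplyr::arrange(
      dplyr::bind_rows(eq$decisions, efa_dec), .data$pixel_id
    )
  }
  dm_all <- attr(agents, "dist_matrix")
  ord_idx <- match(eq$decisions$pixel_id, agents$pixel_id)
  attr(eq$decisions, "dist_matrix") <- dm_all[ord_idx, , drop = FALSE]
  attr(eq$decisions, "cell_area_ha") <- area
  src_row <- eq$supplies$commodity == "src"
  eq$supplies$supply_t[src_row] <- eq$supplies$supply_t[src_row] + efa_supply
  eq$supplies$demand_t[src_row] <- d_src
  eq$efa <- list(
    mode = mode, fraction = scenario$efa_fraction,
    n_pixels = length(efa_ids), pixel_ids = efa_ids,
    supply_t = efa_supply
  )
  eq
}
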