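test_that("net profit follows the revenue-minus-cost arithmetic", {
  ag <- toy_agents(yield_src = 10, yield_annual = 6, dist_km = 20)
  costs <- cost_table(production_src = 500, production_annual = 800,
                      transport_rate = 0.5, fallow_payment = 120)
  mkt <- market_state(price_src = 80, price_annual = 150)
  # 80*10 - 500 - 0.5*10*20
  expect_equal(net_profit(ag, "SRC", mkt, costs), 200)
  expect_equal(net_profit(ag, "ANNUAL", mkt, costs), 150 * 6 - 800)
  expect_equal(net_profit(ag, "FALLOW", mkt, costs), 120)

  zero <- market_state(0, 0)
  free_fallow <- cost_table(production_src = 500, production_annual = 800,
                            transport_rate = 0.5, fallow_payment = 0)
  profits <- c(
    net_profit(ag, "SRC", zero, free_fallow),
    net_profit(ag, "ANNUAL", zero, free_fallow),
    net_profit(ag, "FALLOW", zero, free_fallow)
  )
  expect_equal(profits[1:2], c(-600, -800))
  expect_true(all(profits[3] >= profits[1:2]))  # fallow weakly best

  doubled <- market_state(price_src = 160, price_annual = 150)
  expect_gt(net_profit(ag, "SRC", doubled, costs),
            net_profit(ag, "SRC", mkt, costs))
})

test_that("agents without a reachable plant cannot grow SRC", {
  ag <- toy_agents(10, 6, dist_km = 5)
  attr(ag, "dist_matrix") <- matrix(numeric(), nrow = 1, ncol = 0)
  ag$dist_km <- Inf
  ag$nearest_plant <- NA_integer_
  expect_equal(net_profit(ag, "SRC", market_state(100, 100), cost_table()),
               -Inf)
  br <- best_response(ag, market_state(1e6, 0), cost_table())
  expect_false(br$option == "SRC")
})

test_that("plant choice minimises transport regionally, maximises margin locally", {
  ag <- toy_agents(10, 6, dist_km = 5)
  attr(ag, "dist_matrix") <- matrix(c(5, 9), nrow = 1)
  costs <- cost_table(transport_rate = 1)
  expect_equal(choose_plant(ag, market_state(price_mode = "regional"), costs),
               1L)
  # local prices (70, 90), per-tonne transport (2, 30): 68 beats 60
  attr(ag, "dist_matrix") <- matrix(c(2, 30), nrow = 1)
  mkt <- market_state(price_mode = "local", plant_prices = c(70, 90))
  expect_equal(choose_plant(ag, mkt, costs), 1L)
  single <- toy_agents(10, 6, dist_km = 3)
  expect_equal(choose_plant(single, market_state(), costs), 1L)
})

test_that("best response equals the brute-force argmax on random agents", {
  set.seed(11)
  n <- 1000
  ag <- toy_agents(
    yield_src = runif(n, 2, 14),
    yield_annual = runif(n, 1, 12),
    dist_km = runif(n, 0, 40)
  )
  costs <- cost_table(production_src = 300, production_annual = 900,
                      transport_rate = 0.4, fallow_payment = 150)
  mkt <- market_state(price_src = runif(1, 40, 120),
                      price_annual = runif(1, 100, 250))
  br <- best_response(ag, mkt, costs)
  # independent enumeration oracle
  ps <- mkt$price_src * ag$yield_src - 300 - 0.4 * ag$yield_src * ag$dist_km
  pa <- mkt$price_annual * ag$yield_annual - 900
  pf <- rep(150, n)
  oracle <- ifelse(pa >= pmax(ps, pf), "ANNUAL",
                   ifelse(ps >= pf, "SRC", "FALLOW"))
  expect_identical(br$option, oracle)
  expect_equal(br$profit, pmax(ps, pa, pf))
})

test_that("exact ties resolve to ANNUAL by the documented rule", {
  ag <- toy_agents(10, 5, dist_km = 0)
  costs <- cost_table(production_src = 0, production_annual = 0,
                      transport_rate = 0, fallow_payment = 0)
  # price_src*10 == price_annual*5
  mkt <- market_state(price_src = 50, price_annual = 100)
  expect_equal(best_response(ag, mkt, costs)$option, "ANNUAL")
})

test_that("supply aggregates yields over areas and conserves across plants", {
  ag <- toy_agents(rep(8, 6), rep(5, 6), dist_km = rep(1, 6))
  attr(ag, "dist_matrix") <- cbind(c(1, 1, 9, 9, 1, 9), c(9, 9, 1, 1, 9, 1))
  mkt <- market_state(price_src = 500, price_annual = 0, price_mode = "local",
                      plant_prices = c(500, 500))
  br <- best_response(ag, mkt, cost_table(fallow_payment = 0))
  br$option[5:6] <- "FALLOW"  # keep a mixed decision set
  br$option[4] <- "ANNUAL"
  s <- aggregate_supply(br, by_plant = TRUE)
  expect_equal(s$supply_t[s$commodity == "src"], 3 * 8 * 25)
  expect_equal(s$supply_t[s$commodity == "annual"], 5 * 25)
  per_plant <- attr(s, "plant_supply")
  expect_equal(sum(per_plant$supply_t), s$supply_t[s$commodity == "src"])

  none <- aggregate_supply(br[br$option == "SRC" & FALSE, ], cell_area = 25)
  expect_equal(none$supply_t, c(0, 0))
})

test_that("zero SRC demand leaves the baseline crop/fallow split", {
  ls <- cached_landscape(n = 30, seed = 2)
  ag <- build_agents(ls)
  cal <- calibrate_annual_demand(ag)
  sc <- scenario_config(demand_annual = cal$demand_annual,
                        demand_multiplier = 0)
  eq <- clear_market(ag, sc, plants = ls$plants)
  expect_equal(sum(eq$decisions$option == "SRC"), 0)
  expect_equal(eq$price_src, 0)
  expect_setequal(unique(eq$decisions$option), c("ANNUAL", "FALLOW"))
})

test_that("a two-agent market clears between the reservation prices", {
  # yields 10 and 5 t/ha on 25 ha; alternatives worth 0, SRC cost 100/ha:
  # reservation prices are 10 and 20 EUR/t
  ag <- toy_agents(c(10, 5), c(0.01, 0.01), dist_km = c(0, 0))
  costs <- cost_table(production_src = 100, production_annual = 0,
                      transport_rate = 0, fallow_payment = 0,
                      production_fallow = 0)
  sc <- scenario_config(demand_annual = 0)
  eq <- clear_market(ag, sc, costs, demand_src = 250, demand_annual = 0)
  expect_gte(eq$price_src, 10)
  expect_lt(eq$price_src, 20)
  expect_equal(eq$decisions$option[1], "SRC")
  expect_false(eq$decisions$option[2] == "SRC")
  s <- eq$supplies
  expect_lte(abs(s$supply_t[s$commodity == "src"] - 250), 0.01 * 250)
})

test_that("market clearing is deterministic and epsilon-stable", {
  ls <- cached_landscape(n = 30, seed = 5)
  ag <- build_agents(ls)
  cal <- calibrate_annual_demand(ag)
  sc <- scenario_config(demand_annual = cal$demand_annual)
  eq1 <- clear_market(ag, sc, plants = ls$plants)
  eq2 <- clear_market(ag, sc, plants = ls$plants)
  expect_identical(eq1$price_src, eq2$price_src)
  expect_identical(eq1$decisions$option, eq2$decisions$option)
  expect_lte(equilibrium_stability(eq1), 1e-8)
})

test_that("equilibrium SRC area grows with the demand multiplier", {
  for (s in c(3, 8)) {
    ls <- cached_landscape(n = 30, seed = s, n_plants = 6, capacity = 3000)
    ag <- build_agents(ls)
    cal <- calibrate_annual_demand(ag)
    n_src <- vapply(c(1, 2, 4), function(m) {
      sc <- scenario_config(demand_annual = cal$demand_annual,
                            demand_multiplier = m)
      eq <- clear_market(ag, sc, plants = ls$plants)
      sum(eq$decisions$option == "SRC")
    }, 0L)
    expect_true(all(diff(n_src) >= 0))
  }
})

test_that("infeasible step granularity fails loudly with a trajectory", {
  ag <- toy_agents(c(10, 10), c(0.01, 0.01), dist_km = c(0, 0))
  costs <- cost_table(production_src = 100, production_annual = 0,
                      transport_rate = 0, fallow_payment = 0)
  err <- tryCatch(
    clear_market(ag, scenario_config(demand_annual = 0), costs,
                 demand_src = 375, demand_annual = 0),
    error = function(e) e
  )
  expect_s3_class(err, "srcscape_market_error")
  expect_true(!is.null(err$trajectory))
})

test_that("local price mode conserves supply and clears per plant", {
  ls <- cached_landscape(n = 30, seed = 7, n_plants = 3, capacity = 2500)
  ag <- build_agents(ls)
  cal <- calibrate_annual_demand(ag)
  sc <- scenario_config(price_mode = "local",
                        demand_annual = cal$demand_annual, tol = 0.05)
  eq <- clear_market(ag, sc, plants = ls$plants)
  expect_equal(sum(eq$plant_prices$supply_t),
               eq$supplies$supply_t[eq$supplies$commodity == "src"])
  expect_true(all(eq$plant_prices$price >= 0))
  expect_lte(equilibrium_stability(eq), 1e-8)
})

test_that("annual demand calibration recovers a known demand within 1%", {
  ls <- cached_landscape(n = 30, seed = 4)
  ag <- build_agents(ls)
  base <- calibrate_annual_demand(ag)
  d_star <- base$demand_annual
  eq <- clear_market(ag, scenario_config(demand_annual = d_star),
                     demand_src = 0)
  target <- mean(eq$decisions$option == "ANNUAL")
  cal <- calibrate_annual_demand(
    ag, target_shares = c(annual = target, fallow = 1 - target)
  )
  expect_lte(abs(cal$demand_annual - d_star), 0.01 * d_star)
  expect_lte(abs(cal$achieved_share - target), 0.01)

  expect_equal(calibrate_annual_demand(
    ag, target_shares = c(annual = 0, fallow = 1)
  )$demand_annual, 0)
  expect_error(
    calibrate_annual_demand(ag, target_shares = c(annual = 1, fallow = 0.5)),
    "sum to <= 1"
  )
})

test_that("EFA selection sorts by soil quality with deterministic ties", {
  ag <- toy_agents(rep(8, 10), rep(6, 10), dist_km = rep(1, 10),
                   sqi = c(55, 30, 70, 20, 90, 40, 80, 60, 50, 10))
  expect_equal(efa_selection(ag, 0.3, "bad_soils"), c(10L, 4L, 2L))
  expect_equal(efa_selection(ag, 0.3, "good_soils"), c(5L, 7L, 3L))
  expect_equal(efa_selection(ag, 0, "bad_soils"), integer())
  ties <- toy_agents(rep(8, 4), rep(6, 4), rep(1, 4), sqi = c(5, 5, 5, 5))
  expect_equal(efa_selection(ties, 0.5, "bad_soils"), c(1L, 2L))
})

test_that("EFA allocation converts the mandated share and feeds the market", {
  ls <- cached_landscape(n = 30, seed = 6)
  ag <- build_agents(ls)
  cal <- calibrate_annual_demand(ag)
  sc <- scenario_config(policy = "efa_bad_soils",
                        demand_annual = cal$demand_annual)
  eq <- allocate_efa(ag, sc, plants = ls$plants)
  n_efa <- ceiling(efa_fraction_cap() * nrow(ag))
  expect_equal(sum(eq$decisions$forced), n_efa)
  expect_equal(sum(eq$decisions$option == "SRC"), n_efa)
  forced_sqi <- eq$decisions$sqi[eq$decisions$forced]
  free_sqi <- eq$decisions$sqi[!eq$decisions$forced]
  expect_lte(max(forced_sqi), min(free_sqi) + 1e-9)

  # fraction 0 reduces to the plain market outcome
  sc0 <- sc
  sc0$efa_fraction <- 0
  eq0 <- allocate_efa(ag, sc0, plants = ls$plants)
  plain <- clear_market(ag, scenario_config(
    demand_annual = cal$demand_annual
  ), plants = ls$plants)
  expect_identical(eq0$decisions$option, plain$decisions$option)
})
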