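test_that("carbon storage sums pool densities over areas", {
  pools <- carbon_pool_table()
  d_crop <- pools$total[pools$landuse == "cropland"]
  d_src <- pools$total[pools$landuse == "SRC"]
  uniform <- tibble::tibble(landuse = rep("cropland", 12))
  out <- carbon_storage(uniform, pools, cell_area = 25)
  expect_equal(sum(out$carbon_t), 12 * d_crop * 25)

  flipped <- uniform
  flipped$landuse[1] <- "SRC"
  out2 <- carbon_storage(flipped, pools, cell_area = 25)
  expect_equal(sum(out2$carbon_t) - sum(out$carbon_t), (d_src - d_crop) * 25)

  # randomized map against a per-class histogram oracle
  set.seed(8)
  rand <- tibble::tibble(landuse = sample(lulc_levels(), 300, replace = TRUE))
  out3 <- carbon_storage(rand, pools, cell_area = 4)
  oracle <- sum(table(rand$landuse)[pools$landuse] * pools$total * 4,
                na.rm = TRUE)
  expect_equal(sum(out3$carbon_t), oracle)
  expect_error(carbon_storage(tibble::tibble(landuse = "moon")), "missing")
})

test_that("flow on an inclined plane runs one way and graphs stay acyclic", {
  z <- t(matrix(rep(1:10 * 5, 8), 10, 8))  # rises east, drains west
  fg <- build_flow_graph(z, cell_size = 100)
  nr <- 8
  interior <- which(rep(1:10, each = nr) > 1)
  # every non-west-edge cell drains exactly one row-block west
  expect_true(all(fg$downstream[interior] == interior - nr))
  expect_true(all(is.na(fg$downstream[1:nr])))

  set.seed(3)
  zr <- matrix(runif(400, 0, 50), 20, 20)
  fgr <- build_flow_graph(zr, cell_size = 100)
  for (start in c(1, 57, 200, 400)) {
    i <- start
    for (hop in 1:401) {
      i <- fgr$downstream[i]
      if (is.na(i)) break
    }
    expect_true(is.na(i))  # every path leaves the grid without cycling
  }
})

test_that("a V-valley funnels flow to the valley line", {
  # valley along column 3, tilted south
  z <- outer(5:1 * 0.1, abs(1:5 - 3) * 10, "+")
  fg <- build_flow_graph(z, cell_size = 100)
  nr <- 5
  idx <- function(r, c) (c - 1) * nr + r
  # side cells flow into the valley column (steeper than the diagonal)
  expect_equal(fg$downstream[idx(2, 2)], idx(2, 3))
  expect_equal(fg$downstream[idx(2, 4)], idx(2, 3))
  # valley cells flow straight south
  expect_equal(fg$downstream[idx(2, 3)], idx(3, 3))
  expect_equal(fg$downstream[idx(4, 3)], idx(5, 3))
  expect_true(is.na(fg$downstream[idx(5, 3)]))
})

test_that("closed depressions are filled before routing", {
  z <- matrix(10, 7, 7)
  z[4, 4] <- 1   # pit
  fg <- build_flow_graph(z, cell_size = 100)
  expect_gte(fg$filled[4, 4], 10)
  # the pit cell now drains somewhere
  i <- (4 - 1) * 7 + 4
  for (hop in 1:50) {
    i <- fg$downstream[i]
    if (is.na(i)) break
  }
  expect_true(is.na(i))
})

test_that("phosphorus routing matches the hand path oracle and balances", {
  # 1x3 strip falling west->east: cell1 -> cell2 -> cell3 -> off-grid
  z <- matrix(c(3, 2, 1), 1, 3)
  fg <- build_flow_graph(z, cell_size = 100)
  params <- nutrient_param_table(tibble::tibble(
    landuse = c("cropland", "forest", "water"),
    export_coeff = c(10, 0, 0),
    filter_eff = c(0, 0.4, 0)
  ))
  data <- tibble::tibble(landuse = c("cropland", "forest", "water"))
  out <- p_export(data, fg, params, cell_area = 1)
  expect_equal(out$p_retained_kg, c(0, 4, 0))
  expect_equal(sum(out$p_exported_kg), 6)
  expect_equal(out$p_exported_kg[1], 6)  # attributed to the emitting pixel

  # zero efficiencies: everything exports, nothing retained
  p0 <- nutrient_param_table(tibble::tibble(
    landuse = c("cropland", "forest", "water"),
    export_coeff = c(10, 2, 1), filter_eff = c(0, 0, 0)
  ))
  out0 <- p_export(data, fg, p0, cell_area = 1)
  expect_equal(sum(out0$p_exported_kg), 13)
  expect_equal(sum(out0$p_retained_kg), 0)
})

test_that("mass balance holds on full landscapes", {
  for (s in c(1, 9)) {
    ls <- cached_landscape(n = 25, seed = s)
    stack <- compute_ess_stack(ls)
    pp <- stack$per_pixel
    p_in <- sum(pp$p_emitted_kg)
    expect_lt(abs(p_in - sum(pp$p_exported_kg) - sum(pp$p_retained_kg)),
              1e-6 * p_in)
    s_in <- sum(pp$sed_generated_t)
    expect_lt(abs(s_in - sum(pp$sed_exported_t) - sum(pp$sed_trapped_t)),
              1e-6 * s_in)
  }
})

test_that("improving a downstream filter never raises watershed export", {
  ls <- cached_landscape(n = 20, seed = 2)
  lu <- ls$pixels$lulc
  flow <- build_flow_graph(matrix(ls$pixels$elevation, 20, 20),
                           ls$grid$cell_size)
  base <- p_export(dplyr::mutate(ls$pixels, landuse = lu), flow,
                   cell_area = 25)
  crop_idx <- which(lu == "cropland")[1:10]
  for (i in crop_idx) {
    lu2 <- lu
    lu2[i] <- "forest"
    out <- p_export(dplyr::mutate(ls$pixels, landuse = lu2), flow,
                    cell_area = 25)
    expect_lte(sum(out$p_exported_kg), sum(base$p_exported_kg) + 1e-9)
  }
})

test_that("USLE factors behave linearly and LS matches the formula", {
  expect_equal(usle_soil_loss(60, 0.3, 9, c_factor = 0, p_factor = 1), 0)
  a1 <- usle_soil_loss(60, 0.3, 9, 0.2, 1)
  expect_equal(usle_soil_loss(60, 0.6, 9, 0.2, 1), 2 * a1)
  expect_equal(usle_soil_loss(120, 0.3, 9, 0.2, 1), 2 * a1)
  # 9% slope at the 22.13 m reference length
  expect_equal(ls_factor(9, 22.13), 0.065 + 0.0456 * 9 + 0.00654 * 81,
               tolerance = 1e-12)
  expect_equal(ls_factor(9, 4 * 22.13), 2 * ls_factor(9, 22.13))
  expect_error(ls_factor(-1), ">= 0")
})

test_that("sediment routing matches the trap oracles and balances", {
  z <- matrix(c(3, 2, 1), 1, 3)
  fg <- build_flow_graph(z, cell_size = 100)
  base <- tibble::tibble(
    landuse = c("cropland", "cropland", "cropland"),
    slope = c(9, 9, 9), erosivity_r = 60, erodibility_k = 0.3
  )
  open <- usle_param_table(tibble::tibble(
    landuse = "cropland", c_factor = 0.2, p_factor = 1, trap_eff = 0
  ))
  out <- sediment_export(base, fg, open, cell_area = 1)
  expect_equal(sum(out$sed_exported_t), sum(out$sed_generated_t))

  full <- usle_param_table(tibble::tibble(
    landuse = "cropland", c_factor = 0.2, p_factor = 1, trap_eff = 1
  ))
  out2 <- sediment_export(base, fg, full, cell_area = 1)
  # all upstream load is trapped; only the outlet's own generation leaves
  expect_equal(sum(out2$sed_exported_t), out2$sed_generated_t[3])
  expect_equal(out2$sed_trapped_t[2], out2$sed_generated_t[1])
  expect_equal(sum(out2$sed_generated_t),
               sum(out2$sed_exported_t) + sum(out2$sed_trapped_t))
  # retention includes the avoided on-pixel erosion
  expect_equal(out2$sed_retained_t[1],
               60 * 0.3 * ls_factor(9) * (1 - 0.2) + out2$sed_trapped_t[1])
})

test_that("MSA multiplies pressures and respects its bounds", {
  no_impact <- tibble::tibble(
    landuse = c("forest", "SRC", "cropland"),
    patch_area_ha = c(1e6, NA, NA),
    dist_infra_km = 10, pop_density = 0, ndep_exceedance = -5
  )
  out <- msa(no_impact)
  expect_equal(out$msa, c(1, 0.2, 0.1))

  set.seed(21)
  pressured <- no_impact[rep(1:3, 30), ]
  pressured$patch_area_ha <- ifelse(pressured$landuse == "forest",
                                    runif(90, 1, 5000), NA)
  pressured$dist_infra_km <- runif(90, 0, 10)
  pressured$pop_density <- runif(90, 0, 2000)
  pressured$ndep_exceedance <- runif(90, -5, 30)
  stressed <- msa(pressured)
  expect_true(all(stressed$msa <= rep(out$msa, 30) + 1e-12))
  expect_true(all(stressed$msa >= 0 & stressed$msa <= 1))
  factors <- as.matrix(stressed[, c("msa_lu", "msa_f", "msa_i", "msa_p",
                                    "msa_n")])
  expect_true(all(abs(apply(factors, 1, prod) - stressed$msa) < 1e-12))
  expect_true(all(stressed$msa <= apply(factors, 1, min) + 1e-12))
})

test_that("patch areas come from 4-neighbour connected components", {
  g <- grid_spec(6, 6, cell_size = 500)
  lu <- matrix("cropland", 6, 6)
  lu[3, 3] <- "forest"
  px <- pixels_from_matrix(lu, g)
  out <- patch_sizes(px, g)
  expect_equal(out$patch_area_ha[out$landuse == "forest"], 25)
  expect_true(all(is.na(out$patch_area_ha[out$landuse == "cropland"])))

  checker <- matrix(ifelse(outer(1:6, 1:6, "+") %% 2 == 0,
                           "forest", "water"), 6, 6)
  outc <- patch_sizes(pixels_from_matrix(checker, g), g,
                      natural_classes = "forest")
  expect_true(all(outc$patch_area_ha[outc$landuse == "forest"] == 25))

  # random map against an igraph connected-components oracle
  set.seed(5)
  rand <- matrix(sample(c("forest", "grassland", "urban"), 144, TRUE), 12, 12)
  gr <- grid_spec(12, 12, cell_size = 500)
  got <- patch_sizes(pixels_from_matrix(rand, gr), gr)
  idx <- matrix(seq_len(144), 12, 12)
  edges <- NULL
  for (r in 1:12) for (cc in 1:12) {
    if (r < 12 && rand[r, cc] == rand[r + 1, cc]) {
      edges <- rbind(edges, c(idx[r, cc], idx[r + 1, cc]))
    }
    if (cc < 12 && rand[r, cc] == rand[r, cc + 1]) {
      edges <- rbind(edges, c(idx[r, cc], idx[r, cc + 1]))
    }
  }
  gg <- igraph::graph_from_edgelist(edges, directed = FALSE)
  gg <- igraph::add_vertices(gg, 144 - igraph::vcount(gg))
  comp <- igraph::components(gg)
  oracle_cells <- comp$csize[comp$membership]
  natural <- as.vector(rand) %in% c("forest", "grassland")
  expect_equal(got$patch_area_ha[natural], oracle_cells[natural] * 25)
})

test_that("infrastructure distance finds the nearest urban cell", {
  g <- grid_spec(5, 5, cell_size = 1000)
  lu <- matrix("cropland", 5, 5)
  lu[1, 1] <- "urban"
  px <- pixels_from_matrix(lu, g)
  out <- infrastructure_distance(px)
  expect_equal(out$dist_infra_km[out$landuse == "urban"], 0)
  far <- out[out$row == 5 & out$col == 5, ]
  expect_equal(far$dist_infra_km, sqrt(32), tolerance = 1e-9)
  empty <- infrastructure_distance(pixels_from_matrix(
    matrix("cropland", 3, 3), grid_spec(3, 3)
  ))
  expect_true(all(is.infinite(empty$dist_infra_km)))
})

test_that("converting cropland to SRC moves every service the right way", {
  ls <- cached_landscape(n = 25, seed = 3)
  base <- compute_ess_stack(ls)
  ag <- build_agents(ls)
  worst <- efa_selection(ag, 0.15, "bad_soils")
  lu <- as.character(ls$pixels$lulc)
  lu[ls$pixels$pixel_id %in% worst] <- "SRC"
  conv <- compute_ess_stack(ls, landuse = lu, flow = base$flow)
  val <- function(st, s) st$totals$value[st$totals$service == s]
  expect_gte(val(conv, "msa"), val(base, "msa"))
  expect_gte(val(conv, "carbon"), val(base, "carbon"))
  expect_lte(val(conv, "p_export"), val(base, "p_export"))
  expect_lte(val(conv, "sediment_export"), val(base, "sediment_export"))
})
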