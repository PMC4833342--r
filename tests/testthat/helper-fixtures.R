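# shared fixtures, generated in code and cached per session

cached_landscape <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 30, seed = 1, n_plants = 6, capacity = 2000,
           params = synthesis_params()) {
    key <- paste(n, seed, n_plants, capacity,
                 digest_params(params), sep = "|")
    if (is.null(cache[[key]])) {
      ls <- generate_landscape(grid_spec(n, n), params, seed = seed)
      cache[[key]] <- place_chp_plants(ls, n_plants, capacity, seed = seed)
    }
    cache[[key]]
  }
})

digest_params <- function(p) {
  paste(vapply(p[order(names(p))], function(x) paste(format(x), collapse = ","), ""),
        collapse = ";")
}

# hand-built agent table for market unit tests
toy_agents <- function(yield_src, yield_annual, dist_km,
                       sqi = NULL, cell_area = 25) {
  n <- length(yield_src)
  ag <- tibble::tibble(
    pixel_id = seq_len(n), row = 1L, col = seq_len(n),
    x = as.numeric(seq_len(n)), y = 0,
    sqi = if (is.null(sqi)) rep(50, n) else sqi,
    yield_src = yield_src, yield_annual = yield_annual,
    dist_km = dist_km, nearest_plant = 1L, district_id = 1L
  )
  attr(ag, "dist_matrix") <- matrix(dist_km, ncol = 1)
  attr(ag, "cell_area_ha") <- cell_area
  ag
}

# rook-neighbour Moran's I, written independently of the package
morans_i <- function(m) {
  z <- m - mean(m)
  num <- sum(z[-1, ] * z[-nrow(m), ]) + sum(z[, -1] * z[, -ncol(m)])
  w <- (nrow(m) - 1) * ncol(m) + nrow(m) * (ncol(m) - 1)
  (length(m) / (2 * w)) * (2 * num) / sum(z^2)
}

# independent Horn-stencil slope oracle (interior cells only)
slope_oracle <- function(z, cell) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  for (r in 2:(nr - 1)) {
    for (cc in 2:(nc - 1)) {
      p <- ((z[r - 1, cc + 1] + 2 * z[r, cc + 1] + z[r + 1, cc + 1]) -
              (z[r - 1, cc - 1] + 2 * z[r, cc - 1] + z[r + 1, cc - 1])) /
        (8 * cell)
      q <- ((z[r - 1, cc - 1] + 2 * z[r - 1, cc] + z[r - 1, cc + 1]) -
              (z[r + 1, cc - 1] + 2 * z[r + 1, cc] + z[r + 1, cc + 1])) /
        (8 * cell)
      out[r, cc] <- 100 * sqrt(p^2 + q^2)
    }
  }
  out
}

# pixel tibble on a grid from a land-use matrix plus optional layers
pixels_from_matrix <- function(lu_matrix, grid, ...) {
  px <- srcscape:::grid_coords(grid)
  px$landuse <- factor(as.vector(lu_matrix), levels = lulc_levels())
  extra <- list(...)
  for (nm in names(extra)) px[[nm]] <- as.vector(extra[[nm]])
  px
}
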