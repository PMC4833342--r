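# D8 flow routing: priority-flood sink filling, steepest-descent downstream
# assignment, and multiplicative load attenuation along flow paths

# binary min-heap keyed on (value, index); scalar ops only, O(n log n)
heap_new <- function(n) {
  env <- new.env(parent = emptyenv())
  env$val <- numeric(n)
  env$idx <- integer(n)
  env$size <- 0L
  env
}

heap_push <- function(h, value, index) {
  h$size <- h$size + 1L
  i <- h$size
  h$val[i] <- value
  h$idx[i] <- index
  while (i > 1L) {
    p <- i %/% 2L
    if (h$val[p] > h$val[i] ||
        (h$val[p] == h$val[i] && h$idx[p] > h$idx[i])) {
      tv <- h$val[p]; h$val[p] <- h$val[i]; h$val[i] <- tv
      ti <- h$idx[p]; h$idx[p] <- h$idx[i]; h$idx[i] <- ti
      i <- p
    } else {
      break
    }
  }
}

heap_pop <- function(h) {
  out <- c(h$val[1], h$idx[1])
  h$val[1] <- h$val[h$size]
  h$idx[1] <- h$idx[h$size]
  h$size <- h$size - 1L
  i <- 1L
  repeat {
    l <- 2L * i
    r <- l + 1L
    smallest <- i
    if (l <= h$size &&
        (h$val[l] < h$val[smallest] ||
           (h$val[l] == h$val[smallest] && h$idx[l] < h$idx[smallest]))) {
      smallest <- l
    }
    if (r <= h$size &&
        (h$val[r] < h$val[smallest] ||
           (h$val[r] == h$val[smallest] && h$idx[r] < h$idx[smallest]))) {
      smallest <- r
    }
    if (smallest == i) break
    tv <- h$val[i]; h$val[i] <- h$val[smallest]; h$val[smallest] <- tv
    ti <- h$idx[i]; h$idx[i] <- h$idx[smallest]; h$idx[smallest] <- ti
    i <- smallest
  }
  out
}

# D8 neighbour offsets in the fixed tie-break order N, NE, E, SE, S, SW, W,
# NW (row offset, col offset)
d8_offsets <- function() {
  list(dr = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
       dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))
}

# priority-flood depression filling with a tiny epsilon gradient so every
# interior cell keeps a strictly lower neighbour
fill_sinks <- function(z, eps = 1e-6) {
  nr <- nrow(z)
  nc <- ncol(z)
  n <- nr * nc
  filled <- rep(NA_real_, n)
  seen <- rep(FALSE, n)
  h <- heap_new(n)
  off <- d8_offsets()
  zv <- as.vector(z)
  border <- unique(c(
    seq_len(nr), n - nr + seq_len(nr),
    (seq_len(nc) - 1L) * nr + 1L, seq_len(nc) * nr
  ))
  for (i in border) {
    heap_push(h, zv[i], i)
    seen[i] <- TRUE
    filled[i] <- zv[i]
  }
  while (h$size > 0L) {
    top <- heap_pop(h)
    v <- top[1]
    i <- as.integer(top[2])
    r <- ((i - 1L) %% nr) + 1L
    cc <- ((i - 1L) %/% nr) + 1L
    for (k in 1:8) {
      rr <- r + off$dr[k]
      ccc <- cc + off$dc[k]
      if (rr < 1L || rr > nr || ccc < 1L || ccc > nc) next
      j <- (ccc - 1L) * nr + rr
      if (seen[j]) next
      seen[j] <- TRUE
      filled[j] <- max(zv[j], v + eps)
      heap_push(h, filled[j], j)
    }
  }
  matrix(filled, nr, nc)
}

#' Build a D8 flow graph from an elevation raster
#'
#' Fills closed depressions (priority flood with an epsilon gradient), then
#' assigns every cell the single steepest-descent neighbour of the eight
#' (diagonal distances scaled by sqrt(2)); gradient ties break on the fixed
#' neighbour order N, NE, E, SE, S, SW, W, NW. Cells without a lower
#' neighbour (necessarily on the grid border after filling) are outlets and
#' drain off-grid. The result is acyclic by construction.
#'
#' @param elevation Elevation matrix (m).
#' @param cell_size Cell side (m).
#' @return A `flow_graph`: list with `downstream` (column-major index of the
#'   receiving cell, `NA` at outlets), `order` (indices sorted so every cell
#'   precedes its downstream cell), `filled` elevations, and the grid shape.
#' @export
build_flow_graph <- function(elevation, cell_size = 500) {
  if (!is.matrix(elevation) || any(!is.finite(elevation))) {
    abort("`elevation` must be a finite numeric matrix.")
  }
  nr <- nrow(elevation)
  nc <- ncol(elevation)
  filled <- fill_sinks(elevation)
  off <- d8_offsets()
  dist <- ifelse(off$dr != 0L & off$dc != 0L, sqrt(2), 1) * cell_size
  n <- nr * nc
  best_grad <- rep(0, n)
  downstream <- rep(NA_integer_, n)
  fv <- as.vector(filled)
  rows <- rep(seq_len(nr), nc)
  cols <- rep(seq_len(nc), each = nr)
  for (k in 1:8) {
    rr <- rows + off$dr[k]
    cc <- cols + off$dc[k]
    valid <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    j <- (cc - 1L) * nr + rr
    grad <- rep(-Inf, n)
    grad[valid] <- (fv[valid] - fv[j[valid]]) / dist[k]
    better <- valid & grad > best_grad  # strict: earlier directions win ties
    downstream[better] <- j[better]
    best_grad[better] <- grad[better]
  }
  structure(
    list(
      downstream = downstream,
      order = order(fv, seq_len(n), decreasing = c(TRUE, FALSE),
                    method = "radix"),
      filled = filled, n_rows = nr, n_cols = nc, cell_size = cell_size
    ),
    class = "flow_graph"
  )
}

# route per-pixel emissions downstream; a pixel keeps `eff` of every load
# entering it from upstream (its own emission is not self-filtered).
# Returns the load retained at each pixel, each pixel's source-attributed
# export (the part of its own emission reaching an outlet), and the total
# outlet export. Conserves mass: sum(emission) = export + sum(retained).
route_loads <- function(flow, emission, eff) {
  n <- length(flow$downstream)
  stopifnot(length(emission) == n, length(eff) == n)
  inflow <- rep(0, n)
  retained <- rep(0, n)
  outlet_export <- 0
  down <- flow$downstream
  for (i in flow$order) {
    ret <- inflow[i] * eff[i]
    retained[i] <- ret
    out <- emission[i] + inflow[i] - ret
    d <- down[i]
    if (is.na(d)) {
      outlet_export <- outlet_export + out
    } else {
      inflow[d] <- inflow[d] + out
    }
  }
  # attenuation to outlet, walked from low to high ground
  atten <- rep(NA_real_, n)
  for (i in rev(flow$order)) {
    d <- down[i]
    atten[i] <- if (is.na(d)) 1 else (1 - eff[d]) * atten[d]
  }
  list(
    retained = retained,
    export_source = emission * atten,
    outlet_export = outlet_export,
    attenuation = atten
  )
}

#' Phosphorus export and retention with flow routing
#'
#' Every pixel emits its class export coefficient times its area; the load
#' is routed along the D8 flow graph and attenuated multiplicatively by the
#' filtering efficiency of each downstream pixel it traverses. Export is
#' attributed to the emitting pixel (the share of its emission reaching an
#' outlet); retention is credited to the filtering pixel. Mass balance
#' holds: emitted = exported + retained.
#'
#' @param data Pixel data frame (column-major grid order) with a `landuse`
#'   column.
#' @param flow A [build_flow_graph()] result on the same grid.
#' @param params A [nutrient_param_table()].
#' @param cell_area Cell area (ha).
#' @return `data` with `p_emitted_kg`, `p_exported_kg`, `p_retained_kg`.
#' @export
p_export <- function(data, flow, params = nutrient_param_table(),
                     cell_area = 25) {
  out <- as_tibble(data)
  if (nrow(out) != length(flow$downstream)) {
    abort("`data` and `flow` describe different grids.")
  }
  emission <- join_class_param(out$landuse, params, "export_coeff") * cell_area
  eff <- join_class_param(out$landuse, params, "filter_eff")
  r <- route_loads(flow, emission, eff)
  out$p_emitted_kg <- emission
  out$p_exported_kg <- r$export_source
  out$p_retained_kg <- r$retained
  out
}

# slope-length exponent of the classic USLE LS relation
ls_exponent <- function(slope_pct) {
  ifelse(slope_pct >= 5, 0.5,
         ifelse(slope_pct >= 3, 0.4,
                ifelse(slope_pct >= 1, 0.3, 0.2)))
}

#' USLE LS topographic factor
#'
#' `LS = (L / 22.13)^m * (0.065 + 0.0456 s + 0.00654 s^2)` with slope `s`
#' in percent and the exponent `m` stepping with slope class; at the 22.13 m
#' reference length the length term is 1.
#'
#' @param slope_pct Slope in percent.
#' @param slope_length Slope length (m).
#' @return LS factor (dimensionless).
#' @export
ls_factor <- function(slope_pct, slope_length = 22.13) {
  if (any(slope_pct < 0)) abort("`slope_pct` must be >= 0.")
  (slope_length / 22.13)^ls_exponent(slope_pct) *
    (0.065 + 0.0456 * slope_pct + 0.00654 * slope_pct^2)
}

#' Potential soil loss by the universal soil loss equation
#'
#' `A = R * K * LS * C * P` in t/ha/a.
#'
#' @param erosivity_r Rainfall erosivity R (MJ mm / (ha h a)).
#' @param erodibility_k Soil erodibility K (t ha h / (ha MJ mm)).
#' @param slope_pct Slope (percent).
#' @param c_factor,p_factor Cover-management and support-practice factors.
#' @param slope_length Slope length (m), fixed at the USLE reference plot
#'   length by default.
#' @return Soil loss (t/ha/a), vectorised.
#' @export
usle_soil_loss <- function(erosivity_r, erodibility_k, slope_pct,
                           c_factor, p_factor, slope_length = 22.13) {
  erosivity_r * erodibility_k * ls_factor(slope_pct, slope_length) *
    c_factor * p_factor
}

#' Sediment export and retention with flow routing
#'
#' Each pixel generates USLE soil loss under its actual cover; the load is
#' routed downstream and partially trapped by the vegetation of traversed
#' pixels. Retention combines the on-pixel avoided erosion (the USLE loss
#' the cover prevents relative to bare conditions, `R K LS (1 - C P)`) and
#' the trapped upstream sediment. Routed mass balance holds on the
#' generated loads: generated = exported + trapped.
#'
#' @param data Pixel data frame (column-major) with `landuse`, `slope`,
#'   `erosivity_r`, `erodibility_k`.
#' @param flow A [build_flow_graph()] result.
#' @param params A [usle_param_table()].
#' @param cell_area Cell area (ha).
#' @param slope_length USLE slope length (m).
#' @return `data` with `sed_generated_t`, `sed_exported_t`, `sed_trapped_t`,
#'   `sed_retained_t` (avoided + trapped).
#' @export
sediment_export <- function(data, flow, params = usle_param_table(),
                            cell_area = 25, slope_length = 22.13) {
  out <- as_tibble(data)
  if (nrow(out) != length(flow$downstream)) {
    abort("`data` and `flow` describe different grids.")
  }
  cf <- join_class_param(out$landuse, params, "c_factor")
  pf <- join_class_param(out$landuse, params, "p_factor")
  trap <- join_class_param(out$landuse, params, "trap_eff")
  gen <- usle_soil_loss(out$erosivity_r, out$erodibility_k, out$slope,
                        cf, pf, slope_length) * cell_area
  avoided <- out$erosivity_r * out$erodibility_k *
    ls_factor(out$slope, slope_length) * (1 - cf * pf) * cell_area
  r <- route_loads(flow, gen, trap)
  out$sed_generated_t <- gen
  out$sed_exported_t <- r$export_source
  out$sed_trapped_t <- r$retained
  out$sed_retained_t <- avoided + r$retained
  out
}
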