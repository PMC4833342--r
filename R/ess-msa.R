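#' Habitat patch areas
#'
#' Labels 4-neighbour connected components of the natural land-cover
#' classes and assigns every natural pixel the area of its patch;
#' non-natural pixels get `NA`.
#'
#' @param data Pixel data frame in column-major grid order with `landuse`.
#' @param grid The [grid_spec()] of the data.
#' @param natural_classes Classes forming habitat patches.
#' @return `data` with a `patch_area_ha` column.
#' @export
patch_sizes <- function(data, grid,
                        natural_classes = c("forest", "grassland")) {
  out <- as_tibble(data)
  if (nrow(out) != n_cells(grid)) {
    abort("`data` rows must cover the grid in column-major order.")
  }
  cls <- as.character(out$landuse)
  nr <- grid$n_rows
  nc <- grid$n_cols
  label <- rep(NA_integer_, nr * nc)
  patch_cells <- integer()
  next_label <- 0L
  for (start in seq_len(nr * nc)) {
    if (!is.na(label[start]) || !(cls[start] %in% natural_classes)) next
    next_label <- next_label + 1L
    queue <- start
    label[start] <- next_label
    size <- 0L
    while (length(queue)) {
      i <- queue[length(queue)]
      queue <- queue[-length(queue)]
      size <- size + 1L
      r <- ((i - 1L) %% nr) + 1L
      cc <- ((i - 1L) %/% nr) + 1L
      for (k in 1:4) {
        rr <- r + c(-1L, 1L, 0L, 0L)[k]
        ccc <- cc + c(0L, 0L, -1L, 1L)[k]
        if (rr < 1L || rr > nr || ccc < 1L || ccc > nc) next
        j <- (ccc - 1L) * nr + rr
        if (!is.na(label[j]) || cls[j] != cls[start]) next
        label[j] <- next_label
        queue <- c(queue, j)
      }
    }
    patch_cells[next_label] <- size
  }
  out$patch_area_ha <- ifelse(
    is.na(label), NA_real_, patch_cells[label] * cell_area_ha(grid)
  )
  out
}

#' Distance to the nearest infrastructure pixel
#'
#' Euclidean distance (km) from every cell centre to the nearest cell of an
#' infrastructure class (urban fabric by default, standing in for the road
#' and rail network). `Inf` when the landscape has no infrastructure.
#'
#' @param data Pixel data frame with `x`, `y`, `landuse`.
#' @param infra_classes Infrastructure classes.
#' @return `data` with a `dist_infra_km` column.
#' @export
infrastructure_distance <- function(data, infra_classes = "urban") {
  out <- as_tibble(data)
  infra <- out$landuse %in% infra_classes
  if (!any(infra)) {
    out$dist_infra_km <- rep(Inf, nrow(out))
    return(out)
  }
  xi <- out$x[infra]
  yi <- out$y[infra]
  d2 <- rep(Inf, nrow(out))
  # chunked so the n_pixels x n_infra distance matrix stays small
  chunk <- max(1L, floor(2e6 / length(xi)))
  for (s in seq(1L, nrow(out), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(out))
    m <- outer(out$x[s:e], xi, "-")^2 + outer(out$y[s:e], yi, "-")^2
    d2[s:e] <- do.call(pmin, c(asplit(m, 2), list(d2[s:e])))
  }
  out$dist_infra_km <- sqrt(d2) / 1000
  out$dist_infra_km[infra] <- 0
  out
}

#' Mean species abundance under five pressures
#'
#' The pixel MSA is the product of the pressure factors for land use,
#' habitat fragmentation, infrastructure proximity, population density and
#' N-deposition exceedance, each in `[0, 1]`, so the product never exceeds
#' the smallest factor. An undisturbed pixel scores 1; a pixel fully
#' converted to SRC with every other pressure at its no-impact level scores
#' the SRC land-use factor 0.2. The fragmentation factor applies only to
#' the natural (habitat) classes.
#'
#' @param data Pixel data frame with `landuse`, `patch_area_ha`,
#'   `dist_infra_km`, `pop_density` and `ndep_exceedance` columns (missing
#'   pressure columns are treated as no-impact).
#' @param tables [msa_pressure_tables()].
#' @return `data` with the factor columns `msa_lu`, `msa_f`, `msa_i`,
#'   `msa_p`, `msa_n` and their product `msa`.
#' @export
msa <- function(data, tables = msa_pressure_tables()) {
  out <- as_tibble(data)
  lu <- as.character(out$landuse)
  bad <- setdiff(unique(lu), names(tables$msa_lu))
  if (length(bad)) {
    abort(sprintf("No msa_lu factor for class(es): %s.", toString(bad)))
  }
  n <- nrow(out)
  grab <- function(col) if (col %in% names(out)) out[[col]] else rep(NA_real_, n)
  out$msa_lu <- unname(tables$msa_lu[lu])
  frag <- lookup_factor(grab("patch_area_ha"), tables$fragmentation)
  frag[!(lu %in% tables$natural_classes)] <- 1
  out$msa_f <- frag
  di <- grab("dist_infra_km")
  di[is.infinite(di)] <- NA_real_  # no infrastructure anywhere: no impact
  out$msa_i <- lookup_factor(di, tables$infrastructure)
  out$msa_p <- lookup_factor(grab("pop_density"), tables$population)
  out$msa_n <- lookup_factor(grab("ndep_exceedance"), tables$n_deposition)
  out$msa <- out$msa_lu * out$msa_f * out$msa_i * out$msa_p * out$msa_n
  out
}
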