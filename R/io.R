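# plain-text persistence: one ESRI ASCII grid per layer plus CSV sidecars

numeric_layers <- function() {
  c(
    "elevation", "slope", "aspect", "curvature", "sqi", "awc", "awc_mm",
    "rooting_depth", "erodibility_k", "precip_annual", "precip_mayjun",
    "temp_aprjul", "et0", "erosivity_r", "n_deposition", "pop_density"
  )
}

write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  m <- as_grid_matrix(values, grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2] - grid$n_rows * grid$cell_size),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %g", nodata)
  ), con)
  m[is.na(m)] <- nodata
  for (r in seq_len(grid$n_rows)) {
    writeLines(paste(sprintf("%.10g", m[r, ]), collapse = " "), con)
  }
  invisible(path)
}

read_ascii_grid <- function(path) {
  if (!file.exists(path)) abort(sprintf("Grid file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) < 7L) abort(sprintf("Corrupt ASCII grid header in %s", path))
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1))
  vals <- suppressWarnings(as.numeric(vapply(hdr, `[`, "", 2)))
  expected <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                "nodata_value")
  if (!identical(keys, expected) || any(is.na(vals))) {
    abort(sprintf(
      "Corrupt ASCII grid header in %s (expected keys %s).",
      path, toString(expected)
    ))
  }
  nc <- as.integer(vals[1])
  nr <- as.integer(vals[2])
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr) {
    abort(sprintf("Corrupt ASCII grid in %s: expected %d rows, found %d.",
                  path, nr, length(body)))
  }
  m <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[r]), "\\s+")[[1]]))
    if (length(v) != nc || any(is.na(v))) {
      abort(sprintf("Corrupt ASCII grid in %s at data row %d.", path, r))
    }
    m[r, ] <- v
  }
  m[m == vals[6]] <- NA_real_
  list(
    values = m,
    grid = grid_spec(nr, nc, cell_size = vals[5],
                     origin = c(vals[3], vals[4] + nr * vals[5]))
  )
}

#' Write a landscape to a directory of plain-text files
#'
#' One ESRI ASCII grid per numeric layer, integer-coded grids for the
#' categorical layers with a CSV legend, and CSV tables for CHP plants and
#' districts. [read_landscape()] restores the stack.
#'
#' @param landscape A `landscape`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  stopifnot(inherits(landscape, "landscape"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- landscape$grid
  px <- landscape$pixels
  for (layer in numeric_layers()) {
    write_ascii_grid(px[[layer]], g, file.path(dir, paste0(layer, ".asc")))
  }
  write_ascii_grid(as.integer(px$lulc), g, file.path(dir, "lulc.asc"))
  write_ascii_grid(px$district_id, g, file.path(dir, "district_id.asc"))
  readr::write_csv(
    tibble(code = seq_along(lulc_levels()), class = lulc_levels()),
    file.path(dir, "lulc_legend.csv")
  )
  readr::write_csv(landscape$plants, file.path(dir, "plants.csv"))
  readr::write_csv(landscape$districts, file.path(dir, "districts.csv"))
  yaml::write_yaml(
    list(crs_label = g$crs_label, seed = landscape$seed),
    file.path(dir, "meta.yml")
  )
  invisible(dir)
}

#' Read a landscape written by [write_landscape()]
#'
#' @param dir Directory containing the layer files.
#' @return A `landscape` object.
#' @export
read_landscape <- function(dir) {
  need <- c(paste0(c(numeric_layers(), "lulc", "district_id"), ".asc"),
            "lulc_legend.csv", "plants.csv", "districts.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    abort(sprintf("Missing landscape layer file(s): %s", toString(missing)))
  }
  first <- read_ascii_grid(file.path(dir, paste0(numeric_layers()[1], ".asc")))
  g <- first$grid
  meta <- if (file.exists(file.path(dir, "meta.yml"))) {
    yaml::read_yaml(file.path(dir, "meta.yml"))
  } else {
    list()
  }
  if (!is.null(meta$crs_label)) g$crs_label <- meta$crs_label
  px <- grid_coords(g)
  px[[numeric_layers()[1]]] <- as.vector(first$values)
  for (layer in numeric_layers()[-1]) {
    lyr <- read_ascii_grid(file.path(dir, paste0(layer, ".asc")))
    if (!identical(dim(lyr$values), dim(first$values))) {
      abort(sprintf("Layer %s does not align with the stack grid.", layer))
    }
    px[[layer]] <- as.vector(lyr$values)
  }
  legend <- readr::read_csv(file.path(dir, "lulc_legend.csv"),
                            show_col_types = FALSE)
  codes <- as.vector(read_ascii_grid(file.path(dir, "lulc.asc"))$values)
  px$lulc <- factor(legend$class[match(codes, legend$code)],
                    levels = lulc_levels())
  px$district_id <-
    as.integer(as.vector(read_ascii_grid(file.path(dir, "district_id.asc"))$values))
  plants <- readr::read_csv(file.path(dir, "plants.csv"),
                            show_col_types = FALSE, col_types = "iiiddd")
  plants <- tibble(
    id = as.integer(plants$id %||% integer()),
    row = as.integer(plants$row %||% integer()),
    col = as.integer(plants$col %||% integer()),
    x = as.numeric(plants$x %||% numeric()),
    y = as.numeric(plants$y %||% numeric()),
    capacity = as.numeric(plants$capacity %||% numeric())
  )
  districts <- readr::read_csv(file.path(dir, "districts.csv"),
                               show_col_types = FALSE)
  structure(
    list(
      grid = g, pixels = px, districts = districts, plants = plants,
      params = NULL, seed = meta$seed %||% NA_integer_
    ),
    class = "landscape"
  )
}
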