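#' Carbon storage by land-use class
#'
#' Pixel carbon stock is the summed pool density of its land-use class times
#' the cell area; the landscape total is the sum over pixels.
#'
#' @param data Pixel data frame with a `landuse` column.
#' @param pools A [carbon_pool_table()].
#' @param cell_area Cell area (ha).
#' @return `data` with a `carbon_t` column (t C per pixel).
#' @export
#' @examples
#' carbon_storage(tibble::tibble(landuse = c("cropland", "forest")))
carbon_storage <- function(data, pools = carbon_pool_table(),
                           cell_area = 25) {
  out <- as_tibble(data)
  out$carbon_t <- join_class_param(out$landuse, pools, "total") * cell_area
  out
}
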