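#' Published per-cell total heats of encapsulated chondrocytes
#'
#' The packaged reference dataset: per-well total heat over a 48-h run for
#' 150,000 human articular chondrocytes embedded in 4.5% agarose hydrogels,
#' in four media groups of eight replicate gels each -- cell-free controls
#' ("No Cells"), cells in plain PBS ("Cells Only"), and cells with glucose- or
#' glutamine-enriched media. Values are the published per-cell totals
#' (µJ/cell) reproduced verbatim; the no-cell controls are tabulated on the
#' same per-cell scale in the source table even though their wells hold no
#' cells, and are kept as printed.
#'
#' @return A tibble with columns `well_id`, `group`, `cells`,
#'   `heat_per_cell_uJ` and `total_heat_uJ` (per-cell value scaled by the
#'   cell count; `NA` for the cell-free controls), in column-major well order.
#' @examples
#' heat_anova(chondrocyte_heats(), heat_per_cell_uJ, group)
#' @export
chondrocyte_heats <- function() {
  path <- system.file("extdata", "chondrocyte_total_heat.csv",
                      package = "thermowell", mustWork = TRUE)
  df <- tibble::as_tibble(data.table::fread(path, header = TRUE))
  df$group <- factor(df$group, levels = unique(df$group))
  df$total_heat_uJ <- ifelse(df$cells > 0,
                             df$heat_per_cell_uJ * df$cells, NA_real_)
  df
}
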