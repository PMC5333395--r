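#' Build a serial-dilution well table for a dose-response experiment
#'
#' Lays out one compound over `n_conc` serially diluted concentrations from
#' `top_conc` at ratio `1:ratio`, plus an optional vehicle (0 µM) well, for
#' each requested construct.
#'
#' @param compound Compound identifier.
#' @param top_conc Highest tested concentration, µM.
#' @param n_conc Number of nonzero concentrations.
#' @param ratio Serial dilution ratio (2 or 3).
#' @param constructs Constructs to lay out (`"WT"`, `"MUT"`, `"none"`).
#' @param vehicle Include a 0 µM vehicle well per construct.
#' @return Tibble with `well`, `compound`, `concentration`, `construct`.
#' @export
dose_series_wells <- function(compound, top_conc, n_conc = 8, ratio = 2,
                              constructs = c("WT", "MUT"), vehicle = TRUE) {
  concs <- top_conc / ratio^(seq_len(n_conc) - 1)
  if (vehicle) concs <- c(concs, 0)
  rows <- LETTERS[seq_along(constructs)]
  purrr::map2(constructs, rows, function(con, row) {
    tibble(
      well = sprintf("%s%02d", row, seq_along(concs)),
      compound = compound,
      concentration = concs,
      construct = con
    )
  }) |> purrr::list_rbind()
}

#' Simulate a complete WT/MUT overexpression engagement plate
#'
#' Convenience wrapper producing everything needed to exercise the full
#' analysis path on one compound: a [plate_spec()] covering a WT and a MUT
#' dose series (plus vehicle wells), simulated ground truth, rendered field
#' images and the matching analysis layout.
#'
#' @param truth A [pharmacology_truth()].
#' @param compound Compound identifier.
#' @param top_conc Highest tested concentration, µM.
#' @param n_conc,ratio Dilution-series design (see [dose_series_wells()]).
#' @param constructs Constructs to simulate; use `"none"` for an
#'   endogenous-assay plate.
#' @param fields_per_well,field_px,cells_per_field,pixel_size,transfection_fraction
#'   Imaging geometry and biology, passed to [plate_spec()].
#' @param seed Integer seed.
#' @param noise Render background noise (see [render_field()]).
#' @return List with `plate` (`$cells` ledger and `$fields` images), `spec`,
#'   `layout` (for [run_pipeline()]) and `truth`.
#' @export
simulate_engagement_plate <- function(truth, compound, top_conc,
                                      n_conc = 8, ratio = 2,
                                      constructs = c("WT", "MUT"),
                                      fields_per_well = 4, field_px = 256,
                                      cells_per_field = 80,
                                      pixel_size = 0.65,
                                      transfection_fraction = 0.3,
                                      seed = 1L, noise = TRUE) {
  wells <- dose_series_wells(compound, top_conc, n_conc, ratio, constructs)
  spec <- plate_spec(
    wells,
    fields_per_well = fields_per_well,
    field_shape = c(field_px, field_px),
    pixel_size = pixel_size,
    transfection_fraction = transfection_fraction,
    cells_per_field_mean = cells_per_field,
    dilution_ratio = ratio,
    seed = seed
  )
  plate <- simulate_plate_images(truth, spec, noise = noise)
  layout <- list(
    wells = dplyr::mutate(
      wells,
      mode = ifelse(.data$construct == "none", "endogenous", "overexpression")
    ),
    channels = list(nuclear = "dapi", mark = "mark", flag = "flag"),
    pixel_size = pixel_size,
    fields_per_well = fields_per_well
  )
  list(plate = plate, spec = spec, layout = layout, truth = truth)
}
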