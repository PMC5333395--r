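# Small builders shared across the suite. All fixtures are generated in code.

default_truth <- function(...) {
  pharmacology_truth(ec50_cell = 0.7, ...)
}

# a compact WT/MUT plate spec: n_conc-point 1:2 series from top_conc + vehicle
small_spec <- function(truth = default_truth(), compound = "CMPD",
                       top_conc = 10, n_conc = 6, ratio = 2,
                       constructs = c("WT", "MUT"),
                       fields_per_well = 2, field_px = 128,
                       cells_per_field = 30, seed = 1L, ...) {
  wells <- dose_series_wells(compound, top_conc, n_conc, ratio, constructs)
  plate_spec(wells,
             fields_per_well = fields_per_well,
             field_shape = c(field_px, field_px),
             cells_per_field_mean = cells_per_field,
             dilution_ratio = ratio, seed = seed, ...)
}

# one synthetic field with nuclei at given µm positions/radii, no noise
disc_field <- function(centers_um, radii_um = 6, pixel_size = 0.65,
                       field_px = 128, mark = 200, flag = 100, dapi = 500,
                       eccentricity = 0, theta = 0) {
  n <- nrow(centers_um)
  cells <- tibble::tibble(
    well = "A01", compound = "CMPD", concentration = 0, construct = "none",
    field = 1L, cell = seq_len(n),
    cx = centers_um[, 1] / pixel_size, cy = centers_um[, 2] / pixel_size,
    radius_um = rep_len(radii_um, n),
    eccentricity = rep_len(eccentricity, n), theta = rep_len(theta, n),
    transfected = FALSE, alive = TRUE, condensed = FALSE,
    true_mark = rep_len(mark, n), true_flag = rep_len(flag, n),
    true_dapi = rep_len(dapi, n)
  )
  spec <- plate_spec(
    tibble::tibble(well = "A01", compound = "CMPD", concentration = 0,
                   construct = "none"),
    field_shape = c(field_px, field_px), pixel_size = pixel_size,
    background_level = 0, background_sd = 0
  )
  render_field(cells, spec, noise = FALSE)
}

# per-cell truth table -> per-well series via truth-label gating (no imaging)
wells_from_cells <- function(cells) {
  cells |>
    dplyr::filter(alive) |>
    dplyr::mutate(use = construct == "none" | transfected) |>
    dplyr::group_by(well, compound, concentration, construct) |>
    dplyr::summarise(
      mean_mark = mean(true_mark[use]),
      sd_mark = sd(true_mark[use]),
      n_cells_total = dplyr::n(),
      .groups = "drop"
    )
}
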