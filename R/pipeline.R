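#' Read and validate a plate-layout configuration file
#'
#' The layout is a YAML file with top-level keys `pixel_size` (µm/px),
#' `fields_per_well`, `channels` (map with `nuclear`, `mark` and optionally
#' `flag` entries naming image channels) and `wells` (a list of records with
#' `well`, `compound`, `concentration` in µM, `construct` of WT/MUT/none and
#' optional `mode` of overexpression/endogenous/death). `mode` defaults to
#' `"endogenous"` for construct `"none"` and `"overexpression"` otherwise;
#' endogenous-mode wells must have construct `"none"`.
#'
#' @param path Path to the YAML layout.
#' @return A validated layout list (`wells` tibble, `channels`, `pixel_size`,
#'   `fields_per_well`).
#' @export
read_plate_layout <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_plate_layout(raw)
}

#' @rdname read_plate_layout
#' @param layout A layout list to validate (as produced by parsing the YAML).
#' @export
validate_plate_layout <- function(layout) {
  for (key in c("pixel_size", "channels", "wells")) {
    if (is.null(layout[[key]])) abort(sprintf("layout lacks required key '%s'", key))
  }
  if (layout$pixel_size <= 0) abort("layout pixel_size must be > 0")
  if (is.null(layout$channels$nuclear) || is.null(layout$channels$mark)) {
    abort("layout channels must name at least 'nuclear' and 'mark'")
  }
  wells <- if (is.data.frame(layout$wells)) {
    as_tibble(layout$wells)
  } else {
    dplyr::bind_rows(lapply(layout$wells, as_tibble))
  }
  req <- c("well", "compound", "concentration", "construct")
  missing_cols <- setdiff(req, names(wells))
  if (length(missing_cols)) {
    abort(paste0("layout wells lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(wells$well)) abort("duplicated well ids in layout")
  if (!all(wells$construct %in% c("WT", "MUT", "none"))) {
    abort('layout construct must be "WT", "MUT" or "none"')
  }
  if (any(wells$concentration < 0)) abort("layout concentrations must be >= 0")
  if (!"mode" %in% names(wells)) wells$mode <- NA_character_
  wells$mode <- ifelse(is.na(wells$mode),
                       ifelse(wells$construct == "none", "endogenous",
                              "overexpression"),
                       wells$mode)
  if (!all(wells$mode %in% c("overexpression", "endogenous", "death"))) {
    abort('layout mode must be "overexpression", "endogenous" or "death"')
  }
  bad <- wells$mode == "endogenous" & wells$construct != "none"
  if (any(bad)) {
    abort('endogenous-mode wells must have construct "none"')
  }
  layout$wells <- wells
  layout$fields_per_well <- layout$fields_per_well %||% NA_integer_
  layout
}

#' Run the full high-content engagement pipeline on a plate
#'
#' Stages: segment each field's nuclei, filter (minimum area, border),
#' measure per-channel intensities, compute a plate-wide FLAG gate, aggregate
#' per well (gated for overexpression wells, all cells for endogenous wells),
#' fit a four-parameter logistic per compound, normalize the WT curve to the
#' MUT baseline and test the cytotoxicity signature. A stage failure is
#' localized to its well (recorded in `well_status`), not fatal to the run.
#'
#' @param images One of: the result of [simulate_plate_images()], a list of
#'   [multichannel_field()] objects, or a directory written by
#'   [write_plate()].
#' @param layout Layout list as from [read_plate_layout()] /
#'   [validate_plate_layout()] (or the `layout` element of
#'   [simulate_engagement_plate()]).
#' @param seg_params A [segmentation_params()].
#' @param gate_method,gate_percentile,gate_k Passed to
#'   [compute_gate_threshold()].
#' @param min_gated_cells Low-confidence floor per well.
#' @param z_crit,drop_frac Cytotoxicity-signature thresholds, see
#'   [detect_toxicity_spike()].
#' @param out_dir If given, write `cells.csv`, `wells.csv`, `well_status.csv`
#'   and `fits.json` there.
#' @return A list of class `run_report`: `cells` (per-cell table with gate
#'   flag), `wells` (per-well measurements), `gate`, `engagement` (named list
#'   of [compute_engagement()] results per WT/MUT compound), `fits` (all 4PL
#'   fits incl. endogenous series), `well_status` (every well accounted for:
#'   analysed or excluded with reason), `qc` and `provenance`.
#' @export
run_pipeline <- function(images, layout,
                         seg_params = segmentation_params(),
                         gate_method = "otsu", gate_percentile = 0.95,
                         gate_k = 3, min_gated_cells = 20,
                         z_crit = 3, drop_frac = 0.5,
                         out_dir = NULL) {
  t0 <- Sys.time()
  if (is.character(images)) images <- read_plate(images)
  if (!is.null(images$fields)) images <- images$fields
  layout <- validate_plate_layout(layout)
  wells_meta <- layout$wells
  nuclear <- layout$channels$nuclear
  mark_ch <- layout$channels$mark
  flag_ch <- layout$channels$flag
  mark_col <- paste0("mean_", mark_ch)
  flag_col <- if (!is.null(flag_ch)) paste0("mean_", flag_ch)

  # --- segment / filter / measure, localizing failures to wells ------------
  status <- list()
  cell_tables <- list()
  for (f in images) {
    res <- tryCatch(
      process_field(f, seg_params, nuclear_channel = nuclear),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      status[[length(status) + 1]] <-
        tibble(well = f$well, status = "error", reason = conditionMessage(res))
    } else {
      cell_tables[[length(cell_tables) + 1]] <- res
    }
  }
  cells <- purrr::list_rbind(cell_tables)
  err_status <- purrr::list_rbind(status)

  imaged_wells <- unique(vapply(images, function(f) f$well, character(1)))
  unknown <- setdiff(imaged_wells, wells_meta$well)
  if (length(unknown)) {
    abort(paste0("imaged wells missing from layout: ",
                 paste(unknown, collapse = ", ")))
  }

  well_status <- tibble(well = wells_meta$well) |>
    dplyr::mutate(
      status = dplyr::case_when(
        .data$well %in% err_status$well ~ "error",
        !.data$well %in% imaged_wells ~ "excluded",
        !.data$well %in% cells$well ~ "excluded",
        TRUE ~ "analysed"
      ),
      reason = dplyr::case_when(
        .data$status == "error" ~ "segmentation error",
        !.data$well %in% imaged_wells ~ "no images",
        .data$status == "excluded" ~ "no nuclei",
        TRUE ~ NA_character_
      )
    )

  # --- gate ----------------------------------------------------------------
  oe_wells <- wells_meta$well[wells_meta$mode == "overexpression"]
  gate <- NULL
  if (length(oe_wells) && !is.null(flag_col) && nrow(cells)) {
    pool <- cells[cells$well %in% oe_wells, ]
    none_wells <- wells_meta$well[wells_meta$construct == "none"]
    reference <- if (length(none_wells)) cells[cells$well %in% none_wells, ]
    gate <- tryCatch(
      compute_gate_threshold(pool, method = gate_method, flag_col = flag_col,
                             reference = reference, k = gate_k,
                             percentile = gate_percentile),
      error = function(e) abort(paste0("FLAG gating failed: ", conditionMessage(e)))
    )
    cells$gated <- cells[[flag_col]] > gate$threshold
  } else if (nrow(cells)) {
    cells$gated <- TRUE
  }

  # --- aggregate -----------------------------------------------------------
  wells_tbl <- if (nrow(cells)) {
    quantify_wells(cells, layout = wells_meta, gate = gate,
                   mark_col = mark_col,
                   flag_col = flag_col %||% mark_col,
                   min_gated_cells = min_gated_cells)
  } else {
    tibble()
  }

  # --- fit / engagement ----------------------------------------------------
  engagement <- list()
  fits <- list()
  if (nrow(wells_tbl)) {
    for (cmpd in setdiff(unique(wells_tbl$compound), NA)) {
      wt <- wells_tbl[wells_tbl$compound == cmpd & wells_tbl$construct == "WT", ]
      mut <- wells_tbl[wells_tbl$compound == cmpd & wells_tbl$construct == "MUT", ]
      endo <- wells_tbl[wells_tbl$compound == cmpd & wells_tbl$construct == "none", ]
      if (nrow(wt) >= 4) {
        wt_fit <- tryCatch(fit_4pl(wt, response = "mean_mark"),
                           error = function(e) NULL)
        if (!is.null(wt_fit)) {
          fits[[paste0(cmpd, "_WT")]] <- wt_fit
          if (nrow(mut) && any(mut$concentration == 0)) {
            engagement[[cmpd]] <- compute_engagement(
              wt_fit, wt, mut, z_crit = z_crit, drop_frac = drop_frac
            )
          }
        }
      }
      if (nrow(endo) >= 4) {
        endo_fit <- tryCatch(fit_4pl(endo, response = "mean_mark"),
                             error = function(e) NULL)
        if (!is.null(endo_fit)) fits[[paste0(cmpd, "_endogenous")]] <- endo_fit
      }
    }
  }

  qc <- tibble(
    n_fields = length(images),
    n_cells = nrow(cells),
    cells_per_field = if (length(images)) nrow(cells) / length(images) else NA_real_,
    transfection_efficiency = if (nrow(wells_tbl)) {
      mean(wells_tbl$transfection_efficiency[wells_tbl$construct != "none"],
           na.rm = TRUE)
    } else NA_real_
  )
  report <- structure(
    list(cells = cells, wells = wells_tbl, gate = gate,
         engagement = engagement, fits = fits, well_status = well_status,
         qc = qc,
         provenance = list(
           package = "kdmscreen",
           version = as.character(utils::packageVersion("kdmscreen")),
           threshold_method = seg_params$threshold_method,
           gate_method = gate_method,
           sd_denominator = "n-1",
           min_area_um2 = seg_params$min_area,
           elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
         )),
    class = "run_report"
  )
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d wells (%d analysed), %d cells in %d fields\n",
              nrow(x$well_status),
              sum(x$well_status$status == "analysed"),
              nrow(x$cells), x$qc$n_fields))
  for (cmpd in names(x$engagement)) {
    cat(sprintf("  %s: ", cmpd)); print(x$engagement[[cmpd]])
  }
  invisible(x)
}

#' Write a run report to CSV/JSON files
#'
#' Emits `cells.csv` (per-cell table), `wells.csv` (per-well measurements),
#' `well_status.csv`, and `fits.json` (4PL parameters and engagement
#' summaries).
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$cells, file.path(dir, "cells.csv"))
  readr::write_csv(report$wells, file.path(dir, "wells.csv"))
  readr::write_csv(report$well_status, file.path(dir, "well_status.csv"))
  fits <- lapply(report$fits, function(f) as.list(glance(f)))
  eng <- lapply(report$engagement, function(e) as.list(glance(e)))
  jsonlite::write_json(
    list(fits = fits, engagement = eng, qc = as.list(report$qc),
         gate = if (!is.null(report$gate)) {
           report$gate[c("threshold", "method", "n_total", "n_gated")]
         },
         provenance = report$provenance),
    file.path(dir, "fits.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}
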