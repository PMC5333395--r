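#' Construct a multichannel field object
#'
#' @param channels Named list of equally sized numeric matrices (intensity
#'   a.u.), e.g. `dapi`, `mark`, `flag`.
#' @param pixel_size Physical pixel size, µm/pixel.
#' @param well,field Well identifier and field index.
#' @return An object of class `multichannel_field`.
#' @export
multichannel_field <- function(channels, pixel_size, well = NA_character_,
                               field = NA_integer_) {
  if (!length(channels) || is.null(names(channels)) || any(names(channels) == "")) {
    abort("`channels` must be a non-empty named list of matrices")
  }
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1) abort("all channels must share the same shape")
  if (pixel_size <= 0) abort("`pixel_size` must be > 0")
  structure(
    list(channels = channels, pixel_size = pixel_size,
         well = well, field = as.integer(field)),
    class = "multichannel_field"
  )
}

#' @export
print.multichannel_field <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<multichannel_field> %s field %s: %dx%d px (%.3g um/px), channels: %s\n",
              x$well, x$field, d[1], d[2], x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Render one field of a simulated plate as raster channels
#'
#' Paints each live cell of `cells` (one field's rows of the ledger produced
#' by [simulate_dose_series()]) as an elliptical nucleus into a DAPI raster,
#' and fills the mark and FLAG channels with the cell's true intensity over
#' the same nuclear mask; Gaussian background is then added to every channel.
#' Cells with `alive = FALSE` are skipped unless `spec$keep_condensed_dead`
#' is set, in which case they appear as condensed small nuclei.
#'
#' Pixel coordinates are 0-based and pixel-centred; a nucleus centred on
#' row/column 0 is truncated by the image border.
#'
#' @param cells Tibble of cell truth rows for one field.
#' @param spec A [plate_spec()] (geometry and background parameters).
#' @param noise If `FALSE`, no background is added (noiseless rendering).
#' @return A [multichannel_field()] with channels `dapi`, `mark`, `flag`.
#' @export
render_field <- function(cells, spec, noise = TRUE) {
  stopifnot(inherits(spec, "plate_spec"))
  if (spec$pixel_size <= 0) abort("`pixel_size` must be > 0")
  dims <- spec$field_shape
  dapi <- matrix(0, dims[1], dims[2])
  mark <- matrix(0, dims[1], dims[2])
  flag <- matrix(0, dims[1], dims[2])
  keep <- cells$alive | isTRUE(spec$keep_condensed_dead)
  cells <- cells[keep, , drop = FALSE]
  px <- spec$pixel_size
  for (i in seq_len(nrow(cells))) {
    a <- cells$radius_um[i] * (1 + cells$eccentricity[i]) / px
    b <- cells$radius_um[i] / (1 + cells$eccentricity[i]) / px
    th <- cells$theta[i]
    cx <- cells$cx[i]; cy <- cells$cy[i]
    r_ext <- max(a, b)
    rows <- max(0, floor(cy - r_ext)):min(dims[1] - 1, ceiling(cy + r_ext))
    cols <- max(0, floor(cx - r_ext)):min(dims[2] - 1, ceiling(cx + r_ext))
    if (!length(rows) || !length(cols)) next
    dx <- outer(rep(1, length(rows)), cols - cx)
    dy <- outer(rows - cy, rep(1, length(cols)))
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / b
    inside <- u^2 + v^2 <= 1
    if (!any(inside)) next
    ri <- rows + 1L; ci <- cols + 1L
    sub <- dapi[ri, ci, drop = FALSE]
    sub[inside] <- pmax(sub[inside], cells$true_dapi[i])
    dapi[ri, ci] <- sub
    sub <- mark[ri, ci, drop = FALSE]
    sub[inside] <- pmax(sub[inside], cells$true_mark[i])
    mark[ri, ci] <- sub
    sub <- flag[ri, ci, drop = FALSE]
    sub[inside] <- pmax(sub[inside], cells$true_flag[i])
    flag[ri, ci] <- sub
  }
  if (noise && (spec$background_level > 0 || spec$background_sd > 0)) {
    bg <- function() pmax(matrix(
      rnorm(prod(dims), spec$background_level, spec$background_sd),
      dims[1], dims[2]
    ), 0)
    dapi <- dapi + bg(); mark <- mark + bg(); flag <- flag + bg()
  }
  multichannel_field(
    list(dapi = dapi, mark = mark, flag = flag),
    pixel_size = px,
    well = if (nrow(cells)) cells$well[1] else NA_character_,
    field = if (nrow(cells)) cells$field[1] else NA_integer_
  )
}

#' Simulate a full plate of rendered multichannel fields
#'
#' Runs [simulate_dose_series()] and renders every field, consuming a single
#' RNG stream seeded from `spec$seed` so the whole plate is reproducible.
#'
#' @inheritParams simulate_dose_series
#' @param noise Render with background noise (see [render_field()]).
#' @return A list with `cells` (the ground-truth ledger) and `fields`
#'   (list of [multichannel_field()] objects, one per well/field).
#' @export
simulate_plate_images <- function(truth, spec, noise = TRUE) {
  withr::with_seed(spec$seed, {
    cells <- simulate_dose_series_impl(truth, spec)
    keys <- dplyr::distinct(
      tidyr::crossing(spec$wells["well"], field = seq_len(spec$fields_per_well))
    )
    fields <- purrr::pmap(keys, function(well, field) {
      fc <- cells[cells$well == well & cells$field == field, , drop = FALSE]
      f <- render_field(fc, spec, noise = noise)
      f$well <- well; f$field <- as.integer(field)
      f
    })
    list(cells = cells, fields = fields)
  })
}

#' Write a plate of rendered fields to multi-page TIFFs with a JSON sidecar
#'
#' Each field becomes one multi-page 16-bit TIFF (one page per channel, in
#' sidecar channel order) named `<well>_f<field>.tif`. Intensities are stored
#' scaled by `scale` into the 16-bit range. The sidecar `plate.json` records
#' channel names, pixel size, the intensity scale and the well map; the
#' ground-truth ledger is written as `truth.csv` when `cells` is supplied.
#'
#' @param plate List as returned by [simulate_plate_images()], or a bare list
#'   of [multichannel_field()] objects.
#' @param dir Output directory (created if needed).
#' @param scale Intensity units per 16-bit full scale (a.u. mapped to 65535).
#' @return `dir`, invisibly.
#' @export
write_plate <- function(plate, dir, scale = 4096) {
  fields <- if (!is.null(plate$fields)) plate$fields else plate
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ch_names <- names(fields[[1]]$channels)
  wells <- character(0)
  for (f in fields) {
    pages <- lapply(f$channels, function(m) pmin(pmax(m / scale, 0), 1))
    path <- file.path(dir, sprintf("%s_f%02d.tif", f$well, f$field))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    wells <- union(wells, f$well)
  }
  sidecar <- list(
    channels = ch_names,
    pixel_size_um = fields[[1]]$pixel_size,
    intensity_scale = scale,
    wells = wells,
    n_fields = length(fields)
  )
  jsonlite::write_json(sidecar, file.path(dir, "plate.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(plate$cells)) {
    readr::write_csv(plate$cells, file.path(dir, "truth.csv"))
  }
  invisible(dir)
}

#' Read a plate directory written by [write_plate()]
#'
#' @param dir Directory containing `plate.json` and the per-field TIFFs.
#' @return A list of [multichannel_field()] objects.
#' @export
read_plate <- function(dir) {
  sidecar_path <- file.path(dir, "plate.json")
  if (!file.exists(sidecar_path)) abort(paste0("no plate.json in ", dir))
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  paths <- sort(list.files(dir, pattern = "\\.tif$", full.names = TRUE))
  purrr::map(paths, function(p) {
    pages <- tiff::readTIFF(p, all = TRUE)
    channels <- setNames(
      lapply(pages, function(m) m * sidecar$intensity_scale),
      sidecar$channels
    )
    base <- sub("\\.tif$", "", basename(p))
    well <- sub("_f\\d+$", "", base)
    field <- as.integer(sub("^.*_f(\\d+)$", "\\1", base))
    multichannel_field(channels, sidecar$pixel_size_um, well, field)
  })
}
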