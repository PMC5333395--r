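#' Segmentation parameters
#'
#' Controls the nuclear detection and filtering rules: a binary mask is built
#' from the nuclear channel by Otsu thresholding (after optional Gaussian
#' smoothing), touching nuclei are optionally split by a watershed on the
#' distance transform, and nuclei are then filtered by a minimum physical
#' area and a border-exclusion rule. A nucleus of exactly `min_area` µm²
#' survives the size filter (only *smaller* nuclei are excluded).
#'
#' @param min_area Minimum retained nuclear area, µm².
#' @param exclude_border Drop nuclei with any pixel on the image boundary.
#' @param threshold_method Threshold identifier; only `"otsu"` is built in.
#' @param split_touching Split touching nuclei by distance-transform
#'   watershed.
#' @param smooth_sigma Gaussian pre-smoothing SD in pixels (0 = none).
#' @param watershed_tolerance Minimum depth (in distance-map units) between
#'   neighbouring objects for the watershed to keep them separate.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(min_area = 100,
                                exclude_border = TRUE,
                                threshold_method = "otsu",
                                split_touching = TRUE,
                                smooth_sigma = 1,
                                watershed_tolerance = 1) {
  if (min_area < 0) abort("`min_area` must be >= 0")
  threshold_method <- match.arg(threshold_method, "otsu")
  structure(
    list(min_area = min_area, exclude_border = exclude_border,
         threshold_method = threshold_method,
         split_touching = split_touching, smooth_sigma = smooth_sigma,
         watershed_tolerance = watershed_tolerance),
    class = "segmentation_params"
  )
}

#' Segment nuclei from the nuclear channel of a field
#'
#' Thresholds the designated nuclear channel (Otsu, optionally after Gaussian
#' smoothing), labels connected components (split by distance-transform
#' watershed when `params$split_touching` is set) and reports one record per
#' nucleus with its physical area, centroid and border flag. No filtering is
#' applied here; see [filter_nuclei()]. A field whose "foreground" does not
#' exceed the background by more than 3 background SDs is treated as
#' all-background (0 records) — an Otsu split of pure noise is not a nucleus.
#'
#' @param field A [multichannel_field()].
#' @param params A [segmentation_params()].
#' @param nuclear_channel Name of the nuclear-stain channel.
#' @return A tibble with columns `label`, `area` (µm²), `n_px`,
#'   `centroid_row`, `centroid_col` (0-based pixel-centred coordinates) and
#'   `touches_border`, carrying the label matrix as attribute `"labels"` and
#'   the pixel size as attribute `"pixel_size"`. An all-background image
#'   yields zero rows.
#' @export
segment_nuclei <- function(field, params = segmentation_params(),
                           nuclear_channel = "dapi") {
  stopifnot(inherits(field, "multichannel_field"))
  if (!nuclear_channel %in% names(field$channels)) {
    abort(sprintf("no channel '%s'; available: %s", nuclear_channel,
                  paste(names(field$channels), collapse = ", ")))
  }
  img <- field$channels[[nuclear_channel]]
  rng <- range(img)
  empty <- function() {
    out <- tibble(label = integer(0), area = numeric(0), n_px = integer(0),
                  centroid_row = numeric(0), centroid_col = numeric(0),
                  touches_border = logical(0))
    attr(out, "labels") <- matrix(0L, nrow(img), ncol(img))
    attr(out, "pixel_size") <- field$pixel_size
    attr(out, "params") <- params
    out
  }
  if (diff(rng) <= .Machine$double.eps * max(abs(rng), 1)) return(empty())
  x <- EBImage::Image((img - rng[1]) / diff(rng))
  if (params$smooth_sigma > 0) {
    x <- EBImage::gblur(x, sigma = params$smooth_sigma)
  }
  th <- EBImage::otsu(x, range = c(0, 1))
  mask <- x > th
  if (!any(mask) || all(mask)) return(empty())
  # background-only guard: an Otsu split of pure background noise produces a
  # "foreground" barely above the background; demand real nuclear contrast
  fore <- img[mask]
  back <- img[!mask]
  if (mean(fore) - mean(back) <= 3 * sd(back)) return(empty())
  mask <- EBImage::fillHull(mask)
  labels <- if (params$split_touching) {
    EBImage::watershed(EBImage::distmap(mask),
                       tolerance = params$watershed_tolerance, ext = 1)
  } else {
    EBImage::bwlabel(mask)
  }
  lab <- matrix(as.integer(EBImage::imageData(labels)), nrow(img), ncol(img))
  nucleus_records(lab, field$pixel_size, params)
}

nucleus_records <- function(lab, pixel_size, params) {
  n_lab <- max(lab)
  if (n_lab == 0) {
    out <- tibble(label = integer(0), area = numeric(0), n_px = integer(0),
                  centroid_row = numeric(0), centroid_col = numeric(0),
                  touches_border = logical(0))
  } else {
    idx <- which(lab > 0)
    l <- lab[idx]
    rows0 <- (idx - 1L) %% nrow(lab)      # 0-based row
    cols0 <- (idx - 1L) %/% nrow(lab)     # 0-based col
    n_px <- tabulate(l, n_lab)
    sum_r <- rowsum_by_label(rows0, l, n_lab)
    sum_c <- rowsum_by_label(cols0, l, n_lab)
    on_border <- rows0 == 0L | rows0 == nrow(lab) - 1L |
      cols0 == 0L | cols0 == ncol(lab) - 1L
    border <- rowsum_by_label(as.numeric(on_border), l, n_lab) > 0
    out <- tibble(
      label = seq_len(n_lab),
      area = n_px * pixel_size^2,
      n_px = as.integer(n_px),
      centroid_row = sum_r / n_px,
      centroid_col = sum_c / n_px,
      touches_border = border
    )
    out <- out[out$n_px > 0, , drop = FALSE]
  }
  attr(out, "labels") <- lab
  attr(out, "pixel_size") <- pixel_size
  attr(out, "params") <- params
  out
}

rowsum_by_label <- function(x, labels, n) {
  out <- numeric(n)
  s <- rowsum(x, labels)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Apply the minimum-area and border-exclusion filters
#'
#' Keeps nuclei with `area >= params$min_area` µm² (nuclei *smaller* than the
#' cutoff are excluded, so an exactly-at-cutoff nucleus survives) and, when
#' `params$exclude_border` is set, drops nuclei with any pixel on the image
#' boundary. Row order is preserved and the operation is idempotent.
#'
#' @param records Output of [segment_nuclei()] (or a compatible tibble).
#' @param params A [segmentation_params()].
#' @return The filtered tibble; attributes of `records` are preserved.
#' @export
filter_nuclei <- function(records, params = segmentation_params()) {
  keep <- records$area >= params$min_area
  if (params$exclude_border) keep <- keep & !records$touches_border
  out <- records[keep, , drop = FALSE]
  attr(out, "labels") <- attr(records, "labels")
  attr(out, "pixel_size") <- attr(records, "pixel_size")
  attr(out, "params") <- params
  out
}

#' Measure per-nucleus mean intensities in every channel
#'
#' Adds one `mean_<channel>` column per channel of `field`: the arithmetic
#' mean of that channel over the nucleus mask pixels.
#'
#' @param field The [multichannel_field()] the records were segmented from.
#' @param records Output of [segment_nuclei()] or [filter_nuclei()] (must
#'   carry the `"labels"` attribute from this field).
#' @return `records` with `mean_*` columns appended.
#' @export
measure_nuclei <- function(field, records) {
  lab <- attr(records, "labels")
  if (is.null(lab)) abort("`records` carries no label mask; run segment_nuclei() first")
  if (!all(dim(lab) == dim(field$channels[[1]]))) {
    abort("label mask shape does not match the field")
  }
  if (nrow(records) && any(records$n_px == 0)) abort("empty nucleus mask")
  n_lab <- max(lab, records$label, 0L)
  idx <- which(lab > 0)
  l <- lab[idx]
  out <- records
  for (ch in names(field$channels)) {
    if (length(idx)) {
      sums <- rowsum_by_label(field$channels[[ch]][idx], l, n_lab)
      counts <- tabulate(l, n_lab)
      means <- sums[records$label] / counts[records$label]
    } else {
      means <- numeric(0)
    }
    out[[paste0("mean_", ch)]] <- means
  }
  attr(out, "labels") <- lab
  attr(out, "pixel_size") <- attr(records, "pixel_size")
  attr(out, "params") <- attr(records, "params")
  out
}

#' Segment, filter and measure one field in a single call
#'
#' Convenience wrapper chaining [segment_nuclei()], [filter_nuclei()] and
#' [measure_nuclei()], returning a per-cell tibble annotated with the field's
#' well and index.
#'
#' @inheritParams segment_nuclei
#' @return A tibble of filtered, measured nuclei with `well` and `field`
#'   columns prepended.
#' @export
process_field <- function(field, params = segmentation_params(),
                          nuclear_channel = "dapi") {
  rec <- segment_nuclei(field, params, nuclear_channel)
  rec <- filter_nuclei(rec, params)
  rec <- measure_nuclei(field, rec)
  dplyr::bind_cols(
    tibble(well = rep(field$well, nrow(rec)),
           field = rep(field$field %||% NA_integer_, nrow(rec))),
    as_tibble(rec)
  )
}
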