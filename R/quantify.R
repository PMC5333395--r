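#' Compute the FLAG gate threshold for "strongly overexpressing" cells
#'
#' Determines a single per-plate intensity threshold above which a cell is
#' considered to strongly overexpress the FLAG-tagged demethylase.
#' Methods:
#' \describe{
#'   \item{`"otsu"` (default)}{Otsu's threshold on log10 intensity, assuming a
#'     bimodal transfected/nontransfected mixture. If the split looks
#'     unimodal (either side nearly empty, or the mode separation is below
#'     3.5 pooled SDs on the log scale) a warning is issued and the reference
#'     method is used when `reference` cells are available, otherwise an
#'     error is raised.}
#'   \item{`"reference"`}{Mean + `k` SD of the FLAG intensity of reference
#'     (nontransfected) cells.}
#'   \item{`"percentile"`}{A fixed upper quantile of the plate distribution.}
#' }
#'
#' @param cells Per-cell tibble (pooled across the plate or reference wells).
#' @param method Gating method, see Details.
#' @param flag_col Column holding the FLAG intensity.
#' @param reference Optional tibble of reference (nontransfected) cells for
#'   the `"reference"` method / fallback.
#' @param k SD multiplier for the reference method.
#' @param percentile Quantile of the plate distribution at which the
#'   threshold is placed (0.5 gates the top half; default 0.95 gates the top
#'   5 percent).
#' @return A list of class `gating_result`: `threshold` (a.u.), `method`,
#'   `n_total`, `n_gated`.
#' @export
compute_gate_threshold <- function(cells,
                                   method = c("otsu", "reference", "percentile"),
                                   flag_col = "mean_flag",
                                   reference = NULL, k = 3, percentile = 0.95) {
  method <- match.arg(method)
  x <- cells[[flag_col]]
  x <- x[is.finite(x) & x > 0]
  if (length(x) < 100) {
    warn(sprintf("only %d usable cells for gate calibration (< 100)", length(x)))
  }
  threshold <- switch(method,
    otsu = {
      lx <- log10(x)
      th_log <- otsu_1d(lx)
      lo <- lx[lx < th_log]; hi <- lx[lx >= th_log]
      pooled <- sqrt(((length(lo) - 1) * var(lo) + (length(hi) - 1) * var(hi)) /
                       max(length(lo) + length(hi) - 2, 1))
      sep <- (mean(hi) - mean(lo)) / max(pooled, .Machine$double.eps)
      frac <- min(length(lo), length(hi)) / length(lx)
      # an Otsu split of a single Gaussian yields ~2.65 pooled-SD separation;
      # demand clearly more before trusting the valley
      if (!is.finite(sep) || sep < 3.5 || frac < 0.01) {
        if (!is.null(reference)) {
          warn("FLAG distribution looks unimodal; falling back to the reference method")
          return(compute_gate_threshold(cells, "reference", flag_col,
                                        reference = reference, k = k))
        }
        abort("FLAG distribution looks unimodal and no reference cells were given")
      }
      10^th_log
    },
    reference = {
      if (is.null(reference)) abort("`reference` cells required for the reference method")
      r <- reference[[flag_col]]
      r <- r[is.finite(r)]
      mean(r) + k * sd(r)
    },
    percentile = unname(quantile(x, percentile))
  )
  gated <- cells[[flag_col]] > threshold
  structure(
    list(threshold = threshold, method = method,
         n_total = nrow(cells), n_gated = sum(gated, na.rm = TRUE)),
    class = "gating_result"
  )
}

#' @export
print.gating_result <- function(x, ...) {
  cat(sprintf("<gating_result> method %s: threshold %.4g a.u.; %d/%d cells gated\n",
              x$method, x$threshold, x$n_gated, x$n_total))
  invisible(x)
}

# Otsu's method on a numeric vector (maximum between-class variance on a
# 256-bin histogram), mirroring the image-threshold variant used for masks.
otsu_1d <- function(x, n_bins = 256) {
  rng <- range(x)
  if (diff(rng) <= 0) abort("cannot threshold a constant distribution")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  mids[which.max(sb2)]
}

#' Aggregate gated per-cell measurements into a well measurement
#'
#' Pools the filtered cells of all fields of one well and computes the
#' mean/SD of the histone-mark intensity over the gated subpopulation
#' (overexpression mode) or over all cells (endogenous mode, used for
#' `construct = "none"` wells). The total nucleus count across fields is the
#' survival readout; the gated fraction estimates transfection efficiency.
#' SD uses the sample (n − 1) denominator.
#'
#' @param cells Per-cell tibble for one well (e.g. rows of [process_field()]
#'   output), with columns `field`, the mark column and (in overexpression
#'   mode) the FLAG column.
#' @param threshold FLAG gate threshold (a.u.); ignored in endogenous mode.
#' @param mark_col,flag_col Column names for mark and FLAG intensity.
#' @param mode `"overexpression"` (gate on FLAG) or `"endogenous"` (pool all
#'   cells).
#' @param well,compound,concentration,construct Well metadata; taken from
#'   `cells` columns when present and not supplied.
#' @param min_gated_cells Wells with fewer gated cells are flagged
#'   low-confidence.
#' @return One-row tibble: `well`, `compound`, `concentration`, `construct`,
#'   `mean_mark`, `sd_mark`, `n_cells_total`, `n_cells_gated`, `n_fields`,
#'   `transfection_efficiency`, `low_confidence`, `no_gated_cells`.
#' @export
aggregate_well <- function(cells, threshold = NULL,
                           mark_col = "mean_mark", flag_col = "mean_flag",
                           mode = c("overexpression", "endogenous"),
                           well = NULL, compound = NULL,
                           concentration = NULL, construct = NULL,
                           min_gated_cells = 20) {
  mode <- match.arg(mode)
  meta <- function(arg, col) {
    if (!is.null(arg)) return(arg)
    if (col %in% names(cells) && nrow(cells)) cells[[col]][1] else NA
  }
  construct <- meta(construct, "construct")
  if (mode == "overexpression" && identical(construct, "none")) {
    mode <- "endogenous"
  }
  gated <- if (mode == "endogenous") {
    rep(TRUE, nrow(cells))
  } else {
    if (is.null(threshold)) abort("`threshold` required in overexpression mode")
    cells[[flag_col]] > threshold
  }
  marks <- cells[[mark_col]][gated]
  n_gated <- sum(gated)
  tibble(
    well = meta(well, "well"),
    compound = meta(compound, "compound"),
    concentration = meta(concentration, "concentration"),
    construct = construct,
    mean_mark = if (n_gated > 0) mean(marks) else NA_real_,
    sd_mark = if (n_gated > 1) sd(marks) else NA_real_,
    n_cells_total = nrow(cells),
    n_cells_gated = as.integer(n_gated),
    n_fields = dplyr::n_distinct(cells$field),
    transfection_efficiency = if (nrow(cells) > 0) n_gated / nrow(cells) else NA_real_,
    low_confidence = n_gated < min_gated_cells,
    no_gated_cells = n_gated == 0
  )
}

#' Quantify all wells of a per-cell table
#'
#' Splits a measured per-cell table by well, joins well metadata, and runs
#' [aggregate_well()] on each. Wells of construct `"none"` are pooled
#' ungated (endogenous mode).
#'
#' @param cells Per-cell tibble across the plate (with `well` and `field`
#'   columns).
#' @param layout Tibble mapping `well` to `compound`, `concentration`,
#'   `construct` (omit if `cells` already carries these columns).
#' @param gate A `gating_result` (or a bare threshold); not needed if every
#'   well is endogenous mode.
#' @inheritParams aggregate_well
#' @return Tibble with one [aggregate_well()] row per well.
#' @export
quantify_wells <- function(cells, layout = NULL, gate = NULL,
                           mark_col = "mean_mark", flag_col = "mean_flag",
                           min_gated_cells = 20) {
  if (!is.null(layout)) {
    keep <- setdiff(names(cells), setdiff(names(layout), "well"))
    cells <- dplyr::inner_join(cells[keep], layout, by = "well")
  }
  threshold <- if (inherits(gate, "gating_result")) gate$threshold else gate
  cells |>
    dplyr::group_by(.data$well) |>
    dplyr::group_split() |>
    purrr::map(aggregate_well, threshold = threshold, mark_col = mark_col,
               flag_col = flag_col, min_gated_cells = min_gated_cells) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$compound, .data$construct, .data$concentration)
}
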