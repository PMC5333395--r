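#' Pharmacological ground truth for the synthetic-microscopy generator
#'
#' Bundles the parameters that fully determine the expected histone-mark
#' response of a simulated cell population to an inhibitor: the cellular
#' potency against the overexpressed demethylase, an optional potency against
#' the endogenous enzymes (which raises the mark in mutant-transfected and
#' nontransfected cells), and an optional cytotoxicity component coupling a
#' methylation spike to concentration-dependent cell loss.
#'
#' The expected mark of a cell overexpressing active wild-type (WT) enzyme is
#' \deqn{m(c) = m_{dep} + (m_{base} - m_{dep}) \frac{c^h}{c^h + EC_{50}^h}}
#' so untreated WT cells sit at the depleted level `mark_depleted` and full
#' inhibition restores the nontransfected baseline `mark_baseline`.
#' Cells expressing the catalytically dead mutant (MUT) or no construct sit at
#' `mark_baseline`, plus an endogenous-inhibition Hill term (amplitude
#' `endo_gain * (mark_baseline - mark_depleted)`, midpoint `endogenous_ec50`)
#' when `endogenous_ec50` is finite. When `tc50` is finite a toxicity spike
#' `spike_gain * mark_baseline * (1 - survival(c))` is added to every cell and
#' the live-cell count scales by
#' `survival(c) = tc50^s / (c^s + tc50^s)` with slope `s = survival_hill`.
#'
#' @param ec50_cell Cellular EC50 (µM) against the overexpressed enzyme.
#' @param hill Hill slope of the mark response (unitless, > 0).
#' @param endogenous_ec50 EC50 (µM) against endogenous enzymes, or `NA` for a
#'   compound without measurable endogenous activity in the tested range.
#' @param endo_gain Amplitude of the endogenous-inhibition mark increase as a
#'   fraction of `mark_baseline - mark_depleted`.
#' @param tc50 Half-maximal cell-loss concentration (µM), or `NA` for a
#'   non-toxic compound.
#' @param survival_hill Hill slope of the survival curve (steep by default:
#'   cytotoxic compounds kill over a narrow concentration window).
#' @param spike_gain Methylation-spike amplitude as a fraction of
#'   `mark_baseline`, applied in proportion to the killed fraction.
#' @param mark_baseline Mark intensity (a.u.) of nontransfected cells.
#' @param mark_depleted Mark intensity (a.u.) of cells with fully active
#'   overexpressed enzyme; must be below `mark_baseline`.
#' @param noise_cv Per-cell multiplicative coefficient of variation.
#' @param flag_low,flag_high FLAG-channel log-normal mode centres (a.u.) for
#'   nontransfected and transfected cells.
#' @param flag_sigma_log Log-scale SD of each FLAG mode.
#' @param dapi_mean DAPI intensity centre (a.u.).
#' @param nucleus_radius_um Median nucleus radius (µm).
#'
#' @return An object of class `pharmacology_truth`.
#' @export
pharmacology_truth <- function(ec50_cell,
                               hill = 1,
                               endogenous_ec50 = NA_real_,
                               endo_gain = 1,
                               tc50 = NA_real_,
                               survival_hill = 8,
                               spike_gain = 1,
                               mark_baseline = 200,
                               mark_depleted = 40,
                               noise_cv = 0.15,
                               flag_low = 50,
                               flag_high = 1000,
                               flag_sigma_log = 0.35,
                               dapi_mean = 500,
                               nucleus_radius_um = 6.5) {
  stopifnot(length(ec50_cell) == 1)
  ec50_cell <- as.numeric(ec50_cell)  # NA or Inf = no measurable potency
  if (!is.na(ec50_cell) && ec50_cell <= 0) abort("`ec50_cell` must be > 0")
  if (hill <= 0) abort("`hill` must be > 0")
  if (!(mark_depleted >= 0 && mark_depleted < mark_baseline)) {
    abort("need 0 <= mark_depleted < mark_baseline")
  }
  if (noise_cv < 0) abort("`noise_cv` must be >= 0")
  if (spike_gain < 0) abort("`spike_gain` must be >= 0")
  if (!is.na(tc50) && tc50 <= 0) abort("`tc50` must be > 0 when given")
  structure(
    list(
      ec50_cell = ec50_cell, hill = hill,
      endogenous_ec50 = endogenous_ec50, endo_gain = endo_gain,
      tc50 = tc50, survival_hill = survival_hill, spike_gain = spike_gain,
      mark_baseline = mark_baseline, mark_depleted = mark_depleted,
      noise_cv = noise_cv,
      flag_low = flag_low, flag_high = flag_high,
      flag_sigma_log = flag_sigma_log,
      dapi_mean = dapi_mean, nucleus_radius_um = nucleus_radius_um
    ),
    class = "pharmacology_truth"
  )
}

#' @export
print.pharmacology_truth <- function(x, ...) {
  cat("<pharmacology_truth>\n")
  cat(sprintf("  ec50_cell: %s uM (hill %.2g)\n", format(x$ec50_cell), x$hill))
  cat(sprintf("  endogenous_ec50: %s uM  tc50: %s uM\n",
              format(x$endogenous_ec50), format(x$tc50)))
  cat(sprintf("  mark: baseline %.3g, depleted %.3g a.u.; noise_cv %.2g\n",
              x$mark_baseline, x$mark_depleted, x$noise_cv))
  invisible(x)
}

#' Plate specification for the synthetic-microscopy generator
#'
#' @param wells Data frame with one row per well and columns `well`,
#'   `compound`, `concentration` (µM, 0 = vehicle) and `construct`
#'   (`"WT"`, `"MUT"` or `"none"`).
#' @param fields_per_well Imaged fields per well.
#' @param field_shape Integer vector `c(rows, cols)` in pixels.
#' @param pixel_size Physical pixel size, µm/pixel.
#' @param transfection_fraction Fraction of cells receiving the construct in
#'   transfected wells.
#' @param cells_per_field_mean Mean number of plated cells per field (Poisson).
#' @param dilution_ratio Serial dilution ratio of the concentration series
#'   (2 or 3); the nonzero concentrations of each compound/construct series
#'   must form a geometric series with this ratio.
#' @param margin_um Margin (µm) kept between nucleus centres and the field
#'   edge; 0 lets nuclei be truncated by the border.
#' @param keep_condensed_dead If `TRUE`, dead cells are rendered as condensed
#'   small nuclei (below the 100 µm² filter) instead of being removed.
#' @param background_level,background_sd Additive Gaussian background of the
#'   rendered channels (a.u.).
#' @param seed Integer seed making the plate reproducible.
#'
#' @return An object of class `plate_spec`.
#' @export
plate_spec <- function(wells,
                       fields_per_well = 20,
                       field_shape = c(512, 512),
                       pixel_size = 0.65,
                       transfection_fraction = 0.3,
                       cells_per_field_mean = 300,
                       dilution_ratio = 2,
                       margin_um = 0,
                       keep_condensed_dead = FALSE,
                       background_level = 5,
                       background_sd = 2,
                       seed = 1L) {
  wells <- as_tibble(wells)
  req <- c("well", "compound", "concentration", "construct")
  missing_cols <- setdiff(req, names(wells))
  if (length(missing_cols)) {
    abort(paste0("`wells` lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(wells$concentration < 0)) abort("concentrations must be >= 0")
  if (!all(wells$construct %in% c("WT", "MUT", "none"))) {
    abort('`construct` must be one of "WT", "MUT", "none"')
  }
  if (transfection_fraction < 0 || transfection_fraction > 1) {
    abort("`transfection_fraction` must lie in [0, 1]")
  }
  if (pixel_size <= 0) abort("`pixel_size` must be > 0")
  if (!dilution_ratio %in% c(2, 3)) abort("`dilution_ratio` must be 2 or 3")
  check_geometric_series(wells, dilution_ratio)
  structure(
    list(
      wells = wells, fields_per_well = as.integer(fields_per_well),
      field_shape = as.integer(field_shape), pixel_size = pixel_size,
      transfection_fraction = transfection_fraction,
      cells_per_field_mean = cells_per_field_mean,
      dilution_ratio = dilution_ratio, margin_um = margin_um,
      keep_condensed_dead = keep_condensed_dead,
      background_level = background_level, background_sd = background_sd,
      seed = as.integer(seed)
    ),
    class = "plate_spec"
  )
}

#' @export
print.plate_spec <- function(x, ...) {
  cat("<plate_spec>\n")
  cat(sprintf("  %d wells x %d fields, %dx%d px at %.3g um/px\n",
              nrow(x$wells), x$fields_per_well, x$field_shape[1],
              x$field_shape[2], x$pixel_size))
  cat(sprintf("  ~%g cells/field, transfection %.2g, 1:%d dilution, seed %d\n",
              x$cells_per_field_mean, x$transfection_fraction,
              x$dilution_ratio, x$seed))
  invisible(x)
}

check_geometric_series <- function(wells, ratio, tol = 1e-6) {
  series <- dplyr::group_by(wells, .data$compound, .data$construct)
  keys <- dplyr::group_keys(series)
  concs <- dplyr::group_split(series)
  for (i in seq_along(concs)) {
    cc <- sort(unique(concs[[i]]$concentration))
    cc <- cc[cc > 0]
    if (length(cc) < 2) next
    r <- cc[-1] / cc[-length(cc)]
    if (any(abs(r - ratio) > tol * ratio)) {
      abort(sprintf(
        "nonzero concentrations for %s/%s are not a 1:%d geometric series",
        keys$compound[i], keys$construct[i], ratio
      ))
    }
  }
  invisible(TRUE)
}

#' Hill occupancy fraction
#'
#' `c^h / (c^h + ec50^h)`, the fractional effect at concentration `c` of a
#' Hill curve with midpoint `ec50` and slope `h`. Zero at `c = 0`.
#'
#' @param conc Concentration(s), µM.
#' @param ec50 Midpoint, µM.
#' @param hill Slope.
#' @return Numeric vector in `[0, 1)`.
#' @export
hill_fraction <- function(conc, ec50, hill = 1) {
  if (is.na(ec50) || !is.finite(ec50)) return(rep(0, length(conc)))
  ifelse(conc <= 0, 0, conc^hill / (conc^hill + ec50^hill))
}

#' Surviving fraction of cells at an inhibitor concentration
#'
#' `tc50^s / (c^s + tc50^s)`; equals 1 everywhere when `tc50` is `NA`
#' (non-toxic compound).
#'
#' @param conc Concentration(s), µM.
#' @param truth A [pharmacology_truth()].
#' @return Numeric vector in `(0, 1]`.
#' @export
survival_fraction <- function(conc, truth) {
  if (is.na(truth$tc50)) return(rep(1, length(conc)))
  1 - hill_fraction(conc, truth$tc50, truth$survival_hill)
}

#' Closed-form expected mark intensity for a simulated cell
#'
#' The noiseless expectation of the histone-mark stain for a cell of the given
#' construct/transfection state at concentration `conc` (see
#' [pharmacology_truth()] for the model).
#'
#' @param truth A [pharmacology_truth()].
#' @param conc Concentration(s), µM.
#' @param construct `"WT"`, `"MUT"` or `"none"`.
#' @param transfected Whether the cell carries the construct (always `FALSE`
#'   for construct `"none"`).
#' @return Expected mark intensity (a.u.), vectorized over `conc`.
#' @export
expected_mark <- function(truth, conc, construct, transfected = construct != "none") {
  construct <- match.arg(construct, c("WT", "MUT", "none"))
  if (construct == "none") transfected <- FALSE
  base <- truth$mark_baseline
  depl <- truth$mark_depleted
  if (construct == "WT" && transfected) {
    m <- depl + (base - depl) * hill_fraction(conc, truth$ec50_cell, truth$hill)
  } else {
    m <- rep(base, length(conc))
    if (!is.na(truth$endogenous_ec50)) {
      m <- m + truth$endo_gain * (base - depl) *
        hill_fraction(conc, truth$endogenous_ec50, truth$hill)
    }
  }
  if (!is.na(truth$tc50)) {
    m <- m + truth$spike_gain * base * (1 - survival_fraction(conc, truth))
  }
  m
}
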