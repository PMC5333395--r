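#' Simulate the per-cell ground truth of a dose-response plate
#'
#' Draws cell populations for every well of `spec` under the pharmacological
#' model in `truth`: Poisson cell numbers per field, monolayer (jittered-grid,
#' mutually excluding) nucleus placement, Bernoulli transfection
#' (for WT/MUT wells), Bernoulli survival at the well concentration, and
#' per-cell mark/FLAG/DAPI intensities with mean-preserving multiplicative
#' log-normal noise. The result is the ground-truth ledger used both to render
#' fields ([render_field()]) and to validate recovery by the analysis modules.
#'
#' Dead cells are retained in the ledger with `alive = FALSE`; whether they
#' appear in rendered images is controlled by `spec$keep_condensed_dead`
#' (condensed nuclei below the size filter) — otherwise they are absent from
#' the rendered field, matching a survival readout based on remaining nuclei.
#'
#' @param truth A [pharmacology_truth()].
#' @param spec A [plate_spec()]; `spec$seed` makes the draw reproducible.
#' @return A tibble with one row per plated cell: well metadata
#'   (`well`, `compound`, `concentration`, `construct`), `field`, `cell`,
#'   centre (`cx`, `cy`, 0-based pixel coordinates), `radius_um`,
#'   `eccentricity`, `theta`, `transfected`, `alive`, `condensed`, and true
#'   intensities `true_mark`, `true_flag`, `true_dapi` (a.u.).
#' @export
simulate_dose_series <- function(truth, spec) {
  stopifnot(inherits(truth, "pharmacology_truth"), inherits(spec, "plate_spec"))
  withr::with_seed(spec$seed, simulate_dose_series_impl(truth, spec))
}

simulate_dose_series_impl <- function(truth, spec) {
  wells <- spec$wells
  per_field <- tidyr::crossing(wells, field = seq_len(spec$fields_per_well))
  n_cells <- rpois(nrow(per_field), spec$cells_per_field_mean)
  cells <- per_field[rep(seq_len(nrow(per_field)), n_cells), ]
  cells <- dplyr::group_by(cells, .data$well, .data$field)
  cells <- dplyr::mutate(cells, cell = dplyr::row_number())
  cells <- dplyr::ungroup(cells)

  n <- nrow(cells)
  dims <- spec$field_shape
  margin_px <- spec$margin_um / spec$pixel_size
  # monolayer placement: nuclei exclude each other, so each field's cells sit
  # on a jittered grid with pitch ~2.2 nuclear radii instead of overlapping
  # freely (free overlap would contaminate per-nucleus intensities in a way
  # an adherent monolayer never does)
  cells$cx <- numeric(n)
  cells$cy <- numeric(n)
  grp <- factor(paste(cells$well, cells$field),
                levels = unique(paste(cells$well, cells$field)))
  for (idx in split(seq_len(n), grp)) {
    pos <- place_monolayer(length(idx), dims, margin_px,
                           truth$nucleus_radius_um / spec$pixel_size)
    cells$cx[idx] <- pos$cx
    cells$cy[idx] <- pos$cy
  }
  cells$radius_um <- truth$nucleus_radius_um * exp(rnorm(n, 0, 0.08))
  cells$eccentricity <- runif(n, 0, 0.15)
  cells$theta <- runif(n, 0, pi)
  cells$transfected <- cells$construct != "none" &
    runif(n) < spec$transfection_fraction
  surv <- survival_fraction(cells$concentration, truth)
  cells$alive <- runif(n) < surv
  cells$condensed <- !cells$alive
  cells$radius_um[cells$condensed] <- 3 * exp(rnorm(sum(cells$condensed), 0, 0.08))

  mu <- numeric(n)
  wt <- cells$construct == "WT" & cells$transfected
  for (grp in list(
    list(idx = wt, construct = "WT", transfected = TRUE),
    list(idx = !wt & cells$construct == "MUT" & cells$transfected,
         construct = "MUT", transfected = TRUE),
    list(idx = !cells$transfected, construct = "none", transfected = FALSE)
  )) {
    if (any(grp$idx)) {
      mu[grp$idx] <- expected_mark(truth, cells$concentration[grp$idx],
                                   grp$construct, grp$transfected)
    }
  }
  # nontransfected cells inside WT/MUT wells follow the construct-free model
  cells$true_mark <- mu * lognormal_noise(n, truth$noise_cv)
  flag_mode <- ifelse(cells$transfected, truth$flag_high, truth$flag_low)
  cells$true_flag <- flag_mode *
    exp(rnorm(n, -truth$flag_sigma_log^2 / 2, truth$flag_sigma_log))
  cells$true_dapi <- truth$dapi_mean * lognormal_noise(n, 0.2)
  as_tibble(cells)
}

# Jittered-grid positions for one field: grid pitch 2.2 nuclear radii (a
# dense adherent monolayer), random phase, sites sampled without replacement,
# small jitter. Guarantees near-non-overlapping nuclei while still producing
# touching pairs for the watershed to split. Overflow beyond the number of
# grid sites falls back to uniform placement for the excess cells.
place_monolayer <- function(k, dims, margin_px, radius_px) {
  if (k == 0) return(list(cx = numeric(0), cy = numeric(0)))
  pitch <- 2.2 * radius_px
  lo_x <- margin_px; hi_x <- dims[2] - 1 - margin_px
  lo_y <- margin_px; hi_y <- dims[1] - 1 - margin_px
  nx <- max(1, floor((hi_x - lo_x) / pitch))
  ny <- max(1, floor((hi_y - lo_y) / pitch))
  phase_x <- runif(1, 0, pitch)
  phase_y <- runif(1, 0, pitch)
  gx <- lo_x + phase_x + (seq_len(nx) - 1) * pitch
  gy <- lo_y + phase_y + (seq_len(ny) - 1) * pitch
  gx <- gx[gx <= hi_x]; gy <- gy[gy <= hi_y]
  sites <- expand.grid(cx = gx, cy = gy)
  m <- min(k, nrow(sites))
  pick <- sites[sample.int(nrow(sites), m), , drop = FALSE]
  jitter <- 0.05 * pitch
  cx <- pick$cx + runif(m, -jitter, jitter)
  cy <- pick$cy + runif(m, -jitter, jitter)
  if (k > m) {  # more cells than monolayer sites: overflow placed uniformly
    cx <- c(cx, runif(k - m, lo_x, hi_x))
    cy <- c(cy, runif(k - m, lo_y, hi_y))
  }
  list(cx = cx, cy = cy)
}

#' Simulate a triple-stain (Hoechst / Annexin V / Yo-Pro 3) cell table
#'
#' Draws per-cell stain intensities from a three-class mixture emulating the
#' live-cell death assay: healthy cells are low in both Annexin V and
#' Yo-Pro 3; apoptotic cells are Annexin V-high with Yo-Pro 3 high or low with
#' equal probability (early/late apoptosis); necrotic cells are Yo-Pro 3-high,
#' Annexin V-low. "High" and "low" are log-normal components whose log-scale
#' centres differ by `separability` standard deviations.
#'
#' @param fractions Numeric length-3 vector `(healthy, apoptotic, necrotic)`,
#'   non-negative, summing to 1 (within 1e-9).
#' @param n_cells Number of cells to draw.
#' @param separability Separation of the high and low log-normal components in
#'   units of their common log-scale SD.
#' @param seed Integer seed.
#' @param low_mode Centre of the "low" component (a.u.).
#' @param sigma_log Common log-scale SD of the components.
#' @return A tibble with columns `cell`, `well`, `hoechst`, `annexin`,
#'   `yopro` and the ground-truth label `true_class`
#'   (factor healthy/apoptotic/necrotic).
#' @export
simulate_triple_stain <- function(fractions, n_cells, separability = 4,
                                  seed = 1L, low_mode = 100, sigma_log = 0.35) {
  if (length(fractions) != 3 || any(fractions < 0)) {
    abort("`fractions` must be 3 non-negative numbers (healthy, apoptotic, necrotic)")
  }
  if (abs(sum(fractions) - 1) > 1e-9) abort("`fractions` must sum to 1")
  if (n_cells < 1) abort("`n_cells` must be >= 1")
  classes <- c("healthy", "apoptotic", "necrotic")
  withr::with_seed(as.integer(seed), {
    lab <- sample(classes, n_cells, replace = TRUE, prob = fractions)
    high_shift <- separability * sigma_log
    draw <- function(n, high) {
      exp(log(low_mode) + ifelse(high, high_shift, 0) + rnorm(n, 0, sigma_log))
    }
    annexin_high <- lab == "apoptotic"
    yopro_high <- lab == "necrotic" |
      (lab == "apoptotic" & runif(n_cells) < 0.5)
    tibble(
      cell = seq_len(n_cells),
      well = "A01",
      hoechst = draw(n_cells, TRUE),
      annexin = draw(n_cells, annexin_high),
      yopro = draw(n_cells, yopro_high),
      true_class = factor(lab, levels = classes)
    )
  })
}
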