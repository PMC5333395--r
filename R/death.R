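#' Calibrate Annexin V / Yo-Pro 3 positivity thresholds
#'
#' Default method (`"gmm"`): fit a two-component Gaussian mixture to the log
#' intensities of each channel and place the cut where the two weighted
#' component densities cross — the decision boundary that accounts for
#' unequal negative/positive class sizes. `"otsu"` (maximum between-class
#' variance on log intensity) is retained as a simpler alternative; it
#' assumes a roughly balanced mixture and drifts into the majority mode when
#' one class is rare. `"reference"`: vehicle-well (healthy control) mean +
#' `k` SD per channel, computed on the log scale (fluorescence intensities
#' are approximately log-normal, so the linear-scale rule would call the
#' skewed upper tail positive far more often than the nominal level).
#'
#' @param records Per-cell stain tibble with `annexin` and `yopro` columns
#'   (e.g. from [simulate_triple_stain()]).
#' @param method `"gmm"`, `"otsu"` or `"reference"`.
#' @param reference Control-cell tibble for the reference method (defaults to
#'   `records`, i.e. assumes the input is a healthy control well).
#' @param k SD multiplier for the reference method.
#' @return A list of class `positivity_thresholds` with `annexin_cut`,
#'   `yopro_cut` (a.u.) and `method`.
#' @export
calibrate_positivity <- function(records, method = c("gmm", "otsu", "reference"),
                                 reference = NULL, k = 3) {
  method <- match.arg(method)
  if (nrow(records) < 100) {
    warn(sprintf("only %d cells for threshold calibration (< 100)", nrow(records)))
  }
  cut_for <- function(col) {
    x <- records[[col]]
    x <- x[is.finite(x) & x > 0]
    if (method %in% c("gmm", "otsu")) {
      if (length(unique(x)) < 2) {
        abort(sprintf("channel '%s' is degenerate (constant)", col))
      }
      cut <- if (method == "gmm") gmm_cut_1d(log(x)) else otsu_1d(log(x))
      exp(cut)
    } else {
      r <- if (is.null(reference)) records[[col]] else reference[[col]]
      r <- r[is.finite(r) & r > 0]
      if (sd(r) == 0) abort(sprintf("channel '%s' is degenerate (constant)", col))
      # fluorescence intensities are ~log-normal: cut k SDs above the control
      # mean on the log scale, so the control tail beyond it stays ~Phi(-k)
      exp(mean(log(r)) + k * sd(log(r)))
    }
  }
  structure(
    list(annexin_cut = cut_for("annexin"), yopro_cut = cut_for("yopro"),
         method = method),
    class = "positivity_thresholds"
  )
}

# Two-component Gaussian-mixture decision boundary on a numeric vector:
# the point between the component means where the weighted densities cross.
gmm_cut_1d <- function(x) {
  mclustBIC <- mclust::mclustBIC  # Mclust() resolves this in the caller
  fit <- tryCatch(
    mclust::Mclust(x, G = 2, modelNames = c("E", "V"), verbose = FALSE),
    error = function(e) NULL
  )
  if (is.null(fit)) return(otsu_1d(x))
  mu <- fit$parameters$mean
  sig <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sig) == 1) sig <- rep(sig, 2)
  pro <- fit$parameters$pro
  ord <- order(mu)
  mu <- mu[ord]; sig <- sig[ord]; pro <- pro[ord]
  if (diff(mu) < .Machine$double.eps) return(otsu_1d(x))
  f <- function(t) {
    log(pro[1]) + stats::dnorm(t, mu[1], sig[1], log = TRUE) -
      log(pro[2]) - stats::dnorm(t, mu[2], sig[2], log = TRUE)
  }
  root <- tryCatch(stats::uniroot(f, lower = mu[1], upper = mu[2])$root,
                   error = function(e) NA_real_)
  if (is.finite(root)) root else mean(mu)
}

#' @export
print.positivity_thresholds <- function(x, ...) {
  cat(sprintf("<positivity_thresholds> (%s) annexin >= %.4g, yopro >= %.4g a.u.\n",
              x$method, x$annexin_cut, x$yopro_cut))
  invisible(x)
}

#' Classify cells as healthy, apoptotic or necrotic
#'
#' Applies the triple-stain rule as an ordered rule list: Annexin V-positive
#' cells are apoptotic regardless of Yo-Pro 3 status (early or late
#' apoptosis); otherwise Yo-Pro 3-positive cells are necrotic; remaining
#' (double-negative) cells are healthy. Hoechst serves only to identify the
#' cells, not for classification. The precedence makes the partition
#' exhaustive and exclusive.
#'
#' @param records Per-cell stain tibble with `annexin` and `yopro` columns.
#' @param thr A [calibrate_positivity()] result (thresholds on the same
#'   intensity scale as `records`).
#' @return `records` with a `class` factor column
#'   (healthy/apoptotic/necrotic) appended.
#' @export
classify_death <- function(records, thr) {
  stopifnot(inherits(thr, "positivity_thresholds"))
  cls <- ifelse(records$annexin >= thr$annexin_cut, "apoptotic",
                ifelse(records$yopro >= thr$yopro_cut, "necrotic", "healthy"))
  dplyr::mutate(as_tibble(records),
                class = factor(cls, levels = c("healthy", "apoptotic", "necrotic")))
}

#' Summarize death-classification percentages per well
#'
#' Counts and percentages of healthy/apoptotic/necrotic cells per well, with
#' optional percentile-bootstrap confidence intervals obtained by resampling
#' cells within each well.
#'
#' @param records Per-cell stain tibble.
#' @param thr A [calibrate_positivity()] result (ignored if `records` already
#'   has a `class` column).
#' @param by Grouping column (default `"well"`).
#' @param bootstrap Number of bootstrap resamples for percentage CIs
#'   (0 = none).
#' @param conf_level Bootstrap CI level.
#' @param seed Seed for the bootstrap resampling.
#' @return A tibble with one row per group and class: `n`, `percent`, and
#'   (with `bootstrap > 0`) `percent_low`, `percent_high`; plus `n_cells` per
#'   group.
#' @export
summarize_death <- function(records, thr = NULL, by = "well",
                            bootstrap = 0, conf_level = 0.95, seed = 1L) {
  if (!nrow(records)) abort("no cells to summarize")
  if (!"class" %in% names(records)) {
    if (is.null(thr)) abort("supply `thr` or a pre-classified `class` column")
    records <- classify_death(records, thr)
  }
  classes <- c("healthy", "apoptotic", "necrotic")
  tally <- function(cls) {
    counts <- table(factor(cls, levels = classes))
    tibble(class = classes, n = as.integer(counts),
           percent = 100 * as.integer(counts) / length(cls),
           n_cells = length(cls))
  }
  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::reframe(tally(.data$class))
  if (bootstrap > 0) {
    alpha <- (1 - conf_level) / 2
    boots <- withr::with_seed(as.integer(seed), {
      records |>
        dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
        dplyr::reframe({
          cls <- .data$class
          reps <- replicate(bootstrap, {
            100 * tabulate(sample(as.integer(cls), replace = TRUE),
                           length(classes)) / length(cls)
          })
          tibble(class = classes,
                 percent_low = apply(reps, 1, quantile, alpha),
                 percent_high = apply(reps, 1, quantile, 1 - alpha))
        })
    })
    out <- dplyr::left_join(out, boots, by = c(by, "class"))
  }
  out
}
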