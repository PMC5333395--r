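#' Fit a four-parameter logistic dose-response curve
#'
#' Unweighted least-squares fit of
#' \deqn{y = bottom + \frac{top - bottom}{1 + 10^{\,hill\,(\log_{10} EC_{50} - \log_{10} c)}}}
#' to (concentration, response) points on the log10-concentration axis, with
#' multi-start initialization over Hill slopes \{0.5, 1, 2\} (both signs) and
#' EC50 starts at the dose-grid quartiles. The vehicle point (`conc == 0`)
#' is excluded from the fit; it only informs baselines downstream. The fit is
#' orientation-normalized so `bottom <= top` (the Hill slope keeps the sign
#' of the response direction along concentration). A series whose 4PL does
#' not beat a constant fit (F test at 0.05) is reported as not converged with
#' `flat = TRUE` instead of returning parameters fitted to noise.
#'
#' @param data Data frame of well measurements.
#' @param conc,response Column names of concentration (µM) and response.
#' @param exclude_top_dose Drop the highest concentration before fitting
#'   (used when the top dose is contaminated, e.g. by a toxicity spike).
#' @param ci Compute a profile-likelihood 95% CI on log10 EC50 (falls back to
#'   the asymptotic Wald interval when profiling fails).
#' @return An object of class `fourpl_fit`: estimates (`bottom`, `top`,
#'   `ec50`, `hill`), standard errors, convergence flag, `points_used`,
#'   residual SD, the fitted data, and `ec50_ci` (µM) with its method.
#' @export
fit_4pl <- function(data, conc = "concentration", response = "mean_mark",
                    exclude_top_dose = FALSE, ci = TRUE) {
  d <- tibble(conc = data[[conc]], y = data[[response]])
  d <- d[is.finite(d$conc) & is.finite(d$y), ]
  d <- d[d$conc > 0, ]
  if (exclude_top_dose && nrow(d)) d <- d[d$conc < max(d$conc), ]
  if (dplyr::n_distinct(d$conc) < 4) {
    abort("need >= 4 distinct nonzero concentrations to fit a 4PL")
  }
  failed <- function(flat = FALSE) structure(
    list(bottom = NA_real_, top = NA_real_, ec50 = NA_real_, hill = NA_real_,
         se = c(bottom = NA_real_, top = NA_real_, log10_ec50 = NA_real_,
                hill = NA_real_),
         converged = FALSE, flat = flat, points_used = nrow(d),
         sigma = NA_real_, data = d, conc_range = range(d$conc),
         ec50_ci = c(NA_real_, NA_real_), ci_method = "none"),
    class = "fourpl_fit"
  )
  if (sd(d$y) < 1e-12 * max(abs(d$y), 1)) return(failed(flat = TRUE))

  d$lc <- log10(d$conc)
  starts <- tidyr::crossing(
    hill = c(0.5, 1, 2, -0.5, -1, -2),
    lec50 = log10(unname(quantile(unique(d$conc), c(0.25, 0.5, 0.75))))
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^(hill * (lec50 - lc))),
        data = d,
        start = list(bottom = min(d$y), top = max(d$y),
                     hill = starts$hill[i], lec50 = starts$lec50[i]),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(failed())
  # flat-response guard: the 4PL must beat a constant fit (F test), otherwise
  # report no convergence rather than parameters fitted to noise
  df2 <- nrow(d) - 4
  if (df2 >= 1) {
    rss0 <- sum((d$y - mean(d$y))^2)
    f_stat <- ((rss0 - best$rss) / 3) / (best$rss / df2)
    p_flat <- if (is.finite(f_stat)) {
      stats::pf(f_stat, 3, df2, lower.tail = FALSE)
    } else 0  # RSS of 0: the curve explains the data perfectly
    if (p_flat > 0.05) return(failed(flat = TRUE))
  }
  fit <- best$fit
  cf <- coef(fit)
  # orientation normalization: represent the same curve with bottom <= top
  if (cf["bottom"] > cf["top"]) {
    cf[c("bottom", "top")] <- cf[c("top", "bottom")]
    cf["hill"] <- -cf["hill"]
  }
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 4))
  names(se) <- names(coef(fit))
  if (!is.finite(cf["lec50"])) return(failed)
  out <- structure(
    list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
         ec50 = unname(10^cf["lec50"]), hill = unname(cf["hill"]),
         se = c(bottom = unname(se["bottom"]), top = unname(se["top"]),
                log10_ec50 = unname(se["lec50"]), hill = unname(se["hill"])),
         converged = TRUE, flat = FALSE, points_used = nrow(d),
         sigma = sqrt(best$rss / max(nrow(d) - 4, 1)),
         data = d, conc_range = range(d$conc),
         ec50_ci = c(NA_real_, NA_real_), ci_method = "none"),
    class = "fourpl_fit"
  )
  if (ci) {
    prof <- profile_ec50_ci(d, out)
    out$ec50_ci <- prof$ci
    out$ci_method <- prof$method
  }
  out
}

# 95% CI on log10 EC50: profile the RSS over a fixed-lec50 grid, refitting the
# remaining three parameters, and invert the F test; Wald fallback.
profile_ec50_ci <- function(d, fit) {
  wald <- function() {
    se <- fit$se[["log10_ec50"]]
    if (!is.finite(se)) return(list(ci = c(NA_real_, NA_real_), method = "none"))
    list(ci = 10^(log10(fit$ec50) + c(-1.96, 1.96) * se), method = "asymptotic")
  }
  df <- fit$points_used - 4
  if (df < 1) return(wald())
  rss0 <- fit$sigma^2 * df
  cut <- rss0 * (1 + qf(0.95, 1, df) / df)
  half_width <- max(3 * (fit$se[["log10_ec50"]] %||% 0.5), 0.5, na.rm = TRUE)
  grid <- log10(fit$ec50) + seq(-half_width, half_width, length.out = 41)
  rss <- vapply(grid, function(l0) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^(hill * (l0 - lc))),
        data = d,
        start = list(bottom = fit$bottom, top = fit$top, hill = fit$hill),
        control = minpack.lm::nls.lm.control(maxiter = 100)
      ),
      error = function(e) NULL
    )
    if (is.null(f)) NA_real_ else sum(residuals(f)^2)
  }, numeric(1))
  if (mean(is.finite(rss)) < 0.8) return(wald())
  inside <- is.finite(rss) & rss <= cut
  if (!any(inside)) return(wald())
  lo <- grid[which(inside)[1]]
  hi <- grid[rev(which(inside))[1]]
  list(ci = 10^c(lo, hi), method = "profile")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<fourpl_fit> not converged\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<fourpl_fit> ec50 %.4g uM (hill %.3g), bottom %.4g, top %.4g; %d points\n",
    x$ec50, x$hill, x$bottom, x$top, x$points_used))
  if (x$ci_method != "none") {
    cat(sprintf("  95%% CI on ec50: [%.4g, %.4g] uM (%s)\n",
                x$ec50_ci[1], x$ec50_ci[2], x$ci_method))
  }
  invisible(x)
}

#' Predict the 4PL response at given concentrations
#' @param object A `fourpl_fit`.
#' @param conc Concentrations (µM); the vehicle (0) maps to the curve's
#'   zero-dose asymptote.
#' @param ... Unused.
#' @export
predict.fourpl_fit <- function(object, conc, ...) {
  if (!object$converged) return(rep(NA_real_, length(conc)))
  lc <- log10(pmax(conc, .Machine$double.xmin))
  y <- object$bottom + (object$top - object$bottom) /
    (1 + 10^(object$hill * (log10(object$ec50) - lc)))
  # zero-dose limit: bottom for rising curves (hill > 0), top for falling
  y[conc <= 0] <- if (object$hill >= 0) object$bottom else object$top
  y
}

#' @export
tidy.fourpl_fit <- function(x, ...) {
  tibble(
    term = c("bottom", "top", "ec50", "hill"),
    estimate = c(x$bottom, x$top, x$ec50, x$hill),
    std.error = c(x$se[["bottom"]], x$se[["top"]],
                  if (x$converged) x$ec50 * log(10) * x$se[["log10_ec50"]] else NA_real_,
                  x$se[["hill"]])
  )
}

#' @export
glance.fourpl_fit <- function(x, ...) {
  tibble(
    ec50 = x$ec50, hill = x$hill, bottom = x$bottom, top = x$top,
    ec50_ci_low = x$ec50_ci[1], ec50_ci_high = x$ec50_ci[2],
    sigma = x$sigma, points_used = x$points_used, converged = x$converged
  )
}

#' Compare a wild-type fit to the inactive-mutant baseline
#'
#' Normalizes the wild-type (WT) dose-response to the catalytically inactive
#' mutant (MUT) vehicle level, which approximates complete inhibition of the
#' overexpressed enzyme: engagement is complete when the WT curve plateaus at
#' the MUT baseline. Reports the fitted EC50 with a qualifier: `"exact"`;
#' `"greater_than_top_conc"` when the fitted EC50 exceeds the tested range,
#' or when the series is flat with no observed engagement (an inactive
#' compound's potency is reported as beyond the top tested concentration,
#' e.g. "> 100 µM"); `"not_converged"` for genuine fit failures. Also runs
#' the toxicity-spike detector on the MUT series when it carries cell
#' counts.
#'
#' @param wt_fit A `fourpl_fit` of the WT series.
#' @param wt_series,mut_series Well-measurement tibbles (as from
#'   [quantify_wells()]) for the matched WT and MUT series, each including a
#'   vehicle (concentration 0) point.
#' @param response Response column name.
#' @param z_crit,drop_frac Passed to [detect_toxicity_spike()].
#' @return An object of class `engagement_result`: `ec50`, `ec50_ci`,
#'   `qualifier`, `mut_baseline`, `wt_vehicle`, `max_inhibition_fraction`,
#'   `full_engagement` (fraction >= 0.9) and `toxicity`.
#' @export
compute_engagement <- function(wt_fit, wt_series, mut_series,
                               response = "mean_mark",
                               z_crit = 3, drop_frac = 0.5) {
  stopifnot(inherits(wt_fit, "fourpl_fit"))
  mut_vehicle <- mut_series[mut_series$concentration == 0, ]
  if (!nrow(mut_vehicle)) abort("`mut_series` has no vehicle (concentration 0) point")
  mut_baseline <- mean(mut_vehicle[[response]], na.rm = TRUE)
  wt_vehicle_rows <- wt_series[wt_series$concentration == 0, ]
  wt_vehicle <- if (nrow(wt_vehicle_rows)) {
    mean(wt_vehicle_rows[[response]], na.rm = TRUE)
  } else if (wt_fit$converged) wt_fit$bottom else NA_real_
  if (is.finite(mut_baseline) && is.finite(wt_vehicle) &&
      mut_baseline <= wt_vehicle) {
    warn("MUT baseline does not exceed the WT vehicle level (inverted assay polarity?)")
  }
  wt_top_response <- if (wt_fit$converged) wt_fit$top else NA_real_
  max_inhibition_fraction <-
    (wt_top_response - wt_vehicle) / (mut_baseline - wt_vehicle)
  # observed engagement at any tested dose, used to distinguish "inactive in
  # the tested range" (EC50 beyond the top concentration) from a fit failure
  obs <- wt_series[wt_series$concentration > 0, ]
  obs_fraction <- if (nrow(obs)) {
    (max(obs[[response]], na.rm = TRUE) - wt_vehicle) /
      (mut_baseline - wt_vehicle)
  } else NA_real_
  qualifier <- if (wt_fit$converged) {
    if (wt_fit$ec50 > max(wt_fit$conc_range)) "greater_than_top_conc" else "exact"
  } else if (isTRUE(wt_fit$flat) ||
             (is.finite(obs_fraction) && obs_fraction < 0.25)) {
    "greater_than_top_conc"
  } else {
    "not_converged"
  }
  toxicity <- if ("n_cells_total" %in% names(mut_series) &&
                  any(mut_series$concentration == 0)) {
    tryCatch(
      detect_toxicity_spike(mut_series, wt_series, response = response,
                            z_crit = z_crit, drop_frac = drop_frac),
      error = function(e) NULL
    )
  }
  structure(
    list(ec50 = wt_fit$ec50, ec50_ci = wt_fit$ec50_ci, qualifier = qualifier,
         top_concentration = max(wt_fit$conc_range),
         mut_baseline = mut_baseline, wt_vehicle = wt_vehicle,
         max_inhibition_fraction = max_inhibition_fraction,
         full_engagement = isTRUE(max_inhibition_fraction >= 0.9),
         toxicity = toxicity, wt_fit = wt_fit),
    class = "engagement_result"
  )
}

#' @export
print.engagement_result <- function(x, ...) {
  ec50_txt <- switch(x$qualifier,
    exact = sprintf("%.4g uM", x$ec50),
    greater_than_top_conc = sprintf("> %.4g uM (top tested)", x$top_concentration),
    not_converged = "not converged"
  )
  cat(sprintf("<engagement_result> EC50 %s; max inhibition %.2f of MUT baseline\n",
              ec50_txt, x$max_inhibition_fraction))
  if (!is.null(x$toxicity) && x$toxicity$flagged) {
    cat(sprintf("  cytotoxicity signature at >= %.4g uM\n",
                x$toxicity$onset_concentration))
  }
  invisible(x)
}

#' @export
glance.engagement_result <- function(x, ...) {
  tibble(
    ec50 = x$ec50, ec50_ci_low = x$ec50_ci[1], ec50_ci_high = x$ec50_ci[2],
    qualifier = x$qualifier, mut_baseline = x$mut_baseline,
    max_inhibition_fraction = x$max_inhibition_fraction,
    full_engagement = x$full_engagement,
    toxicity_flagged = !is.null(x$toxicity) && x$toxicity$flagged
  )
}

#' Detect the cytotoxicity signature: methylation spike plus cell-count drop
#'
#' A compound is flagged cytotoxic when, at some common concentration, the
#' MUT-well mark intensity rises more than `z_crit` vehicle SDs above the MUT
#' vehicle mean *and* the total nucleus count falls below `drop_frac` of the
#' vehicle count. A mark rise without the count drop is reported as
#' endogenous/off-target demethylase inhibition, not toxicity (the pattern of
#' active-but-non-toxic compounds).
#'
#' @param mut_series Well-measurement tibble for the MUT (or nontransfected)
#'   series: `concentration`, the response column, `sd_mark`,
#'   `n_cells_total`. Must include a vehicle (concentration 0) row.
#' @param wt_series Optional matched WT series (unused by the rule but kept
#'   for provenance).
#' @param response Response column name.
#' @param z_crit Spike threshold in vehicle SD units.
#' @param drop_frac Count-drop threshold as a fraction of the vehicle count.
#' @return A list of class `toxicity_spike`: `flagged`,
#'   `onset_concentration`, `mut_elevation_z`, `count_drop_fraction`,
#'   `pattern` (`"toxicity"`, `"endogenous_activity"` or `"none"`) and the
#'   per-concentration diagnostic table.
#' @export
detect_toxicity_spike <- function(mut_series, wt_series = NULL,
                                  response = "mean_mark",
                                  z_crit = 3, drop_frac = 0.5) {
  vehicle <- mut_series[mut_series$concentration == 0, ]
  if (!nrow(vehicle)) abort("missing vehicle (concentration 0) point")
  m0 <- mean(vehicle[[response]], na.rm = TRUE)
  s0 <- mean(vehicle$sd_mark, na.rm = TRUE)
  n0 <- mean(vehicle$n_cells_total, na.rm = TRUE)
  d <- mut_series[mut_series$concentration > 0, ]
  d <- d[order(d$concentration), ]
  diag_tbl <- tibble(
    concentration = d$concentration,
    elevation_z = (d[[response]] - m0) / s0,
    count_fraction = d$n_cells_total / n0
  )
  spike <- diag_tbl$elevation_z > z_crit
  drop <- diag_tbl$count_fraction < drop_frac
  both <- spike & drop & is.finite(diag_tbl$elevation_z)
  flagged <- any(both, na.rm = TRUE)
  onset <- if (flagged) min(diag_tbl$concentration[both]) else NA_real_
  pattern <- if (flagged) {
    "toxicity"
  } else if (any(spike, na.rm = TRUE)) "endogenous_activity" else "none"
  at_onset <- if (flagged) which(diag_tbl$concentration == onset)[1] else which.max(diag_tbl$elevation_z)
  structure(
    list(flagged = flagged, onset_concentration = onset,
         mut_elevation_z = diag_tbl$elevation_z[at_onset],
         count_drop_fraction = diag_tbl$count_fraction[at_onset],
         pattern = pattern, z_crit = z_crit, drop_frac = drop_frac,
         table = diag_tbl),
    class = "toxicity_spike"
  )
}

#' @export
print.toxicity_spike <- function(x, ...) {
  cat(sprintf("<toxicity_spike> %s", x$pattern))
  if (x$flagged) {
    cat(sprintf(": onset %.4g uM (z = %.2f, counts at %.2f of vehicle)",
                x$onset_concentration, x$mut_elevation_z,
                x$count_drop_fraction))
  }
  cat("\n")
  invisible(x)
}
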