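#' IC50 predicted by the competitive-inhibition model
#'
#' For an inhibitor competitive with the 2-oxoglutarate (2-OG) co-substrate,
#' the apparent IC50 rises linearly with the co-substrate concentration
#' (Cheng-Prusoff): \deqn{IC_{50}(S) = K_i \left(1 + S / K_m\right)} with
#' `Ki` the inhibition constant and `Km` the apparent Michaelis constant of
#' the enzyme for 2-OG.
#'
#' @param fit A `competitive_fit` (or any list with `ki` and `km_og`, µM).
#' @param s 2-OG concentration(s), µM (>= 0).
#' @return Predicted IC50(s), µM; strictly increasing and linear in `s`.
#' @export
ic50_at <- function(fit, s) {
  if (any(s < 0)) abort("`s` must be >= 0")
  fit$ki * (1 + s / fit$km_og)
}

#' Fit the competitive model to an IC50-versus-2-OG series
#'
#' Weighted linear regression of IC50 on the 2-OG concentration: the
#' intercept estimates `Ki` and `intercept/slope` the apparent `Km` for
#' 2-OG. IC50 series from dose-response fits carry roughly constant
#' *relative* error, so the default weights are 1/IC50²; with them the small-
#' IC50 (low 2-OG) points that determine the intercept are not swamped by
#' the absolute scatter of the high-2-OG points. A fitted
#' intercept or slope that is not positive is rejected with a diagnostic
#' (non-competitive behaviour). For heteroscedastic series a nonlinear refit
#' of `log(IC50)` against the same model is available, which weights the
#' relative rather than absolute error.
#'
#' @param series Data frame of `(s, ic50)` pairs, µM; needs >= 3 distinct
#'   2-OG concentrations.
#' @param s,ic50 Column names.
#' @param weights `"inverse_ic50sq"` (default; weights 1/IC50², matching
#'   constant relative error) or `"none"` (ordinary least squares).
#' @param refit_log Refit on the log-IC50 scale with [minpack.lm::nlsLM()],
#'   initialized at the linear estimates.
#' @return An object of class `competitive_fit`: `ki`, `km_og` (µM),
#'   standard errors (`se`, delta-method for `km_og`), `residual_norm`, the
#'   data, and the fitting choices.
#' @export
fit_competition <- function(series, s = "s", ic50 = "ic50",
                            weights = c("inverse_ic50sq", "none"),
                            refit_log = FALSE) {
  weights <- match.arg(weights)
  d <- tibble(s = series[[s]], ic50 = series[[ic50]])
  d <- d[is.finite(d$s) & is.finite(d$ic50), ]
  if (any(d$s < 0)) abort("2-OG concentrations must be >= 0")
  if (any(d$ic50 <= 0)) abort("IC50 values must be > 0")
  if (dplyr::n_distinct(d$s) < 3) {
    abort("need >= 3 distinct 2-OG concentrations")
  }
  w <- if (weights == "inverse_ic50sq") 1 / d$ic50^2 else NULL
  lin <- lm(ic50 ~ s, data = d, weights = w)
  a <- unname(coef(lin)[1]); b <- unname(coef(lin)[2])
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
    abort(sprintf(
      paste0("series is inconsistent with co-substrate-competitive ",
             "inhibition (intercept %.3g, slope %.3g); IC50 must increase ",
             "linearly with [2-OG]"), a, b))
  }
  ki <- a
  km <- a / b
  V <- vcov(lin)
  se_ki <- sqrt(V[1, 1])
  grad <- c(1 / b, -a / b^2)
  se_km <- sqrt(drop(t(grad) %*% V %*% grad))
  if (refit_log) {
    nl <- tryCatch(
      minpack.lm::nlsLM(log(ic50) ~ log(ki * (1 + s / km)), data = d,
                        start = list(ki = ki, km = km),
                        lower = c(1e-12, 1e-12)),
      error = function(e) NULL
    )
    if (!is.null(nl)) {
      cf <- coef(nl)
      ki <- unname(cf["ki"]); km <- unname(cf["km"])
      ses <- tryCatch(sqrt(diag(vcov(nl))), error = function(e) c(NA, NA))
      se_ki <- unname(ses[1]); se_km <- unname(ses[2])
    }
  }
  resid <- d$ic50 - ki * (1 + d$s / km)
  structure(
    list(ki = ki, km_og = km,
         se = c(ki = se_ki, km_og = se_km),
         residual_norm = sqrt(sum(resid^2)),
         n = nrow(d), data = d, weights = weights, refit_log = refit_log),
    class = "competitive_fit"
  )
}

#' @export
print.competitive_fit <- function(x, ...) {
  cat(sprintf("<competitive_fit> Ki %.4g uM, Km(2-OG) %.4g uM (%d points)\n",
              x$ki, x$km_og, x$n))
  invisible(x)
}

#' @export
tidy.competitive_fit <- function(x, ...) {
  tibble(term = c("ki", "km_og"),
         estimate = c(x$ki, x$km_og),
         std.error = c(x$se[["ki"]], x$se[["km_og"]]))
}

#' @export
glance.competitive_fit <- function(x, ...) {
  tibble(ki = x$ki, km_og = x$km_og, residual_norm = x$residual_norm,
         n = x$n, weights = x$weights, refit_log = x$refit_log)
}

#' Extrapolate inhibitor potency to physiological 2-OG
#'
#' Quantifies how much of the potency drop between biochemical and cellular
#' assays the competitive model explains: predicts the IC50 at the assay
#' 2-OG concentration and at a physiological concentration (default
#' 1000 µM), and their ratio.
#'
#' @param fit A `competitive_fit`.
#' @param s_phys Physiological 2-OG concentration, µM.
#' @param s_assay Assay 2-OG concentration, µM (0 = the zero-co-substrate
#'   limit, where IC50 equals Ki).
#' @return One-row tibble: `ic50_low_s`, `ic50_phys` (µM) and `fold_shift`.
#' @export
physiological_shift <- function(fit, s_phys = 1000, s_assay = 0) {
  ic50_low <- ic50_at(fit, s_assay)
  ic50_phys <- ic50_at(fit, s_phys)
  tibble(ic50_low_s = ic50_low, ic50_phys = ic50_phys,
         fold_shift = ic50_phys / ic50_low)
}
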