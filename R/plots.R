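#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_errorbar scale_x_log10 labs theme_minimal facet_wrap
NULL

#' Plot a fitted four-parameter logistic curve
#'
#' @param object A `fourpl_fit`.
#' @param n_grid Number of points along the fitted curve.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fourpl_fit <- function(object, n_grid = 200, ...) {
  d <- object$data
  p <- ggplot(d, aes(x = .data$conc, y = .data$y)) +
    geom_point() +
    scale_x_log10() +
    labs(x = "concentration (µM)", y = "response (a.u.)") +
    theme_minimal()
  if (object$converged) {
    grid <- tibble(
      conc = 10^seq(log10(min(d$conc)), log10(max(d$conc)), length.out = n_grid)
    )
    grid$y <- predict(object, grid$conc)
    p <- p + geom_line(data = grid, colour = "firebrick")
  }
  p
}

#' Plot WT and MUT dose-response series with the WT fit and MUT baseline
#'
#' @param object An `engagement_result`.
#' @param wt_series,mut_series The well tables used for the fit (optional;
#'   points are drawn when given).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.engagement_result <- function(object, wt_series = NULL,
                                       mut_series = NULL, ...) {
  p <- autoplot(object$wt_fit) +
    ggplot2::geom_hline(yintercept = object$mut_baseline,
                        linetype = "dashed") +
    labs(title = sprintf("EC50 %s", switch(object$qualifier,
      exact = sprintf("%.3g µM", object$ec50),
      greater_than_top_conc = sprintf("> %.3g µM", object$top_concentration),
      not_converged = "not determined")),
      subtitle = "dashed line: MUT vehicle baseline (~complete inhibition)")
  series <- dplyr::bind_rows(
    if (!is.null(wt_series)) dplyr::mutate(wt_series, construct = "WT"),
    if (!is.null(mut_series)) dplyr::mutate(mut_series, construct = "MUT")
  )
  if (!is.null(series) && nrow(series)) {
    series <- series[series$concentration > 0, ]
    p <- p + geom_point(
      data = series,
      aes(x = .data$concentration, y = .data$mean_mark,
          colour = .data$construct),
      inherit.aes = FALSE
    )
  }
  p
}

#' Plot the IC50-versus-2-OG competitive line
#'
#' @param object A `competitive_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.competitive_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(s = seq(0, max(d$s), length.out = 100))
  grid$ic50 <- ic50_at(object, grid$s)
  ggplot(d, aes(x = .data$s, y = .data$ic50)) +
    geom_line(data = grid, colour = "firebrick") +
    geom_point() +
    labs(x = "[2-OG] (µM)", y = "IC50 (µM)",
         title = sprintf("Ki = %.3g µM, Km(2-OG) = %.3g µM",
                         object$ki, object$km_og)) +
    theme_minimal()
}

#' Stacked-bar plot of death-class percentages
#'
#' @param summary A [summarize_death()] tibble.
#' @param by Grouping column used in the summary.
#' @return A ggplot.
#' @export
plot_death_summary <- function(summary, by = "well") {
  ggplot(summary, aes(x = .data[[by]], y = .data$percent, fill = .data$class)) +
    geom_col() +
    labs(x = NULL, y = "% of cells", fill = NULL) +
    theme_minimal()
}
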