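fourpl <- function(conc, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (ec50 / conc)^hill)
}

test_that("noiseless 4PL parameters are recovered essentially exactly", {
  conc <- 10^seq(-2.5, 2, by = 0.5)  # 10 half-log doses
  d <- tibble::tibble(concentration = conc,
                      mean_mark = fourpl(conc, 100, 400, 0.7, 1))
  fit <- fit_4pl(d)
  expect_true(fit$converged)
  expect_lt(abs(log10(fit$ec50) - log10(0.7)), 0.01)
  expect_equal(fit$bottom, 100, tolerance = 1e-3)
  expect_equal(fit$top, 400, tolerance = 1e-3)
  expect_equal(fit$hill, 1, tolerance = 1e-3)
})

test_that("the fit is covariant under unit rescaling of concentration", {
  conc <- 10^seq(-2, 2, by = 0.5)
  y <- fourpl(conc, 50, 250, 1.3, 1.6)
  f_um <- fit_4pl(tibble::tibble(concentration = conc, mean_mark = y))
  f_nm <- fit_4pl(tibble::tibble(concentration = conc * 1000, mean_mark = y))
  expect_equal(f_nm$ec50 / f_um$ec50, 1000, tolerance = 1e-4)
  expect_equal(f_nm$hill, f_um$hill, tolerance = 1e-4)
  expect_equal(f_nm$top, f_um$top, tolerance = 1e-4)
})

test_that("the fit is invariant to affine transforms of the response", {
  conc <- 10^seq(-2, 2, by = 0.5)
  y <- fourpl(conc, 50, 250, 1.3, 1.6)
  f1 <- fit_4pl(tibble::tibble(concentration = conc, mean_mark = y))
  f2 <- fit_4pl(tibble::tibble(concentration = conc, mean_mark = 3 * y + 17))
  expect_equal(f2$ec50, f1$ec50, tolerance = 1e-5)
  expect_equal(f2$hill, f1$hill, tolerance = 1e-5)
  expect_equal(f2$bottom, 3 * f1$bottom + 17, tolerance = 1e-4)
  expect_equal(f2$top, 3 * f1$top + 17, tolerance = 1e-4)
})

test_that("flat or undersized series do not yield garbage parameters", {
  conc <- 10^seq(-2, 2, by = 0.5)
  flat <- tibble::tibble(concentration = conc, mean_mark = 200)
  f <- fit_4pl(flat)
  expect_false(f$converged)
  expect_true(f$flat)
  expect_error(fit_4pl(flat[1:3, ]), "4 distinct")
  # noisy but dose-independent response: F test keeps it non-converged
  noisy <- tibble::tibble(concentration = conc,
                          mean_mark = withr::with_seed(5, rnorm(length(conc), 200, 3)))
  expect_false(fit_4pl(noisy)$converged)
})

test_that("vehicle wells inform baselines but are excluded from the log-dose fit", {
  conc <- 10^seq(-2, 2, by = 0.5)
  d <- tibble::tibble(concentration = c(0, conc),
                      mean_mark = c(999, fourpl(conc, 100, 400, 0.7, 1)))
  fit <- fit_4pl(d)  # the absurd vehicle value must not perturb the fit
  expect_lt(abs(log10(fit$ec50) - log10(0.7)), 0.01)
  expect_equal(fit$points_used, length(conc))
})

test_that("engagement is normalized to the MUT vehicle baseline", {
  conc <- 10^seq(-2, 2, by = 0.5)
  mut <- tibble::tibble(concentration = c(0, conc), mean_mark = 400,
                        sd_mark = 20, n_cells_total = 500)
  # WT plateaus exactly at the MUT baseline: complete engagement
  wt_full <- tibble::tibble(concentration = c(0, conc),
                            mean_mark = c(100, fourpl(conc, 100, 400, 1, 1)))
  fit_full <- fit_4pl(wt_full)
  e_full <- compute_engagement(fit_full, wt_full, mut)
  expect_equal(e_full$mut_baseline, 400)
  expect_equal(e_full$max_inhibition_fraction, 1, tolerance = 1e-3)
  expect_true(e_full$full_engagement)
  expect_equal(e_full$qualifier, "exact")

  # WT plateaus halfway to the MUT baseline
  wt_half <- wt_full
  wt_half$mean_mark <- c(100, fourpl(conc, 100, 250, 1, 1))
  e_half <- compute_engagement(fit_4pl(wt_half), wt_half, mut)
  expect_equal(e_half$max_inhibition_fraction, 0.5, tolerance = 1e-3)

  # inverted polarity warns
  mut_low <- dplyr::mutate(mut, mean_mark = 50)
  expect_warning(compute_engagement(fit_full, wt_full, mut_low), "polarity")
  expect_error(compute_engagement(fit_full, wt_full, mut[mut$concentration > 0, ]),
               "vehicle")
})

test_that("toxicity signature: spike plus count drop flags, spike alone reports endogenous activity", {
  conc <- 100 / 2^(7:0)
  base <- tibble::tibble(concentration = c(0, conc), compound = "X",
                         construct = "MUT")
  # KDIPP51-like: spike and crash at the top of the range (tc50 60 uM)
  truth_tox <- pharmacology_truth(ec50_cell = 0.06, tc50 = 60, spike_gain = 1)
  tox <- base |>
    dplyr::mutate(
      mean_mark = expected_mark(truth_tox, concentration, "MUT"),
      sd_mark = 0.15 * 200,
      n_cells_total = round(1000 * survival_fraction(concentration, truth_tox))
    )
  spike <- detect_toxicity_spike(tox)
  expect_true(spike$flagged)
  expect_equal(spike$pattern, "toxicity")
  expect_gte(spike$onset_concentration, 50)
  expect_lt(spike$count_drop_fraction, 0.5)

  # CPI-455-like: endogenous inhibition raises the MUT mark, counts stable
  truth_endo <- pharmacology_truth(ec50_cell = 0.26, endogenous_ec50 = 60,
                                   endo_gain = 1)
  endo <- base |>
    dplyr::mutate(
      mean_mark = expected_mark(truth_endo, concentration, "MUT"),
      sd_mark = 0.15 * 200,
      n_cells_total = 1000
    )
  s_endo <- detect_toxicity_spike(endo)
  expect_false(s_endo$flagged)
  expect_equal(s_endo$pattern, "endogenous_activity")

  # flat series, flat counts
  quiet <- base |>
    dplyr::mutate(mean_mark = 200, sd_mark = 30, n_cells_total = 1000)
  s_quiet <- detect_toxicity_spike(quiet)
  expect_false(s_quiet$flagged)
  expect_equal(s_quiet$pattern, "none")

  expect_error(detect_toxicity_spike(tox[tox$concentration > 0, ]), "vehicle")
})

test_that("EC50 recovery from seeded synthetic plates meets the accuracy bar", {
  # 200 plates, 20 fields/well, noise_cv 0.15: median |log10 ratio| < 0.15,
  # 90th percentile < 0.3 (within 2x)
  truth <- pharmacology_truth(ec50_cell = 0.7, noise_cv = 0.15)
  errs <- vapply(1:200, function(s) {
    spec <- small_spec(truth, top_conc = 10, n_conc = 8,
                       fields_per_well = 20, cells_per_field = 80, seed = s)
    cells <- simulate_dose_series(truth, spec)
    wells <- wells_from_cells(cells)
    fit <- fit_4pl(wells[wells$construct == "WT", ], ci = FALSE)
    abs(log10(fit$ec50 / 0.7))
  }, numeric(1))
  expect_lt(median(errs), 0.15)
  expect_lt(unname(quantile(errs, 0.9)), 0.3)
})

test_that("the toxicity flag stays quiet on non-toxic plates", {
  # false-flag rate < 5% over 200 plates simulated without any cell loss
  truth <- pharmacology_truth(ec50_cell = 0.7, noise_cv = 0.15)
  flags <- vapply(1:200, function(s) {
    spec <- small_spec(truth, top_conc = 100, n_conc = 8,
                       constructs = "MUT",
                       fields_per_well = 4, cells_per_field = 80, seed = s)
    cells <- simulate_dose_series(truth, spec)
    wells <- wells_from_cells(cells)
    detect_toxicity_spike(wells)$flagged
  }, logical(1))
  expect_lt(mean(flags), 0.05)
})
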