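make_flag_cells <- function(n = 1000, frac_high = 0.3, lo = 50, hi = 1000,
                            sdlog = 0.35, seed = 1) {
  withr::with_seed(seed, {
    transfected <- seq_len(n) <= round(frac_high * n)
    tibble::tibble(
      well = "A01", field = 1L,
      transfected = transfected,
      mean_flag = ifelse(transfected, hi, lo) * exp(rnorm(n, 0, sdlog)),
      mean_mark = 100
    )
  })
}

test_that("the bimodal FLAG gate recovers transfected cells almost perfectly", {
  cells <- make_flag_cells(2000)
  gate <- compute_gate_threshold(cells)
  expect_true(gate$threshold > 50 && gate$threshold < 1000)
  gated <- cells$mean_flag > gate$threshold
  accuracy <- mean(gated == cells$transfected)
  expect_gte(accuracy, 0.99)
})

test_that("degenerate and percentile gating behave as specified", {
  flat <- tibble::tibble(mean_flag = rep(200, 150))
  expect_error(compute_gate_threshold(flat, "otsu"), "constant|unimodal")
  # identical intensities, reference + 3 SD: nothing is strongly overexpressing
  g <- compute_gate_threshold(flat, "reference", reference = flat, k = 3)
  expect_equal(g$n_gated, 0L)
  # median threshold gates exactly the top half of 100 distinct cells
  cells <- tibble::tibble(mean_flag = seq_len(100))
  g50 <- compute_gate_threshold(cells, "percentile", percentile = 0.5)
  expect_equal(g50$n_gated, 50L)
})

test_that("a unimodal plate falls back to the reference gate with a warning", {
  unimodal <- make_flag_cells(500, frac_high = 0)
  ref <- unimodal
  expect_warning(
    g <- compute_gate_threshold(unimodal, "otsu", reference = ref),
    "unimodal"
  )
  expect_equal(g$method, "reference")
})

test_that("well aggregation matches a brute-force recomputation", {
  cells <- tibble::tibble(
    well = "B02", compound = "C", concentration = 1, construct = "WT",
    field = rep(1:2, each = 3),
    mean_mark = c(10, 20, 30, 40, 50, 60),
    mean_flag = c(5, 100, 100, 100, 5, 100)
  )
  w <- aggregate_well(cells, threshold = 50)
  marks <- c(20, 30, 40, 60)  # flag > 50, pooled across fields
  expect_equal(w$mean_mark, mean(marks))
  expect_equal(w$sd_mark, sd(marks))  # sample SD, n-1 denominator
  expect_equal(w$n_cells_total, 6L)
  expect_equal(w$n_cells_gated, 4L)
  expect_equal(w$n_fields, 2L)
  expect_equal(w$transfection_efficiency, 4 / 6)
  expect_true(w$low_confidence)

  # simple documented example: three gated cells {10, 20, 30}
  three <- tibble::tibble(well = "C01", field = 1L, mean_mark = c(10, 20, 30),
                          mean_flag = 100, construct = "WT")
  w3 <- aggregate_well(three, threshold = 0)
  expect_equal(w3$mean_mark, 20)
  expect_equal(w3$sd_mark, 10)
})

test_that("endogenous mode pools every cell across all fields", {
  cells <- tibble::tibble(
    well = "D01", compound = "C", concentration = 0, construct = "none",
    field = rep(1:10, each = 4),
    mean_mark = rnorm(40, 200, 5), mean_flag = runif(40, 0, 10)
  )
  w <- aggregate_well(cells, threshold = 1e9)  # threshold irrelevant
  expect_equal(w$mean_mark, mean(cells$mean_mark))
  expect_equal(w$n_cells_gated, 40L)
  expect_equal(w$n_fields, 10L)
})

test_that("a well with no gated cells is flagged, not dropped", {
  cells <- tibble::tibble(well = "E01", field = 1L, construct = "WT",
                          mean_mark = c(1, 2), mean_flag = c(1, 2))
  w <- aggregate_well(cells, threshold = 10)
  expect_true(w$no_gated_cells)
  expect_true(is.na(w$mean_mark))
})

test_that("gated subset and threshold monotonicity invariants hold", {
  cells <- make_flag_cells(1500, seed = 11)
  gate <- compute_gate_threshold(cells)
  gated <- cells$mean_flag > gate$threshold
  expect_true(all(cells$mean_flag[gated] >= gate$threshold))
  expect_true(all(cells$mean_flag[!gated] <= gate$threshold))
  # raising the threshold never increases the gated count
  thresholds <- sort(runif(25, min(cells$mean_flag), max(cells$mean_flag)))
  counts <- vapply(thresholds, function(th) sum(cells$mean_flag > th), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("active WT demethylase depletes the mark relative to MUT at vehicle", {
  truth <- default_truth()
  spec <- small_spec(cells_per_field = 60, fields_per_well = 2, seed = 14)
  cells <- simulate_dose_series(truth, spec)
  wells <- wells_from_cells(cells)
  wt0 <- wells$mean_mark[wells$construct == "WT" & wells$concentration == 0]
  mut0 <- wells$mean_mark[wells$construct == "MUT" & wells$concentration == 0]
  expect_lt(wt0, mut0)
})
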