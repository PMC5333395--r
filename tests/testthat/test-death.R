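test_that("the triple-stain rule table is applied with apoptotic precedence", {
  thr <- structure(list(annexin_cut = 100, yopro_cut = 100, method = "fixed"),
                   class = "positivity_thresholds")
  records <- tibble::tibble(
    cell = 1:4, well = "A01", hoechst = 500,
    annexin = c(500, 10, 10, 500),
    yopro   = c(500, 500, 10, 10)
  )
  cls <- classify_death(records, thr)$class
  # AnnexinV+/YoPro+ is apoptotic (late), AnnexinV-/YoPro+ necrotic,
  # double-negative healthy, AnnexinV+/YoPro- apoptotic (early)
  expect_equal(as.character(cls), c("apoptotic", "necrotic", "healthy", "apoptotic"))
})

test_that("every cell gets exactly one class and percentages total 100", {
  tbl <- simulate_triple_stain(c(0.5, 0.3, 0.2), 999, separability = 3, seed = 2)
  thr <- calibrate_positivity(tbl)
  cls <- classify_death(tbl, thr)
  expect_false(any(is.na(cls$class)))
  sm <- summarize_death(cls)
  expect_equal(sum(sm$n), 999L)
  expect_equal(sum(sm$percent), 100)
})

test_that("counting matches hand-built labels", {
  records <- tibble::tibble(
    cell = 1:10, well = "A01",
    class = factor(rep(c("healthy", "apoptotic", "necrotic"), c(5, 3, 2)),
                   levels = c("healthy", "apoptotic", "necrotic"))
  )
  sm <- summarize_death(records)
  expect_equal(sm$percent, c(50, 30, 20))

  all_healthy <- tibble::tibble(cell = 1:10, well = "A01",
                                class = factor(rep("healthy", 10),
                                               levels = levels(records$class)))
  expect_equal(summarize_death(all_healthy)$percent, c(100, 0, 0))
  expect_error(summarize_death(records[0, ]), "no cells")
})

test_that("calibration on a separated mixture lands between the modes", {
  tbl <- simulate_triple_stain(c(0.4, 0.3, 0.3), 3000, separability = 6, seed = 6)
  thr <- calibrate_positivity(tbl)
  # low mode at 100, high mode at 100*exp(6*0.35) ~ 816
  expect_gt(thr$annexin_cut, 100)
  expect_lt(thr$annexin_cut, 816)
  expect_gt(thr$yopro_cut, 100)
  expect_lt(thr$yopro_cut, 816)
})

test_that("degenerate channels are rejected during calibration", {
  flat <- tibble::tibble(cell = 1:200, well = "A01", hoechst = 1,
                         annexin = 5, yopro = 5)
  expect_error(calibrate_positivity(flat), "degenerate")
  expect_error(calibrate_positivity(flat, method = "reference"), "degenerate")
})

test_that("reference calibration on healthy controls rarely calls positives", {
  controls <- simulate_triple_stain(c(1, 0, 0), 5000, seed = 12)
  thr <- calibrate_positivity(controls, method = "reference", k = 3)
  cls <- classify_death(controls, thr)
  expect_lt(mean(cls$class != "healthy"), 0.01)
})

test_that("class fractions are recovered from a separable mixture", {
  tbl <- simulate_triple_stain(c(0.2, 0.6, 0.2), 2000, separability = 5, seed = 13)
  sm <- summarize_death(tbl, calibrate_positivity(tbl))
  expect_equal(sm$percent[sm$class == "apoptotic"], 60, tolerance = 3 / 60)
  expect_equal(sm$percent[sm$class == "necrotic"], 20, tolerance = 3 / 20)
})

test_that("classification accuracy reaches 98% on well-separated mixtures", {
  # at 5 SD separation the per-channel Bayes error is ~0.6%, leaving room
  # for the 98% bar; at exactly 4 SD the overlap alone costs ~3.5%
  accs <- vapply(1:50, function(s) {
    tbl <- simulate_triple_stain(c(0.4, 0.35, 0.25), 1500,
                                 separability = 5, seed = s)
    cls <- classify_death(tbl, calibrate_positivity(tbl))
    mean(cls$class == cls$true_class)
  }, numeric(1))
  expect_gte(mean(accs), 0.98)
  expect_gte(min(accs), 0.97)
})

test_that("raising the Annexin V cut never increases the apoptotic count", {
  tbl <- simulate_triple_stain(c(0.3, 0.4, 0.3), 2000, separability = 3, seed = 4)
  cuts <- seq(50, 2000, length.out = 30)
  counts <- vapply(cuts, function(cut) {
    thr <- structure(list(annexin_cut = cut, yopro_cut = 300, method = "fixed"),
                     class = "positivity_thresholds")
    sum(classify_death(tbl, thr)$class == "apoptotic")
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("bootstrap intervals cover the point estimate", {
  tbl <- simulate_triple_stain(c(0.5, 0.3, 0.2), 1000, separability = 5, seed = 20)
  sm <- summarize_death(tbl, calibrate_positivity(tbl), bootstrap = 200)
  expect_true(all(sm$percent_low <= sm$percent + 1e-9))
  expect_true(all(sm$percent_high >= sm$percent - 1e-9))
})
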