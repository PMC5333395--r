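test_that("segmentation errors name available channels; blank fields yield none", {
  f <- disc_field(cbind(40, 40))
  expect_error(segment_nuclei(f, nuclear_channel = "hoechst"),
               "dapi, mark, flag")
  blank <- multichannel_field(list(dapi = matrix(0, 64, 64)), 0.65)
  expect_equal(nrow(segment_nuclei(blank)), 0)
})

test_that("well-separated disks are each recovered with accurate centroids", {
  centers_um <- as.matrix(expand.grid(seq(12, 72, by = 20), seq(12, 72, by = 15)))
  centers_um <- centers_um[1:12, ]
  f <- disc_field(centers_um, radii_um = 5, pixel_size = 0.65, field_px = 128)
  rec <- segment_nuclei(f)
  expect_equal(nrow(rec), 12)
  truth_px <- centers_um / 0.65
  # nearest detected centroid within 1 px of every generated centre
  dist_to_nearest <- apply(truth_px, 1, function(p) {
    min(sqrt((rec$centroid_col - p[1])^2 + (rec$centroid_row - p[2])^2))
  })
  expect_true(all(dist_to_nearest <= 1))
})

test_that("watershed splitting separates overlapping nuclei", {
  # two disks of radius 6 um whose centres are 1.4 radii apart (~30% overlap)
  f <- disc_field(cbind(c(35, 43.4), c(40, 40)), radii_um = 6)
  split_on <- segment_nuclei(f, segmentation_params(split_touching = TRUE))
  split_off <- segment_nuclei(f, segmentation_params(split_touching = FALSE))
  expect_equal(nrow(split_on), 2)
  expect_equal(nrow(split_off), 1)
})

test_that("size and border filters implement the exclusion rules exactly", {
  rec <- tibble::tibble(
    label = 1:5,
    area = c(80, 120, 150, 200, 300),
    n_px = as.integer(c(80, 120, 150, 200, 300) / 0.65^2),
    centroid_row = 10, centroid_col = 10,
    touches_border = c(FALSE, FALSE, FALSE, TRUE, TRUE)
  )
  out <- filter_nuclei(rec, segmentation_params(min_area = 100))
  expect_equal(out$label, c(2L, 3L))

  # identity when the rules are disabled
  ident <- filter_nuclei(rec, segmentation_params(min_area = 0,
                                                  exclude_border = FALSE))
  expect_equal(ident$label, rec$label)

  # strict inequality: exactly-at-cutoff survives, just-below does not
  edge <- tibble::tibble(label = 1:2, area = c(100, 99.9), n_px = c(237L, 236L),
                         centroid_row = 5, centroid_col = 5,
                         touches_border = FALSE)
  expect_equal(filter_nuclei(edge, segmentation_params())$label, 1L)

  # idempotence
  once <- filter_nuclei(rec, segmentation_params())
  twice <- filter_nuclei(once, segmentation_params())
  expect_equal(as.data.frame(once), as.data.frame(twice))
})

test_that("mean intensities are exact channel means over the nucleus mask", {
  f <- disc_field(cbind(c(20, 55), c(20, 55)), radii_um = 6)
  rec <- segment_nuclei(f)
  # uniform channel: every nucleus mean equals the constant
  f$channels$mark[] <- 7.25
  out <- measure_nuclei(f, rec)
  expect_equal(out$mean_mark, rep(7.25, nrow(out)))

  # constructed 4-pixel mask over values {1,2,3,4}
  lab <- matrix(0L, 8, 8)
  lab[3:4, 3:4] <- 1L
  rec4 <- tibble::tibble(label = 1L, area = 4 * 0.65^2, n_px = 4L,
                         centroid_row = 2.5, centroid_col = 2.5,
                         touches_border = FALSE)
  attr(rec4, "labels") <- lab
  attr(rec4, "pixel_size") <- 0.65
  ch <- matrix(0, 8, 8)
  ch[3:4, 3:4] <- c(1, 2, 3, 4)
  fld <- multichannel_field(list(mark = ch), 0.65)
  expect_equal(measure_nuclei(fld, rec4)$mean_mark, 2.5)
})

test_that("per-nucleus means on a noiseless synthetic field match the ledger", {
  cells <- tibble::tibble(
    well = "A01", compound = "C", concentration = 0, construct = "none",
    field = 1L, cell = 1:5,
    cx = c(30, 90, 150, 60, 120), cy = c(30, 40, 30, 110, 120),
    radius_um = c(6.2, 6, 6.5, 7, 6),  # all above the 100 um^2 area filter
    eccentricity = c(0, 0.05, 0.1, 0.15, 0.08),
    theta = c(0, 0.5, 1, 1.5, 2),
    transfected = c(TRUE, FALSE, TRUE, FALSE, TRUE),
    alive = TRUE, condensed = FALSE,
    true_mark = c(40.2, 198.7, 63.1, 210.4, 55.5),
    true_flag = c(950, 48, 1100, 52, 870),
    true_dapi = c(480, 510, 530, 470, 500)
  )
  spec <- plate_spec(
    tibble::tibble(well = "A01", compound = "C", concentration = 0,
                   construct = "none"),
    field_shape = c(192, 192), background_level = 0, background_sd = 0
  )
  fld <- render_field(cells, spec, noise = FALSE)
  fld$well <- "A01"; fld$field <- 1L
  rec <- process_field(fld)
  expect_equal(nrow(rec), 5)
  idx <- vapply(seq_len(nrow(cells)), function(i) {
    which.min((rec$centroid_col - cells$cx[i])^2 +
                (rec$centroid_row - cells$cy[i])^2)
  }, integer(1))
  expect_equal(sort(idx), seq_len(nrow(rec)))
  expect_equal(rec$mean_mark[idx], cells$true_mark, tolerance = 1e-9)
  expect_equal(rec$mean_flag[idx], cells$true_flag, tolerance = 1e-9)
})

test_that("detected nucleus counts conserve the generated counts", {
  # sparse fields of well-separated nuclei: detected == generated in >= 99%
  set.seed(1234)
  n_fields <- 400
  ok <- logical(n_fields)
  spec <- plate_spec(
    tibble::tibble(well = "A01", compound = "C", concentration = 0,
                   construct = "none"),
    field_shape = c(128, 128), pixel_size = 0.65,
    background_level = 5, background_sd = 2
  )
  for (i in seq_len(n_fields)) {
    k <- sample(5:12, 1)
    # rejection-sample centres >= 16 um apart, >= 8 um from the border
    pts <- matrix(numeric(0), 0, 2)
    while (nrow(pts) < k) {
      cand <- runif(2, 8, 75)
      if (!nrow(pts) || all(sqrt(colSums((t(pts) - cand)^2)) > 16)) {
        pts <- rbind(pts, cand)
      }
    }
    cells <- tibble::tibble(
      well = "A01", compound = "C", concentration = 0, construct = "none",
      field = 1L, cell = seq_len(k),
      cx = pts[, 1] / 0.65, cy = pts[, 2] / 0.65,
      radius_um = runif(k, 5, 7), eccentricity = runif(k, 0, 0.15),
      theta = runif(k, 0, pi), transfected = FALSE, alive = TRUE,
      condensed = FALSE, true_mark = 200, true_flag = 100,
      true_dapi = 500 * exp(rnorm(k, 0, 0.2))
    )
    f <- render_field(cells, spec)
    ok[i] <- nrow(segment_nuclei(f)) == k
  }
  expect_gte(mean(ok), 0.99)
})

test_that("reported areas are physical, invariant to pixel size", {
  centers_um <- cbind(c(20, 45, 60), c(30, 55, 20))
  areas <- lapply(c(0.5, 1.0), function(px) {
    f <- disc_field(centers_um, radii_um = 6, pixel_size = px, field_px = round(83 / px))
    rec <- segment_nuclei(f)
    sort(rec$area)
  })
  expect_equal(length(areas[[1]]), 3)
  expect_equal(areas[[1]], areas[[2]], tolerance = 0.10)
})
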