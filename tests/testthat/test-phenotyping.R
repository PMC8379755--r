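# Scale calibration and the eight-trait extractor.

test_that("calibration averages interior ruler element extents exactly", {
  # 10 elements of exactly 20 px -> 20 px/cm
  fix <- ruler_fixture(rep(20, 10))
  sc <- calibrate_scale(fix$image, list(fix$mask))
  expect_true(sc$calibrated)
  expect_equal(sc$px_per_cm, 20.0)

  # interior elements of 19, 20, 21 px -> arithmetic mean 20
  fix2 <- ruler_fixture(c(20, 19, 20, 21, 19, 20, 21, 20))
  sc2 <- calibrate_scale(fix2$image, list(fix2$mask))
  expect_true(sc2$calibrated)
  expect_equal(sc2$px_per_cm, 20.0)

  # element_cm rescales linearly
  sc3 <- calibrate_scale(fix$image, list(fix$mask), element_cm = 0.5)
  expect_equal(sc3$px_per_cm, 40.0)
})

test_that("missing or unusable rulers give an uncalibrated scale, not an error", {
  img <- flat_image(30, 30)
  expect_false(calibrate_scale(img, list())$calibrated)
  # a featureless "ruler" mask has no elements
  expect_false(calibrate_scale(img, list(rect_mask(30, 30, 5:24, 5:24,
                                                   label = "ruler")))$calibrated)
  # uncalibrated traits are emitted in px with the flag set
  tr <- extract_traits(rect_mask(30, 30, 3:26, 10:19), img, px_scale())
  expect_equal(tr$unit, "px")
  expect_equal(tr$length, 24)
})

test_that("width profile of a rectangle is flat and axis-invariant", {
  m <- rect_mask(120, 60, 11:110, 11:50)          # 100 x 40
  p <- width_profile(m)
  expect_equal(p$length_px, 100)
  expect_equal(p$diameter_px, 40)
  expect_true(all(abs(p$w[5:95] - 40) < 1e-9))
  # same mask rotated 90 degrees: identical profile
  m2 <- rect_mask(60, 120, 11:50, 11:110)
  expect_equal(width_profile(m2)$w, p$w)
  expect_error(width_profile(rect_mask(10, 10, 1:3, 1:3)), "too small")
})

test_that("width profile of an ellipse follows the analytic width", {
  m <- ellipse_mask(220, 120, 110, 60, a = 100, b = 50)
  p <- width_profile(m)
  tb <- (seq_len(p$B) - 0.5) / p$B
  analytic <- 100 * sqrt(pmax(4 * tb * (1 - tb), 0))
  expect_lt(max(abs(p$w[10:90] - analytic[10:90])), 2)
})

test_that("ellipse and rectangle traits match closed-form values", {
  img <- flat_image(220, 120, c(120, 80, 40))
  m <- ellipse_mask(220, 120, 110, 60, a = 100, b = 50)
  sc <- px_scale(px_per_cm = 10, n_elements_used = 10, calibrated = TRUE)
  tr <- extract_traits(m, img, sc)
  expect_equal(tr$length, 20.0, tolerance = 0.005)
  expect_equal(tr$diameter, 10.0, tolerance = 0.01)
  expect_equal(tr$aspect_ratio, 2.0, tolerance = 0.015)
  expect_lt(tr$asymmetry, 0.02)
  expect_equal(tr$ellipticity, 1.0, tolerance = 0.03)
  expect_equal(c(tr$mean_r, tr$mean_g, tr$mean_b), c(120, 80, 40))
  expect_equal(tr$unit, "cm")

  # rectangle: ellipticity = A_rect / (pi L D / 4) = 4 / pi
  tr2 <- extract_traits(rect_mask(120, 60, 11:110, 11:50), img, px_scale())
  expect_equal(tr2$ellipticity, 4 / pi, tolerance = 1e-9)
  expect_equal(tr2$length, 100)
  expect_equal(tr2$diameter, 40)
})

test_that("mirroring about the minor axis leaves asymmetry unchanged", {
  sc <- small_scene(seed = 51, n_cobs = 1, px_per_cm = 12)
  img <- sc$image
  m <- Filter(function(x) x$label == "cob", sc$truth$masks)[[1]]
  m_flip <- instance_mask(m$mask[nrow(m$mask):1, ], "cob")
  a1 <- extract_traits(m, img, px_scale())$asymmetry
  img_flip <- raster_image(img$pixels[dim(img$pixels)[1]:1, , ], "flip")
  a2 <- extract_traits(m_flip, img_flip, px_scale())$asymmetry
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("traits are equivariant under integer upscaling", {
  m <- ellipse_mask(130, 70, 65, 35, a = 55, b = 22)
  img <- flat_image(130, 70)
  t1 <- extract_traits(m, img, px_scale())
  s <- 3L
  up <- instance_mask(m$mask %x% matrix(TRUE, s, s), "cob")
  t2 <- extract_traits(up, flat_image(130 * s, 70 * s), px_scale())
  expect_lt(abs(t2$length - s * t1$length), 1 + 1e-9)
  expect_lt(abs(t2$diameter - s * t1$diameter), 1 + 1e-9)
  for (v in c("aspect_ratio", "asymmetry", "ellipticity"))
    expect_lt(abs(t2[[v]] - t1[[v]]), 0.02)
})

test_that("traits are invariant under rotation", {
  m <- ellipse_mask(130, 70, 65, 35, a = 55, b = 22)
  img <- flat_image(130, 70)
  t0 <- extract_traits(m, img, px_scale())
  # 90 degrees: exact (transpose of the grid)
  t90 <- extract_traits(instance_mask(t(m$mask), "cob"),
                        flat_image(70, 130), px_scale())
  for (v in c("length", "diameter", "aspect_ratio", "asymmetry", "ellipticity"))
    expect_equal(t90[[v]], t0[[v]], tolerance = 1e-12)
  # arbitrary angle: the same continuous ellipse rotated by 35 degrees
  m35 <- ellipse_mask(160, 160, 80, 80, a = 55, b = 22, theta = 35 * pi / 180)
  t35 <- extract_traits(m35, flat_image(160, 160), px_scale())
  for (v in c("length", "diameter", "aspect_ratio", "ellipticity"))
    expect_lt(abs(t35[[v]] / t0[[v]] - 1), 0.02)
  expect_lt(abs(t35$asymmetry - t0$asymmetry), 0.02)
})

test_that("traits extracted from ground-truth masks recover the true values", {
  for (seed in c(61, 62)) {
    sc <- small_scene(seed = seed, n_cobs = 3, px_per_cm = 12)
    rulers <- Filter(function(m) m$label == "ruler", sc$truth$masks)
    cobs <- Filter(function(m) m$label == "cob", sc$truth$masks)
    cal <- calibrate_scale(sc$image, rulers)
    expect_true(cal$calibrated)
    for (i in seq_along(cobs)) {
      est <- extract_traits(cobs[[i]], sc$image, cal, cob_id = i)
      tru <- sc$truth$true_traits[i, ]
      expect_lt(abs(est$length / tru$length - 1), 0.02)
      expect_lt(abs(est$diameter / tru$diameter - 1), 0.02)
      expect_lt(abs(est$asymmetry - tru$asymmetry), 0.05)
      expect_lt(abs(est$ellipticity - tru$ellipticity), 0.05)
    }
  }
})

test_that("per-image summaries use the sample SD and flag singletons", {
  img <- flat_image(40, 20)
  mk <- function(len, id) {
    tr <- extract_traits(rect_mask(40, 20, 1:len, 5:14), img, px_scale(),
                         image_id = "a", cob_id = id)
    tr
  }
  s <- summarize_image(list(mk(10, 1), mk(20, 2)))
  expect_equal(s$mean_length, 15)
  expect_equal(s$sd_length, sqrt(50), tolerance = 1e-9)   # 7.0710678
  expect_equal(s$n_cobs, 2L)

  s1 <- summarize_image(list(mk(12, 1)))
  expect_equal(s1$mean_length, 12)
  expect_true(is.na(s1$sd_length))

  s3 <- summarize_image(list(mk(15, 1), mk(15, 2), mk(15, 3)))
  expect_equal(s3$sd_length, 0)
  expect_error(summarize_image(list()), "no cob records")
})
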