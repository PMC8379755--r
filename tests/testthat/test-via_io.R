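# VIA JSON round trips, polygon rasterization, labeled masks, trait tables.

make_via_file <- function(regions, path = tempfile(fileext = ".json"),
                          filename = "img1.png") {
  doc <- list()
  doc[[filename]] <- list(filename = filename, size = -1, regions = regions,
                          file_attributes = list())
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "list")
  path
}

poly_json <- function(xs, ys, label = "cob") {
  list(shape_attributes = list(name = "polygon", all_points_x = xs,
                               all_points_y = ys),
       region_attributes = list(name = label))
}

test_that("read_via parses polygons with class labels from both export shapes", {
  p <- make_via_file(list(poly_json(c(0, 4, 4, 0), c(0, 0, 4, 4), "cob")))
  anns <- read_via(p)
  expect_length(anns, 1L)
  expect_length(anns[["img1.png"]]$regions, 1L)
  expect_equal(anns[["img1.png"]]$regions[[1]]$label, "cob")
  expect_equal(anns[["img1.png"]]$regions[[1]]$vertices[, "x"], c(0, 4, 4, 0))

  # project-style export wraps the same map under _via_img_metadata
  doc <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  p2 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(`_via_settings` = list(ui = "x"),
                            `_via_img_metadata` = doc),
                       p2, auto_unbox = TRUE, null = "list")
  anns2 <- read_via(p2)
  expect_equal(anns2[["img1.png"]]$regions[[1]]$vertices,
               anns[["img1.png"]]$regions[[1]]$vertices)
})

test_that("read_via applies region policies and reports problems", {
  # missing class attribute, policy drop
  reg <- list(shape_attributes = list(name = "polygon",
                                      all_points_x = c(0, 4, 2),
                                      all_points_y = c(0, 0, 3)),
              region_attributes = list())
  p <- make_via_file(list(reg))
  expect_warning(anns <- read_via(p, missing_class = "drop"), "without class")
  expect_length(anns[["img1.png"]]$regions, 0L)
  anns <- suppressWarnings(read_via(p, missing_class = "cob"))
  expect_equal(anns[["img1.png"]]$regions[[1]]$label, "cob")

  # < 3 vertices dropped; unknown labels reported
  p2 <- make_via_file(list(poly_json(c(0, 1), c(0, 1), "cob"),
                           poly_json(c(0, 4, 2), c(0, 0, 3), "tassel")))
  expect_warning(expect_warning(anns2 <- read_via(p2), "< 3 vertices"),
                 "unknown class")
  expect_length(anns2[["img1.png"]]$regions, 0L)

  # malformed JSON names the file
  bad <- tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(read_via(bad), "malformed VIA JSON")
})

test_that("write_via / read_via round-trips vertices and labels exactly", {
  ann <- annotation_set("img7.png", list(
    polygon_region(c(0.5, 10.25, 5), c(1, 2, 9.75), "cob"),
    polygon_region(c(0, 30, 30, 0), c(0, 0, 5, 5), "ruler")))
  p <- tempfile(fileext = ".json")
  write_via(list(ann), p)
  back <- read_via(p)
  expect_equal(names(back), "img7.png")
  expect_equal(length(back[[1]]$regions), 2L)
  for (i in 1:2) {
    expect_identical(back[[1]]$regions[[i]]$vertices, ann$regions[[i]]$vertices)
    expect_identical(back[[1]]$regions[[i]]$label, ann$regions[[i]]$label)
  }
})

test_that("polygon_to_mask follows the pixel-center even-odd convention", {
  # axis-aligned square [0,4]x[0,4]: the 16 centers at 0.5..3.5 are inside
  sq <- polygon_region(c(0, 4, 4, 0), c(0, 0, 4, 4), "cob")
  m <- polygon_to_mask(sq, 6, 6)
  expect_equal(mask_area(m), 16L)
  expect_true(all(m$mask[1:4, 1:4]))
  expect_equal(m$bbox, c(0L, 0L, 4L, 4L))

  # triangle (0,0),(4,0),(0,4): centers with x+y <= 4 (boundary inside) = 10
  tri <- polygon_region(c(0, 4, 0), c(0, 0, 4), "cob")
  expect_equal(mask_area(polygon_to_mask(tri, 6, 6)), 10L)

  # cross-check against an independent point-in-polygon implementation
  poly_x <- c(1.2, 7.8, 6.5, 3.1)
  poly_y <- c(0.7, 2.2, 8.4, 6.9)
  m2 <- polygon_to_mask(polygon_region(poly_x, poly_y, "cob"), 10, 10)
  centers <- expand.grid(r = 1:10, c = 1:10)
  oracle <- pracma::inpolygon(centers$c - 0.5, centers$r - 0.5,
                              poly_x, poly_y, boundary = TRUE)
  expect_equal(as.vector(m2$mask), as.vector(oracle))

  expect_error(polygon_to_mask(polygon_region(c(20, 24, 22), c(20, 20, 24),
                                              "cob"), 6, 6),
               "degenerate or fully outside")
})

test_that("rasterized polygon area converges to the true polygon area", {
  tri_x <- c(50, 450, 200); tri_y <- c(30, 80, 470)
  true_area <- abs(sum(tri_x * c(tri_y[-1], tri_y[1]) -
                       c(tri_x[-1], tri_x[1]) * tri_y)) / 2   # shoelace
  m <- polygon_to_mask(polygon_region(tri_x, tri_y, "cob"), 500, 500)
  expect_lt(abs(mask_area(m) - true_area) / true_area, 0.02)
})

test_that("label images round-trip instance masks", {
  masks <- list(rect_mask(12, 12, 2:5, 2:5), rect_mask(12, 12, 8:11, 7:11))
  p <- tempfile(fileext = ".png")
  write_label_image(masks, p)
  back <- read_label_image(p)
  expect_length(back, 2L)
  expect_identical(back[[1]]$mask, masks[[1]]$mask)
  expect_identical(back[[2]]$mask, masks[[2]]$mask)
})

test_that("trait tables write one row per cob with stable columns", {
  img <- flat_image(40, 40, c(120, 80, 40))
  masks <- list(rect_mask(40, 40, 5:34, 5:14), rect_mask(40, 40, 5:34, 20:29),
                rect_mask(40, 40, 10:29, 32:39))
  recs <- lapply(seq_along(masks), function(i)
    extract_traits(masks[[i]], img, px_scale(), cob_id = i))
  p <- tempfile(fileext = ".csv")
  write_trait_table(recs, p)
  df <- read_trait_table(p)
  expect_equal(nrow(df), 3L)
  expect_equal(names(df), c("image_id", "cob_id", cob_trait_names(), "unit"))

  # empty record list -> header-only CSV
  p0 <- tempfile(fileext = ".csv")
  write_trait_table(list(), p0)
  df0 <- read_trait_table(p0)
  expect_equal(nrow(df0), 0L)
  expect_equal(names(df0), c("image_id", "cob_id", cob_trait_names(), "unit"))
})

test_that("images survive a PNG write/read round trip", {
  img <- small_scene(seed = 21, n_cobs = 1, px_per_cm = 8)$image
  p <- tempfile(fileext = ".png")
  write_image(img, p)
  back <- read_image(p)
  expect_identical(back$pixels, img$pixels)
})

test_that("mask crops are tight-bbox cutouts", {
  sc <- small_scene(seed = 22, n_cobs = 2, px_per_cm = 8)
  cobs <- Filter(function(m) m$label == "cob", sc$truth$masks)
  d <- tempfile()
  paths <- write_mask_crops(sc$truth$masks, sc$image, d)
  expect_length(paths, 2L)
  crop <- png::readPNG(paths[1])
  bb <- cobs[[1]]$bbox
  expect_equal(dim(crop)[1:2], c(bb[3] - bb[1], bb[4] - bb[2]))
})
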