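test_that("PNG and TIFF round-trip pixels exactly and report format errors", {
  img <- uniform_image(10, 10, c(255, 255, 255))
  p <- withr::local_tempfile(fileext = ".png")
  write_image(img, p)
  back <- read_image(p)
  expect_identical(back$pixels, img$pixels)
  expect_identical(dim(back), c(10L, 10L, 3L))

  rnd <- fibroquant:::with_seed(5, array(sample.int(256, 32 * 32 * 3,
                                                    replace = TRUE) - 1L,
                                         dim = c(32, 32, 3)))
  timg <- raster_image(rnd, slide_id = "rnd")
  tp <- withr::local_tempfile(fileext = ".tif")
  write_image(timg, tp)
  expect_identical(read_image(tp)$pixels, timg$pixels)

  gray <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 8, 8), gray, bits.per.sample = 8L)
  expect_error(read_image(gray), class = "fq_unsupported_format")
  expect_error(read_image("no-such-file.png"), class = "fq_input_error")
})

test_that("an alpha channel is dropped on read", {
  p <- withr::local_tempfile(fileext = ".png")
  arr <- array(1, dim = c(6, 6, 4))
  arr[, , 1] <- 0.2
  png::writePNG(arr, p)
  img <- read_image(p)
  expect_identical(dim(img$pixels)[3], 3L)
  expect_true(all(img$pixels[, , 1] == 51L))
})

test_that("TIFF resolution tags populate microns_per_pixel", {
  # hand-crafted minimal little-endian TIFF: 2x2 RGB, uncompressed,
  # XResolution 2000 px/cm -> 5 microns per pixel
  tp <- withr::local_tempfile(fileext = ".tif")
  con <- file(tp, "wb")
  w16 <- function(...) writeBin(as.integer(c(...)), con, size = 2,
                                endian = "little")
  w32 <- function(...) writeBin(as.integer(c(...)), con, size = 4,
                                endian = "little")
  entry <- function(tag, type, count, value) {
    w16(tag, type); w32(count)
    if (type == 3) w16(value, 0) else w32(value)
  }
  writeChar("II", con, eos = NULL); w16(42); w32(8)  # header
  w16(12)                                            # 12 IFD entries
  entry(256, 3, 1, 2); entry(257, 3, 1, 2)           # width, length
  entry(258, 3, 3, 158)                              # bits/sample -> offset
  entry(259, 3, 1, 1); entry(262, 3, 1, 2)           # no compression, RGB
  entry(273, 4, 1, 180)                              # strip offset
  entry(277, 3, 1, 3); entry(278, 3, 1, 2)           # 3 samples, 2 rows
  entry(279, 4, 1, 12)                               # strip bytes
  entry(282, 5, 1, 164); entry(283, 5, 1, 172)       # X/Y resolution
  entry(296, 3, 1, 3)                                # unit = cm
  w32(0)                                             # no next IFD
  w16(8, 8, 8)                                       # bits per sample
  w32(2000, 1, 2000, 1)                              # 2000 px/cm
  writeBin(as.raw(rep(c(10, 20, 30), 4)), con)       # pixel data
  close(con)
  img <- read_image(tp)
  expect_equal(img$microns_per_pixel, 5)
  expect_identical(dim(img$pixels), c(2L, 2L, 3L))
  expect_true(all(img$pixels[, , 2] == 20L))

  # a TIFF without resolution tags reports no physical scale
  plain <- withr::local_tempfile(fileext = ".tif")
  write_image(uniform_image(4, 4, c(1, 2, 3)), plain)
  expect_true(is.na(read_image(plain)$microns_per_pixel))
})

test_that("annotation GeoJSON round-trips roles, labels and vertices", {
  ann <- annotation_set(list(
    rect_poly(0, 0, 10, 10, "cortex"),
    rect_poly(2, 2, 4, 4, "exclusion", "glomerulus"),
    roi_polygon(cbind(c(5, 8, 6.5), c(5, 5, 8)), "ref_positive")),
    slide_id = "s1")
  p <- withr::local_tempfile(fileext = ".geojson")
  write_annotations(ann, p)
  back <- read_annotations(p)
  expect_identical(back$slide_id, "s1")
  expect_length(back$polygons, 3L)
  for (i in 1:3) {
    expect_identical(back$polygons[[i]]$role, ann$polygons[[i]]$role)
    expect_equal(back$polygons[[i]]$vertices, ann$polygons[[i]]$vertices)
  }
  expect_identical(back$polygons[[2]]$label, "glomerulus")

  empty <- annotation_set(list(), slide_id = "none")
  write_annotations(empty, p)
  expect_length(read_annotations(p)$polygons, 0L)
})

test_that("invalid annotation features are rejected with schema errors", {
  bad_role <- list(type = "FeatureCollection", features = list(list(
    type = "Feature", properties = list(role = "medulla"),
    geometry = list(type = "Polygon",
                    coordinates = list(list(c(0, 0), c(1, 0), c(1, 1)))))))
  p <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(bad_role, p, auto_unbox = TRUE)
  expect_error(read_annotations(p), class = "fq_schema_error",
               regexp = "feature 1")
  expect_error(roi_polygon(cbind(c(0, 1), c(0, 1)), "cortex"),
               class = "fq_schema_error")
  expect_error(roi_polygon(cbind(c(0, 1, 2), c(0, 0, 0)), "cortex"),
               class = "fq_schema_error")  # zero area
})

test_that("rasterization follows the pixel-centre half-open convention", {
  ann <- annotation_set(list(rect_poly(0, 0, 10, 10)))
  m <- rasterize(ann, 20, 20)
  expect_identical(sum(m$grid), 100L)
  expect_identical(unique(as.vector(m$grid[1:10, 1:10])), 1L)

  with_excl <- annotation_set(list(rect_poly(0, 0, 10, 10),
                                   rect_poly(2, 2, 4, 4, "exclusion")))
  expect_identical(sum(rasterize(with_excl, 20, 20)$grid), 96L)

  outside <- annotation_set(list(rect_poly(0, 0, 10, 10),
                                 rect_poly(15, 15, 18, 18, "exclusion")))
  expect_identical(rasterize(outside, 20, 20)$grid, m$grid)

  refs_ignored <- annotation_set(list(rect_poly(0, 0, 10, 10),
                                      rect_poly(1, 1, 3, 3, "ref_positive")))
  expect_identical(rasterize(refs_ignored, 20, 20)$grid, m$grid)

  expect_error(rasterize(annotation_set(list(rect_poly(0, 0, 2, 2,
                                                       "exclusion"))), 5, 5),
               class = "fq_precondition_error")
})

test_that("rasterization is deterministic, monotone under exclusions, and counts rectangles exactly", {
  fibroquant:::with_seed(11, {
    for (rep in 1:20) {
      x0 <- sample(0:20, 1); y0 <- sample(0:20, 1)
      w <- sample(1:15, 1); h <- sample(1:15, 1)
      ann <- annotation_set(list(rect_poly(x0, y0, x0 + w, y0 + h)))
      expect_identical(sum(rasterize(ann, 40, 40)$grid), w * h)
      ex <- rect_poly(sample(0:30, 1), sample(0:30, 1),
                      sample(31:40, 1), sample(31:40, 1), "exclusion")
      ann2 <- annotation_set(list(ann$polygons[[1]], ex))
      expect_lte(sum(rasterize(ann2, 40, 40)$grid),
                 sum(rasterize(ann, 40, 40)$grid))
    }
  })
  ann <- annotation_set(list(roi_polygon(cbind(c(1.2, 17.7, 9.1),
                                               c(2.3, 4.4, 16.6)), "cortex")))
  expect_identical(rasterize(ann, 20, 20)$grid, rasterize(ann, 20, 20)$grid)
})

test_that("extract_pixels returns masked pixels in row-major order", {
  px <- array(0L, dim = c(4, 4, 3))
  px[, , 1] <- matrix(0:15, 4, 4, byrow = TRUE)  # R channel encodes row-major index
  img <- raster_image(px)
  got <- extract_pixels(img, list(rect_poly(0, 0, 2, 2, "ref_positive")))
  expect_identical(nrow(got), 4L)
  expect_identical(as.integer(got[, 1]), c(0L, 1L, 4L, 5L))

  two <- extract_pixels(img, list(rect_poly(0, 0, 1, 2, "ref_positive"),
                                  rect_poly(3, 0, 4, 2, "ref_positive")))
  expect_identical(nrow(two), 4L)

  uni <- uniform_image(6, 6, c(7, 8, 9))
  u <- extract_pixels(uni, list(rect_poly(1, 1, 3, 3, "ref_negative")))
  expect_true(all(u[, 1] == 7L & u[, 2] == 8L & u[, 3] == 9L))

  # sliver between pixel centres covers nothing
  sliver <- roi_polygon(cbind(c(0.6, 0.9, 0.9, 0.6), c(0, 0, 4, 4)),
                        "ref_positive")
  expect_error(extract_pixels(img, list(sliver)), class = "fq_empty_selection")
})

test_that("extract_pixels row count equals the rasterized pixel count", {
  img <- uniform_image(30, 30, c(100, 100, 100))
  fibroquant:::with_seed(3, {
    for (rep in 1:10) {
      v <- cbind(runif(5, 0, 30), runif(5, 0, 30))
      p <- tryCatch(roi_polygon(v, "cortex"), error = function(e) NULL)
      if (is.null(p)) next
      n_mask <- sum(rasterize(annotation_set(list(p)), 30, 30)$grid)
      if (n_mask == 0) next
      expect_identical(nrow(extract_pixels(img, list(p))), n_mask)
    }
  })
})
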