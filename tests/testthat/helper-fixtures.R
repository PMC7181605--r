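# Fixtures are built in code: tiny solid-colour rasters, rectangle
# annotations and small synthetic slides shared across test files.

uniform_image <- function(h, w, rgb, slide_id = "uniform") {
  px <- array(0L, dim = c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- as.integer(rgb[ch])
  raster_image(px, slide_id = slide_id)
}

rect_poly <- function(x0, y0, x1, y1, role = "cortex", label = NA_character_) {
  roi_polygon(cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)), role, label)
}

# two well-separated stain-like RGB samples with mild noise
ref_samples <- function(n = 400, seed = 1) {
  fibroquant:::with_seed(seed, list(
    pos = pmin(pmax(matrix(stats::rnorm(3 * n, rep(c(190, 45, 45), each = n), 5),
                           ncol = 3), 0), 255),
    neg = pmin(pmax(matrix(stats::rnorm(3 * n, rep(c(235, 215, 170), each = n), 5),
                           ncol = 3), 0), 255)))
}

# small fast slide config for tests that only need plumbing, not accuracy
small_config <- function(...) {
  synth_config(height = 96, width = 96, n_tubules = 6, n_glomeruli = 1, ...)
}

# fit a calibration from a synthetic slide's own reference patches
cal_from_slide <- function(sl) {
  roles <- sapply(sl$annotations$polygons, `[[`, "role")
  fit_calibration(
    extract_pixels(sl$image, sl$annotations$polygons[roles == "ref_positive"]),
    extract_pixels(sl$image, sl$annotations$polygons[roles == "ref_negative"]),
    slide_id = sl$image$slide_id)
}
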