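# Deterministic synthetic Sirius-Red renal-cortex slides with known
# ground-truth fibrosis fraction.
#
# A slide is rendered procedurally: an octagonal cortical region containing
# non-overlapping tubule ellipses (counterstain ring around a white lumen)
# and glomerular discs, with interstitial fibrosis painted where a seeded
# Gaussian-smoothed noise field exceeds a threshold chosen so the realized
# fraction of the evaluation region (cortex minus glomerular exclusions)
# hits the target exactly. Two control bars of pure positive stain and pure
# counterstain are rendered in the top margin, outside the cortex, and
# serve as fallback reference material when the in-tissue regions are too
# fragmented to host reference patches. Class colours get Gaussian pixel
# noise, then a global batch transform (intensity gain, hue rotation) that
# emulates batch-to-batch staining variation; truth masks are recorded
# before noise.

#' Configuration for a synthetic slide
#'
#' @param height,width canvas size in pixels.
#' @param fibrosis_fraction target fibrosis fraction of the evaluation
#'   region, in `[0, 1]`.
#' @param n_tubules,n_glomeruli structure counts.
#' @param stain_pos_rgb,stain_neg_rgb,background_rgb class colours (8-bit
#'   RGB); defaults approximate Sirius-Red collagen, pale counterstained
#'   tissue and luminal white space.
#' @param batch_gain global intensity gain applied after rendering.
#' @param batch_hue_shift_deg global hue rotation in degrees.
#' @param noise_sd per-channel Gaussian pixel noise SD (intensity units).
#' @param field_smoothness Gaussian blur sigma (px) of the fibrosis field;
#'   larger values give coarser, more connected fibrotic bands.
#' @param seed RNG seed; identical config (incl. seed) gives bit-identical
#'   output.
#' @return A `synth_config` object.
#' @export
synth_config <- function(height = 192, width = 192, fibrosis_fraction = 0.15,
                         n_tubules = 30, n_glomeruli = 2,
                         stain_pos_rgb = c(190, 45, 45),
                         stain_neg_rgb = c(235, 215, 170),
                         background_rgb = c(250, 250, 250),
                         batch_gain = 1.0, batch_hue_shift_deg = 0,
                         noise_sd = 4, field_smoothness = 3, seed = 1L) {
  stopifnot(height >= 96, width >= 96,
            fibrosis_fraction >= 0, fibrosis_fraction <= 1,
            n_tubules >= 0, n_glomeruli >= 0, noise_sd >= 0,
            field_smoothness > 0, batch_gain > 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 fibrosis_fraction = fibrosis_fraction,
                 n_tubules = as.integer(n_tubules),
                 n_glomeruli = as.integer(n_glomeruli),
                 stain_pos_rgb = stain_pos_rgb,
                 stain_neg_rgb = stain_neg_rgb,
                 background_rgb = background_rgb,
                 batch_gain = batch_gain,
                 batch_hue_shift_deg = batch_hue_shift_deg,
                 noise_sd = noise_sd, field_smoothness = field_smoothness,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# ---- small geometry helpers -------------------------------------------

# Pixel-centre coordinate grids (0-based continuous), column-major.
centre_grid <- function(height, width) {
  list(x = matrix(rep(seq_len(width) - 0.5, each = height), height, width),
       y = matrix(rep(seq_len(height) - 0.5, times = width), height, width))
}

ellipse_mask <- function(g, cx, cy, a, b, theta = 0) {
  dx <- g$x - cx; dy <- g$y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

regular_polygon <- function(cx, cy, r, n = 20) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

rect_polygon <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# Exact two-pass Chebyshev distance transform: distance (in pixels, >= 1
# inside) to the nearest FALSE pixel or border. Used to find inscribed
# squares for reference patches.
chebyshev_dt <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  d <- matrix(0L, h, w)
  big <- h + w
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!mask[r, c]) next
    up <- if (r > 1) d[r - 1, c] else 0L
    lf <- if (c > 1) d[r, c - 1] else 0L
    ul <- if (r > 1 && c > 1) d[r - 1, c - 1] else 0L
    ur <- if (r > 1 && c < w) d[r - 1, c + 1] else 0L
    d[r, c] <- min(up, lf, ul, ur, big) + 1L
  }
  for (r in rev(seq_len(h))) for (c in rev(seq_len(w))) {
    if (!mask[r, c]) next
    dn <- if (r < h) d[r + 1, c] else 0L
    rt <- if (c < w) d[r, c + 1] else 0L
    dr <- if (r < h && c < w) d[r + 1, c + 1] else 0L
    dl <- if (r < h && c > 1) d[r + 1, c - 1] else 0L
    d[r, c] <- min(d[r, c], min(dn, rt, dr, dl, big) + 1L)
  }
  d
}

# Greedily pick axis-aligned squares fully inside `mask` until `target_px`
# pixels are collected (or `max_patches` reached). Returns a list of
# 0-based (x0, y0, x1, y1) rectangles; side capped at `max_side`.
pick_patches <- function(mask, target_px = 220L, max_patches = 10L,
                         min_side = 3L, max_side = 40L) {
  patches <- list()
  got <- 0L
  work <- mask
  while (got < target_px && length(patches) < max_patches) {
    d <- chebyshev_dt(work)
    dm <- max(d)
    side <- min(2L * dm - 1L, max_side)
    if (dm < 1L || side < min_side) break
    idx <- which(d == dm)[1]
    rc <- arrayInd(idx, dim(work))
    half <- (side - 1L) %/% 2L
    r0 <- rc[1] - half; c0 <- rc[2] - half
    patches[[length(patches) + 1L]] <-
      c(x0 = c0 - 1, y0 = r0 - 1, x1 = c0 - 1 + side, y1 = r0 - 1 + side)
    got <- got + side^2
    work[max(1, r0 - 1):min(nrow(work), r0 + side),
         max(1, c0 - 1):min(ncol(work), c0 + side)] <- FALSE
  }
  attr(patches, "pixels") <- got
  patches
}

# HSV (h, s, v in [0, 1]) -> RGB in [0, 1], vectorized.
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); tt <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, tt, v)))))
  g <- ifelse(i == 0, tt, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, tt,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

# Global staining-batch transform on an H x W x 3 0..255 array.
apply_batch_transform <- function(px, gain, hue_deg) {
  if (hue_deg != 0) {
    rgb <- cbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
                 as.vector(px[, , 3])) / 255
    hsv <- grDevices::rgb2hsv(t(rgb * 255), maxColorValue = 255)
    out <- hsv_to_rgb(hsv[1, ] + hue_deg / 360, hsv[2, ], hsv[3, ]) * 255
    px <- array(out, dim = dim(px))
  }
  pmin(pmax(px * gain, 0), 255)
}

# ---- the generator -----------------------------------------------------

#' Generate one synthetic Sirius-Red slide with ground truth
#'
#' See the package vignette for the rendering model. The fibrosis threshold
#' is an exact order statistic of the smoothed field over the candidate
#' interstitium, so `realized_fraction` matches the target to within one
#' pixel of the evaluation region.
#'
#' @param config a [synth_config()].
#' @return A `synth_slide`: `image` ([raster_image()]), `annotations`
#'   ([annotation_set()] with cortex, glomerular exclusions and reference
#'   patches), logical truth masks (`truth_fibrosis`, `truth_cortex`,
#'   `truth_glomeruli`, `truth_lumen`, `truth_counterstain`,
#'   `truth_background`), `realized_fraction` and the `config`.
#' @export
generate_slide <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, generate_slide_impl(config))
}

generate_slide_impl <- function(cf) {
  h <- cf$height; w <- cf$width
  g <- centre_grid(h, w)
  slide_id <- sprintf("synth-seed%d", cf$seed)

  # cortical octagon: rectangle inset (top margin hosts the control bars)
  # with cut corners
  top <- 20; m <- 6; cut <- round(min(h, w) / 8)
  x0 <- m; x1 <- w - m; y0 <- top; y1 <- h - m
  cortex_v <- cbind(
    c(x0 + cut, x1 - cut, x1, x1, x1 - cut, x0 + cut, x0, x0),
    c(y0, y0, y0 + cut, y1 - cut, y1, y1, y1 - cut, y0 + cut))
  cortex_poly <- roi_polygon(cortex_v, "cortex")

  # control bars in the top margin (pure stain classes, outside cortex)
  bar_y0 <- 2; bar_y1 <- 16
  pos_bar <- c(2, bar_y0, floor(w / 2) - 4, bar_y1)
  neg_bar <- c(floor(w / 2) + 4, bar_y0, w - 2, bar_y1)
  bar_mask <- function(b) g$x > b[1] & g$x < b[3] & g$y > b[2] & g$y < b[4]
  pos_bar_mask <- bar_mask(pos_bar)
  neg_bar_mask <- bar_mask(neg_bar)

  # fibrosis field first so the field is identical across structure layouts
  field <- matrix(stats::rnorm(h * w), h, w)
  field <- as.matrix(EBImage::gblur(field, sigma = cf$field_smoothness))

  # place glomeruli then tubules, non-overlapping, inside the cortex
  glom_mask <- matrix(FALSE, h, w)
  tub_full <- matrix(FALSE, h, w)
  tub_lumen <- matrix(FALSE, h, w)
  placed <- list()   # (cx, cy, radius) bounding circles
  excl_polys <- list()
  place_ok <- function(cx, cy, r) {
    if (winding_number(cx, cy, cortex_v) == 0L) return(FALSE)
    for (p in placed)
      if ((cx - p[1])^2 + (cy - p[2])^2 < (r + p[3] + 2)^2) return(FALSE)
    TRUE
  }
  rand_centre <- function(r) c(stats::runif(1, x0 + r + 2, x1 - r - 2),
                               stats::runif(1, y0 + r + 2, y1 - r - 2))
  for (i in seq_len(cf$n_glomeruli)) {
    r <- stats::runif(1, 11, 14)
    for (try in 1:200) {
      ctr <- rand_centre(r)
      if (place_ok(ctr[1], ctr[2], r)) {
        glom_mask <- glom_mask | ellipse_mask(g, ctr[1], ctr[2], r, r)
        placed[[length(placed) + 1L]] <- c(ctr, r)
        excl_polys[[length(excl_polys) + 1L]] <-
          roi_polygon(regular_polygon(ctr[1], ctr[2], r + 1.5),
                      "exclusion", label = "glomerulus")
        break
      }
    }
  }
  for (i in seq_len(cf$n_tubules)) {
    a <- stats::runif(1, 4.5, 8); b <- stats::runif(1, 4, a)
    th <- stats::runif(1, 0, pi)
    for (try in 1:200) {
      ctr <- rand_centre(a)
      if (place_ok(ctr[1], ctr[2], a)) {
        tub_full <- tub_full | ellipse_mask(g, ctr[1], ctr[2], a, b, th)
        tub_lumen <- tub_lumen | ellipse_mask(g, ctr[1], ctr[2],
                                              0.55 * a, 0.55 * b, th)
        placed[[length(placed) + 1L]] <- c(ctr, a)
        break
      }
    }
  }

  # evaluation region = cortex minus glomerular exclusion polygons, exactly
  # as the quantification pipeline will rasterize it
  base_ann <- annotation_set(c(list(cortex_poly), excl_polys), slide_id)
  eval_mask <- rasterize(base_ann, h, w)$grid == 1L
  n_eval <- sum(eval_mask)

  # paint fibrosis on the interstitial candidates by exact order statistic
  candidates <- eval_mask & !tub_full & !glom_mask
  n_target <- round(cf$fibrosis_fraction * n_eval)
  if (n_target > sum(candidates))
    fq_error("fq_generation_error", paste0(
      "fibrosis fraction ", cf$fibrosis_fraction, " unattainable: only ",
      sum(candidates), " of ", n_eval, " evaluation pixels are ",
      "interstitium; reduce n_tubules/n_glomeruli"))
  fib <- matrix(FALSE, h, w)
  if (n_target > 0) {
    vals <- field[candidates]
    thr <- sort(vals, decreasing = TRUE)[n_target]
    fib <- candidates & field >= thr
  }
  realized <- sum(fib & eval_mask) / n_eval

  # class layout (truth recorded before noise)
  cortex_mask <- polygons_mask(list(cortex_poly), h, w)
  counterstain <- (cortex_mask & !fib & !tub_lumen & !glom_mask) | neg_bar_mask
  lumen <- tub_lumen & cortex_mask & !fib
  fib_all <- fib | pos_bar_mask
  background <- !(counterstain | lumen | fib_all | glom_mask)

  paint <- function(mask3, col) {
    for (ch in 1:3) {
      plane <- px[, , ch]; plane[mask3] <- col[ch]; px[, , ch] <<- plane
    }
  }
  px <- array(0, dim = c(h, w, 3))
  paint(background, cf$background_rgb)
  paint(counterstain, cf$stain_neg_rgb)
  paint(lumen, cf$background_rgb)
  paint(glom_mask, c(214, 168, 160))   # glomerular tuft (excluded region)
  paint(fib_all, cf$stain_pos_rgb)
  if (cf$noise_sd > 0)
    px <- px + array(stats::rnorm(length(px), 0, cf$noise_sd), dim = dim(px))
  px <- apply_batch_transform(px, cf$batch_gain, cf$batch_hue_shift_deg)
  image <- raster_image(array(as.integer(round(px)), dim = dim(px)),
                        slide_id = slide_id)

  # reference patches: in-tissue squares when large enough, control bars
  # as fallback (both are pure truth regions)
  patch_polys <- function(mask, role) {
    ps <- pick_patches(mask)
    if (attr(ps, "pixels") < MIN_CALIBRATION_PIXELS) return(list())
    lapply(ps, function(b) roi_polygon(
      rect_polygon(b["x0"], b["y0"], b["x1"], b["y1"]), role))
  }
  pos_patches <- patch_polys(fib, "ref_positive")
  if (length(pos_patches) == 0L)
    pos_patches <- patch_polys(pos_bar_mask, "ref_positive")
  neg_patches <- patch_polys(counterstain & cortex_mask, "ref_negative")
  if (length(neg_patches) == 0L)
    neg_patches <- patch_polys(neg_bar_mask, "ref_negative")
  if (length(pos_patches) == 0L || length(neg_patches) == 0L)
    fq_error("fq_generation_error",
             "could not place reference patches; enlarge the canvas")

  ann <- annotation_set(c(list(cortex_poly), excl_polys,
                          pos_patches, neg_patches), slide_id)
  structure(list(image = image, annotations = ann,
                 truth_fibrosis = fib_all, truth_cortex = cortex_mask,
                 truth_glomeruli = glom_mask, truth_lumen = lumen,
                 truth_counterstain = counterstain,
                 truth_background = background,
                 evaluation_mask = eval_mask,
                 realized_fraction = realized, config = cf),
            class = "synth_slide")
}

#' @export
print.synth_slide <- function(x, ...) {
  cat(sprintf("<synth_slide> %s: %dx%d, realized fibrosis %.4f (target %.4f)\n",
              x$image$slide_id, x$config$height, x$config$width,
              x$realized_fraction, x$config$fibrosis_fraction))
  invisible(x)
}

#' Generate a batch of synthetic slides across fractions and stain gains
#'
#' One slide per (fraction, gain) pair of the cartesian product, each with
#' a seed derived from (`seed`, slide index) so batches are reproducible
#' while fields stay independent across slides.
#'
#' @param base a [synth_config()] providing all other parameters.
#' @param fractions fibrosis fractions; default `c(0.05, 0.15, 0.25)`.
#' @param batch_gains staining intensity gains; default `c(0.9, 1.0, 1.1)`.
#' @param seed batch seed.
#' @return List of `synth_slide` objects (fractions varying slowest).
#' @export
generate_batch <- function(base = synth_config(),
                           fractions = c(0.05, 0.15, 0.25),
                           batch_gains = c(0.9, 1.0, 1.1), seed = 1L) {
  if (length(fractions) == 0L || length(batch_gains) == 0L)
    fq_error("fq_precondition_error", "fractions and batch_gains must be non-empty")
  grid <- expand.grid(gain = batch_gains, fraction = fractions,
                      KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    cf <- base
    cf$fibrosis_fraction <- grid$fraction[i]
    cf$batch_gain <- grid$gain[i]
    cf$seed <- derive_seed(seed, i)
    generate_slide(cf)
  })
}

#' Write a synthetic slide to disk
#'
#' Writes the image (PNG), truth masks (PNG, 0/255), annotations (GeoJSON)
#' and a `truth.json` with the realized fraction and config.
#'
#' @param slide a `synth_slide`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_slide <- function(slide, out_dir) {
  stopifnot(inherits(slide, "synth_slide"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_image(slide$image, file.path(out_dir, "image.png"))
  for (m in c("truth_fibrosis", "truth_cortex", "truth_glomeruli",
              "truth_background"))
    png::writePNG(slide[[m]] * 1.0, file.path(out_dir, paste0(m, ".png")))
  write_annotations(slide$annotations, file.path(out_dir, "annotations.geojson"))
  jsonlite::write_json(
    list(slide_id = slide$image$slide_id,
         realized_fraction = slide$realized_fraction,
         config = slide$config[setdiff(names(slide$config), "")]),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
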