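# Raster images, polygon annotations (GeoJSON) and rasterization.
#
# Coordinate convention used throughout: 0-based continuous pixel
# coordinates, x rightward and y downward, so the centre of the pixel at
# (row r, column c) is the point (c + 0.5, r + 0.5). Polygon containment is
# decided at pixel centres under the non-zero winding rule.

VALID_ROLES <- c("cortex", "exclusion", "ref_positive", "ref_negative")

#' Construct an 8-bit RGB raster image
#'
#' @param pixels integer array of dimension H x W x 3 with values in 0..255.
#' @param slide_id slide identifier.
#' @param microns_per_pixel physical resolution, or `NA` when unknown.
#' @return A `raster_image` object.
#' @export
raster_image <- function(pixels, slide_id = "slide", microns_per_pixel = NA_real_) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    fq_error("fq_input_error", "pixels must be an H x W x 3 array")
  if (any(dim(pixels)[1:2] < 1L))
    fq_error("fq_input_error", "image must have H >= 1 and W >= 1")
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L)
    fq_error("fq_input_error", "channel values must lie in [0, 255]")
  structure(list(pixels = pixels, slide_id = as.character(slide_id),
                 microns_per_pixel = as.numeric(microns_per_pixel)),
            class = "raster_image")
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image> %s: %d x %d px, 8-bit RGB%s\n", x$slide_id,
              d[1], d[2],
              if (is.na(x$microns_per_pixel)) ""
              else sprintf(", %.3f um/px", x$microns_per_pixel)))
  invisible(x)
}

#' Construct a region-of-interest polygon
#'
#' @param vertices numeric n x 2 matrix of (x, y) pixel coordinates (x
#'   rightward, y downward, 0-based). The ring is implicitly closed.
#' @param role one of `"cortex"`, `"exclusion"`, `"ref_positive"`,
#'   `"ref_negative"`.
#' @param label optional free-text label (e.g. `"glomerulus"`).
#' @return A `roi_polygon` object.
#' @export
roi_polygon <- function(vertices, role, label = NA_character_) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L)
    fq_error("fq_schema_error", "vertices must be an n x 2 numeric matrix")
  # drop an explicit closing vertex if present
  n <- nrow(vertices)
  if (n >= 2L && all(vertices[1, ] == vertices[n, ]))
    vertices <- vertices[-n, , drop = FALSE]
  if (nrow(vertices) < 3L)
    fq_error("fq_schema_error", "polygon needs at least 3 distinct vertices")
  if (abs(polygon_area(vertices)) < .Machine$double.eps)
    fq_error("fq_schema_error", "polygon encloses zero area")
  role <- match.arg(role, VALID_ROLES)
  structure(list(vertices = unname(vertices), role = role,
                 label = as.character(label)),
            class = "roi_polygon")
}

# Signed area by the shoelace formula (positive = counter-clockwise in the
# y-down coordinate system's own orientation; only |area| matters here).
polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Construct an annotation set for one slide
#'
#' @param polygons list of [roi_polygon()] objects.
#' @param slide_id slide identifier.
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(polygons, slide_id = "slide") {
  if (!all(vapply(polygons, inherits, logical(1), "roi_polygon")))
    fq_error("fq_schema_error", "polygons must all be roi_polygon objects")
  structure(list(slide_id = as.character(slide_id), polygons = polygons),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  roles <- vapply(x$polygons, `[[`, character(1), "role")
  cat(sprintf("<annotation_set> %s: %d polygons (%s)\n", x$slide_id,
              length(roles), paste(sprintf("%s=%d", names(table(roles)),
                                           table(roles)), collapse = ", ")))
  invisible(x)
}

roles_of <- function(annotations) {
  vapply(annotations$polygons, `[[`, character(1), "role")
}

#' Read an 8-bit RGB image from PNG or TIFF
#'
#' An alpha channel, if present, is dropped. For TIFF, physical resolution is
#' taken from the XResolution/ResolutionUnit tags when present (interpreted
#' per TIFF 6.0: unit 2 = inch, unit 3 = centimetre).
#'
#' @param path path to a `.png` or `.tif`/`.tiff` file.
#' @param slide_id slide identifier; defaults to the file stem.
#' @return A [raster_image()].
#' @export
read_image <- function(path, slide_id = NULL) {
  if (!file.exists(path))
    fq_error("fq_input_error", sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  mpp <- NA_real_
  if (ext == "png") {
    arr <- tryCatch(png::readPNG(path), error = function(e)
      fq_error("fq_input_error", sprintf("cannot decode PNG %s: %s", path,
                                         conditionMessage(e))))
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tryCatch(tiff::readTIFF(path, info = TRUE),
                    error = function(e)
      fq_error("fq_input_error", sprintf("cannot decode TIFF %s: %s", path,
                                         conditionMessage(e))))
    info <- attributes(arr)
    if (!is.null(info$x.resolution) && is.finite(info$x.resolution) &&
        info$x.resolution > 0) {
      unit <- if (is.null(info$resolution.unit)) "inch" else info$resolution.unit
      per_unit_um <- switch(as.character(unit),
                            "inch" = 25400, "2" = 25400,
                            "cm" = 10000, "3" = 10000, NA_real_)
      mpp <- per_unit_um / info$x.resolution
    }
  } else {
    fq_error("fq_unsupported_format",
             sprintf("unsupported image extension '%s' (PNG/TIFF only)", ext))
  }
  if (length(dim(arr)) == 2L)
    fq_error("fq_unsupported_format",
             sprintf("grayscale image not supported (need 8-bit RGB): %s", path))
  if (dim(arr)[3] == 4L) arr <- arr[, , 1:3, drop = FALSE]
  if (dim(arr)[3] != 3L)
    fq_error("fq_unsupported_format",
             sprintf("expected RGB(A) channels, got %d: %s", dim(arr)[3], path))
  if (max(arr) > 1 + 1e-9)
    fq_error("fq_unsupported_format",
             sprintf("not decodable as 8-bit RGB: %s", path))
  px <- array(as.integer(round(arr * 255)), dim = dim(arr))
  if (is.null(slide_id))
    slide_id <- tools::file_path_sans_ext(basename(path))
  raster_image(px, slide_id = slide_id, microns_per_pixel = mpp)
}

#' Write an 8-bit RGB image to PNG or TIFF
#'
#' @param image a [raster_image()].
#' @param path output path; format chosen by extension.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "raster_image"))
  arr <- image$pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(arr, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  else fq_error("fq_unsupported_format",
                sprintf("unsupported image extension '%s'", ext))
  invisible(path)
}

#' Read polygon annotations from a GeoJSON FeatureCollection
#'
#' Each feature must be a Polygon with a `role` property in
#' `cortex | exclusion | ref_positive | ref_negative`; an optional `label`
#' property is preserved and unknown properties are ignored. Only the outer
#' ring of each polygon is used.
#'
#' @param path path to a GeoJSON file.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path))
    fq_error("fq_input_error", sprintf("annotation file not found: %s", path))
  gj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e)
    fq_error("fq_schema_error", sprintf("cannot parse GeoJSON %s: %s", path,
                                        conditionMessage(e))))
  if (!identical(gj$type, "FeatureCollection"))
    fq_error("fq_schema_error", "expected a GeoJSON FeatureCollection")
  slide_id <- if (!is.null(gj$name)) gj$name else
    tools::file_path_sans_ext(basename(path))
  polygons <- vector("list", length(gj$features))
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    if (!identical(f$geometry$type, "Polygon"))
      fq_error("fq_schema_error",
               sprintf("feature %d: geometry must be Polygon", i))
    role <- f$properties$role
    if (is.null(role) || !is.character(role) || !(role %in% VALID_ROLES))
      fq_error("fq_schema_error",
               sprintf("feature %d: missing or invalid 'role' property", i))
    ring <- f$geometry$coordinates[[1]]
    verts <- do.call(rbind, lapply(ring, function(p) as.numeric(p[1:2])))
    if (is.null(verts) || nrow(verts) < 3L)
      fq_error("fq_schema_error",
               sprintf("feature %d: polygon ring needs >= 3 vertices", i))
    label <- if (is.null(f$properties$label)) NA_character_ else
      as.character(f$properties$label)
    polygons[[i]] <- roi_polygon(verts, role = role, label = label)
  }
  annotation_set(polygons, slide_id = slide_id)
}

#' Write an annotation set as a GeoJSON FeatureCollection
#'
#' @param annotations an [annotation_set()].
#' @param path output path.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_set"))
  features <- lapply(annotations$polygons, function(p) {
    v <- p$vertices
    ring <- lapply(seq_len(nrow(v) + 1L), function(i) {
      j <- if (i > nrow(v)) 1L else i   # close the ring explicitly
      c(v[j, 1], v[j, 2])
    })
    props <- list(role = jsonlite::unbox(p$role))
    if (!is.na(p$label)) props$label <- jsonlite::unbox(p$label)
    list(type = jsonlite::unbox("Feature"),
         properties = props,
         geometry = list(type = jsonlite::unbox("Polygon"),
                         coordinates = list(ring)))
  })
  gj <- list(type = jsonlite::unbox("FeatureCollection"),
             name = jsonlite::unbox(annotations$slide_id),
             features = features)
  ok <- tryCatch({
    jsonlite::write_json(gj, path, digits = NA, auto_unbox = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) fq_error("fq_io_error", sprintf("cannot write %s", path))
  invisible(path)
}

# Winding number of point set (px, py) for one polygon ring; non-zero means
# inside. Vectorized over points, looped over edges.
winding_number <- function(px, py, vertices) {
  wn <- integer(length(px))
  n <- nrow(vertices)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- vertices[i, 1]; y1 <- vertices[i, 2]
    x2 <- vertices[j, 1]; y2 <- vertices[j, 2]
    cross <- (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1)
    up <- (y1 <= py) & (py < y2) & (cross > 0)
    dn <- (y2 <= py) & (py < y1) & (cross < 0)
    wn <- wn + up - dn
  }
  wn
}

# Logical H x W matrix: pixel centres inside the union of the given polygons
# (non-zero winding per polygon, then union).
polygons_mask <- function(polygons, height, width) {
  inside <- matrix(FALSE, height, width)
  if (length(polygons) == 0L) return(inside)
  px <- rep(seq_len(width) - 0.5, each = height)    # column-major fill
  py <- rep(seq_len(height) - 0.5, times = width)
  for (p in polygons) {
    wn <- winding_number(px, py, p$vertices)
    inside <- inside | matrix(wn != 0L, height, width)
  }
  inside
}

#' Rasterize annotations into an evaluation mask
#'
#' The evaluation region is the union of cortex polygons minus the union of
#' exclusion polygons. Reference patches do not affect the mask. A pixel at
#' (row r, col c), 1-based in R, belongs to a polygon iff its centre
#' (c - 0.5, r - 0.5) in 0-based continuous coordinates lies inside it under
#' the non-zero winding rule.
#'
#' @param annotations an [annotation_set()] with at least one cortex polygon.
#' @param height,width target raster dimensions (must match the image).
#' @return A `label_mask`: list with `grid` (H x W 0/1 integer matrix) and
#'   `provenance`.
#' @export
rasterize <- function(annotations, height, width) {
  stopifnot(inherits(annotations, "annotation_set"))
  roles <- roles_of(annotations)
  if (!any(roles == "cortex"))
    fq_error("fq_precondition_error",
             "rasterize needs at least one cortex polygon")
  cortex <- polygons_mask(annotations$polygons[roles == "cortex"], height, width)
  excl <- polygons_mask(annotations$polygons[roles == "exclusion"], height, width)
  grid <- matrix(0L, height, width)
  grid[cortex & !excl] <- 1L
  structure(list(grid = grid,
                 provenance = sprintf("cortex\\exclusion mask for %s",
                                      annotations$slide_id)),
            class = "label_mask")
}

#' Extract the RGB pixels under a set of polygons
#'
#' Returns the pixels whose centres lie inside the union of the given
#' polygons, as an N x 3 integer matrix in row-major (row, then column)
#' order.
#'
#' @param image a [raster_image()].
#' @param polygons list of [roi_polygon()] objects.
#' @return N x 3 integer matrix of 8-bit RGB values.
#' @export
extract_pixels <- function(image, polygons) {
  stopifnot(inherits(image, "raster_image"))
  if (length(polygons) == 0L)
    fq_error("fq_precondition_error", "no polygons given")
  d <- dim(image$pixels)
  m <- polygons_mask(polygons, d[1], d[2])
  idx <- which(t(m))                    # row-major order
  if (length(idx) == 0L)
    fq_error("fq_empty_selection", "polygon union covers no pixel centres")
  rc <- arrayInd(idx, c(d[2], d[1]))    # transposed: [,1]=col, [,2]=row
  r <- rc[, 2]; c <- rc[, 1]
  cbind(R = image$pixels[cbind(r, c, 1L)],
        G = image$pixels[cbind(r, c, 2L)],
        B = image$pixels[cbind(r, c, 3L)])
}
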