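#' @useDynLib cobpheno, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Coordinate conventions used throughout the package:
#  * pixel coordinates are 0-based; pixel (row r, col c) has its center at
#    (x = c + 0.5, y = r + 0.5) with x rightward and y downward (image
#    convention, matching VIA annotations);
#  * bounding boxes are half-open: c(row_min, col_min, row_max, col_max)
#    covers rows [row_min, row_max) and cols [col_min, col_max);
#  * images are H x W x 3 integer arrays, channel order RGB, values 0..255.

#' Construct a raster image
#'
#' Wraps an H x W x 3 integer pixel array (RGB, values in 0..255) together
#' with an image identifier. All package functions that take an image accept
#' this class.
#'
#' @param pixels numeric or integer array of dimension H x W x 3; values must
#'   lie in \[0, 255\].
#' @param image_id character scalar identifying the image.
#' @param source_path optional path the image was read from.
#' @return An object of class `cob_image`: a list with elements `pixels`
#'   (integer array), `image_id` and `source_path`.
#' @export
raster_image <- function(pixels, image_id = "image", source_path = NA_character_) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one row and one column")
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop("pixel values must lie in [0, 255] and contain no NA")
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, image_id = as.character(image_id),
         source_path = source_path),
    class = "cob_image"
  )
}

#' @export
print.cob_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<cob_image '%s': %d x %d px, RGB>\n", x$image_id, d[1], d[2]))
  invisible(x)
}

#' Image dimensions
#' @param image a `cob_image`.
#' @return Integer vector `c(H, W)`.
#' @export
image_dim <- function(image) {
  stopifnot(inherits(image, "cob_image"))
  dim(image$pixels)[1:2]
}

#' Construct an instance mask
#'
#' A binary pixel mask for a single object instance (a cob or one part of the
#' ruler), with a class label and a confidence score. The tight bounding box
#' is computed from the foreground pixels and stored in half-open 0-based form
#' `c(row_min, col_min, row_max, col_max)`.
#'
#' @param mask logical H x W matrix; must contain at least one `TRUE` pixel.
#' @param label class label, `"cob"` or `"ruler"`.
#' @param confidence real in \[0, 1\]; 1.0 denotes ground truth.
#' @return An object of class `instance_mask`.
#' @export
instance_mask <- function(mask, label = c("cob", "ruler"), confidence = 1.0) {
  label <- match.arg(label)
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  mask <- mask != 0
  if (!any(mask)) stop("mask has no foreground pixels")
  if (confidence < 0 || confidence > 1) stop("confidence must lie in [0, 1]")
  idx <- which(mask, arr.ind = TRUE)
  bbox <- c(min(idx[, 1]) - 1L, min(idx[, 2]) - 1L,
            max(idx[, 1]), max(idx[, 2]))
  structure(
    list(mask = mask, label = label, confidence = as.numeric(confidence),
         bbox = as.integer(bbox)),
    class = "instance_mask"
  )
}

#' @export
print.instance_mask <- function(x, ...) {
  cat(sprintf("<instance_mask '%s': %d px, bbox [%d,%d)x[%d,%d), conf %.2f>\n",
              x$label, sum(x$mask), x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4],
              x$confidence))
  invisible(x)
}

#' Area of an instance mask
#' @param x an `instance_mask`.
#' @return Number of foreground pixels.
#' @export
mask_area <- function(x) {
  stopifnot(inherits(x, "instance_mask"))
  sum(x$mask)
}

#' Construct a polygon region
#'
#' An ordered polygon in image coordinates (x rightward, y downward, 0-based
#' pixel edges) with a class label, as stored by the VIA annotation tool.
#'
#' @param x,y numeric vertex coordinates (equal length, >= 3 vertices).
#' @param label class label, `"cob"` or `"ruler"`.
#' @return An object of class `polygon_region` with a `vertices` matrix
#'   (columns `x`, `y`) and a `label`.
#' @export
polygon_region <- function(x, y, label = c("cob", "ruler")) {
  label <- match.arg(label)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("a polygon needs at least 3 vertices")
  structure(
    list(vertices = cbind(x = as.numeric(x), y = as.numeric(y)), label = label),
    class = "polygon_region"
  )
}

#' Construct an annotation set
#'
#' All labeled polygon regions of one image.
#'
#' @param image_id character scalar.
#' @param regions list of [polygon_region()] objects.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(image_id, regions = list()) {
  ok <- vapply(regions, inherits, logical(1), what = "polygon_region")
  if (!all(ok)) stop("all regions must be polygon_region objects")
  structure(list(image_id = as.character(image_id), regions = regions),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  labs <- vapply(x$regions, `[[`, character(1), "label")
  cat(sprintf("<annotation_set '%s': %d regions (%d cob, %d ruler)>\n",
              x$image_id, length(labs), sum(labs == "cob"), sum(labs == "ruler")))
  invisible(x)
}

# The eight phenotypic traits, in canonical column order.
TRAIT_NAMES <- c("length", "diameter", "aspect_ratio", "asymmetry",
                 "ellipticity", "mean_r", "mean_g", "mean_b")

#' Names of the eight cob traits
#'
#' Canonical order of the eight phenotypic traits emitted per cob: length,
#' diameter, aspect ratio (length/diameter), asymmetry, ellipticity and the
#' mean red, green and blue channel values over the mask.
#'
#' @return Character vector of length 8.
#' @export
cob_trait_names <- function() TRAIT_NAMES
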