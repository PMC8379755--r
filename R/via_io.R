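# I/O: images (PNG/JPG), VIA v2 polygon annotations, labeled mask images,
# trait tables, and polygon-to-mask rasterization.

#' Read an RGB image
#'
#' Reads a PNG or JPEG image into a [raster_image()]. Grayscale images are
#' expanded to three identical channels; an alpha channel, if present, is
#' dropped. Pixel values are rescaled to integers in 0..255 with channel
#' order RGB (BGR sources do not occur with these readers).
#'
#' @param path file path ending in `.png`, `.jpg` or `.jpeg`.
#' @param image_id identifier; defaults to the file name without extension.
#' @return A `cob_image`.
#' @export
read_image <- function(path, image_id = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)            # H x W [x C], values in [0,1]
  } else if (ext %in% c("jpg", "jpeg")) {
    img <- EBImage::readImage(path)     # W x H [x C]
    px <- EBImage::imageData(img)
    px <- if (length(dim(px)) == 2L) t(px) else aperm(px, c(2, 1, 3))
  } else {
    stop("unsupported image format: .", ext)
  }
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3] == 1L) px <- array(px[, , 1], c(dim(px)[1:2], 3L))
  if (is.null(image_id)) image_id <- tools::file_path_sans_ext(basename(path))
  raster_image(round(px * 255), image_id = image_id, source_path = path)
}

#' Write an RGB image as PNG
#'
#' @param image a `cob_image`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "cob_image"))
  px <- image$pixels / 255
  storage.mode(px) <- "double"
  png::writePNG(px, target = path)
  invisible(path)
}

#' Resize an image
#'
#' Bilinear resize to a target width and height (default 1000 x 666, the
#' working resolution used for genebank scans).
#'
#' @param image a `cob_image`.
#' @param width,height target size in pixels.
#' @return A resized `cob_image`.
#' @export
resize_image <- function(image, width = 1000, height = 666) {
  stopifnot(inherits(image, "cob_image"))
  ebi <- EBImage::Image(aperm(image$pixels / 255, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(ebi, w = width, h = height)
  px <- pmin(pmax(aperm(EBImage::imageData(out), c(2, 1, 3)), 0), 1)
  raster_image(round(px * 255), image_id = image$image_id,
               source_path = image$source_path)
}

#' Read VIA v2 polygon annotations
#'
#' Parses the JSON export of the VGG Image Annotator (version 2). Both export
#' shapes are accepted: a full project file (with `_via_img_metadata`) and the
#' plain region-list export (a map from file key to image record). Only
#' polygon regions are kept; regions with fewer than 3 vertices are dropped
#' with a warning, as are regions with a class label other than `"cob"` or
#' `"ruler"` (reported per label).
#'
#' @param path path to the VIA JSON file.
#' @param class_key name of the region attribute holding the class label
#'   (VIA does not fix this; default `"name"`).
#' @param missing_class policy when a region lacks the class attribute:
#'   `"drop"` (default) discards it with a warning, `"cob"` assigns the cob
#'   class.
#' @return Named list of [annotation_set()] objects, keyed by `image_id`
#'   (the annotated file name).
#' @export
read_via <- function(path, class_key = "name", missing_class = c("drop", "cob")) {
  missing_class <- match.arg(missing_class)
  if (!file.exists(path)) stop("VIA file not found: ", path)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed VIA JSON in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  meta <- if (!is.null(doc[["_via_img_metadata"]])) doc[["_via_img_metadata"]] else doc
  if (length(meta) == 0L) return(list())
  meta <- meta[!startsWith(names(meta), "_via")]

  out <- list()
  for (key in names(meta)) {
    rec <- meta[[key]]
    if (!is.list(rec) || is.null(rec$filename))
      stop("malformed VIA record '", key, "': missing filename")
    regions <- rec$regions %||% list()
    parsed <- list()
    n_short <- 0L; n_missing <- 0L; bad_labels <- character(0)
    for (i in seq_along(regions)) {
      reg <- regions[[i]]
      sa <- reg$shape_attributes
      if (is.null(sa) || !identical(sa$name, "polygon")) next
      xs <- unlist(sa$all_points_x); ys <- unlist(sa$all_points_y)
      if (is.null(xs) || is.null(ys) || length(xs) != length(ys))
        stop("malformed VIA record '", key, "', region ", i,
             ": inconsistent polygon coordinates")
      lab <- reg$region_attributes[[class_key]]
      if (is.null(lab) || !nzchar(lab)) {
        if (missing_class == "drop") { n_missing <- n_missing + 1L; next }
        lab <- "cob"
      }
      if (!lab %in% c("cob", "ruler")) { bad_labels <- c(bad_labels, lab); next }
      if (length(xs) < 3L) { n_short <- n_short + 1L; next }
      parsed[[length(parsed) + 1L]] <- polygon_region(xs, ys, lab)
    }
    if (n_short > 0L)
      warning(sprintf("%s: dropped %d region(s) with < 3 vertices", rec$filename, n_short))
    if (n_missing > 0L)
      warning(sprintf("%s: dropped %d region(s) without class attribute '%s'",
                      rec$filename, n_missing, class_key))
    if (length(bad_labels) > 0L)
      warning(sprintf("%s: dropped region(s) with unknown class label(s): %s",
                      rec$filename, paste(unique(bad_labels), collapse = ", ")))
    out[[rec$filename]] <- annotation_set(rec$filename, parsed)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write VIA v2 polygon annotations
#'
#' Serializes annotation sets back to the VIA v2 region-list JSON dialect, so
#' that `read_via(write_via(x))` reproduces vertex lists and labels exactly.
#'
#' @param annotations named list of [annotation_set()] objects.
#' @param path output path.
#' @param class_key region attribute name for the class label.
#' @return `path`, invisibly.
#' @export
write_via <- function(annotations, path, class_key = "name") {
  doc <- list()
  for (ann in annotations) {
    regions <- lapply(ann$regions, function(r) {
      ra <- stats::setNames(list(r$label), class_key)
      list(
        shape_attributes = list(
          name = "polygon",
          all_points_x = as.numeric(r$vertices[, "x"]),
          all_points_y = as.numeric(r$vertices[, "y"])
        ),
        region_attributes = ra
      )
    })
    doc[[ann$image_id]] <- list(
      filename = ann$image_id, size = -1L,
      regions = regions, file_attributes = stats::setNames(list(), character(0))
    )
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "list")
  invisible(path)
}

# Even-odd point-in-polygon test for a set of points; points exactly on the
# boundary count as inside. Vectorized over points.
point_in_polygon <- function(px, py, vx, vy, eps = 1e-9) {
  n <- length(vx)
  inside <- logical(length(px))
  boundary <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # on-segment test
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      tt <- pmin(pmax(((px - x1) * dx + (py - y1) * dy) / len2, 0), 1)
      d2 <- (x1 + tt * dx - px)^2 + (y1 + tt * dy - py)^2
      boundary <- boundary | d2 <= eps^2
    } else {
      boundary <- boundary | ((px - x1)^2 + (py - y1)^2 <= eps^2)
    }
    # crossing test (half-open in y avoids double counting at vertices)
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xint <- x1 + (py - y1) / (y2 - y1) * dx
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside | boundary
}

#' Rasterize a polygon region to an instance mask
#'
#' A pixel belongs to the mask iff its center `(col + 0.5, row + 0.5)` lies
#' inside the polygon under the even-odd rule; centers exactly on the polygon
#' boundary count as inside. This pixel-center convention makes area-derived
#' quantities reproducible bit-for-bit.
#'
#' @param region a [polygon_region()].
#' @param H,W grid size in pixels.
#' @return An [instance_mask()] with the region's label.
#' @export
polygon_to_mask <- function(region, H, W) {
  stopifnot(inherits(region, "polygon_region"))
  vx <- region$vertices[, "x"]; vy <- region$vertices[, "y"]
  # restrict to the polygon's bbox to keep the test cheap
  r0 <- max(0L, floor(min(vy) - 0.5)); r1 <- min(H - 1L, ceiling(max(vy)))
  c0 <- max(0L, floor(min(vx) - 0.5)); c1 <- min(W - 1L, ceiling(max(vx)))
  mask <- matrix(FALSE, H, W)
  if (r1 >= r0 && c1 >= c0) {
    rows <- r0:r1; cols <- c0:c1
    grid <- expand.grid(row = rows, col = cols)
    hit <- point_in_polygon(grid$col + 0.5, grid$row + 0.5, vx, vy)
    mask[cbind(grid$row + 1L, grid$col + 1L)] <- hit
  }
  if (!any(mask))
    stop("polygon covers no pixel centers in a ", H, " x ", W,
         " grid (degenerate or fully outside)")
  instance_mask(mask, label = region$label, confidence = 1.0)
}

#' Read instance masks from a labeled image
#'
#' A labeled mask image encodes one instance per distinct nonzero pixel
#' value. Each nonzero level becomes one instance mask.
#'
#' @param path path to a grayscale PNG whose pixel values are instance labels.
#' @param label class label to assign to all instances (default `"cob"`).
#' @param confidence confidence assigned to all instances.
#' @return List of [instance_mask()] objects, ordered by label value.
#' @export
read_label_image <- function(path, label = "cob", confidence = 1.0) {
  if (!file.exists(path)) stop("label image not found: ", path)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  lv <- round(px * 255)
  labels <- sort(setdiff(unique(as.vector(lv)), 0))
  lapply(labels, function(l) instance_mask(lv == l, label = label,
                                           confidence = confidence))
}

#' Write a label image from instance masks
#'
#' Inverse of [read_label_image()]: instance `i` is written with pixel value
#' `i`. Overlapping masks are resolved in favor of the later instance.
#'
#' @param masks list of `instance_mask` objects (at most 255).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(masks, path) {
  if (length(masks) > 255L) stop("at most 255 instances fit in an 8-bit label image")
  d <- dim(masks[[1]]$mask)
  lv <- matrix(0L, d[1], d[2])
  for (i in seq_along(masks)) lv[masks[[i]]$mask] <- i
  png::writePNG(lv / 255, target = path)
  invisible(path)
}

#' Write a cob trait table as CSV
#'
#' One row per cob with identifier columns (`image_id`, `cob_id`), the eight
#' phenotypic traits in canonical order, and the measurement `unit` flag
#' (`"cm"` when the image was ruler-calibrated, `"px"` otherwise). UTF-8,
#' comma separated, '.' decimal mark.
#'
#' @param records a data frame of cob trait records (as returned by
#'   [phenotype_image()] or [traits_to_df()]), or a list of `cob_traits`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(records, path) {
  df <- if (is.data.frame(records)) records else traits_to_df(records)
  cols <- c("image_id", "cob_id", TRAIT_NAMES, "unit")
  if (nrow(df) == 0L) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  } else {
    missing <- setdiff(cols, names(df))
    if (length(missing) > 0L)
      stop("trait records lack column(s): ", paste(missing, collapse = ", "))
    df <- df[, cols]
  }
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cob trait table
#'
#' @param path CSV written by [write_trait_table()].
#' @return A data frame with identifier, trait and unit columns.
#' @export
read_trait_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Write per-cob mask crops
#'
#' Cuts each cob mask's tight bounding box out of the image and writes it as
#' one PNG per instance (background pixels inside the box are kept, matching
#' the crops genebank curators archive for later analysis).
#'
#' @param masks list of `instance_mask` objects.
#' @param image the `cob_image` the masks refer to.
#' @param dir output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_mask_crops <- function(masks, image, dir) {
  stopifnot(inherits(image, "cob_image"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  ci <- 0L
  for (m in masks) {
    if (m$label != "cob") next
    ci <- ci + 1L
    bb <- m$bbox
    crop <- image$pixels[(bb[1] + 1L):bb[3], (bb[2] + 1L):bb[4], , drop = FALSE]
    p <- file.path(dir, sprintf("%s_cob%02d.png", image$image_id, ci))
    png::writePNG(crop / 255, target = p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
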