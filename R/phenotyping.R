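# Ruler-based scale calibration and extraction of the eight cob traits from
# instance masks: length, diameter, aspect ratio, asymmetry, ellipticity and
# mean R, G, B.

#' Pixel-scale calibration object
#'
#' @param px_per_cm pixels per centimeter (> 0 when calibrated).
#' @param n_elements_used number of ruler elements averaged.
#' @param element_cm physical element size in cm.
#' @param calibrated logical flag; when `FALSE` downstream traits are
#'   reported in pixels.
#' @return An object of class `px_scale`.
#' @export
px_scale <- function(px_per_cm = NA_real_, n_elements_used = 0L,
                     element_cm = 1, calibrated = FALSE) {
  if (calibrated && (!is.finite(px_per_cm) || px_per_cm <= 0))
    stop("a calibrated scale needs px_per_cm > 0")
  if (calibrated && n_elements_used < 1) stop("calibration needs >= 1 element")
  structure(list(px_per_cm = px_per_cm,
                 n_elements_used = as.integer(n_elements_used),
                 element_cm = element_cm, calibrated = isTRUE(calibrated)),
            class = "px_scale")
}

#' @export
print.px_scale <- function(x, ...) {
  if (x$calibrated)
    cat(sprintf("<px_scale: %.3f px/cm from %d elements of %g cm>\n",
                x$px_per_cm, x$n_elements_used, x$element_cm))
  else cat("<px_scale: uncalibrated>\n")
  invisible(x)
}

# Otsu threshold on integer gray values in 0..255 (maximizes between-class
# variance of the histogram); returns a threshold t so that the dark class is
# gray <= t.
otsu_threshold <- function(vals) {
  h <- tabulate(as.integer(round(vals)) + 1L, nbins = 256L)
  n <- sum(h)
  lv <- 0:255
  w1 <- cumsum(h)
  m1 <- cumsum(h * lv)
  mu <- m1[256]
  between <- (mu * w1 - m1 * n)^2 / (w1 * (n - w1))
  between[!is.finite(between)] <- -Inf
  lv[which.max(between)]
}

#' Calibrate the pixel scale from ruler masks
#'
#' Within each ruler mask the grayscale image is binarized with an Otsu
#' threshold computed from the mask pixels only; connected components of both
#' polarities (black and white elements) are extracted, filtered by area and
#' by elongation along the ruler part's major axis, and each component's
#' extent along that axis is taken as one element length in pixels. The
#' scale is the mean element length over both ruler parts divided by the
#' physical element size.
#'
#' Two safeguards make this robust to imperfect masks from automatic
#' segmentation: the mask is eroded by `erode_px` before binarization, so
#' stray border pixels cannot bridge same-polarity elements along the strip
#' edge, and the two components at the ends of each strip are discarded,
#' since only interior elements have exact element-to-element boundaries on
#' both sides. With no ruler mask or fewer than 3 valid elements the result
#' is flagged uncalibrated (not an error: downstream traits are then
#' reported in pixels).
#'
#' @param image the `cob_image`.
#' @param ruler_masks list of `instance_mask` objects (non-ruler labels are
#'   ignored); may be empty.
#' @param element_cm physical size of one ruler element in cm (default 1).
#' @param min_element_area minimum component area in px to count as an
#'   element.
#' @param erode_px mask erosion radius in px (default 2).
#' @param max_elongation maximum ratio of a component's extent along the
#'   strip axis to its extent across it (elements are square; default 3).
#' @return A [px_scale()].
#' @export
calibrate_scale <- function(image, ruler_masks, element_cm = 1,
                            min_element_area = 15, erode_px = 2,
                            max_elongation = 3) {
  stopifnot(inherits(image, "cob_image"))
  ruler_masks <- Filter(function(m) inherits(m, "instance_mask") &&
                          m$label == "ruler", ruler_masks)
  if (length(ruler_masks) == 0L)
    return(px_scale(calibrated = FALSE))
  px <- image$pixels
  gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  extents <- numeric(0)
  for (rm in ruler_masks) {
    mask <- rm$mask
    if (erode_px > 0) {
      brush <- matrix(1, 2 * erode_px + 1, 2 * erode_px + 1)
      mask <- EBImage::erode(mask * 1, brush) > 0
    }
    if (!any(mask)) next
    vals <- gray[mask]
    if (length(unique(round(vals))) < 2L) next
    thr <- otsu_threshold(vals)
    horizontal <- (rm$bbox[4] - rm$bbox[2]) >= (rm$bbox[3] - rm$bbox[1])
    midx <- which(mask, arr.ind = TRUE)
    along_all <- if (horizontal) range(midx[, 2]) else range(midx[, 1])
    for (polarity in c("dark", "light")) {
      bw <- if (polarity == "dark") mask & gray <= thr else mask & gray > thr
      if (!any(bw)) next
      lb <- EBImage::bwlabel(bw * 1)
      for (l in seq_len(max(lb))) {
        idx <- which(lb == l, arr.ind = TRUE)
        if (nrow(idx) < min_element_area) next
        rng_r <- range(idx[, 1]); rng_c <- range(idx[, 2])
        along_rng <- if (horizontal) rng_c else rng_r
        # end-of-strip components lack one element-to-element boundary
        if (along_rng[1] <= along_all[1] || along_rng[2] >= along_all[2]) next
        along <- diff(along_rng) + 1L
        perp <- diff(if (horizontal) rng_r else rng_c) + 1L
        if (along < perp / max_elongation || along > perp * max_elongation) next
        extents <- c(extents, along)
      }
    }
  }
  if (length(extents) < 3L) return(px_scale(calibrated = FALSE))
  px_scale(px_per_cm = mean(extents) / element_cm,
           n_elements_used = length(extents),
           element_cm = element_cm, calibrated = TRUE)
}

#' Width profile of a mask along its principal axis
#'
#' The major axis is the principal eigenvector of the mask's second central
#' moments. Pixel centers are projected onto it, the projection range
#' (plus one pixel pitch) defines the length, and the cross-sectional width
#' is the pixel count per unit length along the axis. The width is first
#' computed in bins of (almost exactly) one pixel pitch -- finer bins would
#' alias against the pixel grid and corrupt the maximum -- and then
#' aggregated onto the `B` requested bins (averaged when `B` is coarser,
#' linearly interpolated when finer). The diameter is the maximum of the
#' pixel-resolution profile. The profile is oriented so that `t = 0` is the
#' narrower (apical) end, judged by the mean width over the outer 10
#' percent of bins; this affects only the direction convention, not any
#' trait magnitude.
#'
#' @param mask an `instance_mask` with at least 10 foreground pixels.
#' @param B number of bins (default 100).
#' @return A list with `w` (width per bin, px), `length_px`, `diameter_px`
#'   (`max(w)`), `binwidth`, `axis` (unit vector, x-y image coordinates,
#'   pointing from apical to basal end) and `centroid`.
#' @export
width_profile <- function(mask, B = 100L) {
  stopifnot(inherits(mask, "instance_mask"))
  idx <- which(mask$mask, arr.ind = TRUE)
  if (nrow(idx) < 10L) stop("mask too small for a width profile (< 10 px)")
  x <- idx[, 2] - 0.5; y <- idx[, 1] - 0.5            # pixel centers
  cx <- mean(x); cy <- mean(y)
  covm <- stats::cov(cbind(x, y))
  ev <- eigen(covm, symmetric = TRUE)
  v1 <- ev$vectors[, 1]
  proj <- (x - cx) * v1[1] + (y - cy) * v1[2]
  pmin_ <- min(proj); pmax_ <- max(proj)
  length_px <- pmax_ - pmin_ + 1
  # pixel-pitch bins (aliasing-safe), then aggregate to B bins
  nb <- max(1L, as.integer(round(length_px)))
  ubw <- length_px / nb
  ub <- pmin(pmax(floor((proj - (pmin_ - 0.5)) / ubw) + 1L, 1L), nb)
  w_unit <- tabulate(ub, nbins = nb) / ubw
  t_unit <- (seq_len(nb) - 0.5) / nb
  if (B <= nb) {
    grpof <- pmin(pmax(ceiling(t_unit * B), 1L), B)
    w <- as.numeric(tapply(w_unit, factor(grpof, levels = seq_len(B)), mean))
  } else {
    w <- stats::approx(t_unit, w_unit, xout = (seq_len(B) - 0.5) / B,
                       rule = 2)$y
  }
  binwidth <- length_px / B
  n10 <- max(1L, floor(B / 10))
  if (mean(w[seq_len(n10)]) > mean(w[seq.int(B - n10 + 1L, B)])) {
    w <- rev(w)
    w_unit <- rev(w_unit)
    v1 <- -v1
  }
  list(w = w, B = as.integer(B), binwidth = binwidth, length_px = length_px,
       diameter_px = max(w_unit), w_px = w_unit, axis = v1,
       centroid = c(x = cx, y = cy))
}

#' Extract the eight phenotypic traits of a cob
#'
#' From a cob instance mask and its image, computes:
#' \itemize{
#'  \item length: extent along the mask's principal axis;
#'  \item diameter: maximum of the width profile;
#'  \item aspect ratio: length / diameter;
#'  \item asymmetry: `sum(|w(t) - w(1-t)|) / (2 sum(w))` over the width
#'    profile -- 0 for a mirror-symmetric cob, bounded by 1;
#'  \item ellipticity: mask area divided by the area of the ellipse with the
#'    same length and diameter (`pi * L * D / 4`) -- 1 for an elliptical
#'    silhouette, > 1 for fuller, barrel-shaped cobs;
#'  \item mean_r, mean_g, mean_b: channel means over all mask pixels (the
#'    complete mask is used because kernel color varies along the cob).
#' }
#' Length and diameter are converted to cm when the scale is calibrated,
#' otherwise reported in pixels with `unit = "px"`.
#'
#' @param mask a cob `instance_mask`.
#' @param image the aligned `cob_image`.
#' @param scale a [px_scale()].
#' @param B number of width-profile bins.
#' @param image_id,cob_id identifiers stored in the record (default: the
#'   image's id, cob id `NA`).
#' @return An object of class `cob_traits`: a list with the identifiers, the
#'   eight traits and the `unit` flag.
#' @export
extract_traits <- function(mask, image, scale = px_scale(), B = 100L,
                           image_id = NULL, cob_id = NA_integer_) {
  stopifnot(inherits(mask, "instance_mask"), inherits(image, "cob_image"))
  if (mask$label != "cob") stop("extract_traits expects a cob mask")
  prof <- width_profile(mask, B = B)
  area <- sum(mask$mask)
  w <- prof$w
  asym <- sum(abs(w - rev(w))) / (2 * sum(w))
  elli <- area / (pi * prof$length_px * prof$diameter_px / 4)
  px <- image$pixels
  means <- vapply(1:3, function(ch) mean(px[, , ch][mask$mask]), numeric(1))
  fac <- if (scale$calibrated) scale$px_per_cm else 1
  unit <- if (scale$calibrated) "cm" else "px"
  structure(list(
    image_id = image_id %||% image$image_id, cob_id = cob_id,
    length = prof$length_px / fac, diameter = prof$diameter_px / fac,
    aspect_ratio = prof$length_px / prof$diameter_px,
    asymmetry = asym, ellipticity = elli,
    mean_r = means[1], mean_g = means[2], mean_b = means[3],
    unit = unit), class = "cob_traits")
}

#' Bind cob trait records into a data frame
#'
#' @param traits list of `cob_traits` records.
#' @return Data frame with `image_id`, `cob_id`, the eight traits and `unit`.
#' @export
traits_to_df <- function(traits) {
  if (inherits(traits, "cob_traits")) traits <- list(traits)
  if (length(traits) == 0L) {
    cols <- c("image_id", "cob_id", TRAIT_NAMES, "unit")
    return(as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                         cols)))
  }
  do.call(rbind, lapply(traits, function(tr)
    data.frame(unclass(tr), stringsAsFactors = FALSE)))
}

#' Per-image trait means and standard deviations
#'
#' Summarizes cob trait records per image: the mean over all cobs of the
#' image -- including any false-positive instances, which is deliberate when
#' benchmarking segmenters, since wrong detections then penalize the
#' per-image mean -- and the sample standard deviation (denominator n - 1),
#' which is undefined (NA) for single-cob images.
#'
#' @param traits a data frame of trait records (or a list of `cob_traits`).
#' @return One row per image: `image_id`, `n_cobs`, `mean_<trait>` and
#'   `sd_<trait>` for each of the eight traits.
#' @export
summarize_image <- function(traits) {
  df <- if (is.data.frame(traits)) traits else traits_to_df(traits)
  if (nrow(df) == 0L) stop("no cob records to summarize")
  out <- lapply(split(df, df$image_id), function(d) {
    row <- data.frame(image_id = d$image_id[1], n_cobs = nrow(d))
    for (tr in TRAIT_NAMES) {
      row[[paste0("mean_", tr)]] <- mean(d[[tr]])
      row[[paste0("sd_", tr)]] <- if (nrow(d) > 1) stats::sd(d[[tr]]) else NA_real_
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the post-segmentation phenotyping workflow on one image
#'
#' The complete per-image pipeline: obtain instance masks (either supplied,
#' e.g. from an external segmenter, or produced by the built-in
#' Felzenszwalb-Huttenlocher segmenter), calibrate the pixel scale from the
#' ruler masks, and extract the eight traits for every cob mask. Cob ids
#' follow the order of the masks (left to right for built-in segmentation).
#'
#' @param image a `cob_image`.
#' @param masks optional list of `instance_mask` objects; `NULL` runs
#'   [fh_segment()] + [segments_to_instances()].
#' @param params [fh_params()] for the built-in segmenter.
#' @param element_cm physical ruler element size in cm.
#' @param B width-profile bins.
#' @return A list with `traits` (data frame, one row per cob), `scale` (the
#'   [px_scale()]) and `instances` (the masks used).
#' @export
phenotype_image <- function(image, masks = NULL, params = fh_params(),
                            element_cm = 1, B = 100L) {
  stopifnot(inherits(image, "cob_image"))
  if (is.null(masks))
    masks <- segments_to_instances(fh_segment(image, params), image, params)
  rulers <- Filter(function(m) m$label == "ruler", masks)
  cobs <- Filter(function(m) m$label == "cob", masks)
  scale <- calibrate_scale(image, rulers, element_cm = element_cm)
  recs <- vector("list", length(cobs))
  for (i in seq_along(cobs))
    recs[[i]] <- extract_traits(cobs[[i]], image, scale, B = B, cob_id = i)
  list(traits = traits_to_df(recs), scale = scale, instances = masks)
}
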