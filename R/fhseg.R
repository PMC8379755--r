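# Classical baseline segmentation: Felzenszwalb-Huttenlocher graph
# segmentation plus rule-based assembly of segments into cob and ruler
# instances. The assembly heuristics are deliberately configurable --
# classical pipelines need per-dataset tuning, which is exactly the weakness
# the evaluation module quantifies.

#' Segmentation parameters
#'
#' @param k scale parameter of the merge threshold `tau(C) = k / |C|`
#'   (larger k favors larger segments).
#' @param sigma Gaussian pre-smoothing sd in pixels (0 disables smoothing).
#' @param min_size minimum segment size in pixels; smaller segments are
#'   absorbed into their most similar neighbor in a final pass.
#' @param min_cob_frac minimum area of a cob instance as a fraction of the
#'   image area.
#' @param border_frac segments covering more than this fraction of the image
#'   border are classified as background.
#' @param bg_tol Euclidean RGB distance to the dominant border color below
#'   which a segment counts as background.
#' @param achromatic_tol maximum channel spread (max - min of mean RGB) for a
#'   segment to count as achromatic (ruler-element candidate).
#' @param dark_max,light_min intensity bounds classifying achromatic segments
#'   as dark or light ruler elements.
#' @param group_gap adjacency tolerance in pixels when grouping segments into
#'   instances (bounding boxes expanded by this much must overlap).
#' @return An object of class `fh_params`.
#' @export
fh_params <- function(k = 300, sigma = 0.6, min_size = 30,
                      min_cob_frac = 5e-4, border_frac = 0.05, bg_tol = 25,
                      achromatic_tol = 45, dark_max = 100, light_min = 165,
                      group_gap = 3) {
  if (k <= 0) stop("k must be > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  if (min_size < 1) stop("min_size must be >= 1")
  structure(list(k = k, sigma = sigma, min_size = as.integer(min_size),
                 min_cob_frac = min_cob_frac, border_frac = border_frac,
                 bg_tol = bg_tol, achromatic_tol = achromatic_tol,
                 dark_max = dark_max, light_min = light_min,
                 group_gap = group_gap),
            class = "fh_params")
}

#' Felzenszwalb-Huttenlocher graph segmentation
#'
#' Segments an RGB image with the graph-based algorithm: each channel is
#' Gaussian-smoothed with `sigma`, pixels form an 8-connected grid graph with
#' edge weight equal to the Euclidean RGB distance, and edges are processed
#' in nondecreasing weight order, merging components `C1`, `C2` when the edge
#' weight does not exceed `min(Int(C1) + k/|C1|, Int(C2) + k/|C2|)` (with
#' `Int(C)` the largest edge weight accepted inside `C`). A final pass merges
#' components smaller than `min_size` into their most similar neighbor.
#' Equal-weight ties are broken by edge construction order (stable sort), so
#' the result is fully deterministic.
#'
#' @param image a `cob_image`.
#' @param params an [fh_params()] object.
#' @return A list with `labels` (H x W integer matrix of segment ids,
#'   contiguous from 0) and `n_segments`.
#' @export
fh_segment <- function(image, params = fh_params()) {
  stopifnot(inherits(image, "cob_image"), inherits(params, "fh_params"))
  px <- image$pixels
  labels <- .fh_segment_cpp(px[, , 1] * 1.0, px[, , 2] * 1.0, px[, , 3] * 1.0,
                            params$k, params$sigma, params$min_size)
  list(labels = labels, n_segments = attr(labels, "n_segments"))
}

# per-segment statistics used by the assembly rules
segment_stats <- function(labels, image) {
  lab <- as.vector(labels) + 1L            # 1-based for tabulate/rowsum
  n <- max(lab)
  size <- tabulate(lab, nbins = n)
  H <- nrow(labels); W <- ncol(labels)
  px <- image$pixels
  mr <- rowsum(as.vector(px[, , 1]) * 1.0, lab)[, 1] / size
  mg <- rowsum(as.vector(px[, , 2]) * 1.0, lab)[, 1] / size
  mb <- rowsum(as.vector(px[, , 3]) * 1.0, lab)[, 1] / size
  rowv <- rep.int(seq_len(H), W)
  colv <- rep(seq_len(W), each = H)
  f <- factor(lab, levels = seq_len(n))
  rmin <- tapply(rowv, f, min); rmax <- tapply(rowv, f, max)
  cmin <- tapply(colv, f, min); cmax <- tapply(colv, f, max)
  on_border <- rowv == 1L | rowv == H | colv == 1L | colv == W
  bcount <- tabulate(lab[on_border], nbins = n)
  data.frame(id = seq_len(n) - 1L, size = size,
             mean_r = mr, mean_g = mg, mean_b = mb,
             intensity = (mr + mg + mb) / 3,
             spread = pmax(mr, mg, mb) - pmin(mr, mg, mb),
             rmin = as.integer(rmin), rmax = as.integer(rmax),
             cmin = as.integer(cmin), cmax = as.integer(cmax),
             border_frac = bcount / (2 * H + 2 * W - 4))
}

# union-find grouping of rows whose expanded bboxes overlap
group_by_adjacency <- function(st, gap) {
  m <- nrow(st)
  parent <- seq_len(m)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (m > 1) {
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (st$rmin[i] - gap <= st$rmax[j] && st$rmin[j] - gap <= st$rmax[i] &&
          st$cmin[i] - gap <= st$cmax[j] && st$cmin[j] - gap <= st$cmax[i]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  vapply(seq_len(m), find, integer(1))
}

#' Assemble segments into cob and ruler instances
#'
#' Applies rule-based post-processing to a segment label grid:
#' \itemize{
#'   \item background: segments covering more than `border_frac` of the image
#'     border, plus segments whose mean color is within `bg_tol` of the
#'     dominant border color;
#'   \item ruler: groups of at least three adjacent achromatic segments that
#'     contain both dark and light members (the alternating-element test);
#'     each group becomes one ruler instance, so a two-part ruler yields two;
#'   \item cobs: the remaining segments, grouped by adjacency; groups whose
#'     total area reaches `min_cob_frac` of the image become cob instances
#'     (confidence 1.0), ordered left to right.
#' }
#'
#' @param seg result of [fh_segment()] (or an H x W integer label matrix).
#' @param image the segmented `cob_image`.
#' @param params an [fh_params()] object.
#' @return List of [instance_mask()] objects (cobs first, then rulers). If no
#'   cob candidate survives the rules, an empty list is returned with a
#'   warning.
#' @export
segments_to_instances <- function(seg, image, params = fh_params()) {
  labels <- if (is.list(seg)) seg$labels else seg
  stopifnot(inherits(image, "cob_image"))
  H <- nrow(labels); W <- ncol(labels)
  st <- segment_stats(labels, image)

  is_bg <- st$border_frac > params$border_frac
  if (any(is_bg)) {
    dom <- st[is_bg, ][which.max(st$size[is_bg]), ]
    dcol <- sqrt((st$mean_r - dom$mean_r)^2 + (st$mean_g - dom$mean_g)^2 +
                 (st$mean_b - dom$mean_b)^2)
    is_bg <- is_bg | dcol <= params$bg_tol
  }

  fg <- st[!is_bg & st$size >= 9L, ]
  instances <- list()

  # ruler assembly: adjacent achromatic dark/light elements
  is_dark <- fg$spread <= params$achromatic_tol & fg$intensity <= params$dark_max
  is_light <- fg$spread <= params$achromatic_tol & fg$intensity >= params$light_min
  cand <- fg[is_dark | is_light, ]
  ruler_ids <- integer(0)
  if (nrow(cand) > 0) {
    grp <- group_by_adjacency(cand, params$group_gap)
    for (g in unique(grp)) {
      members <- cand[grp == g, ]
      dark_n <- sum(members$intensity <= params$dark_max)
      light_n <- sum(members$intensity >= params$light_min)
      if (nrow(members) >= 3 && dark_n >= 1 && light_n >= 1) {
        # a ruler part is a rectangular strip: fill the group's bounding box
        # so boundary pixels between elements (assigned to neither polarity
        # by the segmenter) do not punch holes into the instance
        mask <- matrix(FALSE, H, W)
        mask[min(members$rmin):max(members$rmax),
             min(members$cmin):max(members$cmax)] <- TRUE
        instances[[length(instances) + 1L]] <- instance_mask(mask, "ruler", 1.0)
        ruler_ids <- c(ruler_ids, members$id)
      }
    }
  }

  # cob assembly: remaining foreground segments grouped by adjacency;
  # segments overlapping an accepted ruler's bounding box are element debris
  pool <- fg[!fg$id %in% ruler_ids, ]
  if (length(instances) > 0L && nrow(pool) > 0L) {
    g <- params$group_gap
    debris <- rep(FALSE, nrow(pool))
    for (ri in instances) {
      bb <- ri$bbox   # 0-based half-open -> 1-based inclusive rows/cols
      debris <- debris |
        (pool$rmin - g <= bb[3] & bb[1] + 1L - g <= pool$rmax &
         pool$cmin - g <= bb[4] & bb[2] + 1L - g <= pool$cmax)
    }
    pool <- pool[!debris, ]
  }
  cobs <- list()
  if (nrow(pool) > 0) {
    grp <- group_by_adjacency(pool, params$group_gap)
    for (g in unique(grp)) {
      members <- pool[grp == g, ]
      if (sum(members$size) >= params$min_cob_frac * H * W) {
        mask <- matrix(labels %in% members$id, H, W)
        cobs[[length(cobs) + 1L]] <- instance_mask(mask, "cob", 1.0)
      }
    }
  }
  if (length(cobs) == 0L)
    warning("no cob candidates found in image '", image$image_id, "'")
  # left-to-right ordering gives stable cob ids
  if (length(cobs) > 1L) {
    xs <- vapply(cobs, function(m) (m$bbox[2] + m$bbox[4]) / 2, numeric(1))
    cobs <- cobs[order(xs)]
  }
  c(cobs, instances)
}
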