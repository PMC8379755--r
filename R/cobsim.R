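# Synthetic genebank-style scenes with analytic ground truth: 1-12 cobs laid
# out side by side, a two-part ruler (horizontal + vertical strip of
# alternating black/white 1-cm elements), variable background and colors.

#' Specify a synthetic cob shape
#'
#' A cob silhouette is modeled as a parametric profile of half-widths along
#' the long axis: `h(t) = (D/2) * (4u(1-u))^(1/p)` with `u = t^gamma`,
#' `t` in \[0,1\] running from the apical tip (`t = 0`) to the base. `p`
#' controls flatness (`p = 2` gives an elliptical profile; larger `p` gives
#' fuller, more barrel-shaped cobs), and `gamma >= 1` warps the profile
#' toward the base, producing asymmetric shapes (`gamma = 1` is symmetric).
#' The maximum half-width is exactly `D/2` for every `p` and `gamma`.
#'
#' @param length_cm cob length in cm (> 0, >= `diameter_cm`).
#' @param diameter_cm maximum cob width in cm (> 0).
#' @param p flatness exponent (> 0); 2 = ellipse.
#' @param gamma asymmetry warp (>= 1); 1 = symmetric.
#' @param base_rgb integer RGB triple, the cob's base color.
#' @param speckle_sd standard deviation of per-pixel Gaussian color speckle
#'   emulating kernel texture (>= 0).
#' @return An object of class `cob_shape`.
#' @export
cob_shape <- function(length_cm, diameter_cm, p = 2, gamma = 1,
                      base_rgb = c(190, 140, 60), speckle_sd = 6) {
  if (length_cm <= 0 || diameter_cm <= 0) stop("length and diameter must be > 0")
  if (length_cm < diameter_cm) stop("length_cm must be >= diameter_cm")
  if (!is.finite(p) || p <= 0) stop("p must be finite and > 0")
  if (!is.finite(gamma) || gamma < 1) stop("gamma must be finite and >= 1")
  if (speckle_sd < 0) stop("speckle_sd must be >= 0")
  structure(list(length_cm = length_cm, diameter_cm = diameter_cm,
                 p = p, gamma = gamma,
                 base_rgb = as.numeric(base_rgb), speckle_sd = speckle_sd),
            class = "cob_shape")
}

#' Evaluate the continuous cob profile
#'
#' Half-width (in cm) of the cob silhouette at normalized position `t` along
#' the long axis. Since `u = t^gamma` sweeps all of \[0,1\], the profile
#' attains its maximum `D/2` exactly (at `t = 0.5^(1/gamma)`), and
#' `h(0) = h(1) = 0`.
#'
#' @param spec a [cob_shape()].
#' @param t numeric vector of positions in \[0,1\] (0 = apical tip).
#' @return Half-widths in cm, same length as `t`.
#' @export
cob_profile <- function(spec, t) {
  stopifnot(inherits(spec, "cob_shape"))
  if (any(t < 0 | t > 1)) stop("t must lie in [0, 1]")
  u <- t^spec$gamma
  (spec$diameter_cm / 2) * (4 * u * (1 - u))^(1 / spec$p)
}

#' Specify a synthetic scene
#'
#' A scene holds 1-12 cobs laid out side by side with their apical ends
#' aligned on a common baseline, plus a two-part ruler (one horizontal and
#' one vertical strip of alternating black and white square elements of
#' physical size `element_cm`). The canvas is sized automatically unless
#' `width`/`height` are given, in which case the content must fit.
#'
#' @param cobs list of [cob_shape()] objects (length 1-12).
#' @param px_per_cm true pixel scale (> 0).
#' @param element_cm physical ruler element size in cm (default 1).
#' @param n_elements number of elements per ruler part.
#' @param background_rgb RGB triple of the uniform background.
#' @param background_noise_sd sd of per-pixel Gaussian background noise.
#' @param width,height optional canvas size in px; `NULL` = auto.
#' @param seed integer seed making the rendering deterministic.
#' @param image_id identifier of the generated image.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(cobs, px_per_cm, element_cm = 1, n_elements = 10,
                       background_rgb = c(140, 140, 140),
                       background_noise_sd = 5,
                       width = NULL, height = NULL,
                       seed = 1L, image_id = "scene") {
  if (inherits(cobs, "cob_shape")) cobs <- list(cobs)
  ok <- vapply(cobs, inherits, logical(1), what = "cob_shape")
  if (!all(ok)) stop("`cobs` must be a list of cob_shape objects")
  if (length(cobs) < 1L || length(cobs) > 12L)
    stop("a scene holds between 1 and 12 cobs")
  if (px_per_cm <= 0) stop("px_per_cm must be > 0")
  structure(list(cobs = cobs, px_per_cm = px_per_cm,
                 element_cm = element_cm, n_elements = as.integer(n_elements),
                 background_rgb = as.numeric(background_rgb),
                 background_noise_sd = background_noise_sd,
                 width = width, height = height,
                 seed = as.integer(seed), image_id = as.character(image_id)),
            class = "scene_spec")
}

# Continuous scene layout in 0-based image coordinates. Gaps are chosen so
# that distinct instances can never touch (instance assembly uses a 2-px
# adjacency dilation).
scene_layout <- function(spec) {
  ppc <- spec$px_per_cm
  e <- ppc * spec$element_cm
  m <- 8                                   # canvas margin, px
  gap <- max(8, 0.8 * ppc)                 # spacing between instances, px
  Lpx <- vapply(spec$cobs, function(cb) cb$length_cm * ppc, numeric(1))
  Dpx <- vapply(spec$cobs, function(cb) cb$diameter_cm * ppc, numeric(1))

  ruler_h <- list(x0 = m, y0 = m, nx = spec$n_elements, horizontal = TRUE, e = e)
  ruler_v <- list(x0 = m, y0 = m + e + gap, nx = spec$n_elements,
                  horizontal = FALSE, e = e)

  x_cob0 <- m + e + gap                    # right of the vertical ruler part
  cx <- numeric(length(Lpx))
  x <- x_cob0
  for (i in seq_along(Lpx)) {
    cx[i] <- x + Dpx[i] / 2
    x <- x + Dpx[i] + gap
  }
  h_need <- max(m + e + gap + max(Lpx),               # cobs below top ruler
                ruler_v$y0 + spec$n_elements * e) + m
  w_need <- max(m + spec$n_elements * e,              # top ruler
                x - gap) + m                          # last cob + margin
  H <- if (is.null(spec$height)) ceiling(h_need) else spec$height
  W <- if (is.null(spec$width)) ceiling(w_need) else spec$width
  if (H < h_need || W < w_need)
    stop(sprintf("scene content (%d x %d px) does not fit the %d x %d canvas",
                 ceiling(h_need), ceiling(w_need), H, W))
  y_base <- H - m
  list(H = as.integer(H), W = as.integer(W), y_base = y_base,
       cx = cx, Lpx = Lpx, Dpx = Dpx,
       ruler_h = ruler_h, ruler_v = ruler_v, e = e, margin = m)
}

# mask of a ruler part + element color pattern painted into `canvas`
render_ruler_part <- function(canvas, part) {
  H <- dim(canvas)[1]; W <- dim(canvas)[2]
  e <- part$e
  if (part$horizontal) {
    rows <- which(seq_len(H) - 0.5 >= part$y0 & seq_len(H) - 0.5 < part$y0 + e)
    cols <- which(seq_len(W) - 0.5 >= part$x0 &
                  seq_len(W) - 0.5 < part$x0 + part$nx * e)
    kk <- floor((cols - 0.5 - part$x0) / e)         # element index per column
    for (ci in seq_along(cols)) {
      val <- if (kk[ci] %% 2 == 0) 0 else 255
      canvas[rows, cols[ci], ] <- val
    }
  } else {
    rows <- which(seq_len(H) - 0.5 >= part$y0 &
                  seq_len(H) - 0.5 < part$y0 + part$nx * e)
    cols <- which(seq_len(W) - 0.5 >= part$x0 & seq_len(W) - 0.5 < part$x0 + e)
    kk <- floor((rows - 0.5 - part$y0) / e)
    for (ri in seq_along(rows)) {
      val <- if (kk[ri] %% 2 == 0) 0 else 255
      canvas[rows[ri], cols, ] <- val
    }
  }
  mask <- matrix(FALSE, H, W)
  mask[rows, cols] <- TRUE
  list(canvas = canvas, mask = mask)
}

# True traits from the continuous profile (resolution independent, in cm),
# using the same operational definitions as the trait extractor.
true_cob_traits <- function(cb, n_grid = 2000L) {
  tt <- (seq_len(n_grid) - 0.5) / n_grid
  w <- 2 * cob_profile(cb, tt)                       # widths in cm
  asym <- sum(abs(w - rev(w))) / (2 * sum(w))
  area <- cb$length_cm * mean(w)                     # cm^2
  elli <- area / (pi * cb$length_cm * cb$diameter_cm / 4)
  c(length = cb$length_cm, diameter = cb$diameter_cm,
    aspect_ratio = cb$length_cm / cb$diameter_cm,
    asymmetry = asym, ellipticity = elli,
    mean_r = cb$base_rgb[1], mean_g = cb$base_rgb[2], mean_b = cb$base_rgb[3])
}

# Boundary polygon of a cob in image coordinates (for the VIA annotation).
cob_polygon <- function(cb, cx, y_base, ppc, n = 80L) {
  tt <- seq(0, 1, length.out = n)
  h <- cob_profile(cb, tt) * ppc
  y <- y_base - tt * cb$length_cm * ppc
  xs <- c(cx + h, rev(cx - h)[-1])                  # right side up, left down
  ys <- c(y, rev(y)[-1])
  polygon_region(xs, ys, "cob")
}

#' Render a synthetic scene
#'
#' Renders the scene to an RGB image and returns it together with its exact
#' ground truth: one instance mask per cob, two ruler masks (horizontal and
#' vertical part), a VIA-style polygon annotation set, and the true traits of
#' every cob computed from the continuous profile (in cm, independent of
#' `px_per_cm`). Rendering is deterministic given the scene seed.
#'
#' Cobs are drawn vertically, apical tips down and aligned on a shared
#' baseline. A pixel belongs to a cob mask iff its center lies inside the
#' continuous silhouette.
#'
#' @param spec a [scene_spec()].
#' @return A list with elements `image` (a `cob_image`) and `truth` (a list
#'   with `masks`, `annotation`, `true_traits`, `px_per_cm`).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  lay <- scene_layout(spec)
  H <- lay$H; W <- lay$W; ppc <- spec$px_per_cm

  withr::with_seed(spec$seed, {
    canvas <- array(rep(spec$background_rgb, each = H * W), c(H, W, 3)) +
      array(stats::rnorm(H * W * 3, 0, spec$background_noise_sd), c(H, W, 3))

    rh <- render_ruler_part(canvas, lay$ruler_h)
    rv <- render_ruler_part(rh$canvas, lay$ruler_v)
    canvas <- rv$canvas

    masks <- list()
    regions <- list()
    xc <- seq_len(W) - 0.5; yc <- seq_len(H) - 0.5
    for (i in seq_along(spec$cobs)) {
      cb <- spec$cobs[[i]]
      Lpx <- lay$Lpx[i]
      tt <- (lay$y_base - yc) / Lpx                   # normalized position/row
      ok <- tt >= 0 & tt <= 1
      hpx <- numeric(H)
      hpx[ok] <- cob_profile(cb, tt[ok]) * ppc
      # |x - cx| <= h(t): outer product comparison over the cob's bbox
      mask <- matrix(FALSE, H, W)
      cols <- which(abs(xc - lay$cx[i]) <= lay$Dpx[i] / 2 + 1)
      rows <- which(ok & hpx > 0)
      if (length(rows) && length(cols)) {
        sub <- abs(outer(rep(1, length(rows)), xc[cols] - lay$cx[i])) <=
          outer(hpx[rows], rep(1, length(cols)))
        mask[rows, cols] <- sub
      }
      if (!any(mask)) stop("cob ", i, " rendered to an empty mask (scale too small)")
      npix <- sum(mask)
      for (ch in 1:3) {
        plane <- canvas[, , ch]
        plane[mask] <- cb$base_rgb[ch] + stats::rnorm(npix, 0, cb$speckle_sd)
        canvas[, , ch] <- plane
      }
      masks[[i]] <- instance_mask(mask, "cob", 1.0)
      regions[[length(regions) + 1L]] <- cob_polygon(cb, lay$cx[i], lay$y_base, ppc)
    }

    for (part in list(lay$ruler_h, lay$ruler_v)) {
      e <- part$e
      wpart <- if (part$horizontal) part$nx * e else e
      hpart <- if (part$horizontal) e else part$nx * e
      regions[[length(regions) + 1L]] <- polygon_region(
        x = part$x0 + c(0, wpart, wpart, 0),
        y = part$y0 + c(0, 0, hpart, hpart), "ruler")
    }
    masks <- c(masks,
               list(instance_mask(rh$mask, "ruler", 1.0),
                    instance_mask(rv$mask, "ruler", 1.0)))

    canvas <- round(pmin(pmax(canvas, 0), 255))
    image <- raster_image(canvas, image_id = spec$image_id)
  })

  traits <- do.call(rbind, lapply(spec$cobs, function(cb)
    as.data.frame(as.list(true_cob_traits(cb)))))
  traits <- cbind(image_id = spec$image_id,
                  cob_id = seq_along(spec$cobs), traits, unit = "cm",
                  stringsAsFactors = FALSE)

  list(image = image,
       truth = list(masks = masks,
                    annotation = annotation_set(spec$image_id, regions),
                    true_traits = traits,
                    px_per_cm = ppc))
}

#' Default scene sampling distributions
#'
#' Ranges emulating the variability of genebank cob photographs: 1-12 cobs
#' per image, lengths 8-30 cm, diameters 3-8 cm, profile flatness 1.5-4,
#' asymmetry warp 1-2, pixel scale 8-15 px/cm, mid-tone backgrounds with
#' Gaussian noise (sd 5) and a palette of natural cob colors from white and
#' yellow through red and brown to dark purple.
#'
#' @return Named list of ranges/values understood by [sample_scene_spec()].
#' @export
default_scene_distributions <- function() {
  list(
    n_cobs = c(1, 12),
    length_cm = c(8, 30),
    diameter_cm = c(3, 8),
    p = c(1.5, 4),
    gamma = c(1, 2),
    px_per_cm = c(8, 15),
    speckle_sd = c(4, 10),
    background_gray = c(80, 180),
    background_noise_sd = 5,
    element_cm = 1,
    n_elements = 10,
    cob_palette = list(
      white  = c(228, 218, 192), yellow = c(214, 178, 84),
      orange = c(202, 124, 52),  red    = c(163, 62, 52),
      pink   = c(196, 126, 112), brown  = c(124, 82, 52),
      purple = c(94, 44, 74),    dark   = c(62, 38, 52))
  )
}

#' Draw a random scene specification
#'
#' Samples one scene from the given variability ranges (uniform draws within
#' each range; cob colors from the palette with +/- 15 channel jitter). Cob
#' diameters are capped at the sampled length so every shape is valid.
#'
#' @param distributions ranges as in [default_scene_distributions()].
#' @param seed integer seed; the drawn spec and its rendering are
#'   deterministic given this seed.
#' @param image_id identifier for the scene.
#' @return A [scene_spec()].
#' @export
sample_scene_spec <- function(distributions = default_scene_distributions(),
                              seed = 1L, image_id = "scene") {
  d <- utils::modifyList(default_scene_distributions(), distributions)
  runif1 <- function(r) stats::runif(1, r[1], r[2])
  withr::with_seed(seed, {
    n <- sample(seq(d$n_cobs[1], d$n_cobs[2]), 1)
    cobs <- lapply(seq_len(n), function(i) {
      len <- runif1(d$length_cm)
      dia <- min(runif1(d$diameter_cm), len)
      base <- d$cob_palette[[sample(length(d$cob_palette), 1)]] +
        stats::runif(3, -15, 15)
      cob_shape(len, dia, p = runif1(d$p), gamma = runif1(d$gamma),
                base_rgb = pmin(pmax(base, 0), 255),
                speckle_sd = runif1(d$speckle_sd))
    })
    g <- runif1(d$background_gray)
    bg <- pmin(pmax(g + stats::runif(3, -10, 10), 0), 255)
    scene_spec(cobs, px_per_cm = runif1(d$px_per_cm),
               element_cm = d$element_cm, n_elements = d$n_elements,
               background_rgb = bg,
               background_noise_sd = d$background_noise_sd,
               seed = sample.int(.Machine$integer.max - 1L, 1),
               image_id = image_id)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Renders `n_images` random scenes and writes them as PNG files, one VIA v2
#' JSON annotation file covering all images, and a ground-truth trait CSV
#' (one row per cob). Per-image seeds are derived deterministically from the
#' master seed, so two runs with the same seed produce identical datasets.
#'
#' @param n_images number of scenes.
#' @param distributions ranges as in [default_scene_distributions()].
#' @param seed master seed.
#' @param out_dir output directory; must be empty or absent unless
#'   `overwrite = TRUE`.
#' @param overwrite allow writing into a non-empty directory.
#' @return Invisibly, a manifest list with image file names, the annotation
#'   path, the truth CSV path and the per-image seeds.
#' @export
generate_dataset <- function(n_images, distributions = default_scene_distributions(),
                             seed = 1L, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !overwrite)
    stop("output directory '", out_dir, "' is not empty (use overwrite = TRUE)")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, max(n_images, 1)))
  anns <- list()
  truths <- list()
  files <- character(0)
  for (i in seq_len(n_images)) {
    id <- sprintf("img%04d", i)
    sc <- generate_scene(sample_scene_spec(distributions, seed = seeds[i],
                                           image_id = id))
    f <- paste0(id, ".png")
    write_image(sc$image, file.path(out_dir, f))
    ann <- sc$truth$annotation
    ann$image_id <- f                       # VIA keys by file name
    anns[[f]] <- ann
    tr <- sc$truth$true_traits
    tr$image_id <- f
    truths[[i]] <- tr
    files <- c(files, f)
  }
  write_via(anns, file.path(out_dir, "annotations.json"))
  truth <- if (n_images > 0) do.call(rbind, truths) else
    data.frame(image_id = character(0))
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  invisible(list(images = files,
                 annotations = file.path(out_dir, "annotations.json"),
                 truth = file.path(out_dir, "truth.csv"),
                 seeds = seeds[seq_len(n_images)]))
}

#' Simulate planted two-regime accession trait data
#'
#' Generates cob-level trait records for a mix of phenotypically homogeneous
#' and heterogeneous accession images, emulating a genebank in which some
#' accessions are admixtures of distinct landraces. Homogeneous images draw
#' all cobs from one morph with small within-image trait scatter;
#' heterogeneous images draw cobs from two morphs whose separation and
#' within-morph scatter combine to within-image standard deviations several
#' times larger (strongest on the three color channels, where genebank
#' accessions are most variable).
#'
#' @param n_homogeneous,n_heterogeneous number of images per regime.
#' @param seed integer seed.
#' @param sd_inflation multiplier on morphometric trait SDs for the
#'   heterogeneous regime (default 3).
#' @param color_sd_inflation multiplier on the color-channel SDs (default 6,
#'   the largest inflation).
#' @param n_cob_range range of cobs per image (default 3-12).
#' @return A data frame with columns `image_id`, `cob_id`, `regime`
#'   (`"hom"`/`"het"`, the planted truth) and the seven clustering traits
#'   `length`, `diameter`, `asymmetry`, `ellipticity`, `mean_r`, `mean_g`,
#'   `mean_b`.
#' @export
simulate_accession_traits <- function(n_homogeneous = 300, n_heterogeneous = 150,
                                      seed = 1L, sd_inflation = 3,
                                      color_sd_inflation = 6,
                                      n_cob_range = c(3, 12)) {
  traits <- c("length", "diameter", "asymmetry", "ellipticity",
              "mean_r", "mean_g", "mean_b")
  base_sd <- c(length = 0.9, diameter = 0.28, asymmetry = 0.015,
               ellipticity = 0.02, mean_r = 6, mean_g = 6, mean_b = 6)
  mult <- c(rep(sd_inflation, 4), rep(color_sd_inflation, 3))
  palette <- default_scene_distributions()$cob_palette

  withr::with_seed(seed, {
    n_img <- n_homogeneous + n_heterogeneous
    regime <- rep(c("hom", "het"), c(n_homogeneous, n_heterogeneous))
    rows <- vector("list", n_img)
    for (j in seq_len(n_img)) {
      nc <- sample(seq(n_cob_range[1], n_cob_range[2]), 1)
      col <- palette[[sample(length(palette), 1)]] + stats::runif(3, -20, 20)
      mu <- c(length = stats::rnorm(1, 17, 4), diameter = stats::rnorm(1, 5, 0.8),
              asymmetry = abs(stats::rnorm(1, 0.08, 0.03)),
              ellipticity = stats::rnorm(1, 1.0, 0.05),
              mean_r = col[1], mean_g = col[2], mean_b = col[3])
      jitter <- exp(stats::rnorm(7, 0, 0.25))        # per-image SD variation
      s <- base_sd * jitter
      if (regime[j] == "het") {
        s <- s * mult
        # admixture of two morphs: separation d and within-morph spread such
        # that (d/2)^2 + sigma^2 = s^2
        d <- 1.6 * s; sigma <- 0.6 * s
        side <- sample(c(-0.5, 0.5), nc, replace = TRUE)
        x <- sapply(seq_along(traits), function(k)
          mu[k] + side * d[k] + stats::rnorm(nc, 0, sigma[k]))
      } else {
        x <- sapply(seq_along(traits), function(k) stats::rnorm(nc, mu[k], s[k]))
      }
      x <- matrix(x, nrow = nc)
      colnames(x) <- traits
      rows[[j]] <- data.frame(image_id = sprintf("acc%04d", j),
                              cob_id = seq_len(nc), regime = regime[j],
                              x, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}
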