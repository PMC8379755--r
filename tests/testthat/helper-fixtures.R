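# Fixtures are built in code; no binary test data.

# uniform-color image
flat_image <- function(H, W, rgb = c(100, 100, 100), id = "flat") {
  px <- array(rep(rgb, each = H * W), c(H, W, 3))
  raster_image(px, image_id = id)
}

# rectangle mask, 1-based inclusive rows/cols
rect_mask <- function(H, W, rows, cols, label = "cob") {
  m <- matrix(FALSE, H, W)
  m[rows, cols] <- TRUE
  instance_mask(m, label = label)
}

# discrete ellipse mask: pixel centers inside ((y-cy)/a)^2 + ((x-cx)/b)^2 <= 1
# (a = semi-axis along rows, b = along cols); optionally rotated by theta
ellipse_mask <- function(H, W, cy, cx, a, b, theta = 0, label = "cob") {
  yc <- matrix(seq_len(H) - 0.5, H, W) - cy
  xc <- matrix(rep(seq_len(W) - 0.5, each = H), H, W) - cx
  u <- yc * cos(theta) - xc * sin(theta)
  v <- yc * sin(theta) + xc * cos(theta)
  instance_mask((u / a)^2 + (v / b)^2 <= 1, label = label)
}

# horizontal two-tone ruler strip painted into an image; element widths may
# vary per element. Returns list(image, mask).
ruler_fixture <- function(widths, height = 20, margin = 6, bg = c(140, 150, 160)) {
  W <- 2 * margin + sum(widths)
  H <- 2 * margin + height
  px <- array(rep(bg, each = H * W), c(H, W, 3))
  x0 <- margin
  mask <- matrix(FALSE, H, W)
  rows <- (margin + 1):(margin + height)
  for (k in seq_along(widths)) {
    cols <- (x0 + 1):(x0 + widths[k])
    px[rows, cols, ] <- if (k %% 2 == 1) 0 else 255
    mask[rows, cols] <- TRUE
    x0 <- x0 + widths[k]
  }
  list(image = raster_image(px, image_id = "ruler_fix"),
       mask = instance_mask(mask, label = "ruler"))
}

# small deterministic scene used across tests
small_scene <- function(seed = 5L, n_cobs = 3, px_per_cm = 12) {
  cobs <- lapply(seq_len(n_cobs), function(i)
    cob_shape(length_cm = 10 + 2 * i, diameter_cm = 3.5 + 0.5 * i,
              p = 2 + 0.3 * i, gamma = 1 + 0.2 * (i - 1),
              base_rgb = list(c(200, 150, 60), c(160, 60, 50),
                              c(90, 45, 70))[[((i - 1) %% 3) + 1]],
              speckle_sd = 6))
  generate_scene(scene_spec(cobs, px_per_cm = px_per_cm, seed = seed,
                            image_id = sprintf("scene%d", seed)))
}

# independent brute-force replay of the graph-merge rule for tiny images
# (sigma = 0); mirrors the documented edge construction order: column-major
# pixels, neighbor order down, right, down-right, up-right.
fh_bruteforce <- function(px, k, min_size = 1L) {
  H <- dim(px)[1]; W <- dim(px)[2]
  n <- H * W
  eu <- integer(0); ev <- integer(0); ew <- numeric(0)
  id <- function(r, c) (c - 1L) * H + r
  for (c in seq_len(W)) for (r in seq_len(H)) {
    for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 < 1L || r2 > H || c2 > W) next
      w <- sqrt(sum((px[r, c, ] - px[r2, c2, ])^2))
      eu <- c(eu, id(r, c)); ev <- c(ev, id(r2, c2)); ew <- c(ew, w)
    }
  }
  ord <- order(ew)                         # stable in R: ties keep index order
  parent <- seq_len(n); size <- rep(1L, n); thresh <- rep(k, n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (ei in ord) {
    a <- find(eu[ei]); b <- find(ev[ei])
    if (a == b) next
    if (ew[ei] <= thresh[a] && ew[ei] <= thresh[b]) {
      parent[b] <- a
      size[a] <- size[a] + size[b]
      thresh[a] <- ew[ei] + k / size[a]
    }
  }
  if (min_size > 1L) {
    for (ei in ord) {
      a <- find(eu[ei]); b <- find(ev[ei])
      if (a == b) next
      if (size[a] < min_size || size[b] < min_size) {
        parent[b] <- a; size[a] <- size[a] + size[b]
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  matrix(match(roots, unique(roots)) - 1L, H, W)
}

# exhaustive PAM oracle: best medoid set by total Euclidean distance
pam_bruteforce <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  dmat <- as.matrix(dist(X))
  combs <- utils::combn(n, k)
  best <- NULL; best_obj <- Inf
  for (j in seq_len(ncol(combs))) {
    med <- combs[, j]
    obj <- sum(apply(dmat[, med, drop = FALSE], 1, min))
    if (obj < best_obj - 1e-12) { best_obj <- obj; best <- med }
  }
  labels <- apply(dmat[, best, drop = FALSE], 1, which.min)
  list(medoids = best, objective = best_obj, labels = labels)
}

# two well-separated Gaussian blobs
planted_blobs <- function(n_per = 20, sep = 10, d = 2, seed = 3L) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * d, 0, 0.5), ncol = d),
               matrix(rnorm(n_per * d, sep, 0.5), ncol = d))
    list(X = X, truth = rep(1:2, each = n_per))
  })
}
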