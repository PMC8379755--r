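# Z-scores, SD matrices, CLARA/k-means clustering and cluster-number
# selection.

trait_df <- function(image_id, ...) {
  vals <- list(...)
  n <- length(vals[[1]])
  jit <- seq_len(n)                 # default traits vary so no SD is zero
  base <- data.frame(image_id = image_id, cob_id = seq_len(n),
                     length = 15 + jit, diameter = 5 + 0.2 * jit,
                     asymmetry = 0.1 + 0.01 * jit,
                     ellipticity = 1 + 0.02 * jit, mean_r = 100 + jit,
                     mean_g = 100 + 2 * jit, mean_b = 100 + 3 * jit)
  for (nm in names(vals)) base[[nm]] <- vals[[nm]]
  base
}

test_that("within-image Z-scores standardize each image with the sample SD", {
  m <- rbind(trait_df("a", length = c(2, 4, 6)),
             trait_df("b", length = c(10, 14)))
  z <- within_image_zscores(m)
  expect_equal(z$z$length[z$z$image_id == "a"], c(-1, 0, 1))
  expect_equal(z$z$length[z$z$image_id == "b"], c(-1, 1) / sqrt(2))
  expect_equal(z$n_excluded, 0L)

  # per-image mean 0 / SD 1 to numerical precision, across all traits
  msim <- simulate_accession_traits(15, 10, seed = 5)
  zz <- within_image_zscores(msim)$z
  for (tr in c("length", "mean_b")) {
    mu <- tapply(zz[[tr]], zz$image_id, mean)
    s <- tapply(zz[[tr]], zz$image_id, sd)
    expect_lt(max(abs(mu)), 1e-9)
    expect_lt(max(abs(s - 1)), 1e-9)
  }
})

test_that("degenerate images are excluded from the Z-score route", {
  m <- rbind(trait_df("one", length = 12),                 # single cob
             trait_df("const", length = c(5, 5, 5)),       # zero SD
             trait_df("ok", length = c(4, 6)))
  z <- within_image_zscores(m)
  expect_setequal(z$excluded, c("one", "const"))
  expect_equal(unique(z$z$image_id), "ok")
  expect_error(within_image_zscores(rbind(trait_df("one", length = 1))),
               "all images excluded")
})

test_that("the per-image SD matrix is centered and scaled per column", {
  m <- rbind(trait_df("a", length = c(1, 3)),
             trait_df("b", length = c(2, 6)),
             trait_df("c", length = c(0, 6), diameter = c(4, 6)))
  sm <- image_sd_matrix(m, traits = c("length", "diameter"))
  # hand-computed length SDs: sqrt(2), 2*sqrt(2), 3*sqrt(2) -> scaled -1,0,1
  expect_equal(unname(sm$raw[, "length"]), sqrt(2) * c(1, 2, 3))
  expect_equal(unname(sm$sd_matrix[, "length"]), c(-1, 0, 1))
  expect_equal(unname(colMeans(sm$sd_matrix)), c(0, 0))
  # scaling is idempotent
  again <- scale(sm$sd_matrix)
  expect_equal(unname(again[, ]), unname(sm$sd_matrix[, ]), tolerance = 1e-12)
  # constant column cannot be scaled
  expect_error(image_sd_matrix(rbind(trait_df("a", length = c(1, 3)),
                                     trait_df("b", length = c(2, 4))),
                               traits = c("length", "diameter")),
               "constant SD column")
})

test_that("clara recovers planted clusters and reduces to exhaustive PAM", {
  pb <- planted_blobs(n_per = 25, sep = 8)
  out <- clara_cluster(pb$X, k = 2, seed = 1)
  expect_equal(mclust::adjustedRandIndex(out$labels, pb$truth), 1)

  # k = 1: one label, objective = mean distance to the single medoid
  out1 <- clara_cluster(pb$X[1:12, ], k = 1, seed = 1)
  expect_true(all(out1$labels == 1L))
  dmat <- as.matrix(dist(pb$X[1:12, ]))
  expect_equal(out1$objective, min(colMeans(dmat)), tolerance = 1e-9)

  # small instances equal brute-force PAM (exhaustive medoid search)
  for (s in 1:3) {
    X <- withr::with_seed(s, matrix(rnorm(6 * 2), ncol = 2))
    for (k in 2:3) {
      got <- clara_cluster(X, k = k, seed = s)
      want <- pam_bruteforce(X, k)
      expect_equal(got$objective * nrow(X), want$objective, tolerance = 1e-9)
      expect_equal(mclust::adjustedRandIndex(got$labels, want$labels), 1)
    }
  }
})

test_that("average silhouette selects the planted k and matches hand values", {
  pb <- planted_blobs(n_per = 20, sep = 10)
  sel <- select_k_silhouette(pb$X, k_range = 2:6, seed = 2)
  expect_equal(sel$best_k, 2L)
  expect_equal(nrow(sel$curve), 5L)
  expect_equal(mclust::adjustedRandIndex(sel$outcome$labels, pb$truth), 1)

  # 4 collinear points 0,1,10,11: mean silhouette = (9.5/10.5 + 8.5/9.5)/2
  X4 <- matrix(c(0, 1, 10, 11), ncol = 1)
  sil <- cluster::silhouette(c(1L, 1L, 2L, 2L), dist(X4))
  expect_equal(mean(sil[, "sil_width"]), (9.5 / 10.5 + 8.5 / 9.5) / 2,
               tolerance = 1e-12)
  sel4 <- select_k_silhouette(X4, k_range = 2:3, seed = 1)
  expect_equal(sel4$best_k, 2L)
  expect_equal(sel4$curve$avg_silhouette[1], (9.5 / 10.5 + 8.5 / 9.5) / 2,
               tolerance = 1e-9)

  # a range of size one returns that k
  expect_equal(select_k_silhouette(pb$X, k_range = 4, seed = 1)$best_k, 4L)
})

test_that("k-means recovers planted clusters deterministically", {
  pb <- planted_blobs(n_per = 25, sep = 8)
  out <- kmeans_cluster(pb$X, 2, seed = 3)
  expect_equal(mclust::adjustedRandIndex(out$labels, pb$truth), 1)
  out_b <- kmeans_cluster(pb$X, 2, seed = 3)
  expect_identical(out$labels, out_b$labels)
  # k = n drives the within-cluster sum of squares to zero
  X <- withr::with_seed(1, matrix(rnorm(10), ncol = 2))
  expect_equal(kmeans_cluster(X, nrow(X), seed = 1)$objective, 0)
})

test_that("the gap statistic separates one blob from two", {
  one <- withr::with_seed(8, matrix(rnorm(60 * 2), ncol = 2))
  sel1 <- select_k_gap(one, k_range = 1:5, B = 30, seed = 8)
  expect_equal(sel1$best_k, 1L)
  expect_equal(nrow(sel1$curve), 5L)

  pb <- planted_blobs(n_per = 30, sep = 12, seed = 9)
  sel2 <- select_k_gap(pb$X, k_range = 1:5, B = 30, seed = 9)
  expect_equal(sel2$best_k, 2L)
})

test_that("pca_view matches an explicit eigendecomposition", {
  X <- withr::with_seed(4, matrix(rnorm(5 * 3), ncol = 3))
  pv <- pca_view(X, n_components = 3)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
  expect_equal(pv$sdev^2, ev$values, tolerance = 1e-9)
  for (j in 1:3)
    expect_equal(abs(sum(pv$rotation[, j] * ev$vectors[, j])), 1,
                 tolerance = 1e-9)
  # 2-D data: two components carry all the variance
  X2 <- withr::with_seed(5, matrix(rnorm(20), ncol = 2))
  expect_equal(sum(pca_view(X2)$explained), 1)
})

test_that("both routes recover the planted two-regime design", {
  m <- simulate_accession_traits(80, 40, seed = 11)
  res <- cluster_heterogeneity(m, k_gap = 1:5, B = 30, seed = 11)
  expect_equal(res$zscore_route$best_k, 2L)
  expect_equal(res$sd_route$best_k, 2L)
  reg <- m$regime[match(rownames(res$sd$sd_matrix), m$image_id)]
  expect_gte(mclust::adjustedRandIndex(reg, res$sd_route$outcome$labels), 0.9)

  rep_ <- heterogeneity_report(res)
  expect_equal(nrow(rep_$images), nrow(res$sd$sd_matrix))
  expect_equal(sum(table(rep_$images$cluster_sd)), nrow(rep_$images))
  # the heterogeneous cluster shows larger color SDs
  prof <- rep_$cluster_profiles
  hi <- which.max(prof$mean_r)
  lo <- which.min(prof$mean_r)
  expect_gt(prof$mean_r[hi], 2 * prof$mean_r[lo])
})
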