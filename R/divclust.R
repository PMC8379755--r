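# Heterogeneity clustering: identify images (accessions) with high within-
# image cob diversity via two unsupervised routes --
#   (1) within-image Z-scores of each cob, clustered with CLARA, cluster
#       number selected by the average silhouette;
#   (2) per-image trait standard deviations (centered/scaled), clustered
#       with k-means, cluster number selected by the gap statistic.

CLUSTER_TRAITS <- c("length", "diameter", "asymmetry", "ellipticity",
                    "mean_r", "mean_g", "mean_b")

check_trait_matrix <- function(m, traits = CLUSTER_TRAITS) {
  if (!is.data.frame(m)) stop("trait matrix must be a data frame")
  missing <- setdiff(c("image_id", traits), names(m))
  if (length(missing) > 0L)
    stop("trait matrix lacks column(s): ", paste(missing, collapse = ", "))
  if (anyNA(m[, traits])) stop("trait matrix contains missing values")
  invisible(m)
}

#' Within-image Z-scores of cob traits
#'
#' For cob `i` in image `j`, `Z_ij = (x_ij - mean_j) / sd_j` per trait, with
#' the per-image sample standard deviation (denominator n - 1): each cob's
#' deviation from its image mean on a common scale. Images with fewer than 2
#' cobs, or with a zero standard deviation in any trait, carry no within-
#' image signal and are excluded (their count is reported in the result).
#'
#' @param m cob-level trait data frame with `image_id` and the clustering
#'   trait columns.
#' @param traits trait columns to use (default: length, diameter, asymmetry,
#'   ellipticity and the three color means).
#' @return A list with `z` (data frame: `image_id`, `cob_id` if present, and
#'   the Z-scored traits), `excluded` (character vector of excluded image
#'   ids) and `n_excluded`.
#' @export
within_image_zscores <- function(m, traits = CLUSTER_TRAITS) {
  check_trait_matrix(m, traits)
  keep <- vapply(split(m[, traits, drop = FALSE], m$image_id), function(d) {
    nrow(d) >= 2L && all(vapply(d, stats::sd, numeric(1)) > 0)
  }, logical(1))
  excluded <- names(keep)[!keep]
  if (all(!keep)) stop("all images excluded (need >= 2 cobs and nonzero SDs)")
  d <- m[m$image_id %in% names(keep)[keep], , drop = FALSE]
  z <- d
  for (tr in traits)
    z[[tr]] <- stats::ave(d[[tr]], d$image_id,
                          FUN = function(x) (x - mean(x)) / stats::sd(x))
  keep_cols <- intersect(c("image_id", "cob_id", traits), names(z))
  list(z = z[, keep_cols], excluded = excluded, n_excluded = length(excluded))
}

#' Per-image standard-deviation matrix
#'
#' The within-image sample standard deviation of every trait, one row per
#' image, then centered and scaled column-wise (mean 0, SD 1) so all traits
#' contribute comparably. Images with fewer than 2 cobs are excluded. A
#' column that is constant across images cannot be scaled and raises an
#' error.
#'
#' @inheritParams within_image_zscores
#' @return A list with `sd_matrix` (numeric matrix, rownames = image ids,
#'   scaled), `raw` (unscaled SDs) and `excluded`.
#' @export
image_sd_matrix <- function(m, traits = CLUSTER_TRAITS) {
  check_trait_matrix(m, traits)
  parts <- split(m[, traits, drop = FALSE], m$image_id)
  keep <- vapply(parts, nrow, integer(1)) >= 2L
  excluded <- names(parts)[!keep]
  if (all(!keep)) stop("all images excluded (need >= 2 cobs)")
  raw <- t(vapply(parts[keep],
                  function(d) vapply(d, stats::sd, numeric(1)), numeric(length(traits))))
  colnames(raw) <- traits
  csd <- apply(raw, 2, stats::sd)
  if (any(csd == 0))
    stop("constant SD column(s) cannot be scaled: ",
         paste(traits[csd == 0], collapse = ", "))
  list(sd_matrix = scale(raw), raw = raw, excluded = excluded)
}

#' CLARA medoid clustering
#'
#' Clustering LARge Applications: PAM (partitioning around medoids) run on
#' random subsamples, keeping the medoid set with the lowest total Euclidean
#' dissimilarity over the full data. Datasets no larger than the subsample
#' size are clustered with plain PAM, which CLARA then equals exactly.
#'
#' @param X numeric matrix or data frame of observations x features.
#' @param k number of clusters (>= 1).
#' @param n_samples number of random subsamples (default 5).
#' @param sample_size subsample size; default `min(n, 40 + 2k)` as in the
#'   reference implementation.
#' @param seed integer seed for the subsampling.
#' @return An object of class `cluster_outcome` with `labels`, `k`,
#'   `medoids`, `objective` (average dissimilarity), `method` and `seed`.
#' @export
clara_cluster <- function(X, k, n_samples = 5, sample_size = NULL, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n")
  if (is.null(sample_size)) sample_size <- min(n, 40 + 2 * k)
  fit <- withr::with_seed(seed, {
    if (n <= sample_size) {
      cluster::pam(X, k = k, metric = "euclidean")
    } else {
      cluster::clara(X, k = k, metric = "euclidean", samples = n_samples,
                     sampsize = sample_size, rngR = TRUE, pamLike = TRUE)
    }
  })
  labels <- fit$clustering
  medoids <- if (inherits(fit, "pam")) fit$medoids else fit$medoids
  structure(list(labels = as.integer(labels), k = as.integer(k),
                 medoids = medoids,
                 objective = unname(utils::tail(fit$objective, 1)),
                 method = "clara", seed = as.integer(seed)),
            class = "cluster_outcome")
}

#' k-means clustering
#'
#' Lloyd-style k-means (Hartigan-Wong refinement as implemented in base R),
#' best of `n_init` random initializations by total within-cluster sum of
#' squares; deterministic given the seed.
#'
#' @inheritParams clara_cluster
#' @param n_init number of random starts.
#' @return A `cluster_outcome` with `labels`, `k`, `centers` and `objective`
#'   (total within-cluster sum of squares).
#' @export
kmeans_cluster <- function(X, k, seed = 1L, n_init = 10) {
  X <- as.matrix(X)
  if (k < 1 || k > nrow(X)) stop("k must satisfy 1 <= k <= n")
  if (k == nrow(X)) {
    # every observation its own cluster: exact, WSS = 0
    return(structure(list(labels = seq_len(nrow(X)), k = as.integer(k),
                          centers = X, objective = 0,
                          method = "kmeans", seed = as.integer(seed)),
                     class = "cluster_outcome"))
  }
  fit <- withr::with_seed(seed, stats::kmeans(X, centers = k, nstart = n_init,
                                              iter.max = 50))
  structure(list(labels = as.integer(fit$cluster), k = as.integer(k),
                 centers = fit$centers, objective = fit$tot.withinss,
                 method = "kmeans", seed = as.integer(seed)),
            class = "cluster_outcome")
}

#' @export
print.cluster_outcome <- function(x, ...) {
  cat(sprintf("<cluster_outcome: %s, k = %d, objective = %.4g>\n",
              x$method, x$k, x$objective))
  invisible(x)
}

#' Select the cluster number by average silhouette
#'
#' Runs the clusterer for each candidate `k` and picks the one maximizing
#' the mean silhouette width `s(i) = (b - a) / max(a, b)` (Euclidean
#' distances); ties resolve to the smaller `k`. A candidate range of size 1
#' returns that `k` directly.
#'
#' @param X observations x features.
#' @param k_range candidate cluster numbers (default 2:8).
#' @param clusterer clustering function `(X, k, seed) -> cluster_outcome`
#'   (default [clara_cluster()]).
#' @param seed seed passed to the clusterer.
#' @return A list with `best_k`, `curve` (data frame `k`, `avg_silhouette`)
#'   and `outcome` (the `cluster_outcome` at `best_k`).
#' @export
select_k_silhouette <- function(X, k_range = 2:8, clusterer = clara_cluster,
                                seed = 1L) {
  X <- as.matrix(X)
  k_range <- sort(unique(as.integer(k_range)))
  outcomes <- lapply(k_range, function(k) clusterer(X, k, seed = seed))
  if (length(k_range) == 1L) {
    curve <- data.frame(k = k_range, avg_silhouette = NA_real_)
    return(list(best_k = k_range, curve = curve, outcome = outcomes[[1]]))
  }
  d <- stats::dist(X)
  avg <- vapply(outcomes, function(o) {
    if (o$k < 2) return(NA_real_)
    mean(cluster::silhouette(o$labels, d)[, "sil_width"])
  }, numeric(1))
  best <- which.max(avg)
  list(best_k = k_range[best],
       curve = data.frame(k = k_range, avg_silhouette = avg),
       outcome = outcomes[[best]])
}

#' Select the cluster number by the gap statistic
#'
#' `Gap(k) = E*[log W_k] - log W_k`, where the expectation is over `B`
#' uniform reference draws in the principal-component-aligned bounding box
#' of the data. The selected `k` is the smallest one with
#' `Gap(k) >= Gap(k+1) - s_{k+1}` (the one-standard-error rule).
#'
#' @param X observations x features.
#' @param k_range candidate cluster numbers (default 1:8; must start at 1
#'   or form a contiguous range).
#' @param B number of reference datasets (default 50).
#' @param seed integer seed.
#' @param n_init k-means restarts per fit.
#' @return A list with `best_k`, `curve` (data frame `k`, `gap`, `se`) and
#'   `outcome` (k-means result at `best_k`).
#' @export
select_k_gap <- function(X, k_range = 1:8, B = 50, seed = 1L, n_init = 10) {
  X <- as.matrix(X)
  k_range <- sort(unique(as.integer(k_range)))
  kmax <- max(k_range)
  gap_fit <- withr::with_seed(seed, cluster::clusGap(
    X, FUNcluster = function(x, k) stats::kmeans(x, k, nstart = n_init,
                                                 iter.max = 50),
    K.max = kmax, B = B, spaceH0 = "scaledPCA", verbose = FALSE))
  tab <- gap_fit$Tab[k_range, , drop = FALSE]
  gap <- tab[, "gap"]; se <- tab[, "SE.sim"]
  best_k <- k_range[cluster::maxSE(gap, se, method = "Tibs2001SEmax")]
  outcome <- kmeans_cluster(X, best_k, seed = seed, n_init = n_init)
  list(best_k = best_k,
       curve = data.frame(k = k_range, gap = unname(gap), se = unname(se)),
       outcome = outcome)
}

#' Principal component view of a trait matrix
#'
#' PCA (centered, unscaled) for reporting and plotting; clustering itself
#' runs in full trait space.
#'
#' @param X observations x features.
#' @param n_components number of components to return.
#' @return A list with `scores`, `rotation`, `explained` (proportion of
#'   variance per returned component) and `sdev`.
#' @export
pca_view <- function(X, n_components = 2) {
  X <- as.matrix(X)
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  nc <- min(n_components, ncol(fit$x))
  var_all <- fit$sdev^2
  list(scores = fit$x[, seq_len(nc), drop = FALSE],
       rotation = fit$rotation[, seq_len(nc), drop = FALSE],
       explained = var_all[seq_len(nc)] / sum(var_all),
       sdev = fit$sdev)
}

#' Run both heterogeneity-clustering routes
#'
#' Route 1 computes within-image Z-scores of all cobs and clusters them with
#' CLARA, choosing `k` by the average silhouette; each image is then labeled
#' by the majority cluster of its cobs. Route 2 computes the centered and
#' scaled per-image SD matrix and clusters the images with k-means, choosing
#' `k` by the gap statistic.
#'
#' @param m cob-level trait data frame (see [within_image_zscores()]).
#' @param k_silhouette candidate k for the CLARA route (default 2:8).
#' @param k_gap candidate k for the k-means route (default 1:8).
#' @param B reference draws for the gap statistic.
#' @param seed integer seed used for both routes.
#' @param traits trait columns to use.
#' @return An object of class `heterogeneity_result`: `zscore_route` and
#'   `sd_route` (each with `best_k`, `curve`, `outcome`), the matrices used,
#'   and `seed`.
#' @export
cluster_heterogeneity <- function(m, k_silhouette = 2:8, k_gap = 1:8, B = 50,
                                  seed = 1L, traits = CLUSTER_TRAITS) {
  zs <- within_image_zscores(m, traits)
  sdm <- image_sd_matrix(m, traits)
  z_mat <- as.matrix(zs$z[, traits])
  route1 <- select_k_silhouette(z_mat, k_range = k_silhouette,
                                clusterer = clara_cluster, seed = seed)
  route2 <- select_k_gap(sdm$sd_matrix, k_range = k_gap, B = B, seed = seed)
  structure(list(zscore_route = route1, sd_route = route2,
                 zscores = zs, sd = sdm, seed = as.integer(seed),
                 traits = traits),
            class = "heterogeneity_result")
}

#' Per-image heterogeneity report
#'
#' Combines the two routes into one table: per analyzed image, the majority
#' CLARA cluster of its cobs (Z-score route) and its k-means cluster (SD
#' route), plus per-cluster trait SD summaries showing which traits drive
#' the separation.
#'
#' @param result a `heterogeneity_result` from [cluster_heterogeneity()].
#' @return A list with `images` (data frame: `image_id`, `cluster_zscore`,
#'   `cluster_sd`) and `cluster_profiles` (mean within-image SD per trait
#'   and SD-route cluster).
#' @export
heterogeneity_report <- function(result) {
  stopifnot(inherits(result, "heterogeneity_result"))
  z <- result$zscores$z
  z_lab <- result$zscore_route$outcome$labels
  maj <- vapply(split(z_lab, z$image_id), function(l)
    as.integer(names(sort(table(l), decreasing = TRUE))[1]), integer(1))
  sd_ids <- rownames(result$sd$sd_matrix)
  sd_lab <- stats::setNames(result$sd_route$outcome$labels, sd_ids)
  ids <- intersect(names(maj), sd_ids)
  images <- data.frame(image_id = ids,
                       cluster_zscore = unname(maj[ids]),
                       cluster_sd = unname(sd_lab[ids]),
                       stringsAsFactors = FALSE)
  raw <- result$sd$raw[ids, , drop = FALSE]
  profiles <- stats::aggregate(as.data.frame(raw),
                               by = list(cluster_sd = images$cluster_sd),
                               FUN = mean)
  list(images = images, cluster_profiles = profiles)
}
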