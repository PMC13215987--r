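#' Segmentation configuration
#'
#' @param method One of `"otsu"`, `"kmeans"`, `"fcm"`.
#' @param n_clusters Number of clusters for kmeans/fcm (default 2:
#'   adipose vs rest).
#' @param fuzziness_m Fuzzy c-means fuzziness exponent, > 1 (default 2).
#' @param tol Convergence threshold on the center shift (default 1e-5).
#' @param max_iter Iteration cap (default 300).
#' @param seed Seed for cluster initialization.
#' @param n_start Independent k-means restarts; the run with the lowest
#'   within-cluster SSE wins (guards against local optima of Lloyd's
#'   algorithm on multimodal histograms).
#' @param histogram_bins Histogram resolution for Otsu (default 256).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(method = c("otsu", "kmeans", "fcm"),
                                n_clusters = 2L, fuzziness_m = 2,
                                tol = 1e-5, max_iter = 300L, seed = 1L,
                                n_start = 5L, histogram_bins = 256L) {
  method <- match.arg(method)
  stopifnot(n_clusters >= 2, fuzziness_m > 1, tol > 0, max_iter >= 1,
            n_start >= 1, histogram_bins >= 2)
  structure(list(method = method, n_clusters = as.integer(n_clusters),
                 fuzziness_m = as.numeric(fuzziness_m), tol = as.numeric(tol),
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 n_start = as.integer(n_start),
                 histogram_bins = as.integer(histogram_bins)),
            class = "segmentation_config")
}

segmentation_result <- function(mask, method, threshold = NULL,
                                cluster_centers = NULL, memberships = NULL,
                                n_iter = NULL, objective = NULL) {
  assert_mask(mask)
  structure(list(mask = mask, method = method, threshold = threshold,
                 cluster_centers = cluster_centers, memberships = memberships,
                 n_iter = n_iter, objective = objective),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result>", x$method, "\n")
  cat("  mask:", nrow(x$mask), "x", ncol(x$mask),
      sprintf("(%d adipose px)", sum(x$mask)), "\n")
  if (!is.null(x$threshold)) cat("  threshold:", format(x$threshold), "\n")
  if (!is.null(x$cluster_centers))
    cat("  centers:", paste(format(x$cluster_centers, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Otsu threshold segmentation
#'
#' Computes the threshold maximizing the between-class variance of the
#' intensity histogram and labels pixels strictly above it as adipose
#' (the brighter class; fat is hyperintense on T1-weighted images).
#' Ties are broken towards the lowest maximizing threshold. The returned
#' threshold is the upper edge of the winning histogram bin.
#'
#' @param img Numeric image matrix with at least two distinct values.
#' @param cfg A [segmentation_config()]; only `histogram_bins` is used.
#' @return A `segmentation_result` with the binary mask and the threshold.
#' @export
otsu_segment <- function(img, cfg = segmentation_config("otsu")) {
  stopifnot(is.matrix(img))
  thr <- otsu_threshold(as.vector(img), cfg$histogram_bins)
  mask <- matrix(0L, nrow(img), ncol(img))
  mask[img > thr] <- 1L
  segmentation_result(mask, "otsu", threshold = thr)
}

# Between-class-variance maximization over the bin cut-points of an
# equal-width histogram spanning the data range.
otsu_threshold <- function(x, bins = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2]) {
    stop("cannot threshold a constant image (single value ",
         format(rng[1]), ")", call. = FALSE)
  }
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE), bins),
                nbins = bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  centers <- (edges[-1] + edges[-(bins + 1L)]) / 2
  mu <- cumsum(p * centers)
  mu_t <- mu[bins]
  # candidate cuts after bin k, k = 1..bins-1
  k <- seq_len(bins - 1L)
  w0 <- omega[k]; m0 <- mu[k]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, bins - 1L)
  sigma_b[valid] <- (mu_t * w0[valid] - m0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  best <- which.max(sigma_b)   # which.max takes the first (lowest) maximizer
  edges[best + 1L]
}

# Collapse an image to weighted unique intensity values; clustering on the
# weighted values is exact and far faster than on the raw pixels.
unique_weighted <- function(img) {
  x <- as.vector(img)
  values <- sort(unique(x))
  list(values = values,
       counts = tabulate(match(x, values), nbins = length(values)))
}

# k-means++-style seeding over weighted 1-D samples.
seed_centers <- function(values, counts, k) {
  centers <- numeric(k)
  centers[1] <- values[sample.int(length(values), 1, prob = counts)]
  for (j in seq_len(k - 1L)) {
    d2 <- vapply(values, function(v) min((v - centers[seq_len(j)])^2), numeric(1))
    if (all(d2 == 0)) {
      centers[j + 1L] <- values[sample.int(length(values), 1, prob = counts)]
    } else {
      centers[j + 1L] <- values[sample.int(length(values), 1, prob = counts * d2)]
    }
  }
  centers
}

#' K-means segmentation
#'
#' Flattens the image to 1-D intensity samples and runs Lloyd iterations
#' (k-means++-style seeding from `cfg$seed`) until the center shift drops
#' below `tol` or `max_iter` is reached. The cluster with the highest
#' center is labeled adipose. An empty cluster is re-seeded at the sample
#' farthest from its assigned center rather than dropped.
#'
#' @param img Numeric image matrix with at least `n_clusters` distinct values.
#' @param cfg A [segmentation_config()].
#' @return A `segmentation_result` with mask, `cluster_centers` (sorted
#'   ascending), iteration count and the final within-cluster SSE.
#' @export
kmeans_segment <- function(img, cfg = segmentation_config("kmeans")) {
  stopifnot(is.matrix(img))
  uw <- unique_weighted(img)
  if (length(uw$values) < cfg$n_clusters) {
    stop("image has fewer distinct values (", length(uw$values),
         ") than clusters (", cfg$n_clusters, ")", call. = FALSE)
  }
  fit <- with_seed(cfg$seed, {
    best <- NULL
    for (s in seq_len(cfg$n_start)) {
      cand <- lloyd_1d(uw$values, uw$counts, cfg$n_clusters,
                       cfg$tol, cfg$max_iter)
      if (is.null(best) || cand$sse < best$sse) best <- cand
    }
    best
  })
  adipose <- which.max(fit$centers)
  val_assign <- fit$assign
  mask <- matrix(0L, nrow(img), ncol(img))
  mask[matrix(val_assign[match(img, uw$values)] == adipose, nrow(img))] <- 1L
  segmentation_result(mask, "kmeans",
                      cluster_centers = sort(fit$centers),
                      n_iter = fit$n_iter, objective = fit$sse)
}

lloyd_1d <- function(values, counts, k, tol, max_iter, init = NULL) {
  centers <- if (is.null(init)) seed_centers(values, counts, k) else init
  assign_pts <- function(ctrs) {
    d <- abs(outer(values, ctrs, "-"))
    max.col(-d, ties.method = "first")
  }
  asg <- assign_pts(centers)
  sse_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    new_centers <- centers
    for (j in seq_len(k)) {
      sel <- asg == j
      if (!any(sel)) {
        # re-seed an empty cluster at the sample farthest from all centers
        far <- which.max(vapply(values, function(v) min(abs(v - centers)),
                                numeric(1)))
        new_centers[j] <- values[far]
        message("k-means: empty cluster ", j, " re-seeded at farthest sample")
      } else {
        new_centers[j] <- sum(values[sel] * counts[sel]) / sum(counts[sel])
      }
    }
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    asg <- assign_pts(centers)
    sse_trace <- c(sse_trace, sum(counts * (values - centers[asg])^2))
    if (shift < tol) break
  }
  sse <- sum(counts * (values - centers[asg])^2)
  list(centers = centers, assign = asg, n_iter = it, sse = sse,
       sse_trace = sse_trace)
}

#' Fuzzy c-means segmentation
#'
#' Standard FCM on the flattened intensities: alternating updates of
#' memberships `u_ij = 1 / sum_k (d_ij / d_ik)^(2/(m-1))` and centers as
#' membership^m-weighted means, from k-means++-style initial centers.
#' A pixel coinciding exactly with a center receives membership 1 for
#' that center. The hard mask assigns each pixel to its maximum-membership
#' cluster; the cluster with the highest center is adipose.
#'
#' @param img Numeric image matrix.
#' @param cfg A [segmentation_config()]; uses `fuzziness_m`, `tol`,
#'   `max_iter`, `seed`.
#' @return A `segmentation_result`; `memberships` is an
#'   `nrow x ncol x n_clusters` array (cluster order = ascending center).
#' @export
fcm_segment <- function(img, cfg = segmentation_config("fcm")) {
  stopifnot(is.matrix(img))
  uw <- unique_weighted(img)
  if (length(uw$values) < cfg$n_clusters) {
    stop("image has fewer distinct values (", length(uw$values),
         ") than clusters (", cfg$n_clusters, ")", call. = FALSE)
  }
  fit <- with_seed(cfg$seed, fcm_1d(uw$values, uw$counts, cfg$n_clusters,
                                    cfg$fuzziness_m, cfg$tol, cfg$max_iter))
  ord <- order(fit$centers)
  centers <- fit$centers[ord]
  u <- fit$u[, ord, drop = FALSE]          # values x clusters
  adipose <- cfg$n_clusters                 # last after ordering = brightest
  idx <- match(img, uw$values)
  hard <- max.col(u, ties.method = "last")  # ties towards brighter cluster
  mask <- matrix(0L, nrow(img), ncol(img))
  mask[matrix(hard[idx] == adipose, nrow(img))] <- 1L
  memb <- array(u[idx, , drop = FALSE], dim = c(nrow(img), ncol(img), cfg$n_clusters))
  segmentation_result(mask, "fcm", cluster_centers = centers,
                      memberships = memb, n_iter = fit$n_iter,
                      objective = fit$objective)
}

# FCM membership update for given centers: u_ij = 1 / sum_k
# (d_ij/d_ik)^(2/(m-1)); a sample coinciding with a center takes
# membership 1 there (split over coincident centers).
fcm_memberships <- function(values, centers, m) {
  d <- abs(outer(values, centers, "-"))
  u <- matrix(0, length(values), length(centers))
  zero <- d == 0
  has_zero <- rowSums(zero) > 0
  if (any(has_zero)) {
    u[has_zero, ] <- zero[has_zero, , drop = FALSE] /
      rowSums(zero[has_zero, , drop = FALSE])
  }
  reg <- !has_zero
  if (any(reg)) {
    dp <- d[reg, , drop = FALSE]^(-2 / (m - 1))
    u[reg, ] <- dp / rowSums(dp)
  }
  u
}

# FCM updates over weighted unique values (mathematically identical to
# running on the raw pixels).
fcm_1d <- function(values, counts, c, m, tol, max_iter, init = NULL) {
  centers <- if (is.null(init)) seed_centers(values, counts, c) else init
  memb_from_centers <- function(ctrs) fcm_memberships(values, ctrs, m)
  u <- memb_from_centers(centers)
  obj <- function(ctrs, u) {
    d <- abs(outer(values, ctrs, "-"))
    sum(counts * (u^m) * d^2)
  }
  obj_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    w <- (u^m) * counts
    new_centers <- colSums(w * values) / colSums(w)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    u <- memb_from_centers(centers)
    obj_trace <- c(obj_trace, obj(centers, u))
    if (shift < tol) break
  }
  list(centers = centers, u = u, n_iter = it,
       objective = obj(centers, u), obj_trace = obj_trace)
}

#' Segment a slice with a chosen backend
#'
#' Dispatcher over the three interchangeable backends.
#'
#' @param img Numeric image matrix (typically the output of [enhance()]).
#' @param cfg A [segmentation_config()]; `cfg$method` selects the backend.
#' @return A `segmentation_result`.
#' @export
segment_slice <- function(img, cfg = segmentation_config()) {
  switch(cfg$method,
         otsu = otsu_segment(img, cfg),
         kmeans = kmeans_segment(img, cfg),
         fcm = fcm_segment(img, cfg))
}
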