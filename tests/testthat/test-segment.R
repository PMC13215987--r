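test_that("Otsu on a perfectly bimodal image selects exactly the bright pixels", {
  img <- matrix(c(rep(0.1, 60), rep(0.9, 40)), 10, 10)
  res <- otsu_segment(img)
  expect_identical(res$mask, slicefat:::mask_int(img == 0.9))
  expect_true(res$threshold > 0.1 && res$threshold < 0.9)
})

test_that("Otsu threshold equals exhaustive between-class-variance search", {
  x <- c(0, 1, 1, 2, 8, 9, 9, 10)
  img <- matrix(x, 2, 4)
  res <- otsu_segment(img)
  expect_equal(res$threshold, oracle_otsu(x))

  set.seed(17)
  for (i in 1:20) {
    img <- matrix(runif(48), 6, 8)
    expect_equal(otsu_segment(img)$threshold, oracle_otsu(as.vector(img)))
  }
})

test_that("constant images raise a degenerate-input error naming the value", {
  expect_error(otsu_segment(matrix(0.5, 4, 4)), "0.5")
  expect_error(kmeans_segment(matrix(0.5, 4, 4)), "distinct")
  expect_error(fcm_segment(matrix(0.5, 4, 4)), "distinct")
})

test_that("k-means equals Otsu on well-separated bimodal images and is deterministic", {
  set.seed(3)
  img <- matrix(sample(c(0.1, 0.9), 100, replace = TRUE), 10, 10)
  km1 <- kmeans_segment(img, segmentation_config("kmeans", seed = 5L))
  km2 <- kmeans_segment(img, segmentation_config("kmeans", seed = 5L))
  ot <- otsu_segment(img)
  expect_identical(km1$mask, ot$mask)
  expect_identical(km1$mask, km2$mask)
  expect_identical(km1$cluster_centers, km2$cluster_centers)
})

test_that("1-D k-means partition matches exhaustive contiguous-split search", {
  vals <- c(0, 0.1, 0.5, 0.9, 1.0)
  img <- matrix(vals, 1, 5)
  km <- kmeans_segment(img, segmentation_config("kmeans", seed = 2L))
  # the optimal 2-partition of sorted 1-D data is a contiguous split;
  # enumerate all splits and minimize SSE (this input has two global
  # optima with equal SSE, so compare objectives and membership in the
  # optimal set rather than a unique partition)
  sses <- vapply(1:4, function(s) {
    lo <- vals[1:s]; hi <- vals[(s + 1):5]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }, numeric(1))
  best_sse <- min(sses)
  expect_equal(km$objective, best_sse, tolerance = 1e-10)
  optimal_masks <- lapply(which(abs(sses - best_sse) < 1e-12), function(s)
    slicefat:::mask_int(matrix(vals > vals[s], 1, 5)))
  expect_true(any(vapply(optimal_masks, identical, logical(1), y = km$mask)))

  # a uniquely optimal instance must reproduce that exact partition
  vals2 <- c(0, 0.1, 0.45, 0.9, 1.0)
  km2 <- kmeans_segment(matrix(vals2, 1, 5), segmentation_config("kmeans"))
  sses2 <- vapply(1:4, function(s) {
    lo <- vals2[1:s]; hi <- vals2[(s + 1):5]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }, numeric(1))
  s_star <- which.min(sses2)
  expect_identical(km2$mask,
                   slicefat:::mask_int(matrix(vals2 > vals2[s_star], 1, 5)))
})

test_that("k-means SSE is monotone non-increasing across Lloyd iterations", {
  set.seed(12)
  vals <- runif(200)
  fit <- slicefat:::lloyd_1d(sort(unique(vals)), rep(1L, length(unique(vals))),
                             k = 2, tol = 0, max_iter = 25,
                             init = c(0.2, 0.21))
  expect_true(all(diff(fit$sse_trace) <= 1e-12))
})

test_that("an emptied k-means cluster is re-seeded, never dropped", {
  # both initial centers far above the data: one cluster captures all pixels
  fit <- suppressMessages(
    slicefat:::lloyd_1d(c(0.1, 0.2, 0.3, 0.9), rep(1L, 4), k = 2,
                        tol = 1e-8, max_iter = 50, init = c(5, 6)))
  expect_length(unique(fit$assign), 2)
  expect_message(
    slicefat:::lloyd_1d(c(0.1, 0.2, 0.3, 0.9), rep(1L, 4), k = 2,
                        tol = 1e-8, max_iter = 50, init = c(5, 6)),
    "re-seeded")
})

test_that("FCM memberships are a valid partition of unity", {
  set.seed(4)
  img <- matrix(runif(15 * 12), 15, 12)
  res <- fcm_segment(img)
  sums <- apply(res$memberships, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-12)
  expect_true(all(res$memberships >= 0 & res$memberships <= 1))
})

test_that("large fuzziness drives memberships towards the uniform 1/c limit", {
  # the limit is a property of the membership update itself: for fixed
  # distinct centers and non-coincident pixels, u -> 1/c as m grows
  vals <- c(0.05, 0.2, 0.45, 0.8, 0.95)
  u_m2 <- slicefat:::fcm_memberships(vals, c(0.3, 0.7), m = 2)
  u_big <- slicefat:::fcm_memberships(vals, c(0.3, 0.7), m = 200)
  expect_lt(max(abs(u_big - 0.5)), 0.01)
  expect_gt(max(abs(u_m2 - 0.5)), 0.2)  # far from uniform at moderate m
})

test_that("FCM updates match a hand-rolled implementation step for step", {
  vals <- c(0.05, 0.2, 0.45, 0.8, 0.95)
  init <- c(0.1, 0.9)
  m <- 2
  got <- slicefat:::fcm_1d(vals, rep(1L, 5), c = 2, m = m, tol = 0,
                           max_iter = 3, init = init)
  # independent implementation of the two alternating update equations
  centers <- init
  for (step in 1:3) {
    u <- matrix(0, 5, 2)
    for (i in 1:5) {
      d <- abs(vals[i] - centers)
      if (any(d == 0)) {
        u[i, ] <- as.numeric(d == 0) / sum(d == 0)
      } else {
        for (j in 1:2) u[i, j] <- 1 / sum((d[j] / d)^(2 / (m - 1)))
      }
    }
    for (j in 1:2) centers[j] <- sum(u[, j]^m * vals) / sum(u[, j]^m)
  }
  expect_equal(got$centers, centers, tolerance = 1e-12)
})

test_that("FCM objective is monotone non-increasing and pixels at centers get full membership", {
  set.seed(9)
  vals <- sort(unique(runif(150)))
  fit <- slicefat:::fcm_1d(vals, rep(1L, length(vals)), c = 2, m = 2,
                           tol = 0, max_iter = 20, init = c(0.3, 0.31))
  expect_true(all(diff(fit$obj_trace) <= 1e-10))

  # a value exactly at a center: membership 1 there, no NaN. Two values
  # seeded at themselves are a fixed point, so the convention is visible
  # after the update as well.
  fit2 <- slicefat:::fcm_1d(c(0.2, 0.8), rep(1L, 2), c = 2, m = 2,
                            tol = 1e-9, max_iter = 1, init = c(0.2, 0.8))
  expect_equal(fit2$u[1, 1], 1)
  expect_equal(fit2$u[2, 2], 1)
  expect_false(anyNA(fit2$u))
})

test_that("FCM agrees with an established independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(6)
  x <- runif(120)
  img <- matrix(x, 12, 10)
  res <- fcm_segment(img, segmentation_config("fcm", tol = 1e-9))
  ref <- e1071::cmeans(matrix(x, ncol = 1), centers = 2, m = 2,
                       iter.max = 500)
  expect_equal(sort(res$cluster_centers), sort(as.vector(ref$centers)),
               tolerance = 1e-3)
})

test_that("all three backends agree exactly on noiseless bimodal phantoms", {
  ph <- generate_slice_phantom(phantom_spec(noise_sd = 0, seed = 13L))
  pre <- enhance(ph$image)
  masks <- lapply(c("otsu", "kmeans", "fcm"), function(m)
    segment_slice(pre, segmentation_config(m))$mask)
  expect_identical(masks[[1]], masks[[2]])
  expect_identical(masks[[1]], masks[[3]])
  # adipose is the brighter class
  expect_true(mean(pre[masks[[1]] == 1L]) > mean(pre[masks[[1]] == 0L]))
})
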