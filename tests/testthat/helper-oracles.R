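# Independent brute-force oracles used across test files. These are kept
# deliberately naive (explicit loops, direct definitions) so they cannot
# share a bug with the vectorized implementations they check.

# Exhaustive Otsu: try every histogram cut-point, maximize between-class
# variance computed directly from the two groups of samples.
oracle_otsu <- function(x, bins = 256L) {
  edges <- seq(min(x), max(x), length.out = bins + 1L)
  best_sigma <- -Inf
  best_thr <- NA_real_
  n <- length(x)
  for (k in seq_len(bins - 1L)) {
    thr <- edges[k + 1L]
    # group samples by bin (bin index <= k vs > k), matching histogram
    # semantics rather than raw values
    bin <- pmin(findInterval(x, edges, rightmost.closed = TRUE), bins)
    lo <- bin <= k
    if (!any(lo) || all(lo)) next
    centers <- (edges[-1] + edges[-(bins + 1L)]) / 2
    w0 <- mean(lo)
    mu0 <- mean(centers[bin[lo]])
    mu1 <- mean(centers[bin[!lo]])
    sigma <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (sigma > best_sigma + 1e-15) {
      best_sigma <- sigma
      best_thr <- thr
    }
  }
  best_thr
}

# All-pairs Hausdorff distance.
oracle_hausdorff <- function(a, b) {
  pa <- which(a == 1L, arr.ind = TRUE)
  pb <- which(b == 1L, arr.ind = TRUE)
  h_dir <- function(p, q) {
    mx <- 0
    for (i in seq_len(nrow(p))) {
      dmin <- Inf
      for (j in seq_len(nrow(q))) {
        d <- sqrt((p[i, 1] - q[j, 1])^2 + (p[i, 2] - q[j, 2])^2)
        if (d < dmin) dmin <- d
      }
      if (dmin > mx) mx <- dmin
    }
    mx
  }
  max(h_dir(pa, pb), h_dir(pb, pa))
}

# Per-pixel accumulation of region areas and centroids.
oracle_region_props <- function(labeled) {
  labs <- sort(unique(labeled[labeled > 0]))
  out <- data.frame(label = labs, area = NA_real_, r = NA_real_, c = NA_real_)
  for (i in seq_along(labs)) {
    area <- 0; sr <- 0; sc <- 0
    for (rr in seq_len(nrow(labeled))) {
      for (cc in seq_len(ncol(labeled))) {
        if (labeled[rr, cc] == labs[i]) {
          area <- area + 1; sr <- sr + rr; sc <- sc + cc
        }
      }
    }
    out$area[i] <- area; out$r[i] <- sr / area; out$c[i] <- sc / area
  }
  out
}

# Flood-fill 8-connected labeling (BFS over an explicit stack).
oracle_label_8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nextlab <- 0L
  for (r0 in seq_len(nrow(mask))) {
    for (c0 in seq_len(ncol(mask))) {
      if (mask[r0, c0] == 1L && lab[r0, c0] == 0L) {
        nextlab <- nextlab + 1L
        stack <- list(c(r0, c0))
        lab[r0, c0] <- nextlab
        while (length(stack) > 0) {
          p <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          for (dr in -1:1) for (dc in -1:1) {
            r <- p[1] + dr; c <- p[2] + dc
            if (r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) &&
                mask[r, c] == 1L && lab[r, c] == 0L) {
              lab[r, c] <- nextlab
              stack[[length(stack) + 1L]] <- c(r, c)
            }
          }
        }
      }
    }
  }
  lab
}

# Direct windowed local mean/variance Wiener filter on interior pixels.
oracle_wiener_interior <- function(img, window, noise_var) {
  wr <- window[1]; wc <- window[2]
  br <- floor((wr - 1) / 2); ar <- wr - 1 - br
  bc <- floor((wc - 1) / 2); ac <- wc - 1 - bc
  out <- matrix(NA_real_, nrow(img), ncol(img))
  for (r in (1 + br):(nrow(img) - ar)) {
    for (c in (1 + bc):(ncol(img) - ac)) {
      win <- img[(r - br):(r + ar), (c - bc):(c + ac)]
      m <- mean(win)
      v <- mean(win^2) - m^2
      denom <- max(v, noise_var)
      g <- if (denom > 0) max(v - noise_var, 0) / denom else 0
      out[r, c] <- m + g * (img[r, c] - m)
    }
  }
  out
}

# Grayscale erosion/dilation by direct min/max over the selem support,
# replicate-padded; tophat/bottomhat as the standard compositions.
oracle_morph <- function(img, selem, op = c("tophat", "bottomhat")) {
  op <- match.arg(op)
  kr <- (nrow(selem) - 1) / 2; kc <- (ncol(selem) - 1) / 2
  filt <- function(x, f) {
    out <- matrix(NA_real_, nrow(x), ncol(x))
    for (r in seq_len(nrow(x))) {
      for (c in seq_len(ncol(x))) {
        vals <- c()
        for (i in -kr:kr) for (j in -kc:kc) {
          if (selem[i + kr + 1, j + kc + 1] > 0) {
            rr <- min(max(r + i, 1), nrow(x))
            cc <- min(max(c + j, 1), ncol(x))
            vals <- c(vals, x[rr, cc])
          }
        }
        out[r, c] <- f(vals)
      }
    }
    out
  }
  if (op == "tophat") {
    img - filt(filt(img, min), max)
  } else {
    filt(filt(img, max), min) - img
  }
}

# Random binary mask with at least one foreground pixel.
random_mask <- function(nr, nc, p = 0.3) {
  repeat {
    m <- matrix(rbinom(nr * nc, 1L, p), nr, nc)
    if (sum(m) > 0) return(m)
  }
}
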