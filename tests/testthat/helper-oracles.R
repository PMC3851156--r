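# Independent brute-force oracles. Each is written as plain loops over the
# definition so it shares no code path with the implementation it checks.

# Otsu: exhaustive search over all quantized levels, explicit class stats.
oracle_otsu <- function(image, n_levels = 256L) {
  rng <- range(image)
  width <- (rng[2] - rng[1]) / n_levels
  bin <- pmin(floor((as.vector(image) - rng[1]) / width), n_levels - 1L)
  levels <- rng[1] + (seq_len(n_levels) - 0.5) * width
  vals <- levels[bin + 1L]
  best_t <- NA_real_
  best_bcv <- -Inf
  for (t_idx in seq_len(n_levels - 1L)) {
    t <- levels[t_idx]
    lo <- vals[vals <= t]
    hi <- vals[vals > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(vals)
    w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best_bcv + 1e-12 * max(best_bcv, 1)) {
      best_bcv <- bcv
      best_t <- t
    }
  }
  best_t
}

# Moment ellipse: corrected coordinate covariance + eigen().
oracle_shape <- function(pixels) {
  n <- nrow(pixels)
  mu <- colMeans(pixels)
  cov <- matrix(0, 2, 2)
  for (i in seq_len(n)) {
    d <- pixels[i, ] - mu
    cov <- cov + d %*% t(d)
  }
  cov <- cov / n + diag(2) / 12
  e <- eigen(cov, symmetric = TRUE)
  v <- e$vectors[, 1] # eigenvector of the larger eigenvalue
  phi <- if (abs(e$values[1] - e$values[2]) <= 1e-12 * sum(e$values)) {
    0
  } else {
    (atan2(-v[2], v[1]) * 180 / pi) %% 180
  }
  list(L = 4 * sqrt(e$values[1]), omega = 4 * sqrt(e$values[2]),
       Ar = sqrt(e$values[1] / e$values[2]), phi = phi)
}

# Hough: dense accumulator built pixel by pixel, theta by theta.
oracle_hough <- function(pixels, image_diag, theta_step = 1, rho_step = 1) {
  thetas <- seq(0, 180 - theta_step, by = theta_step)
  n_rho <- max(1L, ceiling(2 * image_diag / rho_step))
  acc <- matrix(0L, length(thetas), n_rho)
  for (i in seq_len(nrow(pixels))) {
    for (j in seq_along(thetas)) {
      rad <- thetas[j] * pi / 180
      rho <- pixels[i, 2] * cos(rad) + pixels[i, 1] * sin(rad)
      b <- floor((rho + image_diag) / rho_step) + 1
      b <- min(max(b, 1), n_rho)
      acc[j, b] <- acc[j, b] + 1L
    }
  }
  best <- c(NA, NA)
  best_v <- -1L
  for (j in seq_along(thetas)) {  # smallest theta, then smallest rho wins
    for (b in seq_len(n_rho)) {
      if (acc[j, b] > best_v) {
        best_v <- acc[j, b]
        best <- c(j, b)
      }
    }
  }
  list(theta_deg = thetas[best[1]],
       rho = -image_diag + (best[2] - 0.5) * rho_step,
       votes = best_v)
}

# Connected components: BFS flood fill, first-encounter raster order.
oracle_label <- function(map, connectivity = 8L) {
  h <- nrow(map)
  w <- ncol(map)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8L) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  k <- 0L
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      if (map[r, c] && lab[r, c] == 0L) {
        k <- k + 1L
        queue <- list(c(r, c))
        lab[r, c] <- k
        while (length(queue) > 0) {
          p <- queue[[1]]
          queue <- queue[-1]
          for (i in seq_len(nrow(nb))) {
            rr <- p[1] + nb[i, 1]
            cc <- p[2] + nb[i, 2]
            if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
                map[rr, cc] && lab[rr, cc] == 0L) {
              lab[rr, cc] <- k
              queue <- c(queue, list(c(rr, cc)))
            }
          }
        }
      }
    }
  }
  lab
}

# random connected-ish pixel blob for moment tests (0-based coords)
random_blob <- function(n = 40, spread = 12) {
  base <- cbind(
    row = round(cumsum(stats::rnorm(n, 0, spread / 8))) + spread,
    col = round(cumsum(stats::rnorm(n, 0.8, spread / 8))) + spread
  )
  unique(pmax(base, 0))
}
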