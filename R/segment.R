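#' Otsu's optimal threshold
#'
#' Quantizes the image into `n_levels` uniform bins over its intensity range
#' and returns the level maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` of the classes `{<= t}` and `{> t}`. When several
#' levels tie, the smallest is returned.
#'
#' @param image Numeric matrix; must contain at least two distinct quantized
#'   levels.
#' @param n_levels Number of uniform histogram bins (default 256).
#'
#' @return The threshold intensity (center of the winning bin).
#' @export
#' @examples
#' img <- matrix(c(rep(0, 50), rep(1, 50)), 10, 10)
#' otsu_threshold(img) < 0.5
otsu_threshold <- function(image, n_levels = 256L) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort_param("`image` must be a numeric matrix")
  }
  if (!is.numeric(n_levels) || length(n_levels) != 1L || n_levels < 2L) {
    abort_param("`n_levels` must be a single integer >= 2")
  }
  n_levels <- as.integer(n_levels)
  rng <- range(image)
  if (!(rng[2] > rng[1])) {
    abort_degenerate("no threshold separates a constant image")
  }
  width <- (rng[2] - rng[1]) / n_levels
  bin <- pmin(floor((as.vector(image) - rng[1]) / width), n_levels - 1L)
  counts <- tabulate(bin + 1L, n_levels)
  if (sum(counts > 0L) < 2L) {
    abort_degenerate("no threshold separates a constant image")
  }
  n <- length(image)
  levels <- rng[1] + (seq_len(n_levels) - 0.5) * width
  w0 <- cumsum(counts) / n
  m0 <- cumsum(counts * levels) / n
  mu_t <- m0[n_levels]
  # between-class variance at each candidate threshold (class 1 = bins <= t)
  bcv <- (mu_t * w0 - m0)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- -Inf
  bcv[n_levels] <- -Inf # both classes must be non-empty
  levels[which.max(bcv)]
}

#' Binarize an image at a threshold
#'
#' Pixels strictly greater than `threshold` become candidate fiber pixels
#' (`TRUE`) of the binary map.
#'
#' @param image Numeric matrix.
#' @param threshold Finite intensity threshold.
#'
#' @return Logical matrix of the same shape.
#' @export
binarize <- function(image, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold)) {
    abort_param("`threshold` must be a single finite number")
  }
  image > threshold
}

#' Label connected components of a binary map
#'
#' Partitions the `TRUE` pixels into connected components (8-connectivity by
#' default, so diagonally touching pixels join -- thin diagonal fascicle
#' traces would fragment under 4-connectivity). Labels are assigned 1..K in
#' the order each component is first encountered in a row-major raster scan.
#'
#' @param map Logical matrix (the binary map).
#' @param connectivity 8 (default) or 4.
#'
#' @return A tibble with one row per component: `label`, `area`, and `pixels`,
#'   a list-column of two-column matrices of 0-based `(row, col)` pixel
#'   coordinates.
#' @export
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
#' label_regions(m)$area # one component of two pixels
label_regions <- function(map, connectivity = 8L) {
  if (!is.matrix(map) || !is.logical(map)) {
    abort_param("`map` must be a logical matrix")
  }
  if (!connectivity %in% c(4L, 8L)) {
    abort_param("`connectivity` must be 4 or 8")
  }
  idx <- which(map)
  if (length(idx) == 0L) {
    return(tibble::tibble(label = integer(), area = integer(),
                          pixels = list()))
  }
  h <- nrow(map)
  w <- ncol(map)
  row1 <- ((idx - 1L) %% h) + 1L
  col1 <- ((idx - 1L) %/% h) + 1L
  rank <- integer(h * w)
  rank[idx] <- seq_along(idx)

  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) {
    offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  }
  edges <- integer(0)
  for (off in offsets) {
    r2 <- row1 + off[1]
    c2 <- col1 + off[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nb <- (c2[ok] - 1L) * h + r2[ok]
    hit <- map[nb]
    if (any(hit)) {
      edges <- c(edges, rbind(rank[idx[ok]][hit], rank[nb][hit]))
    }
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership

  # relabel in first-encounter raster (row-major) order
  raster_key <- (row1 - 1L) * w + (col1 - 1L)
  first_key <- tapply(raster_key, memb, min)
  relabel <- integer(length(first_key))
  relabel[order(first_key)] <- seq_along(first_key)
  lab <- relabel[memb]

  ord <- order(lab)
  split_at <- split(ord, lab[ord])
  pixels <- lapply(split_at, function(i) {
    cbind(row = row1[i] - 1L, col = col1[i] - 1L)
  })
  pixels <- unname(pixels)
  tibble::tibble(
    label = seq_along(pixels),
    area = vapply(pixels, nrow, integer(1)),
    pixels = pixels
  )
}

# shape descriptors of one pixel set (0-based (row, col) matrix)
shape_of_pixels <- function(p) {
  n <- nrow(p)
  rbar <- mean(p[, 1])
  cbar <- mean(p[, 2])
  dr <- p[, 1] - rbar
  dc <- p[, 2] - cbar
  # normalized central second moments with the 1/12 unit-pixel correction
  a <- sum(dr * dr) / n + 1 / 12
  d <- sum(dc * dc) / n + 1 / 12
  b <- sum(dr * dc) / n
  tr <- a + d
  disc <- sqrt((a - d)^2 + 4 * b^2)
  emax <- (tr + disc) / 2
  emin <- (tr - disc) / 2
  if (disc <= 1e-12 * tr) {
    phi <- 0 # isotropic region: deterministic tie-break
  } else if (abs(b) <= 1e-14 * tr) {
    phi <- if (a >= d) 0 else 90
  } else {
    v_r <- b
    v_c <- emax - a
    phi <- fold180(atan2(-v_c, v_r) * 180 / pi)
  }
  L <- 4 * sqrt(emax)
  omega <- 4 * sqrt(emin)
  c(centroid_row = rbar, centroid_col = cbar, L = L, omega = omega,
    Ar = L / omega, phi_deg = phi)
}

#' Moment-equivalent ellipse descriptors of labelled regions
#'
#' Fills in, for every region, the centroid and the axes of the ellipse with
#' the same normalized second central moments as the pixel set: major-axis
#' length `L`, minor-axis length `omega`, aspect ratio `Ar = L / omega`, and
#' the major-axis orientation `phi_deg` in degrees from the downward image
#' vertical, in `[0, 180)`. The diagonal second moments carry the standard
#' 1/12 unit-square pixel correction, so a single pixel has a well-defined
#' ellipse (`L = omega = 4 * sqrt(1/12)`, `Ar = 1`).
#'
#' @param regions A tibble from [label_regions()] (or any tibble with a
#'   `pixels` list-column of 0-based coordinate matrices).
#'
#' @return The input tibble with columns `centroid_row`, `centroid_col`, `L`,
#'   `omega`, `Ar`, `phi_deg` appended.
#' @export
#' @examples
#' m <- matrix(FALSE, 5, 120); m[3, 11:110] <- TRUE
#' region_shape(label_regions(m))$Ar # 100: a 1 x 100 bar
region_shape <- function(regions) {
  if (!is.data.frame(regions) || !"pixels" %in% names(regions)) {
    abort_param("`regions` must be a tibble with a `pixels` list-column")
  }
  if (nrow(regions) == 0L) {
    shape_cols <- c("centroid_row", "centroid_col", "L", "omega", "Ar",
                    "phi_deg")
    for (col in shape_cols) regions[[col]] <- double()
    return(regions)
  }
  stats <- t(vapply(regions$pixels, shape_of_pixels, double(6)))
  dplyr::bind_cols(regions, tibble::as_tibble(stats))
}
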