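# Internal helpers: classed conditions, clamping, separable Gaussian
# convolution with reflective boundaries, angle folding.

abort_param <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "mfod_param_error")
}

abort_degenerate <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "mfod_degenerate_error")
}

abort_contract <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "mfod_contract_error")
}

abort_io <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "mfod_io_error")
}

abort_format <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "mfod_format_error")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

check_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort_param("`%s` must be a numeric matrix", arg)
  }
  if (nrow(image) < 1L || ncol(image) < 1L) {
    abort_param("`%s` must have at least one row and one column", arg)
  }
  if (anyNA(image) || any(!is.finite(image))) {
    abort_param("`%s` contains non-finite intensities", arg)
  }
  if (any(image < 0)) {
    abort_param("`%s` contains negative intensities", arg)
  }
  invisible(image)
}

# Sampled Gaussian and its first two derivatives, truncated at 4*sigma.
# All orders share the zeroth-order normalisation so that smoothing a
# constant gives the constant back and derivative kernels keep the
# analytic scaling of d^k/dx^k G_sigma.
gaussian_kernel <- function(sigma, order = 0L) {
  r <- ceiling(4 * sigma)
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  s <- sum(g)
  switch(as.character(order),
    "0" = g / s,
    "1" = (-x / sigma^2) * g / s, # odd: sums to zero exactly
    "2" = {
      k <- ((x^2 - sigma^2) / sigma^4) * g / s
      k - mean(k) # zero-sum so constant fields are annihilated exactly
    },
    abort_param("unsupported derivative order %s", order)
  )
}

# Correlation of `img` with a 1-D kernel along one margin (1 = down the
# rows, 2 = across the columns), mirror-reflected boundaries.
conv1_reflect <- function(img, kernel, margin) {
  k <- length(kernel)
  r <- (k - 1L) %/% 2L
  n <- if (margin == 1L) nrow(img) else ncol(img)
  if (r > 0L && n < r) {
    abort_degenerate(
      "image dimension %d is smaller than the kernel half-width %d", n, r
    )
  }
  idx <- if (r > 0L) c(r:1L, seq_len(n), n:(n - r + 1L)) else seq_len(n)
  out <- matrix(0, nrow(img), ncol(img))
  if (margin == 1L) {
    pad <- img[idx, , drop = FALSE]
    for (i in seq_len(k)) {
      out <- out + kernel[i] * pad[i:(i + nrow(img) - 1L), , drop = FALSE]
    }
  } else {
    pad <- img[, idx, drop = FALSE]
    for (i in seq_len(k)) {
      out <- out + kernel[i] * pad[, i:(i + ncol(img) - 1L), drop = FALSE]
    }
  }
  out
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel(sigma, 0L)
  conv1_reflect(conv1_reflect(img, k, 1L), k, 2L)
}

# Fold an angle in degrees into [0, 180).
fold180 <- function(a) {
  a <- a %% 180
  a[a >= 180 | a < 0] <- 0
  a
}

deg2rad <- function(a) a * pi / 180

empty_line_table <- function() {
  tibble::tibble(
    order = integer(), angle_deg = double(), method = character(),
    anchor_row = double(), anchor_col = double(),
    L = double(), omega = double(), Ar = double(),
    region_label = integer(), votes = integer()
  )
}
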