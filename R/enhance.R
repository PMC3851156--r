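#' Parameters for multiscale vessel-enhancement filtering
#'
#' Bundles the tunables of the Hessian-based vesselness filter used to enhance
#' fascicles and aponeuroses before binarization: the Gaussian scales at which
#' the Hessian is estimated, the blobness sensitivity `beta`, the structureness
#' sensitivity `c`, and the contrast polarity.
#'
#' @param scales Strictly increasing Gaussian standard deviations, in pixels,
#'   at which the scale-normalized Hessian is computed. Fascicle bands in
#'   clinical sonograms are a few pixels to roughly ten pixels wide, so the
#'   default covers sigma 1--5.
#' @param beta Sensitivity of the eigenvalue-ratio (blobness) term; larger
#'   values tolerate blobbier structures. Dimensionless, must be positive.
#' @param c Sensitivity of the structureness term, in units of the
#'   scale-normalized second-derivative magnitude. The default `"auto"` sets
#'   `c` per scale to half the maximum Frobenius norm of the scale-normalized
#'   Hessian over the image, which makes the filter contrast-adaptive.
#' @param polarity `"bright"` enhances bright structures on a dark background
#'   (hyperechoic fascia on muscle tissue); the only polarity supported.
#'
#' @return A list of class `vesselness_params`.
#' @seealso [mvef()]
#' @export
#' @examples
#' p <- vesselness_params(scales = c(1, 2, 4))
#' p$beta
vesselness_params <- function(scales = c(1, 2, 3, 4, 5), beta = 0.5,
                              c = "auto", polarity = "bright") {
  if (length(scales) < 1L || any(!is.finite(scales)) || any(scales <= 0)) {
    abort_param("`scales` must be a non-empty vector of positive values")
  }
  if (is.unsorted(scales, strictly = TRUE)) {
    abort_param("`scales` must be strictly increasing")
  }
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) {
    abort_param("`beta` must be a single positive number")
  }
  auto_c <- identical(c, "auto")
  if (!auto_c && (!is.numeric(c) || length(c) != 1L || c <= 0)) {
    abort_param("`c` must be \"auto\" or a single positive number")
  }
  polarity <- match.arg(polarity, "bright")
  structure(
    list(scales = as.double(scales), beta = as.double(beta),
         c = if (auto_c) "auto" else as.double(c), polarity = polarity),
    class = "vesselness_params"
  )
}

#' Eigenvalues of the scale-normalized image Hessian
#'
#' Estimates per-pixel second-order structure at one Gaussian scale: the image
#' is correlated with sampled Gaussian-derivative kernels (truncated at
#' 4*sigma, mirror-reflected boundaries) to form the Hessian
#' `[[I_rr, I_rc], [I_rc, I_cc]]`, each entry multiplied by `sigma^2` for
#' scale normalization, and the symmetric 2x2 eigenproblem is solved in closed
#' form at every pixel.
#'
#' @param image Numeric matrix of non-negative intensities (rows increase
#'   downward).
#' @param sigma Gaussian scale in pixels; must be positive.
#'
#' @return A list with matrices `lambda1` and `lambda2`, same shape as
#'   `image`, ordered so that `abs(lambda1) <= abs(lambda2)` pixelwise.
#' @export
#' @examples
#' ridge <- -outer((0:20 - 10)^2, rep(1, 31)) # bright ridge along columns
#' ev <- hessian_eigenvalues(ridge - min(ridge), sigma = 2)
#' ev$lambda2[11, 16] # close to -2 * sigma^2
hessian_eigenvalues <- function(image, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    abort_param("`sigma` must be a single positive number")
  }
  if (!is.matrix(image) || !is.numeric(image)) {
    abort_param("`image` must be a numeric matrix")
  }
  klen <- 2L * ceiling(4 * sigma) + 1L
  if (nrow(image) < klen || ncol(image) < klen) {
    abort_degenerate(
      "image (%d x %d) is smaller than the truncated Gaussian kernel; minimum size is %d x %d at sigma = %g",
      nrow(image), ncol(image), klen, klen, sigma
    )
  }
  k0 <- gaussian_kernel(sigma, 0L)
  k1 <- gaussian_kernel(sigma, 1L)
  k2 <- gaussian_kernel(sigma, 2L)
  s2 <- sigma^2
  h_rr <- s2 * conv1_reflect(conv1_reflect(image, k2, 1L), k0, 2L)
  h_cc <- s2 * conv1_reflect(conv1_reflect(image, k0, 1L), k2, 2L)
  h_rc <- s2 * conv1_reflect(conv1_reflect(image, k1, 1L), k1, 2L)

  tr <- h_rr + h_cc
  disc <- sqrt((h_rr - h_cc)^2 + 4 * h_rc^2)
  e1 <- (tr + disc) / 2
  e2 <- (tr - disc) / 2
  swap <- abs(e1) > abs(e2)
  lambda1 <- ifelse(swap, e2, e1)
  lambda2 <- ifelse(swap, e1, e2)
  dim(lambda1) <- dim(image)
  dim(lambda2) <- dim(image)
  list(lambda1 = lambda1, lambda2 = lambda2)
}

#' Vesselness response from a Hessian eigenvalue pair
#'
#' Maps ordered Hessian eigenvalues to a tubularity score in `[0, 1]`. For the
#' bright-on-dark polarity the response is 0 wherever `lambda2 >= 0`
#' (dark-on-bright curvature), and otherwise
#' `exp(-R_B^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))` with blobness
#' `R_B = lambda1 / lambda2` and structureness `S = sqrt(lambda1^2 +
#' lambda2^2)`.
#'
#' @param lambda1,lambda2 Eigenvalue scalars or equal-shaped arrays with
#'   `abs(lambda1) <= abs(lambda2)` elementwise.
#' @param params A [vesselness_params()] object with a numeric (resolved) `c`.
#'
#' @return Vesselness values in `[0, 1]`, same shape as the inputs.
#' @export
#' @examples
#' p <- vesselness_params(c = 1)
#' vesselness_response(0, -sqrt(2), p) # 1 - exp(-1)
vesselness_response <- function(lambda1, lambda2, params) {
  if (!inherits(params, "vesselness_params")) {
    abort_param("`params` must be created by vesselness_params()")
  }
  if (identical(params$c, "auto")) {
    abort_param("`params$c` must be resolved to a number before calling vesselness_response()")
  }
  if (length(lambda1) != length(lambda2)) {
    abort_param("`lambda1` and `lambda2` must have the same length")
  }
  tol <- 1e-9 * pmax(abs(lambda2), 1)
  if (any(abs(lambda1) > abs(lambda2) + tol)) {
    abort_contract("eigenvalue ordering violated: need abs(lambda1) <= abs(lambda2)")
  }
  rb2 <- ifelse(lambda2 == 0, 0, (lambda1 / ifelse(lambda2 == 0, 1, lambda2))^2)
  s2 <- lambda1^2 + lambda2^2
  v <- exp(-rb2 / (2 * params$beta^2)) * (1 - exp(-s2 / (2 * params$c^2)))
  v[lambda2 >= 0] <- 0
  v
}

#' Multiscale vessel-enhancement filter (MVEF)
#'
#' Enhances bright tubular structures (fascicles, aponeuroses) in a sonogram:
#' the vesselness response is computed at every scale in `params$scales` and
#' the per-pixel maximum over scales is returned. Input intensities are
#' min-max normalized to `[0, 1]` first so the automatic structureness
#' sensitivity is independent of the input intensity range.
#'
#' @inheritParams hessian_eigenvalues
#' @param params A [vesselness_params()] object.
#'
#' @return Enhanced image, same shape as `image`, values in `[0, 1]`. A
#'   constant input yields an all-zero output.
#' @export
#' @examples
#' img <- matrix(0.1, 40, 60)
#' img[19:22, 6:55] <- 0.9 # a horizontal band
#' enh <- mvef(img, vesselness_params(scales = c(1, 2, 3)))
#' range(enh)
mvef <- function(image, params = vesselness_params()) {
  check_image(image)
  rng <- range(image)
  if (rng[2] > rng[1]) {
    image <- (image - rng[1]) / (rng[2] - rng[1])
  } else {
    return(matrix(0, nrow(image), ncol(image)))
  }
  out <- matrix(0, nrow(image), ncol(image))
  for (sigma in params$scales) {
    ev <- hessian_eigenvalues(image, sigma)
    p_s <- params
    if (identical(params$c, "auto")) {
      smax <- sqrt(max(ev$lambda1^2 + ev$lambda2^2))
      if (smax == 0) next
      p_s$c <- smax / 2
    }
    out <- pmax(out, vesselness_response(ev$lambda1, ev$lambda2, p_s))
  }
  out
}
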