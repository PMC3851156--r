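#' Detector configuration
#'
#' All tunables of the iterative longest-region-first line detector. The
#' defaults are the settings used for adult sonograms of biceps, forearm and
#' gastrocnemius: aspect-ratio threshold `T1 = 5`, width threshold
#' `T2 = 30` px, last-to-first length ratio `T3 = 10%`, at most `N = 7` lines
#' per frame, and a 17-px removal width (8 px to each side of a detected
#' line). For reduced-architecture imaging (e.g. an aged subject where only
#' the triceps surae envelope is visible) `N = 4` is the documented preset.
#'
#' @param T1 Aspect-ratio threshold (dimensionless, > 0): a region is routed
#'   to the fast ellipse path only if `Ar > T1`.
#' @param T2 Width threshold in pixels (> 0): the ellipse path also requires
#'   `omega < T2`.
#' @param T3 Last-to-first length ratio in (0, 1]: detection stops once the
#'   current region's major-axis length drops below `T3 * L1`.
#' @param N Maximum number of lines per frame (>= 1).
#' @param removal_width Odd strip width in pixels removed around each detected
#'   line; half-width is `(removal_width - 1) / 2`.
#' @param theta_step,rho_step Hough accumulator resolutions in degrees and
#'   pixels.
#' @param connectivity Pixel connectivity for component labelling, 8 or 4.
#' @param drop_terminal_short_line If `TRUE`, the final line that triggers the
#'   `L^n < L^1 * T3` stop is dropped from the output instead of kept.
#' @param mvef A [vesselness_params()] object used by [run_pipeline()].
#' @param seed Integer seed echoed into run manifests (the detector itself is
#'   deterministic).
#'
#' @return A list of class `detector_config`.
#' @export
#' @examples
#' detector_config(N = 4) # reduced-architecture preset
detector_config <- function(T1 = 5, T2 = 30, T3 = 0.1, N = 7L,
                            removal_width = 17L, theta_step = 1,
                            rho_step = 1, connectivity = 8L,
                            drop_terminal_short_line = FALSE,
                            mvef = vesselness_params(), seed = 1L) {
  if (!is.numeric(T1) || T1 <= 0) abort_param("`T1` must be > 0")
  if (!is.numeric(T2) || T2 <= 0) abort_param("`T2` must be > 0")
  if (!is.numeric(T3) || T3 <= 0 || T3 > 1) {
    abort_param("`T3` must lie in (0, 1]")
  }
  if (!is.numeric(N) || N < 1L) abort_param("`N` must be >= 1")
  if (!is.numeric(removal_width) || removal_width < 1L ||
      removal_width %% 2 != 1) {
    abort_param("`removal_width` must be odd and >= 1")
  }
  if (!is.numeric(theta_step) || theta_step <= 0) {
    abort_param("`theta_step` must be > 0")
  }
  if (!is.numeric(rho_step) || rho_step <= 0) {
    abort_param("`rho_step` must be > 0")
  }
  if (!connectivity %in% c(4L, 8L)) {
    abort_param("`connectivity` must be 4 or 8")
  }
  if (!inherits(mvef, "vesselness_params")) {
    abort_param("`mvef` must be created by vesselness_params()")
  }
  structure(
    list(T1 = as.double(T1), T2 = as.double(T2), T3 = as.double(T3),
         N = as.integer(N), removal_width = as.integer(removal_width),
         theta_step = as.double(theta_step), rho_step = as.double(rho_step),
         connectivity = as.integer(connectivity),
         drop_terminal_short_line = isTRUE(drop_terminal_short_line),
         mvef = mvef, seed = as.integer(seed)),
    class = "detector_config"
  )
}

#' Classify a region by its shape measures
#'
#' A region is a single-fiber trace (ellipse path) iff it is long and thin:
#' `Ar > T1` and `omega < T2`, both strict. Everything else -- branched merged
#' fibers, wide blobs -- is routed to the Hough path.
#'
#' @param Ar Aspect ratio(s), >= 1.
#' @param omega Minor-axis width(s) in pixels, > 0.
#' @param config A [detector_config()].
#'
#' @return `"ellipse"` or `"hough"` (vectorized).
#' @export
#' @examples
#' classify_region(6, 20, detector_config()) # "ellipse"
#' classify_region(5, 20, detector_config()) # boundary is strict: "hough"
classify_region <- function(Ar, omega, config = detector_config()) {
  ifelse(Ar > config$T1 & omega < config$T2, "ellipse", "hough")
}

#' Hough line detection on one region's pixels
#'
#' Standard `(rho, theta)` voting restricted to a single region: only the
#' given pixels vote, never the whole map. The line normal form is
#' `rho = col * cos(theta) + row * sin(theta)` with `theta` sampled on
#' `[0, 180)` degrees at `theta_step` and `rho` binned on
#' `[-image_diag, image_diag]` at `rho_step`. The accumulator's global
#' maximum wins; ties are broken by smallest `theta`, then smallest `rho`.
#'
#' @param pixels Two-column matrix of 0-based `(row, col)` coordinates.
#' @param image_diag Diagonal length of the source image in pixels (bounds
#'   `abs(rho)`); defaults to the diagonal of the pixel bounding box.
#' @param theta_step,rho_step Accumulator resolutions (degrees, pixels).
#'
#' @return A list with `theta_deg`, `rho` (winning bin center) and integer
#'   `votes`.
#' @export
#' @examples
#' px <- cbind(row = rep(10, 50), col = 0:49)
#' hough_line(px, image_diag = 60) # theta 90, rho ~ 10, 50 votes
hough_line <- function(pixels, image_diag = NULL, theta_step = 1,
                       rho_step = 1) {
  if (is.null(dim(pixels)) || ncol(pixels) != 2L || nrow(pixels) == 0L) {
    abort_contract("`pixels` must be a non-empty two-column (row, col) matrix")
  }
  if (is.null(image_diag)) {
    image_diag <- sqrt(max(pixels[, 1])^2 + max(pixels[, 2])^2) + 1
  }
  thetas <- seq(0, 180 - theta_step, by = theta_step)
  n_rho <- max(1L, ceiling(2 * image_diag / rho_step))
  rows <- pixels[, 1]
  cols <- pixels[, 2]
  best <- list(theta_deg = NA_real_, rho = NA_real_, votes = -1L)
  for (th in thetas) {
    rad <- deg2rad(th)
    rho <- cols * cos(rad) + rows * sin(rad)
    bin <- clamp(floor((rho + image_diag) / rho_step) + 1, 1, n_rho)
    acc <- tabulate(bin, n_rho)
    v <- max(acc)
    if (v > best$votes) {
      b <- which.max(acc) # first maximum = smallest rho
      best <- list(theta_deg = th,
                   rho = -image_diag + (b - 0.5) * rho_step,
                   votes = as.integer(v))
    }
  }
  best
}

#' MFO angle of a Hough-detected line
#'
#' Converts the winning normal angle `theta` into the reported MFO convention:
#' the angle between the line and the downward image vertical (the vector
#' from the up-left to the bottom-left image corner), folded into `[0, 180)`.
#' The line direction is perpendicular to its normal,
#' `(d_col, d_row) = (-sin(theta), cos(theta))`, and the angle of that
#' direction from `(0, +1)` is computed with `atan2` and folded. Under this
#' parameterization the map works out to the identity on `[0, 180)`.
#'
#' @param theta_deg Hough normal angle in `[0, 180)`.
#' @return The MFO angle in degrees, `[0, 180)`.
#' @export
line_angle_from_theta <- function(theta_deg) {
  if (any(!is.finite(theta_deg)) || any(theta_deg < 0) ||
      any(theta_deg >= 180)) {
    abort_contract("`theta_deg` must lie in [0, 180)")
  }
  rad <- deg2rad(theta_deg)
  d_col <- -sin(rad)
  d_row <- cos(rad)
  # signed angle of (d_row, d_col) from the downward vertical, folded mod 180
  fold180(-atan2(d_col, d_row) * 180 / pi)
}

#' MFO angle of an ellipse-path region
#'
#' The region orientation `phi` from [region_shape()] is already measured from
#' the downward image vertical, so this is the identity; it exists as an
#' explicit seam so an alternate orientation convention could be adapted in
#' one place.
#'
#' @param phi Region orientation in degrees, `[0, 180)`.
#' @return The MFO angle in degrees.
#' @export
ellipse_angle_to_mfo <- function(phi) {
  phi
}

#' Remove pixels near a detected line
#'
#' Clears every `TRUE` pixel whose perpendicular distance to the infinite line
#' through the detected line's anchor is at most `(removal_width - 1) / 2`,
#' across the whole map. Working map-wide (not just within the source region)
#' suppresses noise along the line and consumes collinear fragments of the
#' same broken fiber, so their angle is not measured twice.
#'
#' @param map Logical matrix.
#' @param line A one-row line table (or list) with `angle_deg`, `anchor_row`,
#'   `anchor_col`.
#' @param removal_width Odd strip width in pixels.
#'
#' @return A new logical matrix; the input is not modified.
#' @export
remove_line_pixels <- function(map, line, removal_width = 17L) {
  if (!is.matrix(map) || !is.logical(map)) {
    abort_param("`map` must be a logical matrix")
  }
  if (!is.numeric(removal_width) || removal_width < 1L ||
      removal_width %% 2 != 1) {
    abort_param("`removal_width` must be odd and >= 1")
  }
  idx <- which(map)
  if (length(idx) == 0L) return(map)
  h <- nrow(map)
  r <- ((idx - 1L) %% h)      # 0-based
  c <- ((idx - 1L) %/% h)
  a <- deg2rad(line$angle_deg)
  # unit normal to direction (d_row, d_col) = (cos a, -sin a)
  dist <- abs((r - line$anchor_row) * sin(a) + (c - line$anchor_col) * cos(a))
  out <- map
  out[idx[dist <= (removal_width - 1) / 2 + 1e-9]] <- FALSE
  out
}

#' Iterative longest-region-first line detection
#'
#' Runs the detection loop on a binary map: (1) label the current map and
#' take the region with the largest major-axis length `L` (ties: larger area,
#' then smaller label); (2) classify it by shape -- long-and-thin regions
#' yield their angle directly from the moment-equivalent ellipse, others from
#' a Hough transform over that region's pixels only; (3) record the line;
#' (4) remove pixels within the removal strip of the detected line map-wide;
#' (5) stop when `N` lines have been found or the current length has dropped
#' below `T3 * L1`, else repeat. The line that triggers the length-ratio stop
#' is kept in the output by default (see
#' `detector_config(drop_terminal_short_line = )`).
#'
#' @param map Logical matrix (binary candidate-fiber map).
#' @param config A [detector_config()].
#'
#' @return A tibble with one row per detected line: `order`, `angle_deg`,
#'   `method` (`"ellipse"` or `"hough"`), `anchor_row`, `anchor_col`, `L`,
#'   `omega`, `Ar`, `region_label`, `votes` (`NA` for ellipse-path lines).
#'   Empty maps give an empty table. Deterministic for fixed input and
#'   config.
#' @export
detect_lines <- function(map, config = detector_config()) {
  if (!is.matrix(map) || !is.logical(map)) {
    abort_param("`map` must be a logical matrix")
  }
  diag_len <- sqrt(nrow(map)^2 + ncol(map)^2)
  lines <- list()
  L1 <- NA_real_
  n <- 0L
  current <- map
  repeat {
    regions <- region_shape(label_regions(current, config$connectivity))
    if (nrow(regions) == 0L) break
    pick <- regions[order(-regions$L, -regions$area, regions$label)[1], ]
    n <- n + 1L
    if (n == 1L) L1 <- pick$L
    method <- classify_region(pick$Ar, pick$omega, config)
    if (method == "ellipse") {
      angle <- ellipse_angle_to_mfo(pick$phi_deg)
      anchor_row <- pick$centroid_row
      anchor_col <- pick$centroid_col
      votes <- NA_integer_
    } else {
      hl <- hough_line(pick$pixels[[1]], image_diag = diag_len,
                       theta_step = config$theta_step,
                       rho_step = config$rho_step)
      angle <- line_angle_from_theta(hl$theta_deg)
      # anchor: projection of the region centroid onto the detected line
      rad <- deg2rad(hl$theta_deg)
      s <- hl$rho - (pick$centroid_row * sin(rad) +
                       pick$centroid_col * cos(rad))
      anchor_row <- pick$centroid_row + s * sin(rad)
      anchor_col <- pick$centroid_col + s * cos(rad)
      votes <- hl$votes
    }
    lines[[n]] <- tibble::tibble(
      order = n, angle_deg = angle, method = method,
      anchor_row = anchor_row, anchor_col = anchor_col,
      L = pick$L, omega = pick$omega, Ar = pick$Ar,
      region_label = pick$label, votes = votes
    )
    terminal_short <- pick$L < L1 * config$T3
    if (terminal_short && config$drop_terminal_short_line) {
      lines[[n]] <- NULL
    }
    if (n >= config$N || terminal_short) break
    current <- remove_line_pixels(
      current, lines[[n]], config$removal_width
    )
  }
  if (length(lines) == 0L) return(empty_line_table())
  dplyr::bind_rows(lines)
}
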