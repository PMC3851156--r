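#' Specify one synthetic fiber band
#'
#' Describes a bright, straight band of known orientation for the synthetic
#' sonogram generator: the stand-in for a fascicle or aponeurosis trace.
#'
#' @param angle_deg Ground-truth MFO in degrees from the downward image
#'   vertical, in `[0, 180)`.
#' @param center `(row, col)` of the band center, 0-based pixels.
#' @param length,width Band dimensions in pixels; `length >= width >= 1`.
#' @param intensity Peak brightness in `(0, 1]`.
#' @param broken Optional list of `c(start, end)` gap intervals along the band
#'   axis (axis coordinate runs from `-length/2` to `length/2`), used to
#'   synthesize broken-fiber fragments.
#'
#' @return A list of class `bar_spec`.
#' @export
#' @examples
#' bar_spec(angle_deg = 30, center = c(60, 80), length = 90, width = 5)
bar_spec <- function(angle_deg, center, length, width, intensity = 0.85,
                     broken = NULL) {
  if (!is.numeric(angle_deg) || angle_deg < 0 || angle_deg >= 180) {
    abort_param("`angle_deg` must lie in [0, 180)")
  }
  if (length(center) != 2L || any(!is.finite(center))) {
    abort_param("`center` must be a (row, col) pair")
  }
  if (!is.numeric(length) || !is.numeric(width) || width < 1 ||
      length < width) {
    abort_param("need length >= width >= 1")
  }
  if (!is.numeric(intensity) || intensity <= 0 || intensity > 1) {
    abort_param("`intensity` must lie in (0, 1]")
  }
  if (!is.null(broken)) {
    if (!is.list(broken) ||
        !all(vapply(broken, function(g) length(g) == 2L && g[1] < g[2],
                    logical(1)))) {
      abort_param("`broken` must be a list of c(start, end) intervals")
    }
  }
  structure(
    list(angle_deg = as.double(angle_deg), center = as.double(center),
         length = as.double(length), width = as.double(width),
         intensity = as.double(intensity), broken = broken),
    class = "bar_spec"
  )
}

#' Specify a synthetic sonogram scene
#'
#' A frame of given shape holding one or more bright bands over a darker
#' background, degraded the way B-mode frames are: Gaussian blur (the finite
#' beam/point-spread width) followed by multiplicative unit-mean gamma
#' speckle. Identical specs (including `seed`) render identical frames.
#'
#' @param shape `(height, width)` in pixels.
#' @param bars List of [bar_spec()] objects.
#' @param background_level Mean background intensity in `[0, 1)`.
#' @param speckle Gamma shape parameter of the unit-mean multiplicative
#'   speckle; smaller is noisier. `Inf` disables the noise. The default 4 is
#'   a strongly speckled but readable clinical appearance.
#' @param blur_sigma Gaussian blur standard deviation in pixels.
#' @param seed Integer RNG seed (the only source of randomness).
#'
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(160, 220), bars = list(),
                       background_level = 0.08, speckle = 4,
                       blur_sigma = 1, seed = 1L) {
  if (length(shape) != 2L || any(shape < 1)) {
    abort_param("`shape` must be (height, width), both >= 1")
  }
  if (!all(vapply(bars, inherits, logical(1), "bar_spec"))) {
    abort_param("`bars` must be a list of bar_spec() objects")
  }
  if (background_level < 0 || background_level >= 1) {
    abort_param("`background_level` must lie in [0, 1)")
  }
  if (!(is.numeric(speckle) && (speckle > 0))) {
    abort_param("`speckle` must be a positive shape parameter (Inf = none)")
  }
  if (blur_sigma < 0) abort_param("`blur_sigma` must be >= 0")
  structure(
    list(shape = as.integer(shape), bars = bars,
         background_level = as.double(background_level),
         speckle = as.double(speckle), blur_sigma = as.double(blur_sigma),
         seed = as.integer(seed)),
    class = "scene_spec"
  )
}

# anti-aliased coverage field of one bar on an h x w canvas (0-based coords)
bar_field <- function(bar, h, w) {
  a <- deg2rad(bar$angle_deg)
  d <- c(cos(a), -sin(a))   # along-axis direction (row, col)
  nv <- c(sin(a), cos(a))   # unit normal
  corners_t <- c(-1, 1) * bar$length / 2
  corners_u <- c(-1, 1) * bar$width / 2
  for (t in corners_t) {
    for (u in corners_u) {
      p <- bar$center + t * d + u * nv
      if (p[1] < 0 || p[1] > h - 1 || p[2] < 0 || p[2] > w - 1) {
        abort_param(
          "bar at angle %g extends outside the %d x %d frame", bar$angle_deg,
          h, w
        )
      }
    }
  }
  rr <- matrix(0:(h - 1), h, w) - bar$center[1]
  cc <- matrix(0:(w - 1), h, w, byrow = TRUE) - bar$center[2]
  t_ax <- rr * d[1] + cc * d[2]
  u_ax <- rr * nv[1] + cc * nv[2]
  cov <- clamp(bar$width / 2 - abs(u_ax) + 0.5, 0, 1) *
    clamp(bar$length / 2 - abs(t_ax) + 0.5, 0, 1)
  for (g in bar$broken %||% list()) {
    cov[t_ax >= g[1] & t_ax <= g[2]] <- 0
  }
  bar$intensity * cov
}

#' Render a synthetic sonogram frame with exact ground truth
#'
#' Draws each band as an anti-aliased rotated rectangle (soft 1-px edges, so
#' the moment orientation of the noiseless band matches its nominal angle to
#' sub-degree accuracy), composites with the background level, blurs, applies
#' per-pixel multiplicative gamma speckle with the spec's seed, and clips to
#' `[0, 1]`.
#'
#' @param spec A [scene_spec()].
#' @return A list with `image` (numeric matrix) and `truth`, a tibble of
#'   per-bar ground truth (`bar`, `angle_deg`, `length`, `width`,
#'   `centroid_row`, `centroid_col`).
#' @export
#' @examples
#' sc <- render_scene(scene_spec(bars = list(
#'   bar_spec(30, c(80, 110), 100, 5))))
#' sc$truth
render_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) {
    abort_param("`spec` must be created by scene_spec()")
  }
  h <- spec$shape[1]
  w <- spec$shape[2]
  field <- matrix(0, h, w)
  for (bar in spec$bars) {
    field <- pmax(field, bar_field(bar, h, w))
  }
  img <- clamp(spec$background_level + field, 0, 1)
  if (spec$blur_sigma > 0) img <- gaussian_blur(img, spec$blur_sigma)
  if (is.finite(spec$speckle)) {
    s <- withr::with_seed(
      spec$seed,
      matrix(stats::rgamma(h * w, shape = spec$speckle, rate = spec$speckle),
             h, w)
    )
    img <- img * s
  }
  img <- clamp(img, 0, 1)
  truth <- tibble::tibble(
    bar = seq_along(spec$bars),
    angle_deg = vapply(spec$bars, `[[`, double(1), "angle_deg"),
    length = vapply(spec$bars, `[[`, double(1), "length"),
    width = vapply(spec$bars, `[[`, double(1), "width"),
    centroid_row = vapply(spec$bars, function(b) b$center[1], double(1)),
    centroid_col = vapply(spec$bars, function(b) b$center[2], double(1))
  )
  list(image = img, truth = truth)
}

#' Render two crossing bands forming one branched component
#'
#' Builds the branched-region pattern (two merged fiber traces): as
#' [render_scene()], but requires exactly two bars sharing enough overlap
#' that the noiseless binarization is a single connected component (checked
#' internally).
#'
#' @param spec A [scene_spec()] with exactly two intersecting bars.
#' @return As [render_scene()].
#' @export
render_crossing <- function(spec) {
  if (!inherits(spec, "scene_spec") || length(spec$bars) != 2L) {
    abort_param("`spec` must be a scene_spec() with exactly two bars")
  }
  h <- spec$shape[1]
  w <- spec$shape[2]
  f1 <- bar_field(spec$bars[[1]], h, w)
  f2 <- bar_field(spec$bars[[2]], h, w)
  cut <- 0.5 * min(vapply(spec$bars, `[[`, double(1), "intensity"))
  mask <- pmax(f1, f2) > cut
  if (!any(f1 > cut & f2 > cut)) {
    abort_param("the two bars do not overlap")
  }
  if (nrow(label_regions(mask)) != 1L) {
    abort_param("the two bars do not form a single connected component")
  }
  render_scene(spec)
}

#' Render a frame sequence with a per-frame angle trajectory
#'
#' Emulates a cine loop of a contracting muscle: all frames share the base
#' geometry, but every bar's angle is offset per frame (e.g. a sinusoid
#' mimicking a cyclic torque waveform). Per-frame speckle seeds are derived
#' deterministically from the base seed.
#'
#' @param base A [scene_spec()].
#' @param n_frames Number of frames (>= 1).
#' @param angle_trajectory Numeric vector of per-frame angle offsets in
#'   degrees, length `n_frames`.
#'
#' @return A list with `frames` (list of matrices) and `truth` (per-frame
#'   ground-truth tibble with a leading `frame` column).
#' @export
#' @examples
#' seq <- render_sequence(
#'   scene_spec(bars = list(bar_spec(35, c(80, 110), 100, 5))),
#'   n_frames = 3, angle_trajectory = c(0, 2, 4))
#' seq$truth$angle_deg
render_sequence <- function(base, n_frames, angle_trajectory) {
  if (!inherits(base, "scene_spec")) {
    abort_param("`base` must be created by scene_spec()")
  }
  if (!is.numeric(n_frames) || n_frames < 1L) {
    abort_param("`n_frames` must be >= 1")
  }
  n_frames <- as.integer(n_frames)
  if (length(angle_trajectory) != n_frames) {
    abort_param("`angle_trajectory` must have one offset per frame")
  }
  frames <- vector("list", n_frames)
  truths <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    sp <- base
    sp$bars <- lapply(base$bars, function(b) {
      b$angle_deg <- (b$angle_deg + angle_trajectory[f]) %% 180
      b
    })
    sp$seed <- as.integer((base$seed + f - 1L) %% .Machine$integer.max)
    sc <- render_scene(sp)
    frames[[f]] <- sc$image
    truths[[f]] <- dplyr::mutate(sc$truth, frame = f, .before = 1)
  }
  list(frames = frames, truth = purrr::list_rbind(truths))
}
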