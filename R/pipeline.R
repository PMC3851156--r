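#' Run the full MFO estimation pipeline on one frame
#'
#' Enhancement, binarization, and iterative line detection in one call:
#' `enhanced = mvef(image)`, `map = binarize(enhanced,
#' otsu_threshold(enhanced))`, `lines = detect_lines(map, config)`. A frame
#' whose enhanced image is constant (e.g. a blank frame) produces a warning
#' and an empty line table rather than an error, so sequence processing
#' survives dropped frames.
#'
#' @param image Numeric matrix of non-negative intensities.
#' @param config A [detector_config()].
#'
#' @return An object of class `mfo_frame`: a list with `image`, `enhanced`,
#'   `map`, `threshold`, `lines` (tibble) and the `config` echo.
#' @seealso [tidy.mfo_frame()], [glance.mfo_frame()], [autoplot.mfo_frame()]
#' @export
#' @examples
#' scene <- render_scene(scene_spec(bars = list(
#'   bar_spec(angle_deg = 25, center = c(80, 110), length = 120, width = 5))))
#' res <- run_pipeline(scene$image)
#' res$lines$angle_deg
run_pipeline <- function(image, config = detector_config()) {
  check_image(image)
  enhanced <- mvef(image, config$mvef)
  rng <- range(enhanced)
  if (!(rng[2] > rng[1])) {
    rlang::warn("enhanced image is constant; no lines detected",
                class = "mfod_blank_frame")
    map <- matrix(FALSE, nrow(image), ncol(image))
    threshold <- NA_real_
    lines <- empty_line_table()
  } else {
    threshold <- otsu_threshold(enhanced)
    map <- binarize(enhanced, threshold)
    lines <- detect_lines(map, config)
  }
  structure(
    list(image = image, enhanced = enhanced, map = map,
         threshold = threshold, lines = lines, config = config),
    class = "mfo_frame"
  )
}

#' Run the pipeline over a frame sequence
#'
#' @param frames List of numeric matrices (e.g. from [read_frames()] or
#'   [render_sequence()]).
#' @param config A [detector_config()].
#'
#' @return An object of class `mfo_run`: a list of `mfo_frame` results.
#' @export
process_frames <- function(frames, config = detector_config()) {
  if (!is.list(frames)) abort_param("`frames` must be a list of matrices")
  structure(purrr::map(frames, run_pipeline, config = config),
            class = "mfo_run")
}

#' @export
print.mfo_frame <- function(x, ...) {
  cat(sprintf("<mfo_frame> %d x %d px, threshold %.4g, %d line(s) (%d via Hough)\n",
              nrow(x$image), ncol(x$image), x$threshold, nrow(x$lines),
              sum(x$lines$method == "hough")))
  print(x$lines)
  invisible(x)
}

#' @export
print.mfo_run <- function(x, ...) {
  cat(sprintf("<mfo_run> %d frame(s), %d line(s) total\n",
              length(x), sum(purrr::map_int(x, ~ nrow(.x$lines)))))
  invisible(x)
}

#' Tidy the detected lines of a frame
#'
#' @param x An `mfo_frame`.
#' @param ... Unused.
#' @return The line tibble (one row per detected line).
#' @export
tidy.mfo_frame <- function(x, ...) {
  x$lines
}

#' Tidy the detected lines of a run
#'
#' @param x An `mfo_run`.
#' @param ... Unused.
#' @return A tibble of all frames' lines with a leading `frame` index column.
#' @export
tidy.mfo_run <- function(x, ...) {
  if (length(x) == 0L) {
    return(dplyr::bind_cols(tibble::tibble(frame = integer()),
                            empty_line_table()))
  }
  purrr::list_rbind(purrr::imap(
    x, function(fr, i) dplyr::mutate(fr$lines, frame = i, .before = 1)
  ))
}

#' One-row frame summary
#'
#' @param x An `mfo_frame`.
#' @param ... Unused.
#' @return A tibble with the Otsu threshold, candidate-pixel and region
#'   counts, and how many lines used each path. The Hough-path count is the
#'   quantity the method's efficiency argument rests on, so it is surfaced
#'   here and in logs.
#' @export
glance.mfo_frame <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold,
    n_candidate_px = sum(x$map),
    n_regions = nrow(label_regions(x$map, x$config$connectivity)),
    n_lines = nrow(x$lines),
    n_ellipse = sum(x$lines$method == "ellipse"),
    n_hough = sum(x$lines$method == "hough")
  )
}

#' Per-frame run summary
#'
#' @param x An `mfo_run`.
#' @param ... Unused.
#' @return One [glance.mfo_frame()] row per frame with a `frame` column.
#' @export
glance.mfo_run <- function(x, ...) {
  purrr::list_rbind(purrr::imap(
    x, function(fr, i) dplyr::mutate(glance(fr), frame = i, .before = 1)
  ))
}

#' Plot detected lines over a frame
#'
#' Grayscale frame with the detected lines drawn through their anchors,
#' colour-coded by estimation path: yellow for ellipse-moment lines, red for
#' Hough-detected lines (the field's customary tagging).
#'
#' @param object An `mfo_frame`.
#' @param show Which image to use as the backdrop: the original frame, the
#'   enhanced image, or the binary map.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mfo_frame <- function(object, show = c("image", "enhanced", "map"),
                               ...) {
  show <- match.arg(show)
  img <- object[[show]]
  if (is.logical(img)) img <- img * 1
  h <- nrow(img)
  w <- ncol(img)
  px <- tibble::tibble(
    col = rep(seq_len(w) - 1L, each = h),
    row = rep(seq_len(h) - 1L, times = w),
    value = as.vector(img)
  )
  segs <- object$lines
  if (nrow(segs) > 0) {
    rad <- deg2rad(segs$angle_deg)
    half <- segs$L / 2
    segs <- dplyr::mutate(
      segs,
      row0 = .data$anchor_row - half * cos(rad),
      col0 = .data$anchor_col + half * sin(rad),
      row1 = .data$anchor_row + half * cos(rad),
      col1 = .data$anchor_col - half * sin(rad)
    )
  }
  p <- ggplot2::ggplot(px, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL)
  if (nrow(segs) > 0) {
    p <- p + ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$col0, y = .data$row0, xend = .data$col1,
                   yend = .data$row1, colour = .data$method),
      linewidth = 0.8
    ) +
      ggplot2::scale_colour_manual(
        values = c(ellipse = "yellow", hough = "red"), name = "path"
      )
  }
  p
}
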