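#' Read an image file, multi-page TIFF, or frame directory
#'
#' Reads grayscale frames for analysis. A directory is treated as a sequence
#' in lexicographic filename order; a multi-page TIFF yields one frame per
#' page. Colour inputs are converted to luminance (Rec. 709 weights) and all
#' intensities are scaled into `[0, 1]`. Supported formats: PNG, TIFF
#' (including multi-page), and uncompressed 8/24-bit BMP.
#'
#' @param path Path to an image file or a directory of numbered frames.
#' @return A list of numeric matrices, all the same size.
#' @export
read_frames <- function(path) {
  if (length(path) != 1L || !is.character(path)) {
    abort_param("`path` must be a single path")
  }
  if (!file.exists(path)) abort_io("cannot read '%s': no such file", path)
  frames <- if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff|bmp)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) {
      abort_io("directory '%s' contains no readable frames", path)
    }
    unlist(lapply(files, read_one_file), recursive = FALSE)
  } else {
    read_one_file(path)
  }
  dims <- vapply(frames, dim, integer(2))
  if (ncol(dims) > 1L && any(dims != dims[, 1])) {
    abort_format("mixed frame sizes in sequence '%s'", path)
  }
  frames
}

read_one_file <- function(file) {
  ext <- tolower(tools::file_ext(file))
  raw <- tryCatch(
    switch(ext,
      png = list(png::readPNG(file)),
      tif = ,
      tiff = tiff::readTIFF(file, all = TRUE),
      bmp = list(read_bmp(file)),
      abort_format("unsupported image format '.%s' for '%s'", ext, file)
    ),
    error = function(e) {
      if (inherits(e, "mfod_format_error")) rlang::cnd_signal(e)
      abort_io("cannot read '%s': %s", file, conditionMessage(e))
    }
  )
  lapply(raw, to_gray)
}

to_gray <- function(x) {
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] >= 3L) {
      x <- 0.2126 * x[, , 1] + 0.7152 * x[, , 2] + 0.0722 * x[, , 3]
    } else {
      x <- x[, , 1]
    }
  }
  clamp(matrix(as.double(x), nrow(x), ncol(x)), 0, 1)
}

# Minimal reader for uncompressed 8-bit (palette) and 24-bit BMP files.
read_bmp <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  if (!identical(as.integer(magic), c(0x42L, 0x4DL))) {
    abort_format("'%s' is not a BMP file", file)
  }
  readBin(con, "raw", 8L) # file size + reserved
  data_offset <- readBin(con, "integer", 1L, 4L, endian = "little")
  header_size <- readBin(con, "integer", 1L, 4L, endian = "little")
  if (header_size < 40L) abort_format("unsupported BMP header in '%s'", file)
  w <- readBin(con, "integer", 1L, 4L, endian = "little")
  h <- readBin(con, "integer", 1L, 4L, endian = "little")
  readBin(con, "integer", 1L, 2L, endian = "little") # planes
  bpp <- readBin(con, "integer", 1L, 2L, endian = "little")
  compression <- readBin(con, "integer", 1L, 4L, endian = "little")
  if (compression != 0L || !bpp %in% c(8L, 24L)) {
    abort_format("only uncompressed 8/24-bit BMP is supported ('%s')", file)
  }
  top_down <- h < 0
  h <- abs(h)
  palette <- NULL
  if (bpp == 8L) {
    seek(con, 14L + header_size)
    n_colors <- (data_offset - 14L - header_size) %/% 4L
    pal <- matrix(as.integer(readBin(con, "raw", n_colors * 4L)), nrow = 4L)
    palette <- (0.0722 * pal[1, ] + 0.7152 * pal[2, ] + 0.2126 * pal[3, ]) / 255
  }
  seek(con, data_offset)
  stride <- ((w * bpp %/% 8L + 3L) %/% 4L) * 4L
  bytes <- readBin(con, "raw", stride * h)
  img <- matrix(0, h, w)
  for (i in seq_len(h)) {
    row_bytes <- as.integer(bytes[((i - 1L) * stride + 1L):((i - 1L) * stride + w * bpp %/% 8L)])
    line <- if (bpp == 8L) {
      palette[row_bytes + 1L]
    } else {
      m <- matrix(row_bytes, nrow = 3L) # B, G, R
      (0.0722 * m[1, ] + 0.7152 * m[2, ] + 0.2126 * m[3, ]) / 255
    }
    r <- if (top_down) i else h - i + 1L
    img[r, ] <- line
  }
  img
}

#' Crop frames to a region of interest
#'
#' Clinical sonograms carry vendor annotation bars and imaging tags around
#' the image content; analyses run on a cropped region of interest.
#'
#' @param frames List of matrices from [read_frames()].
#' @param roi `(top, left, height, width)`, 0-based top/left corner; must lie
#'   within every frame.
#' @return List of cropped frames.
#' @export
crop_frames <- function(frames, roi) {
  if (length(roi) != 4L || any(roi[3:4] < 1)) {
    abort_param("`roi` must be (top, left, height, width)")
  }
  lapply(frames, function(f) {
    if (roi[1] < 0 || roi[2] < 0 || roi[1] + roi[3] > nrow(f) ||
        roi[2] + roi[4] > ncol(f)) {
      abort_param("`roi` does not lie within a %d x %d frame", nrow(f),
                  ncol(f))
    }
    f[(roi[1] + 1):(roi[1] + roi[3]), (roi[2] + 1):(roi[2] + roi[4]),
      drop = FALSE]
  })
}

#' Write run results to disk
#'
#' Writes the consolidated line table as `lines.csv` (RFC 4180, full-precision
#' angles that re-parse exactly), a structured `manifest.yml` echoing the
#' configuration and package version, and optionally per-frame overlay PNGs
#' and intermediate images (32-bit float TIFF of the enhanced image, 0/255
#' PNG of the binary map).
#'
#' @param run An `mfo_run` (or a single `mfo_frame`).
#' @param dir Output directory; created if missing.
#' @param overlay Write `overlay_%03d.png` with detected lines drawn over the
#'   frame (yellow = ellipse path, red = Hough path)?
#' @param save_intermediate Write `enhanced_%03d.tif` and `map_%03d.png`?
#' @return Invisibly, the path of the line-table CSV.
#' @export
write_results <- function(run, dir, overlay = FALSE,
                          save_intermediate = FALSE) {
  if (inherits(run, "mfo_frame")) run <- structure(list(run), class = "mfo_run")
  if (!inherits(run, "mfo_run")) {
    abort_param("`run` must be an mfo_run or mfo_frame")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lines <- tidy(run)
  lines <- lines[, c("frame", "order", "angle_deg", "method", "L", "omega",
                     "Ar", "anchor_row", "anchor_col", "votes")]
  # 17 significant digits so every double re-parses to the same value
  for (col in c("angle_deg", "L", "omega", "Ar", "anchor_row",
                "anchor_col")) {
    lines[[col]] <- sprintf("%.17g", lines[[col]])
  }
  csv <- file.path(dir, "lines.csv")
  readr::write_csv(lines, csv)
  cfg <- if (length(run) > 0) run[[1]]$config else detector_config()
  manifest <- list(
    package = "mfodetect",
    version = as.character(utils::packageVersion("mfodetect")),
    n_frames = length(run),
    seed = cfg$seed,
    config = config_to_list(cfg)
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  for (i in seq_along(run)) {
    if (overlay) {
      png::writePNG(overlay_array(run[[i]]),
                    file.path(dir, sprintf("overlay_%03d.png", i)))
    }
    if (save_intermediate) {
      tiff::writeTIFF(run[[i]]$enhanced,
                      file.path(dir, sprintf("enhanced_%03d.tif", i)),
                      bits.per.sample = 32L)
      png::writePNG(run[[i]]$map * 1,
                    file.path(dir, sprintf("map_%03d.png", i)))
    }
  }
  invisible(csv)
}

config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$mvef <- unclass(out$mvef)
  out
}

# RGB array of the frame with detected lines drawn in
overlay_array <- function(frame_result) {
  img <- clamp(frame_result$image, 0, 1)
  h <- nrow(img)
  w <- ncol(img)
  rgb <- array(rep(img, 3L), dim = c(h, w, 3L))
  cols <- list(ellipse = c(1, 1, 0), hough = c(1, 0, 0))
  ln <- frame_result$lines
  for (i in seq_len(nrow(ln))) {
    a <- deg2rad(ln$angle_deg[i])
    ts <- seq(-ln$L[i] / 2, ln$L[i] / 2, by = 0.25)
    r <- round(ln$anchor_row[i] + ts * cos(a)) + 1
    c <- round(ln$anchor_col[i] - ts * sin(a)) + 1
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    colr <- cols[[ln$method[i]]]
    for (ch in 1:3) rgb[cbind(r[ok], c[ok], ch)] <- colr[ch]
  }
  rgb
}
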