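#' Render a GAW as a synthetic endoscopy-like frame stack
#'
#' Produces grayscale frames showing a dark, vertically oriented, lens-shaped
#' glottis on a bright background, one frame per GAW sample. The glottal
#' midline (anterior-posterior axis) is vertical and centred. Pixels are
#' filled in order of increasing elliptical radius (fixed length-to-width
#' aspect), so the dark-pixel count of every frame equals the rounded target
#' area exactly — segmentation can be validated against the GAW to within
#' rounding.
#'
#' @param gaw A `gaw_record`.
#' @param image_size `c(height, width)` in pixels.
#' @param aspect Glottis length-to-width ratio of the rendered ellipse.
#' @param bg,fg Background (bright) and glottis (dark) gray levels, 0-255.
#' @return A numeric array of dimension `height x width x n_frames` with
#'   values in 0-255, class `gaw_frame_stack`, with attribute `fs_fps`.
#' @export
#' @examples
#' gaw <- generate_gaw(kinematic_params(n_cycles = 4, peak_area_px = 300,
#'                                      noise_sd = 0))
#' stack <- render_frames(gaw, image_size = c(48, 24))
#' dim(stack)
render_frames <- function(gaw, image_size = c(96, 48), aspect = 6,
                          bg = 220, fg = 25) {
  h <- as.integer(image_size[1]); w <- as.integer(image_size[2])
  areas <- round(gaw$total_area)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  r2 <- ((xs - cx) * aspect)^2 + (ys - cy)^2
  ord <- order(r2, ys, xs)              # deterministic fill order
  if (max(areas) > length(ord)) {
    abort("canvas overflow: peak area exceeds image capacity.")
  }
  # reject shapes wider than the canvas: width of N filled pixels ~ sqrt(N/(pi*aspect))*2
  if (2 * sqrt(max(areas) / (pi * aspect)) > w) {
    abort("canvas overflow: peak-area ellipse wider than the image.")
  }
  n <- length(areas)
  stack <- array(bg, dim = c(h, w, n))
  for (k in seq_len(n)) {
    if (areas[k] > 0) {
      frame <- matrix(bg, h, w)
      frame[ord[seq_len(areas[k])]] <- fg
      stack[, , k] <- frame
    }
  }
  structure(stack, fs_fps = gaw_fs(gaw), class = "gaw_frame_stack")
}

#' Write / read a frame stack
#'
#' Stacks are stored either as one multi-page 8-bit grayscale TIFF or as a
#' directory of numbered PNGs.
#'
#' @param stack A `gaw_frame_stack` (height x width x frames, values 0-255).
#' @param path Output path: a `.tif`/`.tiff` file, or a directory for PNGs.
#' @param fs_fps Frame rate to attach on reading (read path carries none).
#' @return `write_frame_stack()` returns `path` invisibly;
#'   `read_frame_stack()` returns a `gaw_frame_stack`.
#' @export
write_frame_stack <- function(stack, path) {
  imgs <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k] / 255)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(imgs, path, bits.per.sample = 8L)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_along(imgs)) {
      png::writePNG(imgs[[k]], file.path(path, sprintf("frame_%05d.png", k)))
    }
  }
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path, fs_fps = NA_real_) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) abort("no PNG frames found in directory.")
    imgs <- lapply(files, png::readPNG)
  } else {
    imgs <- tiff::readTIFF(path, all = TRUE)
  }
  imgs <- lapply(imgs, function(m) if (length(dim(m)) == 3) m[, , 1] else m)
  stack <- array(unlist(imgs), dim = c(dim(imgs[[1]]), length(imgs))) * 255
  structure(stack, fs_fps = fs_fps, class = "gaw_frame_stack")
}
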