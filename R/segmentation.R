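#' Segmentation configuration
#'
#' Settings for threshold-based glottis segmentation: the glottis is the
#' largest dark (at or below `intensity_threshold`) 4-connected component
#' inside the region of interest.
#'
#' @param intensity_threshold Grayscale cutoff in `[0, 255]`; pixels with
#'   values `<=` the cutoff are candidate glottis pixels.
#' @param roi Optional region of interest `c(x0, y0, x1, y1)` in 0-based,
#'   half-open pixel coordinates (columns `x0 <= x < x1`, rows
#'   `y0 <= y < y1`, rows running anterior to posterior). `NULL` uses the
#'   whole frame.
#' @param min_component_px Components smaller than this are ignored; a frame
#'   whose largest dark component is below the cutoff gets area 0.
#' @return An object of class `segmentation_config`.
#' @export
#' @examples
#' segmentation_config(intensity_threshold = 100)
segmentation_config <- function(intensity_threshold = 128, roi = NULL,
                                min_component_px = 0) {
  stopifnot_scalar_number(intensity_threshold, "intensity_threshold",
                          lower = 0, upper = 255)
  if (min_component_px < 0) abort("`min_component_px` must be >= 0.")
  if (!is.null(roi)) {
    if (length(roi) != 4 || any(!is.finite(roi))) {
      abort("`roi` must be c(x0, y0, x1, y1).")
    }
    if (roi[3] <= roi[1] || roi[4] <= roi[2]) abort("empty roi.")
  }
  structure(
    list(intensity_threshold = intensity_threshold, roi = roi,
         min_component_px = as.integer(min_component_px)),
    class = "segmentation_config"
  )
}

# 4-connected component labelling of a logical matrix by run merging:
# vertical runs of TRUE pixels per column are nodes; runs in adjacent
# columns whose row ranges overlap are joined with union-find.
label_components_4 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  runs_col <- integer(0); runs_s <- integer(0); runs_e <- integer(0)
  run_of <- matrix(0L, h, w)
  for (x in seq_len(w)) {
    col <- mask[, x]
    if (!any(col)) next
    r <- rle(col)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    for (i in keep) {
      runs_col <- c(runs_col, x)
      runs_s <- c(runs_s, starts[i])
      runs_e <- c(runs_e, ends[i])
      run_of[starts[i]:ends[i], x] <- length(runs_col)
    }
  }
  n_runs <- length(runs_col)
  if (n_runs == 0) {
    return(list(labels = matrix(0L, h, w), sizes = integer(0)))
  }
  parent <- seq_len(n_runs)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n_runs)) {
    x <- runs_col[i]
    if (x == 1L) next
    prev <- unique(run_of[runs_s[i]:runs_e[i], x - 1L])
    for (j in prev[prev > 0L]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n_runs), find, integer(1))
  comp <- match(roots, unique(roots))
  labels <- matrix(0L, h, w)
  sizes <- numeric(max(comp))
  for (i in seq_len(n_runs)) {
    labels[runs_s[i]:runs_e[i], runs_col[i]] <- comp[i]
    sizes[comp[i]] <- sizes[comp[i]] + (runs_e[i] - runs_s[i] + 1L)
  }
  list(labels = labels, sizes = as.integer(sizes))
}

#' Segment the glottis in a single frame
#'
#' Thresholds the frame at `cfg$intensity_threshold` and keeps the largest
#' dark 4-connected component inside the region of interest; its pixel count
#' is the glottal area. Returns area 0 when no component reaches
#' `cfg$min_component_px`.
#'
#' @param frame A single-channel numeric matrix with values in 0-255.
#' @param cfg A [segmentation_config()].
#' @return A list with `area` (pixels) and `mask` (full-frame logical matrix
#'   of the selected component).
#' @export
#' @examples
#' f <- matrix(200, 10, 10); f[3:6, 4:6] <- 50
#' segment_frame(f, segmentation_config())$area
segment_frame <- function(frame, cfg = segmentation_config()) {
  if (length(dim(frame)) != 2) {
    abort("`frame` must be a single-channel (2-d) image.")
  }
  h <- nrow(frame); w <- ncol(frame)
  if (!is.null(cfg$roi)) {
    x0 <- cfg$roi[1]; y0 <- cfg$roi[2]; x1 <- cfg$roi[3]; y1 <- cfg$roi[4]
    if (x0 < 0 || y0 < 0 || x1 > w || y1 > h) abort("roi outside frame.")
    cols <- (x0 + 1):x1
    rows <- (y0 + 1):y1
  } else {
    cols <- seq_len(w); rows <- seq_len(h)
  }
  dark <- matrix(FALSE, h, w)
  dark[rows, cols] <- frame[rows, cols] <= cfg$intensity_threshold
  lab <- label_components_4(dark)
  mask <- matrix(FALSE, h, w)
  if (!length(lab$sizes) || max(lab$sizes) < max(1L, cfg$min_component_px)) {
    return(list(area = 0, mask = mask))
  }
  best <- which.max(lab$sizes)
  mask[lab$labels == best] <- TRUE
  list(area = sum(mask), mask = mask)
}

#' Extract a GAW from a frame stack
#'
#' Segments every frame and splits the glottis into left and right halves
#' along the glottal midline, defined as the principal (major) axis of the
#' time-union of all frame masks — a per-stack axis that stays defined when
#' the glottis closes. Pixels on the left of the axis count toward
#' `left_area`; pixels exactly on the axis alternate by row parity so a
#' symmetric glottis splits evenly. By construction
#' `left_area + right_area == total_area` on every frame.
#'
#' @param stack A `gaw_frame_stack` (or plain `height x width x n` array).
#' @param cfg A [segmentation_config()].
#' @param fs_fps Frame rate of the stack; defaults to the stack's own
#'   attribute.
#' @return A `gaw_record` with per-frame total and half areas.
#' @export
extract_gaw <- function(stack, cfg = segmentation_config(), fs_fps = NULL) {
  d <- dim(stack)
  if (length(d) != 3 || d[3] < 1) abort("`stack` must hold at least 1 frame.")
  fs_fps <- fs_fps %||% attr(stack, "fs_fps")
  if (is.null(fs_fps) || !is.finite(fs_fps)) {
    abort("supply `fs_fps` (stack carries no frame rate).")
  }
  n <- d[3]
  masks <- vector("list", n)
  total <- numeric(n)
  for (k in seq_len(n)) {
    seg <- segment_frame(stack[, , k], cfg)
    masks[[k]] <- seg$mask
    total[k] <- seg$area
  }
  union_mask <- Reduce(`|`, masks)
  if (!any(union_mask)) {
    # all-bright stack: an all-zero GAW; downstream cycle detection will
    # flag "no oscillation"
    return(new_gaw_record(total_area = total, fs_fps = fs_fps,
                          left_area = total, right_area = total * 0,
                          provenance = "segmented (empty union mask)"))
  }
  side <- axis_side_map(union_mask)
  left <- vapply(masks, function(m) sum(m & side < 0), numeric(1))
  right <- vapply(masks, function(m) sum(m & side > 0), numeric(1))
  new_gaw_record(
    total_area = total, fs_fps = fs_fps,
    left_area = left, right_area = right,
    provenance = "segmented"
  )
}

# Signed side of each pixel relative to the principal axis of `mask`:
# -1 left, +1 right; pixels exactly on the axis alternate by row parity.
axis_side_map <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  ys <- row(mask)[mask]; xs <- col(mask)[mask]
  cx <- mean(xs); cy <- mean(ys)
  cv <- stats::cov(cbind(xs - cx, ys - cy))
  if (any(!is.finite(cv))) cv <- diag(2)        # single-pixel union
  eg <- eigen(cv, symmetric = TRUE)
  major <- eg$vectors[, 1]
  normal <- c(-major[2], major[1])
  if (normal[1] < 0 || (normal[1] == 0 && normal[2] < 0)) normal <- -normal
  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), times = w), h, w)
  s <- (X - cx) * normal[1] + (Y - cy) * normal[2]
  side <- sign(s)
  on_axis <- side == 0
  if (any(on_axis)) {
    side[on_axis] <- ifelse(Y[on_axis] %% 2 == 0, -1, 1)
  }
  side
}
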