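#' Plan a frame-rate sweep
#'
#' Defines the set of target frame rates emulated from a master recording.
#' The default reproduces a stepwise reduction in 1 kfps steps from a
#' 15 kfps master down to 1 kfps.
#'
#' @param master_fps Master frame rate in frames per second.
#' @param target_fps Target rates; must be positive, unique, ascending and
#'   no larger than `master_fps`.
#' @return An object of class `rate_sweep_plan`.
#' @export
#' @examples
#' rate_sweep_plan()
rate_sweep_plan <- function(master_fps = 15000,
                            target_fps = seq(1000, 15000, by = 1000)) {
  stopifnot_scalar_number(master_fps, "master_fps", lower = 0,
                          strict_lower = TRUE)
  if (!length(target_fps)) abort("`target_fps` must be non-empty.")
  if (any(target_fps <= 0)) abort("target rates must be strictly positive.")
  if (any(target_fps > master_fps)) {
    abort("every target rate must be <= `master_fps`.")
  }
  if (anyDuplicated(target_fps) || is.unsorted(target_fps, strictly = TRUE)) {
    abort("target rates must be unique and sorted ascending.")
  }
  structure(list(master_fps = master_fps, target_fps = as.numeric(target_fps)),
            class = "rate_sweep_plan")
}

#' Emulate a slower camera by frame decimation
#'
#' Output frame `j` (0-based) holds the master frame at index
#' `floor(j * master_fps / target_fps)` — the nearest preceding captured
#' instant, with no interpolation or averaging, the way a slower camera
#' samples a subset of instants. The output has
#' `floor(duration_s * target_fps)` frames, preserving the total duration to
#' within one master frame; left/right halves are resampled with the same
#' index map.
#'
#' @param gaw A `gaw_record` at the master rate.
#' @param target_fps Target frame rate, `0 < target_fps <= ` master rate.
#' @return A `gaw_record` at `target_fps`.
#' @export
#' @examples
#' gaw <- generate_gaw(kinematic_params(n_cycles = 6))
#' nrow(decimate_gaw(gaw, 5000)) / nrow(gaw)
decimate_gaw <- function(gaw, target_fps) {
  master <- gaw_fs(gaw)
  stopifnot_scalar_number(target_fps, "target_fps", lower = 0,
                          strict_lower = TRUE)
  if (target_fps > master) abort("`target_fps` must be <= the master rate.")
  n <- nrow(gaw)
  if (target_fps == master) {
    return(gaw)
  }
  n_out <- floor(n * target_fps / master + 1e-9)
  j <- seq_len(n_out) - 1
  idx <- floor(j * master / target_fps + 1e-9) + 1
  idx <- pmin(idx, n)
  new_gaw_record(
    total_area = gaw$total_area[idx],
    fs_fps = target_fps,
    left_area = if ("left_area" %in% names(gaw)) gaw$left_area[idx],
    right_area = if ("right_area" %in% names(gaw)) gaw$right_area[idx],
    provenance = sprintf("%s | decimated to %g fps",
                         attr(gaw, "provenance") %||% "", target_fps),
    ground_truth = gaw_ground_truth(gaw)
  )
}

#' Build the full rate sweep
#'
#' Decimates every recording to every target rate of the plan — the
#' Cartesian product that turns `n` master recordings into
#' `n * length(target_fps)` sample recordings.
#'
#' @param recordings A named list of `gaw_record`s (names become recording
#'   ids; unnamed lists get `rec01`, `rec02`, ...).
#' @param plan A [rate_sweep_plan()].
#' @return A tibble with columns `recording_id`, `fps` and a list-column
#'   `gaw` holding the decimated records, one row per (recording, rate).
#' @export
#' @examples
#' recs <- lapply(synthetic_cohort(2, n_cycles = 8), generate_gaw)
#' sweep <- build_sweep(recs, rate_sweep_plan(target_fps = c(5000, 15000)))
#' nrow(sweep)
build_sweep <- function(recordings, plan = rate_sweep_plan()) {
  if (!length(recordings)) abort("`recordings` must be non-empty.")
  if (!inherits(plan, "rate_sweep_plan")) {
    abort("`plan` must be a rate_sweep_plan().")
  }
  ids <- names(recordings) %||% sprintf("rec%02d", seq_along(recordings))
  if (is.null(names(recordings))) names(recordings) <- ids
  grid <- tidyr::expand_grid(recording_id = ids, fps = plan$target_fps)
  grid$gaw <- purrr::map2(grid$recording_id, grid$fps, function(id, r) {
    decimate_gaw(recordings[[id]], r)
  })
  grid
}
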