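#' Detect oscillation cycles and phase landmarks in a GAW
#'
#' Segments a GAW into glottal cycles bounded by successive opening instants
#' and computes, per cycle, the phase landmarks every downstream parameter
#' depends on: period, open/closed and opening/closing durations, peak and
#' minimum area, dynamic range, and (when half waveforms are present) the
#' left and right peak times.
#'
#' Detection proceeds in two passes. Candidate boundaries are upward
#' crossings of the mid level (baseline plus half the global dynamic range),
#' which are robust to noise. Each candidate is then refined to the opening
#' instant: the frame after the last frame at or below the closure level
#' `c = baseline + closure_threshold_rel * (cycle-local max - baseline)`
#' within the preceding half period (`baseline` is the global minimum area).
#' If no such frame exists — typical for noisy signals under the zero
#' threshold — the mid-level crossing itself is kept.
#'
#' Within each cycle (half-open `[t_start, t_end)`, frame `k` at time
#' `k / fs`): closed frames are those with area strictly below the closure
#' level, so with `closure_threshold_rel = 0` the closed phase is empty and
#' OQ equals 1 — the near-unity open quotient seen when a posterior glottal
#' gap keeps the waveform off its baseline. Opening runs from the cycle
#' start to the (earliest) peak frame and includes the partial frame during
#' which the waveform crossed the closure level (a half-sample convention
#' that balances the quantization of the opening and closing landmarks
#' without sub-frame interpolation); closing runs from the peak frame to
#' the first closed frame after it, or to the cycle end if the cycle never
#' closes. The open duration is capped at the period. Partial first/last
#' cycles are discarded and at most `max_cycles` cycles are retained from
#' the start.
#'
#' @param gaw A `gaw_record`.
#' @param closure_threshold_rel Closure level as a fraction of the
#'   cycle-local dynamic range above baseline. 0 (default) treats only the
#'   baseline itself as closed; 0.01 and 0.05 reproduce the 1%- and
#'   5%-of-maximum closure conventions used in the clinical literature.
#' @param max_cycles Analysis window: number of complete cycles kept.
#' @return A `cycle_set`: a tibble with one row per cycle (columns
#'   `t_start`, `t_end`, `T_s`, `open_s`, `closed_s`, `opening_s`,
#'   `closing_s`, `peak_time`, `peak_area`, `min_area`, `dyn_range`,
#'   `t_M_left`, `t_M_right`) and attributes `fs_fps`, `f0_hz`, `n_used`.
#' @export
#' @examples
#' gaw <- generate_gaw(kinematic_params(n_cycles = 10, noise_sd = 0))
#' cs <- detect_cycles(gaw)
#' attr(cs, "n_used")
detect_cycles <- function(gaw, closure_threshold_rel = 0, max_cycles = 106) {
  stopifnot_scalar_number(closure_threshold_rel, "closure_threshold_rel",
                          lower = 0, upper = 1)
  area <- gaw$total_area
  fs <- gaw_fs(gaw)
  n <- length(area)
  b <- min(area)
  gmax <- max(area)
  if (gmax - b <= 0) abort("no oscillation: constant signal.")
  mid <- b + 0.5 * (gmax - b)
  tol <- 1e-9 * (gmax - b)         # guards the <= comparison against roundoff
  up <- which(area[-1] > mid & area[-n] <= mid) + 1L
  if (length(up) < 3) abort("no oscillation: fewer than 2 complete cycles.")
  period_est <- median(diff(up))
  half_win <- max(1L, floor(period_est / 2))

  n_bound <- length(up)
  boundaries <- integer(n_bound)
  for (j in seq_len(n_bound)) {
    seg_end <- if (j < n_bound) up[j + 1] - 1L else up[j]
    seg_start <- if (j < n_bound) up[j] else up[j - 1]
    local_max <- max(area[seg_start:seg_end])
    c_lev <- b + closure_threshold_rel * (local_max - b)
    w0 <- max(1L, up[j] - half_win)
    w <- w0:up[j]
    low <- w[area[w] <= c_lev + tol]
    boundaries[j] <- if (length(low)) max(low) + 1L else up[j]
  }
  boundaries <- unique(boundaries)
  if (length(boundaries) < 3) abort("no oscillation: fewer than 2 complete cycles.")
  n_cyc <- min(length(boundaries) - 1L, max_cycles)

  has_halves <- all(c("left_area", "right_area") %in% names(gaw))
  rows <- vector("list", n_cyc)
  for (i in seq_len(n_cyc)) {
    s <- boundaries[i]; e <- boundaries[i + 1]
    idx <- s:(e - 1L)
    seg <- area[idx]
    T_s <- (e - s) / fs
    local_max <- max(seg)
    c_lev <- b + closure_threshold_rel * (local_max - b)
    peak_rel <- which.max(seg)                  # earliest tie wins
    peak_idx <- idx[peak_rel]
    # the frame during which the waveform crossed the closure level counts
    # toward the opening phase (half-sample convention, no interpolation)
    opening_s <- peak_rel / fs
    closed_after <- which(seg < c_lev & seq_along(seg) >= peak_rel)
    closing_s <- if (length(closed_after)) {
      (closed_after[1] - peak_rel) / fs
    } else {
      (length(seg) - peak_rel + 1L) / fs
    }
    open_s <- min(opening_s + closing_s, T_s)
    closed_s <- T_s - open_s
    min_area <- min(seg)
    tml <- tmr <- NA_real_
    if (has_halves) {
      lseg <- gaw$left_area[idx]; rseg <- gaw$right_area[idx]
      tml <- (idx[which.max(lseg)] - 1L) / fs
      tmr <- (idx[which.max(rseg)] - 1L) / fs
    }
    rows[[i]] <- tibble(
      t_start = (s - 1L) / fs, t_end = (e - 1L) / fs, T_s = T_s,
      open_s = open_s, closed_s = closed_s,
      opening_s = opening_s, closing_s = closing_s,
      peak_time = (peak_idx - 1L) / fs,
      peak_area = area[peak_idx], min_area = min_area,
      dyn_range = area[peak_idx] - min_area,
      t_M_left = tml, t_M_right = tmr
    )
  }
  cs <- dplyr::bind_rows(rows)
  structure(cs,
    fs_fps = fs, f0_hz = 1 / mean(cs$T_s), n_used = nrow(cs),
    class = c("cycle_set", class(cs))
  )
}

#' Fundamental frequency of a cycle set
#'
#' The phonatory fundamental frequency as the reciprocal of the mean cycle
#' period over the analysis window.
#'
#' @param cycles A `cycle_set` from [detect_cycles()].
#' @return F0 in Hz.
#' @export
#' @examples
#' gaw <- generate_gaw(kinematic_params(f0_hz = 200, n_cycles = 10,
#'                                      jitter_ms = 0, noise_sd = 0))
#' estimate_f0(detect_cycles(gaw))
estimate_f0 <- function(cycles) {
  if (!inherits(cycles, "cycle_set")) abort("`cycles` must be a cycle_set.")
  if (nrow(cycles) < 2) abort("need at least 2 cycles to estimate F0.")
  1 / mean(cycles$T_s)
}

#' Serialize a cycle set
#'
#' Writes the per-cycle landmark table as tidy CSV or JSON (with the frame
#' rate and cycle count as top-level fields) for inspection.
#'
#' @param cycles A `cycle_set`.
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_cycles <- function(cycles, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(fs_fps = attr(cycles, "fs_fps"), f0_hz = attr(cycles, "f0_hz"),
           n_used = attr(cycles, "n_used"), cycles = as_tibble(cycles)),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    readr::write_csv(as_tibble(cycles), path)
  }
  invisible(path)
}
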