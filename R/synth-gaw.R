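#' Kinematic parameters of a synthetic glottal area waveform
#'
#' Bundles and validates the ground-truth kinematics for [generate_gaw()].
#' Defaults emulate sustained phonation of a vocally healthy adult female as
#' captured by a laryngeal high-speed camera: fundamental frequency near
#' 176 Hz, a 15 kfps master recording spanning 106 oscillation cycles, a
#' small posterior glottal gap, near-perfect left-right symmetry and low
#' cycle-to-cycle perturbation.
#'
#' @param f0_hz Fundamental frequency in Hz.
#' @param fs_fps Master recording frame rate in frames per second. Must give
#'   at least 4 samples per cycle (`fs_fps / f0_hz >= 4`).
#' @param n_cycles Number of complete oscillation cycles to generate.
#' @param open_quotient Fraction of each period the glottis is open, in
#'   `[0, 1]`.
#' @param speed_quotient Ratio of opening to closing duration, positive.
#' @param gap_fraction Closed-phase floor area as a fraction of the nominal
#'   peak area, in `[0, 1)`. A positive value models a posterior glottal
#'   chink that keeps the glottis from closing completely.
#' @param phase_asym Left-right peak-time offset as a fraction of the period,
#'   in `(-1, 1)`. Zero is perfect left-right symmetry; the generated value
#'   is exactly the Phase Asymmetry (PA) ground truth.
#' @param jitter_ms Requested mean absolute difference between consecutive
#'   cycle durations, in milliseconds.
#' @param shimmer_db Requested mean absolute dB difference between
#'   consecutive cycle peak amplitudes.
#' @param noise_sd Standard deviation of additive area noise in pixels
#'   (applied to the total area; each half receives half the noise so the
#'   halves always sum to the total).
#' @param peak_area_px Nominal cycle peak area in pixels.
#' @param seed Integer seed; identical parameters give bit-identical output.
#'
#' @return An object of class `kinematic_params` (a named list).
#' @seealso [generate_gaw()], [synthetic_cohort()]
#' @export
#' @examples
#' kp <- kinematic_params(f0_hz = 200, n_cycles = 10, jitter_ms = 0)
#' kp$f0_hz
kinematic_params <- function(f0_hz = 176,
                             fs_fps = 15000,
                             n_cycles = 106,
                             open_quotient = 0.9,
                             speed_quotient = 1.25,
                             gap_fraction = 0.06,
                             phase_asym = -0.02,
                             jitter_ms = 0.3,
                             shimmer_db = 0.2,
                             noise_sd = 10,
                             peak_area_px = 6000,
                             seed = 1L) {
  stopifnot_scalar_number(f0_hz, "f0_hz", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(fs_fps, "fs_fps", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(open_quotient, "open_quotient", lower = 0, upper = 1)
  stopifnot_scalar_number(speed_quotient, "speed_quotient", lower = 0,
                          strict_lower = TRUE)
  stopifnot_scalar_number(gap_fraction, "gap_fraction", lower = 0, upper = 1)
  if (gap_fraction >= 1) abort("`gap_fraction` must be < 1.")
  stopifnot_scalar_number(phase_asym, "phase_asym", lower = -1, upper = 1)
  stopifnot_scalar_number(jitter_ms, "jitter_ms", lower = 0)
  stopifnot_scalar_number(shimmer_db, "shimmer_db", lower = 0)
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 0)
  stopifnot_scalar_number(peak_area_px, "peak_area_px", lower = 0,
                          strict_lower = TRUE)
  if (n_cycles < 1) abort("`n_cycles` must be >= 1.")
  if (fs_fps / f0_hz < 4) {
    abort("`fs_fps / f0_hz` must be >= 4 (at least 4 samples per cycle).")
  }
  structure(
    list(
      f0_hz = f0_hz, fs_fps = fs_fps, n_cycles = as.integer(n_cycles),
      open_quotient = open_quotient, speed_quotient = speed_quotient,
      gap_fraction = gap_fraction, phase_asym = phase_asym,
      jitter_ms = jitter_ms, shimmer_db = shimmer_db, noise_sd = noise_sd,
      peak_area_px = peak_area_px, seed = as.integer(seed)
    ),
    class = "kinematic_params"
  )
}

#' @export
print.kinematic_params <- function(x, ...) {
  cat("<kinematic_params>\n")
  cat(sprintf("  F0 %g Hz @ %g fps, %d cycles\n", x$f0_hz, x$fs_fps, x$n_cycles))
  cat(sprintf("  OQ %g, SQ %g, gap %g, PA %g\n", x$open_quotient,
              x$speed_quotient, x$gap_fraction, x$phase_asym))
  cat(sprintf("  jitter %g ms, shimmer %g dB, noise sd %g px, peak %g px, seed %d\n",
              x$jitter_ms, x$shimmer_db, x$noise_sd, x$peak_area_px, x$seed))
  invisible(x)
}

# One glottal pulse: quarter-sine opening and closing limbs joined smoothly
# at the peak, atop a constant closed-phase floor. The limbs leave the floor
# with finite slope, so relative-threshold landmarks sit within a fraction
# of a percent of the true phase boundaries.
pulse_area <- function(tau, T, A, floor_px, open_quotient, speed_quotient) {
  n <- length(tau)
  T <- rep_len(T, n)
  A <- rep_len(A, n)
  open_s <- open_quotient * T
  opening <- open_s * speed_quotient / (1 + speed_quotient)
  closing <- open_s / (1 + speed_quotient)
  a <- rep(floor_px, n)
  i1 <- tau >= 0 & tau < opening
  a[i1] <- floor_px + (A[i1] - floor_px) *
    sin(pi * tau[i1] / (2 * opening[i1]))
  i2 <- tau >= opening & tau < open_s
  a[i2] <- floor_px + (A[i2] - floor_px) *
    cos(pi * (tau[i2] - opening[i2]) / (2 * closing[i2]))
  a
}

# Scale i.i.d. standard-normal draws so the realized mean absolute first
# difference of the perturbed sequence matches `target` (two-pass
# calibration; exact for the dB-amplitude case, first-order exact for the
# log-period case).
scale_to_mean_absdiff <- function(eps, target) {
  if (target == 0 || length(eps) < 2) return(rep(0, length(eps)))
  d <- mean(abs(diff(eps)))
  if (d == 0) return(rep(0, length(eps)))
  eps * (target / d)
}

#' Generate a synthetic glottal area waveform
#'
#' Builds a sampled GAW (total area plus left/right halves) from kinematic
#' ground truth. Each cycle is a smooth open-phase pulse — quarter-sine
#' opening and closing limbs whose durations stand in the ratio
#' `speed_quotient` — atop a closed-phase floor of
#' `gap_fraction * peak_area_px`. Cycle periods carry Gaussian log-period
#' perturbation calibrated so the realized mean absolute period difference
#' matches `jitter_ms`; cycle peak amplitudes carry Gaussian dB perturbation
#' calibrated so the realized mean absolute dB difference matches
#' `shimmer_db` exactly. The left and right half waveforms are each half the
#' pulse with peak times offset by `+/- phase_asym * T / 2`, making the Phase
#' Asymmetry ground truth exactly `phase_asym`; the total is their sum.
#' Additive Gaussian noise is split equally between the halves so
#' `left + right == total` holds by construction.
#'
#' A short closed-floor lead-in and a rising stub after the last cycle are
#' appended so that downstream cycle detection sees all `n_cycles` cycles as
#' complete (bounded by opening instants on both sides).
#'
#' @param params A [kinematic_params()] object.
#' @return A `gaw_record`: a tibble with columns `frame` (0-based), `time_s`,
#'   `total_area`, `left_area`, `right_area`, plus attributes `fs_fps`,
#'   `provenance` and `ground_truth`. The ground truth records the input
#'   parameters, per-cycle onsets/periods/amplitudes/peak times, and the
#'   realized jitter (`mJT_ms`) and shimmer (`mSH_db`).
#' @export
#' @examples
#' gaw <- generate_gaw(kinematic_params(n_cycles = 8, noise_sd = 0))
#' head(gaw)
#' attr(gaw, "ground_truth")$mJT_ms
generate_gaw <- function(params) {
  if (!inherits(params, "kinematic_params")) {
    abort("`params` must be created by kinematic_params().")
  }
  p <- params
  T0 <- 1 / p$f0_hz
  if (p$open_quotient * T0 * p$fs_fps < 2) {
    abort("unresolvable pulse: open phase shorter than 2 frames at this rate.")
  }
  with_local_seed(p$seed, {
    n <- p$n_cycles
    # periods: Gaussian on log-period, rescaled so mean |dT| hits jitter_ms
    eps <- rnorm(n)
    jit_s <- p$jitter_ms / 1000
    if (jit_s > 0 && n >= 2) {
      c0 <- jit_s / (T0 * mean(abs(diff(eps))))
      Ti <- T0 * exp(c0 * eps)
      # second pass absorbs the (tiny) convexity of exp()
      c1 <- c0 * jit_s / mean(abs(diff(Ti)))
      Ti <- T0 * exp(c1 * eps)
    } else {
      Ti <- rep(T0, n)
    }
    # amplitudes: Gaussian on dB scale; calibration is exact in dB
    db <- scale_to_mean_absdiff(rnorm(n), p$shimmer_db)
    Ai <- p$peak_area_px * 10^(db / 20)

    floor_px <- p$gap_fraction * p$peak_area_px
    onsets <- cumsum(c(0, Ti[-n]))
    open_s <- p$open_quotient * Ti
    opening <- open_s * p$speed_quotient / (1 + p$speed_quotient)

    lead_in <- 0.25 * T0
    stub <- 0.6 * opening[1]               # rises past the mid level, then stops
    total_dur <- lead_in + sum(Ti) + stub
    n_frames <- floor(total_dur * p$fs_fps)
    t <- (seq_len(n_frames) - 1) / p$fs_fps

    cyc <- findInterval(t - lead_in, c(onsets, sum(Ti)))
    # cyc == 0: lead-in floor; cyc == n + 1: trailing stub of a virtual cycle
    cyc_idx <- pmin(pmax(cyc, 1L), n)
    Tc <- Ti[cyc_idx]
    Ac <- Ai[cyc_idx]
    tau <- t - lead_in - onsets[cyc_idx]
    in_stub <- cyc > n
    if (any(in_stub)) {
      Tc[in_stub] <- T0
      Ac[in_stub] <- p$peak_area_px
      tau[in_stub] <- t[in_stub] - lead_in - sum(Ti)
    }
    shift <- p$phase_asym * Tc / 2
    half <- function(s) {
      tt <- (tau - s) %% Tc
      pulse_area(tt, Tc, Ac, floor_px, p$open_quotient, p$speed_quotient) / 2
    }
    left <- half(shift)                   # left peak at opening + shift
    right <- half(-shift)
    lead_mask <- cyc == 0
    left[lead_mask] <- floor_px / 2
    right[lead_mask] <- floor_px / 2

    if (p$noise_sd > 0) {
      nz <- rnorm(n_frames, sd = p$noise_sd) / 2
      left <- pmax(left + nz, 0)
      right <- pmax(right + nz, 0)
    }
    total <- left + right

    t_peak <- lead_in + onsets + opening
    # The total waveform is the sum of two half pulses shifted by
    # +/- phase_asym * T / 2, so its open phase is the union of two shifted
    # open windows: longer than each half's by |phase_asym| * T, split
    # equally between the opening and closing limbs. These effective
    # quotients are the ground truth for measurements on the total GAW.
    pa_abs <- abs(p$phase_asym)
    oq_total <- min(1, p$open_quotient + pa_abs)
    opening_frac <- p$open_quotient * p$speed_quotient / (1 + p$speed_quotient)
    closing_frac <- p$open_quotient / (1 + p$speed_quotient)
    sq_total <- (opening_frac + pa_abs / 2) / (closing_frac + pa_abs / 2)
    truth <- list(
      params = p,
      oq_total = oq_total,
      sq_total = sq_total,
      cq_total = closing_frac + pa_abs / 2,
      onsets_s = lead_in + onsets,
      periods_s = Ti,
      peak_areas_px = Ai,
      t_peak_s = t_peak,
      t_M_left_s = t_peak + p$phase_asym * Ti / 2,
      t_M_right_s = t_peak - p$phase_asym * Ti / 2,
      mJT_ms = if (n >= 2) mean(abs(diff(Ti))) * 1000 else 0,
      mSH_db = if (n >= 2) mean(abs(diff(20 * log10(Ai)))) else 0
    )
    new_gaw_record(
      total_area = total, left_area = left, right_area = right,
      fs_fps = p$fs_fps,
      provenance = sprintf("synthetic (seed %d)", p$seed),
      ground_truth = truth
    )
  })
}

#' Construct a GAW record
#'
#' Low-level constructor for the tabular GAW container used throughout the
#' package: one row per video frame, total glottal area in pixels and
#' (optionally) the left/right half areas.
#'
#' @param total_area Numeric vector of total areas (pixels, `>= 0`).
#' @param fs_fps Frame rate in frames per second.
#' @param left_area,right_area Optional half areas; when present they must
#'   sum to `total_area` within numeric tolerance.
#' @param provenance Free-text origin note.
#' @param ground_truth Optional generator ground truth (kept as an attribute).
#' @return A tibble of class `gaw_record` with columns `frame` (0-based),
#'   `time_s`, `total_area` and, if supplied, `left_area`/`right_area`.
#' @export
new_gaw_record <- function(total_area, fs_fps, left_area = NULL,
                           right_area = NULL, provenance = "",
                           ground_truth = NULL) {
  n <- length(total_area)
  if (n < 2) abort("a GAW needs at least 2 frames.")
  if (any(total_area < 0)) abort("areas must be >= 0.")
  stopifnot_scalar_number(fs_fps, "fs_fps", lower = 0, strict_lower = TRUE)
  out <- tibble(
    frame = seq_len(n) - 1L,
    time_s = (seq_len(n) - 1) / fs_fps,
    total_area = as.numeric(total_area)
  )
  if (!is.null(left_area) || !is.null(right_area)) {
    if (is.null(left_area) || is.null(right_area)) {
      abort("supply both `left_area` and `right_area` or neither.")
    }
    if (length(left_area) != n || length(right_area) != n) {
      abort("half areas must have the same length as `total_area`.")
    }
    if (any(left_area < 0) || any(right_area < 0)) abort("areas must be >= 0.")
    tol <- 1e-6 * max(1, max(total_area))
    if (max(abs(left_area + right_area - total_area)) > tol) {
      abort("`left_area + right_area` must equal `total_area` per frame.")
    }
    out$left_area <- as.numeric(left_area)
    out$right_area <- as.numeric(right_area)
  }
  structure(out,
    fs_fps = fs_fps, provenance = provenance, ground_truth = ground_truth,
    class = c("gaw_record", class(out))
  )
}

#' Frame rate of a GAW record
#' @param gaw A `gaw_record`.
#' @return Frame rate in frames per second.
#' @export
gaw_fs <- function(gaw) {
  fs <- attr(gaw, "fs_fps")
  if (is.null(fs)) abort("`gaw` carries no frame-rate attribute.")
  fs
}

#' Generator ground truth of a synthetic GAW
#' @param gaw A `gaw_record` produced by [generate_gaw()].
#' @return The ground-truth list, or `NULL` for non-synthetic records.
#' @export
gaw_ground_truth <- function(gaw) attr(gaw, "ground_truth")

#' Kinematic parameters for a synthetic study cohort
#'
#' Draws per-recording kinematic parameters emulating repeated sustained-
#' phonation takes from one healthy female speaker: fundamental frequency
#' 176 +/- 11 Hz across takes, a small posterior glottal gap (gap fraction
#' 0.05-0.07), slight left-right asymmetry (PA about -0.02), and low jitter
#' and shimmer, all recorded at a 15 kfps master rate over 106 cycles.
#'
#' @param n_recordings Number of recordings (takes).
#' @param seed Integer seed for the cohort draw; each recording also gets its
#'   own derived generator seed.
#' @param n_cycles,fs_fps Passed to every recording.
#' @return A list of [kinematic_params()] objects.
#' @export
#' @examples
#' cohort <- synthetic_cohort(3, seed = 7, n_cycles = 12)
#' length(cohort)
synthetic_cohort <- function(n_recordings = 20, seed = 1L,
                             n_cycles = 106, fs_fps = 15000) {
  if (n_recordings < 1) abort("`n_recordings` must be >= 1.")
  with_local_seed(seed, {
    lapply(seq_len(n_recordings), function(i) {
      kinematic_params(
        f0_hz = rnorm(1, 176, 11),
        fs_fps = fs_fps,
        n_cycles = n_cycles,
        open_quotient = stats::runif(1, 0.88, 0.92),
        speed_quotient = stats::runif(1, 1.20, 1.30),
        gap_fraction = stats::runif(1, 0.05, 0.07),
        phase_asym = stats::runif(1, -0.03, -0.01),
        jitter_ms = stats::runif(1, 0.25, 0.35),
        shimmer_db = stats::runif(1, 0.15, 0.25),
        noise_sd = 10,
        peak_area_px = stats::runif(1, 5000, 7000),
        seed = as.integer(seed) * 1000L + i
      )
    })
  })
}

#' Write / read a GAW record as delimited text
#'
#' The CSV dialect has header `frame,time_s,total_area,left_area,right_area`
#' (half-area columns present only when the record has them). `write_gaw()`
#' also writes a JSON sidecar `<path>.json` carrying the frame rate,
#' provenance and — for synthetic records — the generator ground truth.
#'
#' @param gaw A `gaw_record`.
#' @param path Output CSV path.
#' @return `write_gaw()` returns `path` invisibly; `read_gaw()` returns a
#'   `gaw_record`.
#' @export
write_gaw <- function(gaw, path) {
  readr::write_csv(as_tibble(gaw), path)
  side <- list(
    fs_fps = gaw_fs(gaw),
    provenance = attr(gaw, "provenance") %||% ""
  )
  gt <- gaw_ground_truth(gaw)
  if (!is.null(gt)) {
    side$ground_truth <- c(unclass(gt$params),
      list(mJT_ms = gt$mJT_ms, mSH_db = gt$mSH_db))
  }
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gaw
#' @export
read_gaw <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    fs <- side$fs_fps
    prov <- side$provenance %||% ""
  } else {
    fs <- 1 / median(diff(d$time_s))
    prov <- path
  }
  new_gaw_record(
    total_area = d$total_area, fs_fps = fs,
    left_area = d[["left_area"]], right_area = d[["right_area"]],
    provenance = prov
  )
}
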