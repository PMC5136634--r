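#' Time quotients of the glottal cycle
#'
#' Computes the per-cycle phase-duration ratios and averages them over the
#' analysis window: Open Quotient `OQ = open / T`, Closing Quotient
#' `CQ = closing / T`, Rate Quotient `RQ = (closed + opening) / closing`,
#' Speed Quotient `SQ = opening / closing`, Asymmetry Quotient
#' `ASQ = SQ / (SQ + 1)` and Speed Index `SI = (SQ - 1) / (SQ + 1)`. ASQ and
#' SI are derived per cycle and then averaged, consistently with the other
#' quotients, so the identity `SI = 2 * ASQ - 1` carries over to the means.
#' Cycles with zero closing duration are excluded from RQ/SQ/ASQ/SI with a
#' warning; if all cycles are excluded those four values are `NA`.
#'
#' @param cycles A `cycle_set` from [detect_cycles()].
#' @return A one-row tibble with columns `OQ`, `CQ`, `RQ`, `SQ`, `ASQ`, `SI`.
#' @export
#' @examples
#' cs <- toy_cycle_set(T_s = 0.010, open_s = 0.008, opening_s = 0.005,
#'                     closing_s = 0.003)
#' compute_time_quotients(cs)
compute_time_quotients <- function(cycles) {
  if (nrow(cycles) < 1) abort("need at least 1 cycle.")
  oq <- cycles$open_s / cycles$T_s
  cq <- cycles$closing_s / cycles$T_s
  ok <- cycles$closing_s > 0
  if (!all(ok)) {
    warn(sprintf("%d cycle(s) with zero closing duration excluded from RQ/SQ/ASQ/SI.",
                 sum(!ok)))
  }
  if (any(ok)) {
    sq_i <- cycles$opening_s[ok] / cycles$closing_s[ok]
    rq_i <- (cycles$closed_s[ok] + cycles$opening_s[ok]) / cycles$closing_s[ok]
    sq <- mean(sq_i); rq <- mean(rq_i)
    asq <- mean(sq_i / (sq_i + 1))
    si <- mean((sq_i - 1) / (sq_i + 1))
  } else {
    sq <- rq <- asq <- si <- NA_real_
  }
  tibble(OQ = mean(oq), CQ = mean(cq), RQ = rq, SQ = sq, ASQ = asq, SI = si)
}

#' Amplitude dynamics of the GAW
#'
#' Per cycle: the Maximum Area Declination Rate `MADR` is the most negative
#' first difference of the total area (pixels/frame, negative — the fastest
#' closing velocity); the Amplitude Quotient `AMQ` is the cycle dynamic
#' range divided by that cycle's MADR (frames, negative); the Glottis Gap
#' Index `GGI` is the minimum-to-peak area ratio; the Phase Asymmetry `PA`
#' is the normalized left-right peak-time offset
#' `(t_M(left) - t_M(right)) / T`, zero for perfect symmetry. Cycle values
#' are averaged; flat cycles (MADR `>= 0`) contribute no AMQ, and PA is `NA`
#' when half waveforms are absent.
#'
#' @param gaw The `gaw_record` the cycles came from.
#' @param cycles A `cycle_set`.
#' @return A one-row tibble with columns `MADR`, `AMQ`, `GGI`, `PA`.
#' @export
compute_amplitude_dynamics <- function(gaw, cycles) {
  if (nrow(cycles) < 1) abort("need at least 1 cycle.")
  fs <- gaw_fs(gaw)
  madr_i <- amq_i <- numeric(nrow(cycles))
  for (i in seq_len(nrow(cycles))) {
    idx <- (round(cycles$t_start[i] * fs) + 1L):(round(cycles$t_end[i] * fs))
    d <- diff(gaw$total_area[idx])
    madr_i[i] <- min(d)
    amq_i[i] <- if (madr_i[i] < 0) cycles$dyn_range[i] / madr_i[i] else NA_real_
  }
  if (anyNA(amq_i)) warn("flat cycle(s): AMQ undefined for some cycles.")
  ggi <- mean(cycles$min_area / cycles$peak_area)
  pa <- if (all(is.finite(cycles$t_M_left)) && all(is.finite(cycles$t_M_right))) {
    mean((cycles$t_M_left - cycles$t_M_right) / cycles$T_s)
  } else {
    NA_real_
  }
  tibble(
    MADR = mean(madr_i),
    AMQ = if (all(is.na(amq_i))) NA_real_ else mean(amq_i, na.rm = TRUE),
    GGI = ggi, PA = pa
  )
}

#' Amplitude perturbation measures
#'
#' Over consecutive cycle pairs with dynamic ranges `r[i]`, `r[i+1]`:
#' Amplitude Periodicity `AP` is the mean min/max ratio; Mean Shimmer `mSH`
#' the mean absolute dB difference `|20 log10(r[i+1]/r[i])|`; the Amplitude
#' Variability Index `AVI` the dB-scaled coefficient of variation
#' `20 log10(sd(r)/mean(r))` over all cycles; and Shimmer
#' `SH = 100 * mSH / mean(20 log10(r / 1 px))` — the dB reference of 1 pixel
#' makes the denominator an absolute dB level, so SH depends on the pixel
#' calibration of the recording. Pairs touching a zero dynamic range are
#' skipped with a warning; all skipped gives `NA`.
#'
#' @param cycles A `cycle_set` (needs `>= 2` cycles).
#' @return A one-row tibble with columns `AP`, `AVI`, `mSH`, `SH`.
#' @export
#' @examples
#' compute_amplitude_perturbation(toy_cycle_set(dyn_range = c(10, 8, 10)))
compute_amplitude_perturbation <- function(cycles) {
  if (nrow(cycles) < 2) abort("need at least 2 cycles.")
  r <- cycles$dyn_range
  a <- r[-length(r)]; bb <- r[-1]
  ok <- a > 0 & bb > 0
  if (!all(ok)) warn(sprintf("%d pair(s) with zero dynamic range skipped.", sum(!ok)))
  if (!any(ok)) {
    return(tibble(AP = NA_real_, AVI = NA_real_, mSH = NA_real_, SH = NA_real_))
  }
  ap <- mean(pmin(a[ok], bb[ok]) / pmax(a[ok], bb[ok]))
  msh <- mean(abs(20 * log10(bb[ok] / a[ok])))
  avi <- if (mean(r) > 0 && sd(r) > 0) 20 * log10(sd(r) / mean(r)) else NA_real_
  mean_db <- mean(20 * log10(r[r > 0]))
  sh <- if (is.finite(mean_db) && mean_db != 0) 100 * msh / mean_db else NA_real_
  tibble(AP = ap, AVI = avi, mSH = msh, SH = sh)
}

#' Time perturbation measures
#'
#' Mean Jitter `mJT` is the mean absolute difference between consecutive
#' cycle durations in milliseconds; Jitter `JT` expresses it as a percentage
#' of the mean cycle duration.
#'
#' @param cycles A `cycle_set` (needs `>= 2` cycles).
#' @return A one-row tibble with columns `mJT` (ms), `JT` (%).
#' @export
#' @examples
#' compute_time_perturbation(toy_cycle_set(T_s = c(0.009, 0.011, 0.009)))
compute_time_perturbation <- function(cycles) {
  if (nrow(cycles) < 2) abort("need at least 2 cycles.")
  T_ms <- cycles$T_s * 1000
  mjt <- mean(abs(diff(T_ms)))
  tibble(mJT = mjt, JT = 100 * mjt / mean(T_ms))
}

# --- spectral helpers (exposed for direct testing) ---------------------------

# Power spectrum of the mean-removed, Hann-windowed analysis window,
# zero-padded to at least `pad_factor` times its length (next power of two).
# Returns positive-frequency bins, DC excluded.
gaw_power_spectrum <- function(x, fs, pad_factor = 4) {
  x <- x - mean(x)
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  nfft <- 2^ceiling(log2(pad_factor * n))
  X <- fft(c(x * w, numeric(nfft - n)))
  half <- nfft %/% 2
  power <- Mod(X[2:(half + 1)])^2
  freq <- (1:half) * fs / nfft
  list(freq = freq, power = power)
}

# Logical index of harmonic-band bins: within +/- bw * f0 of k * f0.
harmonic_bins <- function(freq, f0, bw = 0.12) {
  k_max <- floor(max(freq) / f0)
  if (k_max < 1) return(rep(FALSE, length(freq)))
  harm <- rep(FALSE, length(freq))
  for (k in seq_len(k_max)) {
    harm <- harm | abs(freq - k * f0) <= bw * f0
  }
  harm
}

# Spectral flatness in dB: 10 log10(GM / AM) of power coefficients
# (zero coefficients excluded; always <= 0).
spectral_flatness_db <- function(power) {
  p <- power[power > 0]
  if (!length(p)) return(NA_real_)
  10 * (mean(log10(p)) - log10(mean(p)))
}

# Normalized noise energy in dB with in-band noise estimation: the noise
# level inside each harmonic band is estimated from the flanking
# non-harmonic bins of the same inter-harmonic stretch and added to the
# out-of-band noise energy, then referenced to the total energy. A pure
# noise signal scores ~0 dB; a noiseless periodic signal is strongly
# negative.
nne_db <- function(freq, power, f0, bw = 0.12) {
  harm <- harmonic_bins(freq, f0, bw)
  e_total <- sum(power)
  if (e_total <= 0) return(NA_real_)
  e_out <- sum(power[!harm])
  k_max <- floor(max(freq) / f0)
  e_in_est <- 0
  for (k in seq_len(k_max)) {
    in_band <- abs(freq - k * f0) <= bw * f0
    flank <- !harm & abs(freq - k * f0) <= 0.5 * f0
    if (any(in_band)) {
      level <- if (any(flank)) mean(power[flank]) else 0
      e_in_est <- e_in_est + level * sum(in_band)
    }
  }
  10 * log10((e_out + e_in_est) / e_total)
}

#' Spectral noise measures of the GAW
#'
#' Computes the four frequency-space parameters on the analysis window
#' (mean-removed, Hann-windowed, zero-padded discrete Fourier transform;
#' positive frequencies, DC excluded). Bins within `+/- harm_bw * F0` of
#' each harmonic `k * F0` form the harmonic energy `E_harm`; the remainder
#' is the noise energy `E_noise = E_total - E_harm` (the partition is exact).
#' Harmonic Intensity `HI = 100 * E_harm / E_total` (%),
#' Harmonics-to-Noise Ratio `HNR = 10 log10(E_harm / E_noise)` dB (capped at
#' +/- 120 dB with a warning when one side vanishes), Spectral Flatness
#' `SPF = 10 log10(GM / AM)` of the power coefficients (dB, `<= 0`), and
#' Normalized Noise Energy `NNE` (dB) referenced to the total energy, with
#' the in-band noise level estimated from the flanking non-harmonic bins —
#' so pure noise scores near 0 dB.
#'
#' @param gaw A `gaw_record`.
#' @param cycles A `cycle_set` locating the analysis window and supplying F0.
#' @param harm_bw Harmonic half-bandwidth as a fraction of F0.
#' @param pad_factor Zero-padding factor for the DFT.
#' @return A one-row tibble with columns `HI`, `HNR`, `NNE`, `SPF`.
#' @export
compute_spectral_noise <- function(gaw, cycles, harm_bw = 0.12,
                                   pad_factor = 4) {
  fs <- gaw_fs(gaw)
  i0 <- round(cycles$t_start[1] * fs) + 1L
  i1 <- round(cycles$t_end[nrow(cycles)] * fs)
  x <- gaw$total_area[i0:i1]
  f0 <- attr(cycles, "f0_hz") %||% estimate_f0(cycles)
  ps <- gaw_power_spectrum(x, fs, pad_factor)
  harm <- harmonic_bins(ps$freq, f0, harm_bw)
  e_total <- sum(ps$power)
  e_harm <- sum(ps$power[harm])
  e_noise <- e_total - e_harm
  hi <- 100 * e_harm / e_total
  hnr <- if (e_noise <= 0) {
    warn("noise energy is zero; HNR capped at +120 dB.")
    120
  } else if (e_harm <= 0) {
    warn("harmonic energy is zero; HNR capped at -120 dB.")
    -120
  } else {
    min(max(10 * log10(e_harm / e_noise), -120), 120)
  }
  tibble(
    HI = hi, HNR = hnr,
    NNE = nne_db(ps$freq, ps$power, f0, harm_bw),
    SPF = spectral_flatness_db(ps$power)
  )
}

#' Compute all twenty GAW parameters
#'
#' Runs every parameter family on one GAW at one frame rate and assembles a
#' single tidy row. Component failures never abort: the affected fields are
#' set to `NA` and the reason is recorded in the `undefined` column (e.g.
#' `"PA:missing_halves"`).
#'
#' @param gaw A `gaw_record`.
#' @param cycles Optional `cycle_set`; detected from `gaw` when omitted.
#' @param closure_threshold_rel,max_cycles Passed to [detect_cycles()] when
#'   `cycles` is omitted.
#' @param harm_bw,pad_factor Passed to [compute_spectral_noise()].
#' @return A one-row tibble with the twenty parameter columns (in
#'   [gaw_parameter_names()] order) plus `fps`, `n_cycles_used` and
#'   `undefined`.
#' @export
#' @examples
#' gaw <- generate_gaw(kinematic_params(n_cycles = 12))
#' compute_gaw_parameters(gaw, closure_threshold_rel = 0.01)
compute_gaw_parameters <- function(gaw, cycles = NULL,
                                   closure_threshold_rel = 0,
                                   max_cycles = 106,
                                   harm_bw = 0.12, pad_factor = 4) {
  reasons <- character(0)
  note <- function(fields, why) {
    reasons <<- c(reasons, paste0(fields, ":", why))
  }
  na_row <- function(nms) {
    stats::setNames(as.list(rep(NA_real_, length(nms))), nms)
  }
  if (is.null(cycles)) {
    cycles <- tryCatch(
      detect_cycles(gaw, closure_threshold_rel, max_cycles),
      error = function(e) NULL
    )
  }
  if (is.null(cycles) || nrow(cycles) < 2) {
    vals <- na_row(GAW_PARAMETER_NAMES)
    note("all", "no_oscillation")
    return(as_tibble(c(vals, list(
      fps = gaw_fs(gaw), n_cycles_used = 0L,
      undefined = paste(reasons, collapse = ";")
    ))))
  }
  grab <- function(expr, nms, why) {
    out <- tryCatch(suppressWarnings(expr), error = function(e) NULL)
    if (is.null(out)) {
      note(nms, why)
      return(na_row(nms))
    }
    bad <- nms[vapply(out[nms], function(v) is.na(v), logical(1))]
    if (length(bad)) note(bad, why)
    as.list(out[nms])
  }
  tq <- grab(compute_time_quotients(cycles),
             c("OQ", "CQ", "RQ", "SQ", "ASQ", "SI"), "degenerate_cycles")
  ad <- grab(compute_amplitude_dynamics(gaw, cycles),
             c("MADR", "AMQ", "GGI", "PA"),
             if (all(c("left_area", "right_area") %in% names(gaw)))
               "flat_cycle" else "missing_halves")
  ap <- grab(compute_amplitude_perturbation(cycles),
             c("AP", "AVI", "mSH", "SH"), "zero_dyn_range")
  tp <- grab(compute_time_perturbation(cycles), c("mJT", "JT"), "too_few_cycles")
  sn <- grab(compute_spectral_noise(gaw, cycles, harm_bw, pad_factor),
             c("HI", "HNR", "NNE", "SPF"), "degenerate_spectrum")
  vals <- c(tq, ad, ap, tp, sn)[GAW_PARAMETER_NAMES]
  as_tibble(c(vals, list(
    fps = gaw_fs(gaw),
    n_cycles_used = nrow(cycles),
    undefined = paste(unique(reasons), collapse = ";")
  )))
}

#' Compute parameters across a rate sweep
#'
#' Maps [compute_gaw_parameters()] over the rows of a [build_sweep()] table
#' and returns the long parameter-by-rate-by-recording table used by the
#' stability analysis.
#'
#' @param sweep A tibble from [build_sweep()].
#' @inheritParams compute_gaw_parameters
#' @return A tibble with columns `recording_id`, `fps`, `parameter`, `value`.
#' @export
sweep_parameters <- function(sweep, closure_threshold_rel = 0,
                             max_cycles = 106, harm_bw = 0.12,
                             pad_factor = 4) {
  wide <- purrr::pmap(sweep, function(recording_id, fps, gaw) {
    row <- compute_gaw_parameters(gaw,
      closure_threshold_rel = closure_threshold_rel,
      max_cycles = max_cycles, harm_bw = harm_bw, pad_factor = pad_factor)
    dplyr::mutate(row, recording_id = recording_id, .before = 1)
  })
  dplyr::bind_rows(wide) |>
    tidyr::pivot_longer(dplyr::all_of(GAW_PARAMETER_NAMES),
                        names_to = "parameter", values_to = "value") |>
    dplyr::select("recording_id", "fps", "parameter", "value")
}

#' Toy cycle set for examples and tests
#'
#' Builds a minimal `cycle_set` tibble directly from per-cycle landmark
#' durations, bypassing detection — handy for worked examples with
#' hand-computable parameter values.
#'
#' @param T_s Period(s) in seconds (recycled to the longest argument).
#' @param open_s,opening_s,closing_s Phase durations in seconds.
#' @param dyn_range,peak_area,min_area Areas in pixels.
#' @param t_M_left,t_M_right Half-waveform peak times in seconds.
#' @param fs_fps Nominal frame rate attribute.
#' @return A `cycle_set` tibble.
#' @export
toy_cycle_set <- function(T_s = 0.01, open_s = T_s, opening_s = open_s / 2,
                          closing_s = open_s - opening_s,
                          dyn_range = 100, peak_area = 100,
                          min_area = peak_area - dyn_range,
                          t_M_left = NA_real_, t_M_right = NA_real_,
                          fs_fps = 1000) {
  n <- max(lengths(list(T_s, open_s, opening_s, closing_s, dyn_range)))
  cs <- tibble(
    T_s = rep_len(T_s, n), open_s = rep_len(open_s, n),
    opening_s = rep_len(opening_s, n), closing_s = rep_len(closing_s, n),
    dyn_range = rep_len(dyn_range, n), peak_area = rep_len(peak_area, n),
    min_area = rep_len(min_area, n),
    t_M_left = rep_len(t_M_left, n), t_M_right = rep_len(t_M_right, n)
  )
  cs$closed_s <- cs$T_s - cs$open_s
  cs$t_start <- cumsum(c(0, cs$T_s[-n]))
  cs$t_end <- cs$t_start + cs$T_s
  cs$peak_time <- cs$t_start + cs$opening_s
  structure(cs, fs_fps = fs_fps, f0_hz = 1 / mean(cs$T_s), n_used = n,
            class = c("cycle_set", class(cs)))
}
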