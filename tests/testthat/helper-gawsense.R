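# Shared fixtures, built in code.

# Small, fast, noiseless synthetic recording for landmark tests.
quiet_params <- function(...) {
  kinematic_params(noise_sd = 0, jitter_ms = 0, shimmer_db = 0,
                   phase_asym = 0, ...)
}

# Long-table of i.i.d. noise shaped like a sweep (null model for the
# stability statistics).
null_sweep_table <- function(n_rec = 20, rates = seq(1000, 15000, 1000),
                             params = "p1") {
  tbl <- tidyr::expand_grid(
    recording_id = sprintf("r%02d", seq_len(n_rec)),
    fps = rates,
    parameter = params
  )
  tbl$value <- rnorm(nrow(tbl))
  tbl
}

# Symmetric significance matrix from a set of (i, j) pairs.
sig_matrix <- function(k, pairs = list()) {
  m <- matrix(FALSE, k, k)
  for (p in pairs) m[p[1], p[2]] <- m[p[2], p[1]] <- TRUE
  m
}
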