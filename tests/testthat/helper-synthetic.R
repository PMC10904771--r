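# shared builders for small synthetic inputs

# triangle AP: rises from base to peak over `rise` ms, falls over `fall` ms
triangle_vm <- function(base = -80, peak = 20, rise = 1, fall = 1,
                        t_start = 2, dt = 0.01, total = 8) {
  tt <- seq(0, total, by = dt)
  v <- rep(base, length(tt))
  up <- tt >= t_start & tt < t_start + rise
  v[up] <- base + (peak - base) * (tt[up] - t_start) / rise
  dn <- tt >= t_start + rise & tt <= t_start + rise + fall
  v[dn] <- peak - (peak - base) * (tt[dn] - (t_start + rise)) / fall
  vm_trace(v, dt = dt, t0 = 0)
}

# two-band movie: pixels in [0, split) um get value a, [split, len) get b
two_band_movie <- function(a = 1, b = 3, split = 20, len = 40,
                           n_frames = 10, dt = 0.1) {
  px <- seq_len(len)
  vals <- ifelse((px - 0.5) < split, a, b)
  fluor_movie(matrix(rep(vals, each = n_frames), nrow = n_frames),
              um_per_px = 1, dt = dt)
}

# noiseless sum-of-logistics trace on an 8 ms, 10 kHz grid
na_truth_trace <- function(amps, t_half, tau, dt = 0.1, total = 8) {
  tt <- seq(0, total, by = dt)
  f <- numeric(length(tt))
  for (i in seq_along(amps)) {
    f <- f + amps[i] * stats::plogis((tt - t_half[i]) / tau[i])
  }
  time_series(f, dt = dt, t0 = 0)
}

default_toxin <- function() {
  toxin_model(ec50 = 30, hill_n = 1.5, slowdown = 2.4,
              persistent_frac = 0.15)
}
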