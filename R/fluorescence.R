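#' Fluorescence forward model
#'
#' Maps a noise-free ground-truth signal to raw camera counts:
#' `F(t) = f0 * bleach(t) * (1 + gain * truth(t) / f0) + noise`, where
#' `bleach(t) = (1 - sum(amps)) + sum(amps * exp(-t / taus))` equals 1 at
#' t = 0. All randomness in the package's synthetic data flows from `seed`.
#'
#' @param f0 Baseline fluorescence, camera counts (> 0).
#' @param gain Counts per unit ground-truth signal (per mV for a voltage
#'   indicator, per unit influx for ion indicators).
#' @param bleach_amps,bleach_taus Multi-exponential bleaching amplitudes
#'   (fractions of f0) and time constants (ms, > 0); equal lengths.
#' @param noise_sd Additive Gaussian noise SD, counts.
#' @param frame_khz Acquisition frame rate, kHz (20 for the voltage
#'   indicator, 10 for ion indicators).
#' @param seed Integer RNG seed.
#' @return An object of class `axf_fwd`.
#' @export
fluor_forward_model <- function(f0 = 1000, gain = 2,
                                bleach_amps = c(0.03, 0.01),
                                bleach_taus = c(300, 40),
                                noise_sd = 2, frame_khz = 10, seed = 1L) {
  stopifnot(
    f0 > 0, noise_sd >= 0, frame_khz > 0,
    length(bleach_amps) == length(bleach_taus),
    all(bleach_taus > 0)
  )
  structure(
    list(f0 = f0, gain = gain, bleach_amps = as.numeric(bleach_amps),
         bleach_taus = as.numeric(bleach_taus), noise_sd = noise_sd,
         frame_khz = frame_khz, seed = as.integer(seed)),
    class = "axf_fwd"
  )
}

# bleach factor at times t (ms); equals 1 at t = 0
bleach_curve <- function(t, amps, taus) {
  b <- rep(1 - sum(amps), length(t))
  for (k in seq_along(amps)) b <- b + amps[k] * exp(-t / taus[k])
  b
}

# run expr with a private, seeded RNG stream; restores global RNG state
with_private_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# resample a trace to frame_khz by block-averaging; requires integer ratio
resample_to_frames <- function(x, frame_khz) {
  dt_frame <- 1 / frame_khz
  ratio <- dt_frame / x$dt
  if (ratio < 1 - 1e-9) {
    stop("frame rate exceeds the sampling rate of the ground-truth trace")
  }
  r <- round(ratio)
  if (abs(ratio - r) > 1e-6) {
    stop("frame interval must be an integer multiple of the truth dt")
  }
  if (r == 1L) return(x)
  n_frames <- floor(length(x$values) / r)
  v <- colMeans(matrix(x$values[seq_len(n_frames * r)], nrow = r))
  time_series(v, dt = dt_frame, t0 = x$t0 + (r - 1) * x$dt / 2,
              units = x$units)
}

#' Render raw fluorescence trials from a ground-truth trace
#'
#' Applies the forward model to a noise-free ground-truth signal, producing
#' `n_trials` independently noisy trials plus the same number of matching
#' signal-free ("dark") trials, which carry only bleaching and noise and are
#' the input for [fit_bleach()]. Identical seeds give bitwise-identical
#' output.
#'
#' @param truth An `axf_ts` ground-truth signal (sampled at least as fast as
#'   `fwd$frame_khz`).
#' @param fwd A [fluor_forward_model()].
#' @param n_trials Number of trials (>= 1).
#' @return List with `trials` and `dark`, each a list of `axf_ts` traces in
#'   camera counts, plus `truth_frames`, the resampled noise-free truth.
#' @export
render_fluorescence <- function(truth, fwd, n_trials = 5L) {
  stopifnot(inherits(truth, "axf_ts"), inherits(fwd, "axf_fwd"),
            n_trials >= 1L)
  tf <- resample_to_frames(truth, fwd$frame_khz)
  t_rel <- ts_time(tf) - tf$t0
  bl <- bleach_curve(t_rel, fwd$bleach_amps, fwd$bleach_taus)
  clean <- fwd$f0 * bl * (1 + fwd$gain * tf$values / fwd$f0)
  dark_clean <- fwd$f0 * bl
  n <- length(clean)
  with_private_rng(fwd$seed, {
    trials <- lapply(seq_len(n_trials), function(i) {
      ts_with_values(tf, clean + stats::rnorm(n, sd = fwd$noise_sd))
    })
    dark <- lapply(seq_len(n_trials), function(i) {
      ts_with_values(tf, dark_clean + stats::rnorm(n, sd = fwd$noise_sd))
    })
    list(trials = trials, dark = dark,
         truth_frames = ts_with_values(tf, clean))
  })
}

#' Synthetic fluorescence movie of an axon
#'
#' A movie is a frames-by-pixels matrix with a linear axial coordinate:
#' pixel `j` sits at `(j - 1) * um_per_px` um from the soma edge. This
#' builder paints one band of pixels per simulated compartment (nearest
#' compartment by axial distance) so that ROI extraction over the movie can
#' be checked against the per-compartment ground truth.
#'
#' @param signal Matrix (time x compartments) of per-compartment values.
#' @param positions Compartment positions, um.
#' @param dt Frame interval, ms.
#' @param um_per_px Axial size of one pixel, um.
#' @param axon_um Total axial extent covered by pixels, um.
#' @param t0 Time of first frame, ms.
#' @return An object of class `axf_movie`: list with `frames` (time x
#'   pixels), `um_per_px`, `dt`, `t0`.
#' @export
synth_movie <- function(signal, positions, dt, um_per_px = 1,
                        axon_um = max(positions), t0 = 0) {
  stopifnot(is.matrix(signal), ncol(signal) == length(positions))
  px_pos <- seq(0, axon_um - um_per_px, by = um_per_px) + um_per_px / 2
  nearest <- vapply(px_pos, function(p) which.min(abs(positions - p)),
                    integer(1))
  structure(
    list(frames = signal[, nearest, drop = FALSE],
         um_per_px = um_per_px, dt = dt, t0 = t0),
    class = "axf_movie"
  )
}

#' @rdname synth_movie
#' @param frames Time-by-pixels matrix of raw values.
#' @export
fluor_movie <- function(frames, um_per_px, dt, t0 = 0) {
  stopifnot(is.matrix(frames), um_per_px > 0, dt > 0)
  structure(list(frames = frames, um_per_px = um_per_px, dt = dt, t0 = t0),
            class = "axf_movie")
}

#' Write / read a movie as a TIFF stack
#'
#' Frames are written as a multi-page grayscale TIFF (one page per frame),
#' scaled to `[0, 1]` by `scale`; metadata (`um_per_px`, `dt`, `t0`,
#' `scale`) goes to a YAML sidecar so the round trip is lossless up to the
#' 16-bit quantisation of the TIFF writer.
#'
#' @param movie An `axf_movie`.
#' @param path Output TIFF path; the sidecar is `<path>.yaml`.
#' @param scale Divisor mapping counts to `[0, 1]`.
#' @return `path`, invisibly (writer); an `axf_movie` (reader).
#' @export
write_movie_tiff <- function(movie, path, scale = max(movie$frames)) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF export")
  }
  stopifnot(inherits(movie, "axf_movie"), scale > 0)
  pages <- lapply(seq_len(nrow(movie$frames)), function(i) {
    matrix(pmin(pmax(movie$frames[i, ] / scale, 0), 1), nrow = 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(
    list(um_per_px = movie$um_per_px, dt = movie$dt, t0 = movie$t0,
         scale = scale),
    paste0(path, ".yaml")
  )
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF import")
  }
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- do.call(rbind, lapply(pages, function(p) as.numeric(t(p))))
  fluor_movie(frames * meta$scale, um_per_px = meta$um_per_px,
              dt = meta$dt, t0 = meta$t0)
}
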