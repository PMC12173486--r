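#' Synthetic triceps-surae gait force profile
#'
#' A smooth, non-negative, single-peaked total-force curve over the gait
#' cycle emulating musculoskeletal-model triceps-surae force estimates
#' during walking: zero at the cycle boundaries, rising through stance
#' to a single late-stance peak.  The shape is a normalised beta-like
#' bump `(t/p)^(k p) ((1-t)/(1-p))^(k (1-p))`, which peaks exactly at
#' `t = p`.  The curve is fully deterministic; `seed` is accepted for
#' interface uniformity but unused.
#'
#' The default peak force (3300 N) produces a peak uniform tendon stress
#' of about 30 MPa over the default distal cross-section -- a
#' physiological peak Achilles load during walking.
#'
#' @param n number of gait increments (>= 2; default 100, one percent
#'   steps).
#' @param peak_force peak total force, N.
#' @param peak_location peak position as a fraction of the cycle
#'   (default 0.45, late stance).
#' @param sharpness shape exponent scale (larger = narrower peak).
#' @param seed unused (determinism is unconditional).
#' @return a [gait_profile()] with attribute `increment_fraction`.
#' @export
synth_gait_profile <- function(n = 100, peak_force = 3300,
                               peak_location = 0.45, sharpness = 6,
                               seed = NULL) {
  if (n < 2) stop("'n' must be >= 2")
  if (peak_force < 0) stop("'peak_force' must be >= 0")
  if (peak_location <= 0 || peak_location >= 1)
    stop("'peak_location' must lie in (0, 1)")
  t <- seq_len(n) / (n + 1)
  p <- peak_location
  shape <- (t / p)^(sharpness * p) * ((1 - t) / (1 - p))^(sharpness * (1 - p))
  prof <- gait_profile(peak_force * shape / max(shape))
  attr(prof, "increment_fraction") <- t
  prof
}

#' Synthetic plane-wave spatiotemporal map with known ground truth
#'
#' Constructs `u(x, t) = pulse(t - x/c)` -- a forward
#' (distal-to-proximal) travelling half-sine pulse at a known speed --
#' plus an optional backward reflection from the far end scaled by
#' `reflection`, plus seeded Gaussian noise at a stated signal-to-noise
#' ratio (SNR defined as `20 log10(signal RMS / noise RMS)` in dB).
#' Validation fixture for the Radon estimator and directional filter;
#' the ground-truth speed travels with the object.
#'
#' @param true_speed wave speed, m s^-1 (> 0).
#' @param dx,dt sample spacings, m and s.
#' @param n_x,n_t numbers of position and time samples.
#' @param reflection reflection coefficient in \[0, 1\].
#' @param snr_db signal-to-noise ratio in dB (`Inf` = noiseless).
#' @param pulse_width temporal half-sine pulse width, s.
#' @param seed RNG seed for the noise (required when `snr_db` is
#'   finite); maps are reproducible given the seed.
#' @return a [spatiotemporal_map()] with `meta$true_speed` and the full
#'   generation spec in `meta`.
#' @export
synth_plane_wave_map <- function(true_speed, dx = 1e-3, dt = 1e-5,
                                 n_x = 64, n_t = 100, reflection = 0,
                                 snr_db = Inf, pulse_width = 250e-6,
                                 seed = NULL) {
  if (true_speed <= 0) stop("'true_speed' must be > 0")
  if (reflection < 0 || reflection > 1)
    stop("'reflection' must lie in [0, 1]")
  pulse <- function(t) ifelse(t >= 0 & t <= pulse_width,
                              sin(pi * t / pulse_width), 0)
  x <- (seq_len(n_x) - 1) * dx
  tt <- (seq_len(n_t) - 1) * dt
  L <- x[n_x]
  u <- outer(x, tt, function(x, t) pulse(t - x / true_speed))
  if (reflection > 0)
    u <- u + reflection *
      outer(x, tt, function(x, t) pulse(t - (2 * L - x) / true_speed))
  if (is.finite(snr_db)) {
    if (is.null(seed)) stop("'seed' is required for noisy maps")
    sig_rms <- sqrt(mean(u^2))
    noise_sd <- sig_rms / 10^(snr_db / 20)
    old <- .Random.seed_exists()
    on.exit(old(), add = TRUE)
    set.seed(seed)
    u <- u + matrix(stats::rnorm(n_x * n_t, sd = noise_sd), n_x, n_t)
  }
  spatiotemporal_map(u, dx, dt, meta = list(
    true_speed = true_speed, reflection = reflection, snr_db = snr_db,
    pulse_width = pulse_width, seed = if (is.null(seed)) NA else seed,
    synthetic = TRUE))
}

# save/restore the global RNG state so fixture generation is hermetic
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}
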