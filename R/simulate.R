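#' Configuration for the synthetic sEMG / force simulator
#'
#' Defines a simulated multi-muscle isometric recording: each muscle has a
#' slow nonnegative activation profile (up-down force ramps through the MVC
#' levels, a sway-like low-frequency drift, or a constant level), each
#' channel is that profile amplitude-modulating an independent band-limited
#' stochastic carrier, and the force target follows the log-linear model of
#' the true profiles plus white measurement noise. All stages are
#' deterministic given `seed`.
#'
#' @param n_muscles number of muscles (default 4, an upper-limb-like set).
#' @param n_channels_per_muscle channels per muscle array (default 3).
#' @param fs sampling rate in Hz (default 2048).
#' @param duration_s record length in seconds (default 25, a series of slow
#'   up-down ramps; `fs * duration_s`
#'   must be at least 100).
#' @param carrier_band_hz band of the sEMG carrier, default `c(15, 450)` Hz.
#' @param carrier_dist `"laplacian"` (default; matches the heavy-tailed
#'   amplitude statistics of voluntary sEMG) or `"gaussian"`.
#' @param profile `"ramp"` (default), `"sway"`, or `"constant"`.
#' @param mvc_levels ramp peak levels as fractions of MVC, default
#'   `c(0.3, 0.5, 0.7)`.
#' @param baseline resting activation level, default 0.05 MVC (keeps the
#'   log model away from the silent-muscle floor).
#' @param true_weights generative weights `(w0, w1..wM)`; default intercept 1
#'   and per-muscle weights `2.5, 2.0, 1.5, ...` decreasing by 0.5 (floored
#'   at 0.5).
#' @param noise_sd force noise SD as a fraction of the noise-free force
#'   range, default 0.05.
#' @param seed integer root seed.
#' @return A list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(n_muscles = 4L, n_channels_per_muscle = 3L,
                            fs = 2048, duration_s = 25,
                            carrier_band_hz = c(15, 450),
                            carrier_dist = c("laplacian", "gaussian"),
                            profile = c("ramp", "sway", "constant"),
                            mvc_levels = c(0.3, 0.5, 0.7),
                            baseline = 0.05,
                            true_weights = NULL,
                            noise_sd = 0.05, seed = 1L) {
  carrier_dist <- match.arg(carrier_dist)
  profile <- match.arg(profile)
  stopifnot(n_muscles >= 1L, n_channels_per_muscle >= 1L, fs > 0,
            duration_s * fs >= 100, noise_sd >= 0, baseline > 0)
  if (carrier_band_hz[1L] <= 0 || carrier_band_hz[2L] >= fs / 2 ||
      carrier_band_hz[2L] <= carrier_band_hz[1L])
    stop("carrier band must lie strictly inside (0, fs/2)", call. = FALSE)
  if (is.null(true_weights))
    true_weights <- c(1, pmax(2.5 - 0.5 * (seq_len(n_muscles) - 1L), 0.5))
  if (length(true_weights) != n_muscles + 1L)
    stop("`true_weights` must have length n_muscles + 1", call. = FALSE)
  structure(list(n_muscles = as.integer(n_muscles),
                 n_channels_per_muscle = as.integer(n_channels_per_muscle),
                 fs = fs, duration_s = duration_s,
                 carrier_band_hz = carrier_band_hz,
                 carrier_dist = carrier_dist, profile = profile,
                 mvc_levels = mvc_levels, baseline = baseline,
                 true_weights = as.numeric(true_weights),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' Per-muscle activation profiles
#'
#' Generates the slow nonnegative activation profile of each muscle. Ramp
#' mode cycles through the configured MVC levels with triangular up-down
#' ramps above the baseline; each muscle's cycle is phase-shifted so the
#' regressors of different muscles are not collinear. Sway mode low-pass
#' filters (0.5 Hz) a seeded random walk and rescales it between baseline
#' and the highest MVC level. Constant mode holds the first MVC level.
#'
#' @param config a [syntheticConfig()].
#' @return Numeric matrix, `N` samples x `n_muscles`, all values > 0.
#' @export
generateProfile <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  N <- as.integer(round(config$fs * config$duration_s))
  M <- config$n_muscles
  set.seed(config$seed)
  P <- matrix(config$baseline, N, M)
  if (config$profile == "constant") {
    P[] <- config$mvc_levels[1L]
    return(P)
  }
  if (config$profile == "ramp") {
    levels <- config$mvc_levels
    cycle <- unlist(lapply(levels, function(lv) {
      half <- max(2L, as.integer(round(N / (2L * length(levels)) / 2L)) * 2L)
      up <- seq(config$baseline, lv, length.out = half)
      c(up, rev(up))
    }))
    for (i in seq_len(M)) {
      shift <- as.integer(round((i - 1L) * length(cycle) / (2L * M)))
      tiled <- rep_len(c(utils::tail(cycle, shift), cycle,
                         rep(cycle, ceiling(N / length(cycle)))), N)
      P[, i] <- tiled
    }
    return(P)
  }
  # sway: random-phase multisine below 0.5 Hz with 1/f amplitude weighting
  # (postural-sway-like slow drift), rescaled to [baseline, max level]
  top <- max(config$mvc_levels)
  t <- seq_len(N) / config$fs
  freqs <- seq(0.03, 0.45, by = 0.03)
  for (i in seq_len(M)) {
    ph <- stats::runif(length(freqs), 0, 2 * pi)
    sm <- colSums((1 / freqs) * sin(2 * pi * outer(freqs, t) + ph))
    rngw <- range(sm)
    P[, i] <- config$baseline +
      (top - config$baseline) * (sm - rngw[1L]) / diff(rngw)
  }
  P
}

#' White carrier innovations of a given amplitude distribution
#'
#' Unit-variance white noise used as the sEMG carrier before band-limiting:
#' Gaussian, or Laplacian (excess kurtosis 3) as voluntary sEMG amplitude
#' statistics suggest. Note that band-pass filtering mixes samples and pulls
#' the filtered carrier back toward Gaussian, so the distribution switch is
#' observable on these innovations, not on the filtered signal.
#'
#' @param n number of samples.
#' @param dist `"laplacian"` or `"gaussian"`.
#' @return Numeric vector with unit variance in expectation.
#' @export
carrierNoise <- function(n, dist = c("laplacian", "gaussian")) {
  dist <- match.arg(dist)
  if (dist == "gaussian") stats::rnorm(n)
  else {
    u <- stats::runif(n, -0.5, 0.5)
    -sign(u) * log(1 - 2 * abs(u)) / sqrt(2)   # unit-variance Laplace
  }
}

#' Synthetic multi-channel sEMG
#'
#' Builds each channel as `profile(t) * carrier(t)`, where the carrier is
#' white noise of the configured distribution band-pass filtered to the
#' carrier band and normalized to unit RMS. Channels of one muscle share the
#' profile but carry independent carriers.
#'
#' @param config a [syntheticConfig()].
#' @param profiles optional profile matrix from [generateProfile()] (computed
#'   from `config` when omitted).
#' @return List of per-muscle [signalMatrix()] objects (muscle ids
#'   `"m1"`, `"m2"`, ...).
#' @export
generateEmg <- function(config, profiles = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (is.null(profiles)) profiles <- generateProfile(config)
  N <- nrow(profiles)
  bp <- filterSpec("bandpass", 4L, config$carrier_band_hz, zero_lag = TRUE)
  set.seed(config$seed + 1L)
  lapply(seq_len(config$n_muscles), function(i) {
    ch <- vapply(seq_len(config$n_channels_per_muscle), function(j) {
      w <- carrierNoise(N, config$carrier_dist)
      carrier <- as.numeric(unclass(
        butterworthFilter(signalMatrix(w, config$fs), bp)))
      carrier <- carrier / sqrt(mean(carrier^2))
      profiles[, i] * carrier
    }, numeric(N))
    signalMatrix(matrix(ch, nrow = N), config$fs, muscle_id = paste0("m", i))
  })
}

#' Synthetic force target
#'
#' Generates the force from the log-linear model of the true activation
#' profiles: `f(t) = w0 + sum_i wi * ln(max(profile_i, eps))`, plus white
#' Gaussian noise with SD equal to `noise_sd` times the noise-free force
#' range. `eps` is the same relative floor the fitter uses, so the
#' generative and fitted model classes coincide.
#'
#' @param config a [syntheticConfig()].
#' @param profiles profile matrix from [generateProfile()].
#' @return One-channel [signalMatrix()] of force.
#' @export
generateForce <- function(config, profiles = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (is.null(profiles)) profiles <- generateProfile(config)
  eps <- 1e-8 * max(profiles)
  w <- config$true_weights
  f <- rep(w[1L], nrow(profiles))
  for (i in seq_len(config$n_muscles))
    f <- f + w[i + 1L] * log(pmax(profiles[, i], eps))
  set.seed(config$seed + 2L)
  if (config$noise_sd > 0) {
    rngf <- diff(range(f))
    if (rngf == 0) rngf <- max(abs(f), 1)
    f <- f + stats::rnorm(length(f), 0, config$noise_sd * rngf)
  }
  signalMatrix(f, config$fs)
}

#' Assemble a complete synthetic dataset
#'
#' Composes profiles, sEMG and force into one object carrying the
#' ground-truth weights, and optionally writes it in the delimited on-disk
#' layout (see [writeDataset()]).
#'
#' @param config a [syntheticConfig()].
#' @param dir optional directory; when given the dataset and its manifest
#'   are written there.
#' @return A list of class `SyntheticDataset`: `emg` (per-muscle
#'   `SignalMatrix`), `true_envelopes` (per-muscle [envelope()] of the
#'   profiles), `force`, `epsilon_floor` and the `config`.
#' @export
makeDataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  profiles <- generateProfile(config)
  emg <- generateEmg(config, profiles)
  force <- generateForce(config, profiles)
  true_env <- lapply(seq_len(config$n_muscles), function(i)
    envelope(profiles[, i], config$fs, paste0("m", i)))
  ds <- structure(list(emg = emg, true_envelopes = true_env, force = force,
                       epsilon_floor = 1e-8 * max(profiles),
                       config = config),
                  class = "SyntheticDataset")
  if (!is.null(dir)) writeDataset(ds, dir)
  ds
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat(sprintf("SyntheticDataset: %d muscle(s) x %d channel(s), %d samples @ %g Hz, %s profile, %s carrier\n",
              x$config$n_muscles, x$config$n_channels_per_muscle,
              nSamples(x$force), x$config$fs, x$config$profile,
              x$config$carrier_dist))
  invisible(x)
}
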