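#' Butterworth filtering of sampled signals
#'
#' Applies a Butterworth filter channel-wise. With `zero_lag = TRUE` in the
#' spec the filter runs forward and then backward over the signal, so the net
#' phase response is zero and the magnitude response of the stated-order
#' design is squared. Startup transients are suppressed by odd-reflection
#' padding of length `3 * (order + 1)` samples at both ends before the
#' two-pass filtering; the padding is discarded afterwards.
#'
#' @param sig a [signalMatrix()].
#' @param spec a [filterSpec()], validated against `samplingRate(sig)`.
#' @return A `SignalMatrix` of the same shape, fs and labels.
#' @seealso [estimateEnvelope()], [conditionForce()], [bandpassPreset()]
#' @export
butterworthFilter <- function(sig, spec) {
  if (!inherits(sig, "SignalMatrix")) stop("`sig` must be a SignalMatrix", call. = FALSE)
  fs <- samplingRate(sig)
  validateSpecFs(spec, fs)
  wn <- spec$cutoffs_hz / (fs / 2)
  bt <- signal::butter(spec$order, wn,
                       type = if (spec$kind == "lowpass") "low" else "pass")
  out <- apply(unclass(sig), 2L, function(ch) {
    if (spec$zero_lag) filtfiltReflect(bt$b, bt$a, ch, spec$order)
    else as.numeric(signal::filter(bt$b, bt$a, ch))
  })
  out <- matrix(out, nrow = nrow(sig))
  signalMatrix(out, fs, channel_labels = attr(sig, "channel_labels"),
               muscle_id = muscleId(sig))
}

# forward-backward IIR filtering with odd-reflection end padding
# (length 3*(order+1); short signals fall back to the longest feasible pad)
# and steady-state filter initialisation at the first padded value, so a
# 2 Hz smoother does not spend its long time constant climbing from zero.
filtfiltReflect <- function(b, a, x, order) {
  n <- length(x)
  np <- min(3L * (order + 1L), n - 1L)
  if (np > 0L) {
    head_pad <- 2 * x[1L] - x[seq(np + 1L, 2L, by = -1L)]
    tail_pad <- 2 * x[n] - x[seq(n - 1L, n - np, by = -1L)]
    xp <- c(head_pad, x, tail_pad)
  } else xp <- x
  dc <- sum(b) / sum(a)
  nstate <- length(a) - 1L
  # filter memory: samples until the slowest pole has decayed to 1%
  pr <- max(abs(polyroot(rev(a))))
  mem <- if (pr >= 1) length(xp) else min(length(xp),
                                          ceiling(log(0.01) / log(pr)))
  # steady-state level at each record edge: local linear trend extrapolated
  # to the boundary — exact for smooth signals, the local mean for noisy
  # (e.g. rectified) ones
  edgeLevel <- function(z) {
    w <- max(2L, min(length(z), mem))
    zz <- z[seq_len(w)]
    tt <- seq_len(w)
    fit <- stats::lm.fit(cbind(1, tt), zz)$coefficients
    fit[1L]   # intercept: level just before sample 1
  }
  onePass <- function(z) {
    lev <- edgeLevel(z)
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(lev, nstate),
                              init.y = rep(lev * dc, nstate)))
  }
  y <- onePass(xp)
  y <- rev(onePass(rev(y)))
  if (np > 0L) y[(np + 1L):(np + n)] else y
}

#' Full-wave rectification
#'
#' Elementwise absolute value of the sEMG signal — the first stage of envelope
#' extraction.
#'
#' @param sig a [signalMatrix()].
#' @return A `SignalMatrix` of |x|, same shape and metadata.
#' @export
fullWaveRectify <- function(sig) {
  if (!inherits(sig, "SignalMatrix")) stop("`sig` must be a SignalMatrix", call. = FALSE)
  signalMatrix(abs(unclass(sig)), samplingRate(sig),
               channel_labels = attr(sig, "channel_labels"),
               muscle_id = muscleId(sig))
}

#' Per-channel sEMG envelope
#'
#' Full-wave rectifies each channel and smooths it with a zero-lag
#' second-order Butterworth low-pass filter (default cutoff 2 Hz, suitable
#' for slow isometric contractions). Filter ringing can undershoot zero; the
#' output is clipped at zero so it remains a valid amplitude.
#'
#' @param sig band-pass-conditioned sEMG as a [signalMatrix()].
#' @param cutoff_hz low-pass cutoff in Hz, default `2`.
#' @return A `SignalMatrix` of nonnegative per-channel envelopes.
#' @export
estimateEnvelope <- function(sig, cutoff_hz = 2.0) {
  rect <- fullWaveRectify(sig)
  env <- butterworthFilter(rect, filterSpec("lowpass", 2L, cutoff_hz, zero_lag = TRUE))
  env_data <- pmax(unclass(env), 0)
  signalMatrix(env_data, samplingRate(sig),
               channel_labels = attr(sig, "channel_labels"),
               muscle_id = muscleId(sig))
}

#' Representative (median) envelope of a muscle
#'
#' Collapses the per-channel envelopes of one muscle into a single
#' representative trace: the per-sample median across channels (for an even
#' channel count, the mean of the two middle order statistics). Alternatively
#' a single user-selected channel can be taken as representative via
#' `channel`.
#'
#' @param envelopes a `SignalMatrix` of nonnegative per-channel envelopes.
#' @param channel optional single channel index; when given, that channel is
#'   returned unchanged instead of the median.
#' @return An [envelope()] carrying the muscle id of the input.
#' @export
medianEnvelope <- function(envelopes, channel = NULL) {
  if (!inherits(envelopes, "SignalMatrix"))
    stop("`envelopes` must be a SignalMatrix", call. = FALSE)
  m <- unclass(envelopes)
  if (any(m < 0)) stop("envelopes must be nonnegative", call. = FALSE)
  id <- muscleId(envelopes)
  if (is.null(id)) id <- "muscle"
  vals <- if (!is.null(channel)) {
    if (channel < 1L || channel > ncol(m)) stop("channel index out of range", call. = FALSE)
    m[, channel]
  } else if (ncol(m) == 1L) m[, 1L] else apply(m, 1L, stats::median)
  envelope(vals, samplingRate(envelopes), muscle_id = id)
}

#' Condition the force/target signal
#'
#' Zero-lag fourth-order Butterworth low-pass (default 1 Hz) applied to the
#' scalar force or target channel, removing measurement noise while keeping
#' the slow contraction dynamics.
#'
#' @param force one-channel [signalMatrix()].
#' @param cutoff_hz low-pass cutoff in Hz, default `1`.
#' @return The filtered force `SignalMatrix`.
#' @export
conditionForce <- function(force, cutoff_hz = 1.0) {
  if (!inherits(force, "SignalMatrix")) stop("`force` must be a SignalMatrix", call. = FALSE)
  if (ncol(force) != 1L) stop("force must have exactly one channel", call. = FALSE)
  butterworthFilter(force, filterSpec("lowpass", 4L, cutoff_hz, zero_lag = TRUE))
}

#' Band-pass presets for the two recording configurations
#'
#' Returns the conditioning band-pass used for each montage: `"lower_limb"`
#' gives a fourth-order 15-350 Hz design, `"upper_limb"` a fourth-order
#' 20-450 Hz design, both zero-lag.
#'
#' @param dataset `"lower_limb"` or `"upper_limb"`.
#' @return A [filterSpec()].
#' @export
bandpassPreset <- function(dataset = c("lower_limb", "upper_limb")) {
  dataset <- match.arg(dataset)
  if (dataset == "lower_limb") filterSpec("bandpass", 4L, c(15, 350), zero_lag = TRUE)
  else filterSpec("bandpass", 4L, c(20, 450), zero_lag = TRUE)
}
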