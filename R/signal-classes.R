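#' Multi-channel sampled signal
#'
#' A `SignalMatrix` is the container for every time-aligned sampled signal in
#' the package: raw or filtered sEMG (samples in rows, channels in columns),
#' per-channel envelopes, and the scalar force/target signal (one column).
#'
#' @param data numeric matrix or vector, `N` samples by `C` channels. A vector
#'   is promoted to a one-column matrix.
#' @param fs sampling rate in Hz, a single positive number.
#' @param channel_labels optional character vector of length `C`.
#' @param muscle_id optional single string naming the muscle the channels
#'   belong to.
#' @return An object of class `SignalMatrix`: the data matrix with attributes
#'   `fs`, `channel_labels` and `muscle_id`.
#' @examples
#' x <- signalMatrix(matrix(rnorm(2048 * 2), ncol = 2), fs = 2048)
#' nSamples(x)
#' @export
signalMatrix <- function(data, fs, channel_labels = NULL, muscle_id = NULL) {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, ncol = 1L)
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix or vector", call. = FALSE)
  if (nrow(data) < 1L || ncol(data) < 1L)
    stop("`data` must have at least one sample and one channel", call. = FALSE)
  if (!all(is.finite(data)))
    stop("signal contains non-finite values", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  if (!is.null(channel_labels)) {
    channel_labels <- as.character(channel_labels)
    if (length(channel_labels) != ncol(data))
      stop("`channel_labels` length must equal the channel count", call. = FALSE)
  }
  structure(data,
            fs = as.numeric(fs),
            channel_labels = channel_labels,
            muscle_id = if (is.null(muscle_id)) NULL else as.character(muscle_id)[1L],
            class = c("SignalMatrix", "matrix"))
}

#' @export
print.SignalMatrix <- function(x, ...) {
  cat(sprintf("SignalMatrix: %d samples x %d channel(s) @ %g Hz (%.3f s)%s\n",
              nrow(x), ncol(x), samplingRate(x), nrow(x) / samplingRate(x),
              if (is.null(muscleId(x))) "" else paste0(", muscle ", muscleId(x))))
  invisible(x)
}

#' Accessors for sampled-signal objects
#'
#' @param x a `SignalMatrix` or `Envelope`.
#' @return `samplingRate`: the sampling rate in Hz. `nSamples`: the number of
#'   samples. `muscleId`: the muscle identifier or `NULL`.
#' @export
samplingRate <- function(x) attr(x, "fs")

#' @rdname samplingRate
#' @export
nSamples <- function(x) if (is.matrix(x)) nrow(x) else length(x)

#' @rdname samplingRate
#' @export
muscleId <- function(x) attr(x, "muscle_id")

#' Representative envelope of one muscle
#'
#' An `Envelope` is the nonnegative, slowly varying amplitude trace of one
#' muscle's sEMG — the regressor of the log-linear force model. It is a
#' numeric vector with `fs` and `muscle_id` attributes.
#'
#' @param values nonnegative numeric vector.
#' @param fs sampling rate in Hz.
#' @param muscle_id string identifying the muscle.
#' @return An object of class `Envelope`.
#' @export
envelope <- function(values, fs, muscle_id = "muscle") {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("empty envelope", call. = FALSE)
  if (!all(is.finite(values))) stop("envelope contains non-finite values", call. = FALSE)
  if (any(values < 0)) stop("envelope values must be nonnegative", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  structure(values, fs = as.numeric(fs),
            muscle_id = as.character(muscle_id)[1L],
            class = "Envelope")
}

#' @export
print.Envelope <- function(x, ...) {
  cat(sprintf("Envelope '%s': %d samples @ %g Hz, range [%.4g, %.4g]\n",
              muscleId(x), length(x), samplingRate(x),
              min(x), max(x)))
  invisible(x)
}

#' Butterworth filter specification
#'
#' Describes a low-pass or band-pass Butterworth design. `order` is the order
#' of the underlying one-pass design; with `zero_lag = TRUE` the filter is run
#' forward and backward, which squares the magnitude response and cancels the
#' phase.
#'
#' @param kind `"lowpass"` or `"bandpass"`.
#' @param order positive integer order of the one-pass design.
#' @param cutoffs_hz one (lowpass) or two strictly increasing (bandpass)
#'   positive cutoff frequencies in Hz, below Nyquist of the target signal.
#' @param zero_lag logical; apply forward-backward for zero net phase.
#' @return An object of class `FilterSpec`.
#' @examples
#' filterSpec("bandpass", 4, c(20, 450))   # upper-limb sEMG conditioning
#' filterSpec("lowpass", 2, 2)             # envelope smoother
#' @export
filterSpec <- function(kind = c("lowpass", "bandpass"), order, cutoffs_hz,
                       zero_lag = TRUE) {
  kind <- match.arg(kind)
  if (!is.numeric(order) || length(order) != 1L || order < 1 || order != round(order))
    stop("`order` must be a positive integer", call. = FALSE)
  cutoffs_hz <- as.numeric(cutoffs_hz)
  nexp <- if (kind == "lowpass") 1L else 2L
  if (length(cutoffs_hz) != nexp)
    stop(sprintf("%s filter needs %d cutoff(s)", kind, nexp), call. = FALSE)
  if (any(cutoffs_hz <= 0) || any(!is.finite(cutoffs_hz)))
    stop("cutoffs must be positive and finite", call. = FALSE)
  if (nexp == 2L && cutoffs_hz[2L] <= cutoffs_hz[1L])
    stop("band edges must be strictly increasing", call. = FALSE)
  structure(list(kind = kind, order = as.integer(order),
                 cutoffs_hz = cutoffs_hz, zero_lag = isTRUE(zero_lag)),
            class = "FilterSpec")
}

#' @export
print.FilterSpec <- function(x, ...) {
  cat(sprintf("FilterSpec: %s Butterworth, order %d, cutoff(s) %s Hz%s\n",
              x$kind, x$order, paste(x$cutoffs_hz, collapse = "-"),
              if (x$zero_lag) ", zero-lag" else ""))
  invisible(x)
}

# shared validation of a spec against a sampling rate
validateSpecFs <- function(spec, fs) {
  if (!inherits(spec, "FilterSpec")) stop("`spec` must be a FilterSpec", call. = FALSE)
  if (any(spec$cutoffs_hz >= fs / 2))
    stop(sprintf("cutoff at or above Nyquist (%g Hz)", fs / 2), call. = FALSE)
  invisible(spec)
}
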