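# Small, fast study configurations used across tests. The carrier band is
# scaled into the Nyquist range of the reduced sampling rates.

tinyConfig <- function(seed = 1L, ...) {
  defaults <- list(n_muscles = 2L, n_channels_per_muscle = 2L, fs = 512,
                   duration_s = 4, carrier_band_hz = c(15, 200), seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(syntheticConfig, args)
}

# deterministic envelopes for model-fitting tests: smooth positive traces
# with muscle-specific frequencies so neither the raw nor the log-transformed
# regressors are collinear
toyEnvelopes <- function(N = 200, M = 2, fs = 100) {
  lapply(seq_len(M), function(i)
    envelope(0.1 + 0.25 * (1 + sin(2 * pi * ((0.6 + 0.4 * i) * seq_len(N) / N) + i)),
             fs, paste0("m", i)))
}

forceFrom <- function(envelopes, weights, eps = 1e-8, noise = 0, seed = 1) {
  set.seed(seed)
  f <- rep(weights[1L], length(envelopes[[1L]]))
  for (i in seq_along(envelopes))
    f <- f + weights[i + 1L] * log(pmax(as.numeric(envelopes[[i]]), eps))
  f + stats::rnorm(length(f), 0, noise)
}
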