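# High-level pipeline: envelope extraction, per-family fitting recipes,
# split conventions and roster-wide comparison.

#' Full model roster
#'
#' @return Character vector of the fourteen estimators: the proposed
#'   log-linear model, structures 1-9, OLS, RLS, SVR and ANN.
#' @export
modelRoster <- function() {
  c("proposed", paste0("model", 1:9), "OLS", "RLS", "SVR", "ANN")
}

#' Extract representative envelopes from raw sEMG
#'
#' Per muscle: optional conditioning band-pass, rectification + 2 Hz
#' zero-lag low-pass per channel, then the representative envelope (median
#' across channels, or one selected channel).
#'
#' @param emg list of per-muscle [signalMatrix()] objects.
#' @param bandpass optional [filterSpec()] (e.g. [bandpassPreset()]) applied
#'   before envelope extraction; synthetic data is already band-limited so
#'   the default is none.
#' @param cutoff_hz envelope low-pass cutoff, default 2 Hz.
#' @param channel optional representative channel index (default: median).
#' @return List of [envelope()]s, one per muscle.
#' @export
extractEnvelopes <- function(emg, bandpass = NULL, cutoff_hz = 2.0,
                             channel = NULL) {
  lapply(emg, function(sig) {
    if (!is.null(bandpass)) sig <- butterworthFilter(sig, bandpass)
    medianEnvelope(estimateEnvelope(sig, cutoff_hz), channel = channel)
  })
}

subsetEnvelopes <- function(envelopes, idx) {
  lapply(envelopes, function(e) envelope(e[idx], samplingRate(e), muscleId(e)))
}

#' Data-allocation convention of a model family
#'
#' Families needing a validation set for tuning or restart selection (the
#' PSO structures, RLS, SVR, ANN) use 30/20/50 estimation/validation/test;
#' the single-solve least-squares families (proposed, structures 1, 5, 6, 8,
#' 9, OLS) use 50/50 estimation/test.
#'
#' @param family model family name.
#' @param N number of samples.
#' @param scheme passed to [allocateData()].
#' @return A `Split`.
#' @export
defaultSplit <- function(family, N, scheme = "contiguous") {
  needs_val <- family %in% c("model2", "model3", "model4", "model7",
                             "RLS", "SVR", "ANN")
  if (needs_val) allocateData(N, c(0.3, 0.2, 0.5), scheme)
  else allocateData(N, c(0.5, 0.5), scheme)
}

#' Fit any roster model with its prescribed recipe
#'
#' Dispatches to the family's fitter, fitting on the split's estimation set
#' only (validation is used where the recipe calls for it; the test set is
#' never touched).
#'
#' @param family model family name (see [modelRoster()]).
#' @param envelopes list of [envelope()]s.
#' @param force one-channel [signalMatrix()] or numeric vector.
#' @param split a `Split`; `NULL` uses [defaultSplit()].
#' @param seed integer seed for the stochastic fitters (PSO, ANN).
#' @param pso_config optional [psoConfig()] override for the PSO families.
#' @return A `LogLinearModel` (family `"proposed"`) or `BaselineFit`.
#' @export
fitModel <- function(family, envelopes, force, split = NULL, seed = 1L,
                     pso_config = NULL) {
  b <- as.numeric(unclass(force))
  N <- length(b)
  if (is.null(split)) split <- defaultSplit(family, N)
  eidx <- split$estimation_idx
  env_e <- subsetEnvelopes(envelopes, eidx)
  f_e <- b[eidx]
  fs <- samplingRate(envelopes[[1L]])
  if (family == "proposed")
    return(fitLogLinear(env_e, signalMatrix(f_e, fs)))
  if (family %in% c("model1", "model5", "model6", "model8", "model9", "OLS"))
    return(fitLipModel(family, env_e, f_e))
  if (family %in% c("model2", "model3", "model4", "model7"))
    return(fitPsoModel(family, envelopes, b, split, config = pso_config,
                       seed = seed))
  if (family == "RLS") return(fitRidge(env_e, f_e))
  if (family == "SVR") return(fitSvr(envelopes, b, split))
  if (family == "ANN") return(fitAnn(envelopes, b, split, seed = seed))
  stop("unknown family: ", family, call. = FALSE)
}

#' Predict from any roster model
#'
#' @param fit object returned by [fitModel()].
#' @param envelopes list of [envelope()]s.
#' @return Numeric vector of predicted force.
#' @export
predictModel <- function(fit, envelopes) {
  if (inherits(fit, "LogLinearModel"))
    as.numeric(unclass(predictForce(fit, envelopes)))
  else predictBaseline(fit, envelopes)
}

# parameter count for adjusted R^2
modelParamCount <- function(fit, M) {
  if (inherits(fit, "LogLinearModel")) return(M + 1L)
  if (fit$family == "ANN") return(length(fit$params))
  length(fit$params)
}

#' Evaluate a fitted model on one index set
#'
#' @param fit fitted model.
#' @param envelopes full-record envelope list.
#' @param force full-record force.
#' @param idx indices of the evaluation set (e.g. `split$test_idx`).
#' @return List with `metrics` ([computeMetrics()]), `bland_altman`
#'   ([blandAltman()]) and `bias_test` ([biasTTest()]).
#' @export
evaluateOnSplit <- function(fit, envelopes, force, idx) {
  b <- as.numeric(unclass(force))[idx]
  pred <- predictModel(fit, subsetEnvelopes(envelopes, idx))
  list(metrics = computeMetrics(b, pred, modelParamCount(fit, length(envelopes))),
       bland_altman = blandAltman(b, pred),
       bias_test = biasTTest(b, pred))
}

#' Run the full roster on one or more recordings
#'
#' For each recording (a `SyntheticDataset` or a list with `emg` and
#' `force`), extracts envelopes, fits every requested family with its
#' prescribed split and evaluates it on the test set. With two or more
#' recordings the models are then compared by repeated-measures ANOVA on
#' test R^2 (recordings as the repeated unit) with Bonferroni-adjusted
#' pairwise contrasts against the proposed model.
#'
#' @param datasets list of recordings.
#' @param families roster subset, default [modelRoster()].
#' @param seed integer seed for stochastic fitters.
#' @param scheme split scheme, default contiguous.
#' @param pso_config optional [psoConfig()] override.
#' @return List of class `ComparisonReport`: `table` (per-family
#'   mean/sd/min/max of r, R^2, adj. R^2 across recordings), `scores`
#'   (recordings x families R^2 matrix), `anova`/`pairwise` when >= 2
#'   recordings.
#' @export
compareModels <- function(datasets, families = modelRoster(), seed = 1L,
                          scheme = "contiguous", pso_config = NULL) {
  if (inherits(datasets, "SyntheticDataset")) datasets <- list(datasets)
  scores <- matrix(NA_real_, length(datasets), length(families),
                   dimnames = list(NULL, families))
  rows <- list()
  per <- array(NA_real_, dim = c(length(datasets), length(families), 3L),
               dimnames = list(NULL, families, c("r", "R2", "adjR2")))
  for (di in seq_along(datasets)) {
    ds <- datasets[[di]]
    envs <- extractEnvelopes(ds$emg)
    N <- nSamples(ds$force)
    for (fam in families) {
      split <- defaultSplit(fam, N, scheme)
      fit <- fitModel(fam, envs, ds$force, split, seed = seed,
                      pso_config = pso_config)
      ev <- evaluateOnSplit(fit, envs, ds$force, split$test_idx)
      per[di, fam, ] <- c(ev$metrics$r, ev$metrics$R2, ev$metrics$adjR2)
      scores[di, fam] <- ev$metrics$R2
    }
  }
  tab <- do.call(rbind, lapply(families, function(fam) {
    row <- data.frame(family = fam)
    for (m in c("r", "R2", "adjR2")) {
      v <- per[, fam, m]
      row[[paste0(m, "_mean")]] <- mean(v)
      row[[paste0(m, "_sd")]] <- if (length(v) > 1L) stats::sd(v) else NA_real_
      row[[paste0(m, "_min")]] <- min(v)
      row[[paste0(m, "_max")]] <- max(v)
    }
    row
  }))
  out <- list(table = tab, scores = scores)
  if (length(datasets) >= 2L && length(families) >= 2L) {
    ref <- if ("proposed" %in% families) "proposed" else families[1L]
    cmp <- compareModelsRM(scores, reference = ref)
    out$anova <- cmp$anova
    out$pairwise <- cmp$pairwise
  }
  structure(out, class = "ComparisonReport")
}

#' @export
print.ComparisonReport <- function(x, ...) {
  cat("Model comparison (test-set metrics across recordings):\n")
  print(x$table, row.names = FALSE, digits = 4)
  if (!is.null(x$anova)) print(x$anova)
  invisible(x)
}
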