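#' Allocate samples to estimation / validation / test sets
#'
#' Partitions `N` time-ordered samples according to `fractions`. The
#' `"contiguous"` scheme keeps time blocks intact (estimation first, then
#' validation, then test), which respects the autocorrelation of sampled
#' contractions; `"interleaved"` spreads short sample runs cyclically across
#' the sets. Two fractions are read as (estimation, test) with an empty
#' validation set; three as (estimation, validation, test).
#'
#' @param N number of samples.
#' @param fractions numeric vector of 2 or 3 positive fractions summing to 1.
#' @param scheme `"contiguous"` (default) or `"interleaved"`.
#' @return A list of class `Split`: `estimation_idx`, `validation_idx`,
#'   `test_idx` (1-based, disjoint, covering `1:N`), plus `scheme` and
#'   `fractions`.
#' @examples
#' s <- allocateData(1000, c(0.3, 0.2, 0.5))
#' lengths(s[1:3])   # 300 200 500
#' @export
allocateData <- function(N, fractions, scheme = c("contiguous", "interleaved")) {
  scheme <- match.arg(scheme)
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1", call. = FALSE)
  if (!length(fractions) %in% 2:3) stop("need 2 or 3 fractions", call. = FALSE)
  if (any(fractions <= 0)) stop("fractions must be positive", call. = FALSE)
  if (N < length(fractions)) stop("fewer samples than sets", call. = FALSE)
  if (scheme == "contiguous") {
    bounds <- round(cumsum(fractions) * N)
    bounds[length(bounds)] <- N
    starts <- c(1, utils::head(bounds, -1) + 1)
    sets <- mapply(function(s, e) if (s <= e) s:e else integer(0),
                   starts, bounds, SIMPLIFY = FALSE)
  } else {
    # tile a length-20 label pattern so each short run of samples is shared
    counts <- diff(c(0, round(cumsum(fractions) * 20)))
    pattern <- rep(seq_along(fractions), counts)
    labels <- rep_len(pattern, N)
    sets <- lapply(seq_along(fractions), function(g) which(labels == g))
  }
  if (length(fractions) == 2L) sets <- list(sets[[1L]], integer(0), sets[[2L]])
  structure(list(estimation_idx = sets[[1L]], validation_idx = sets[[2L]],
                 test_idx = sets[[3L]], scheme = scheme, fractions = fractions),
            class = "Split")
}

statTestResult <- function(test_name, statistic, p_value, df = NA_real_,
                           adj_p_value = NA_real_, extra = list()) {
  structure(c(list(test_name = test_name, statistic = statistic,
                   p_value = p_value, df = df, adj_p_value = adj_p_value),
              extra),
            class = "StatTestResult")
}

#' @export
print.StatTestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s\n", x$test_name, x$statistic,
              x$p_value,
              if (!is.na(x$adj_p_value)) sprintf(" (adj. p = %.4g)", x$adj_p_value) else ""))
  invisible(x)
}

#' Goodness-of-fit metrics
#'
#' Pearson r, coefficient of determination R^2 = 1 - SSE/SST (with the
#' squared total sum of squares SST = sum((y - mean(y))^2)), adjusted R^2
#' penalised by the model's parameter count k, RMSE and MAE. R^2 can be
#' negative for models worse than the mean predictor; it is reported, not
#' clipped.
#'
#' @param measured,predicted numeric vectors of equal length (>= 3).
#' @param k number of fitted parameters (for adjusted R^2).
#' @return A list of class `Metrics`.
#' @export
computeMetrics <- function(measured, predicted, k) {
  measured <- as.numeric(unclass(measured)); predicted <- as.numeric(unclass(predicted))
  if (length(measured) != length(predicted)) stop("length mismatch", call. = FALSE)
  N <- length(measured)
  if (N < 3L) stop("need at least 3 samples", call. = FALSE)
  SST <- sum((measured - mean(measured))^2)
  if (SST == 0) stop("measured signal is constant; R^2 undefined", call. = FALSE)
  e <- measured - predicted
  SSE <- sum(e^2)
  R2 <- 1 - SSE / SST
  adjR2 <- 1 - (1 - R2) * (N - 1) / (N - k - 1)
  structure(list(r = if (stats::sd(predicted) == 0) NA_real_
                     else stats::cor(measured, predicted),
                 R2 = R2, adjR2 = adjR2,
                 RMSE = sqrt(SSE / N), MAE = mean(abs(e)),
                 SSE = SSE, SST = SST, N = N, k = as.integer(k)),
            class = "Metrics")
}

#' @export
print.Metrics <- function(x, ...) {
  cat(sprintf("Metrics (N = %d, k = %d): r = %.4f, R2 = %.4f, adj.R2 = %.4f, RMSE = %.4g, MAE = %.4g\n",
              x$N, x$k, x$r, x$R2, x$adjR2, x$RMSE, x$MAE))
  invisible(x)
}

#' Bland-Altman residual summary
#'
#' Residual (predicted - measured) bias, its standard deviation, agreement
#' limits at `bias +/- sd_multiplier * SD` (multiplier 1 by default, matching
#' the mean +/- SD convention for regression residuals; use 1.96 for the
#' classical agreement-limit convention), and the least-squares regression of
#' the residual on the measured signal (slope/intercept of the trend line).
#'
#' @param measured,predicted numeric vectors of equal length (>= 2).
#' @param sd_multiplier width of the agreement limits in SD units.
#' @return A list of class `BlandAltmanSummary`.
#' @export
blandAltman <- function(measured, predicted, sd_multiplier = 1) {
  measured <- as.numeric(unclass(measured)); predicted <- as.numeric(unclass(predicted))
  if (length(measured) != length(predicted)) stop("length mismatch", call. = FALSE)
  if (length(measured) < 2L) stop("need at least 2 samples", call. = FALSE)
  res <- predicted - measured
  bias <- mean(res); s <- stats::sd(res)
  fitline <- stats::lm.fit(cbind(1, measured), res)$coefficients
  structure(list(bias = bias, sd = s,
                 upper = bias + sd_multiplier * s,
                 lower = bias - sd_multiplier * s,
                 residual_regression = c(slope = unname(fitline[2L]),
                                         intercept = unname(fitline[1L])),
                 sd_multiplier = sd_multiplier),
            class = "BlandAltmanSummary")
}

#' @export
print.BlandAltmanSummary <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias = %.4g, SD = %.4g, limits [%.4g, %.4g] (+/- %g SD)\n",
              x$bias, x$sd, x$lower, x$upper, x$sd_multiplier))
  invisible(x)
}

#' Paired t-test for prediction bias
#'
#' Tests whether the mean residual (predicted - measured) differs from zero.
#' Degenerate residuals with zero variance and zero mean return `t = 0,
#' p = 1`; zero variance with nonzero mean returns `p = 0`.
#'
#' @param measured,predicted numeric vectors of equal length (>= 2).
#' @return A `StatTestResult`.
#' @export
biasTTest <- function(measured, predicted) {
  res <- as.numeric(unclass(predicted)) - as.numeric(unclass(measured))
  if (length(res) < 2L) stop("need at least 2 paired samples", call. = FALSE)
  if (stats::sd(res) == 0) {
    if (abs(mean(res)) < .Machine$double.eps * 100)
      return(statTestResult("paired t-test (bias)", 0, 1, df = length(res) - 1L))
    return(statTestResult("paired t-test (bias)", Inf, 0, df = length(res) - 1L))
  }
  tt <- stats::t.test(res, mu = 0)
  statTestResult("paired t-test (bias)", unname(tt$statistic), tt$p.value,
                 df = unname(tt$parameter))
}

#' Repeated-measures comparison of models
#'
#' One-way within-subject (repeated-measures) ANOVA of a score matrix
#' (subjects in rows, models in columns), followed by pairwise paired
#' t-tests of a reference model against every other model with Bonferroni
#' adjustment (`adj_p = min(1, m * p)`). The repeated unit can be whatever
#' the rows are — subjects or recording epochs.
#'
#' @param scores numeric matrix, subjects x models, complete (no NA).
#' @param reference column index or name of the model the pairwise contrasts
#'   compare against (default 1).
#' @return List with `anova` (a `StatTestResult` with the F statistic and
#'   both df) and `pairwise` (data.frame of contrasts with raw and adjusted
#'   p-values).
#' @export
compareModelsRM <- function(scores, reference = 1L) {
  scores <- as.matrix(scores)
  if (anyNA(scores)) stop("score matrix must be complete", call. = FALSE)
  ns <- nrow(scores); nm <- ncol(scores)
  if (ns < 2L || nm < 2L) stop("need >= 2 subjects and >= 2 models", call. = FALSE)
  if (is.null(colnames(scores))) colnames(scores) <- paste0("model", seq_len(nm))
  if (is.character(reference)) reference <- match(reference, colnames(scores))
  d <- data.frame(score = as.numeric(scores),
                  model = factor(rep(colnames(scores), each = ns),
                                 levels = colnames(scores)),
                  subject = factor(rep(seq_len(ns), nm)))
  fit <- stats::aov(score ~ model + Error(subject), data = d)
  tab <- summary(fit)[["Error: Within"]][[1L]]
  rn <- trimws(rownames(tab))
  ss_m <- tab[rn == "model", "Sum Sq"]; df_m <- tab[rn == "model", "Df"]
  ss_e <- tab[rn == "Residuals", "Sum Sq"]; df_e <- tab[rn == "Residuals", "Df"]
  tiny <- 1e-12 * max(sum(scores^2), 1)
  if (ss_e <= tiny) {              # degenerate: no within-cell variance
    Fv <- if (ss_m <= tiny) 0 else Inf
    p <- if (ss_m <= tiny) 1 else 0
  } else {
    Fv <- (ss_m / df_m) / (ss_e / df_e)
    p <- stats::pf(Fv, df_m, df_e, lower.tail = FALSE)
  }
  an <- statTestResult("rm-ANOVA", Fv, p, df = c(df_m, df_e))
  others <- setdiff(seq_len(nm), reference)
  m <- length(others)
  pw <- do.call(rbind, lapply(others, function(j) {
    diffs <- scores[, reference] - scores[, j]
    if (stats::sd(diffs) == 0) {
      tstat <- if (mean(diffs) == 0) 0 else Inf
      p <- if (mean(diffs) == 0) 1 else 0
    } else {
      tt <- stats::t.test(diffs, mu = 0)
      tstat <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(reference = colnames(scores)[reference],
               model = colnames(scores)[j],
               mean_difference = mean(diffs),
               t = tstat, p_value = p,
               adj_p_value = min(1, m * p))
  }))
  list(anova = an, pairwise = pw)
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U with the statistic `U = #(a > b) + 0.5 #(a = b)`
#' counted over all cross-group pairs. For small problems
#' (`n_a * n_b <= 400`) the exact permutation p-value is computed by a
#' shift-algorithm dynamic program over midranks, which stays exact under
#' ties; larger problems use the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param group_a,group_b nonempty numeric vectors.
#' @return A `StatTestResult` (statistic U, attribute-free two-sided p).
#' @export
mannWhitney <- function(group_a, group_b) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be nonempty", call. = FALSE)
  n1 <- length(a); n2 <- length(b)
  ranks <- rank(c(a, b))
  R1 <- sum(ranks[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2
  if (n1 * n2 <= 400) {
    p <- exactRankSumP(ranks, n1)
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    ties <- table(c(a, b))
    tiecorr <- sum(ties^3 - ties) / (nt * (nt - 1))
    sigma <- sqrt(n1 * n2 / 12 * (nt + 1 - tiecorr))
    z <- (U - mu - sign(U - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  statTestResult("Mann-Whitney U", U, p, extra = list(n = c(n1, n2)))
}

# exact permutation distribution of the group-a rank sum, ties included:
# DP over doubled midranks (integers), counting subsets of size n1 by sum.
exactRankSumP <- function(ranks, n1) {
  v <- as.integer(round(2 * ranks))
  nt <- length(v)
  smax <- sum(sort(v, decreasing = TRUE)[seq_len(n1)])
  smin <- sum(sort(v)[seq_len(n1)])
  # dp[j+1, s+1] = #subsets of size j with doubled-rank sum s
  dp <- matrix(0, n1 + 1L, smax + 1L)
  dp[1L, 1L] <- 1
  for (x in v) {
    jmax <- n1
    for (j in jmax:1) {
      cols <- (x + 1L):(smax + 1L)
      dp[j + 1L, cols] <- dp[j + 1L, cols] + dp[j, cols - x]
    }
  }
  dist <- dp[n1 + 1L, ]
  total <- sum(dist)
  obs <- sum(v[seq_len(n1)])
  lower <- sum(dist[seq_len(obs + 1L)]) / total        # P(S <= obs)
  upper <- sum(dist[(obs + 1L):(smax + 1L)]) / total   # P(S >= obs)
  min(1, 2 * min(lower, upper))
}

#' ROC curve with Youden-optimal cutoff
#'
#' Treats higher scores as more indicative of the positive class. The AUC is
#' computed through the rank (Mann-Whitney) identity, so it equals the
#' fraction of correctly ordered positive/negative pairs (ties counted 1/2).
#' The operating cutoff maximises the Youden index J = sensitivity +
#' specificity - 1; ties are broken toward the cutoff with higher
#' specificity.
#'
#' @param scores numeric scores.
#' @param labels binary labels (logical, 0/1, or a two-level factor whose
#'   second level is positive).
#' @return A list of class `ROCResult`: `auc`, `cutoff`, `sensitivity`,
#'   `specificity`, `youden`, `curve` (data.frame of cutoff/sens/spec), and
#'   the data for paired AUC comparison.
#' @export
rocYouden <- function(scores, labels) {
  scores <- as.numeric(scores)
  y <- binaryLabels(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  pos <- scores[y == 1L]; neg <- scores[y == 0L]
  n1 <- length(pos); n0 <- length(neg)
  ranks <- rank(c(pos, neg))
  auc <- (sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cuts <- sort(unique(scores))
  # predict positive when score >= cutoff; also allow the all-positive rule
  cand <- c(-Inf, cuts)
  sens <- vapply(cand, function(cc) mean(pos >= cc), numeric(1))
  spec <- vapply(cand, function(cc) mean(neg < cc), numeric(1))
  J <- sens + spec - 1
  best <- which(J >= max(J) - 1e-12)
  best <- best[which.max(spec[best])]
  structure(list(auc = auc, cutoff = cand[best],
                 sensitivity = sens[best], specificity = spec[best],
                 youden = J[best],
                 curve = data.frame(cutoff = cand, sensitivity = sens,
                                    specificity = spec),
                 scores = scores, labels = y),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f; Youden cutoff = %.4g (sens %.3f, spec %.3f, J = %.3f)\n",
              x$auc, x$cutoff, x$sensitivity, x$specificity, x$youden))
  invisible(x)
}

binaryLabels <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stop("labels must have two levels", call. = FALSE)
    as.integer(labels == levels(labels)[2L])
  } else if (is.logical(labels)) as.integer(labels)
  else {
    u <- sort(unique(labels))
    if (!all(u %in% c(0, 1))) stop("numeric labels must be 0/1", call. = FALSE)
    as.integer(labels)
  }
}

#' Paired comparison of two AUCs
#'
#' DeLong-style test of the difference between the AUCs of two score vectors
#' computed on the same subjects, using the covariance of the placement
#' values of positives and negatives. A zero-variance difference (e.g., a
#' feature against itself) returns `z = 0, p = 1`.
#'
#' @param roc_a,roc_b `ROCResult`s from [rocYouden()], built from identically
#'   labelled, equally long score vectors.
#' @return A `StatTestResult` (z statistic, two-sided p) with the AUC
#'   difference in `$extra`.
#' @export
compareAuc <- function(roc_a, roc_b) {
  stopifnot(inherits(roc_a, "ROCResult"), inherits(roc_b, "ROCResult"))
  if (length(roc_a$labels) != length(roc_b$labels) ||
      any(roc_a$labels != roc_b$labels))
    stop("ROC results are not paired on the same subjects", call. = FALSE)
  y <- roc_a$labels
  placements <- function(scores) {
    pos <- scores[y == 1L]; neg <- scores[y == 0L]
    cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
    list(V10 = rowMeans(cmp), V01 = colMeans(cmp))
  }
  pa <- placements(roc_a$scores); pb <- placements(roc_b$scores)
  m <- sum(y == 1L); n <- sum(y == 0L)
  S10 <- stats::cov(cbind(pa$V10, pb$V10))
  S01 <- stats::cov(cbind(pa$V01, pb$V01))
  var_diff <- (S10[1, 1] + S10[2, 2] - 2 * S10[1, 2]) / m +
              (S01[1, 1] + S01[2, 2] - 2 * S01[1, 2]) / n
  d <- roc_a$auc - roc_b$auc
  if (var_diff <= 0) {
    z <- 0; p <- if (abs(d) < 1e-12) 1 else 0
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  statTestResult("paired AUC difference (DeLong)", z, p,
                 extra = list(auc_difference = d, variance = var_diff))
}

#' Minimum sample size for a multiple-regression F-test
#'
#' Smallest N at which the overall F-test of a k-predictor linear model with
#' expected coefficient of determination `R2_expected` reaches the requested
#' power at level `alpha`. Effect size f^2 = R^2/(1 - R^2); the noncentrality
#' parameter follows the lambda = f^2 * N convention; numerator df = k,
#' denominator df = N - k - 1 (so N >= k + 2 always).
#'
#' @param R2_expected expected R^2 in (0, 1).
#' @param k number of predictors (>= 1).
#' @param power target power in (0, 1), default 0.80.
#' @param alpha significance level in (0, 1), default 0.05.
#' @param max_n search cap.
#' @return Integer minimum N.
#' @examples
#' regressionSampleSize(0.964, 5)    # 8
#' regressionSampleSize(0.960, 11)   # 14
#' @export
regressionSampleSize <- function(R2_expected, k, power = 0.80, alpha = 0.05,
                                 max_n = 100000L) {
  stopifnot(R2_expected > 0, R2_expected < 1, k >= 1,
            power > 0, power < 1, alpha > 0, alpha < 1)
  f2 <- R2_expected / (1 - R2_expected)
  for (N in (k + 2L):max_n) {
    df2 <- N - k - 1L
    crit <- stats::qf(1 - alpha, k, df2)
    pow <- stats::pf(crit, k, df2, ncp = f2 * N, lower.tail = FALSE)
    if (pow >= power) return(as.integer(N))
  }
  stop("requested power not reachable within max_n samples", call. = FALSE)
}

#' Per-epoch timing of a model's train and test paths
#'
#' Splits the signals into consecutive epochs of `epoch_ms` milliseconds and
#' wall-clocks `fit_fn` and `predict_fn` on each epoch. Reported in
#' microseconds as mean, SD, min and max; figures depend on the host and are
#' descriptive only.
#'
#' @param fit_fn function(envelopes, force) -> fitted model, called per epoch.
#' @param predict_fn function(fit, envelopes) -> predictions.
#' @param envelopes list of [envelope()]s.
#' @param force measured force.
#' @param epoch_ms epoch length in milliseconds, default 250.
#' @return A list of class `TimingReport` with per-path summaries and the
#'   epoch sample count; empty if no complete epoch fits.
#' @export
timingHarness <- function(fit_fn, predict_fn, envelopes, force,
                          epoch_ms = 250) {
  fs <- samplingRate(envelopes[[1L]])
  len <- as.integer(round(fs * epoch_ms / 1000))
  N <- length(envelopes[[1L]])
  n_epochs <- N %/% len
  if (n_epochs == 0L)
    return(structure(list(n_epochs = 0L, epoch_samples = len,
                          train = NULL, test = NULL),
                     class = "TimingReport"))
  b <- as.numeric(unclass(force))
  train_us <- test_us <- numeric(n_epochs)
  for (ep in seq_len(n_epochs)) {
    idx <- ((ep - 1L) * len + 1L):(ep * len)
    envs <- lapply(envelopes, function(e) envelope(e[idx], fs, muscleId(e)))
    fe <- b[idx]
    t0 <- proc.time()[["elapsed"]]
    fit <- fit_fn(envs, fe)
    t1 <- proc.time()[["elapsed"]]
    predict_fn(fit, envs)
    t2 <- proc.time()[["elapsed"]]
    train_us[ep] <- (t1 - t0) * 1e6
    test_us[ep] <- (t2 - t1) * 1e6
  }
  summ <- function(x) c(mean = mean(x), sd = stats::sd(x),
                        min = min(x), max = max(x))
  structure(list(n_epochs = n_epochs, epoch_samples = len,
                 train = summ(train_us), test = summ(test_us)),
            class = "TimingReport")
}

#' @export
print.TimingReport <- function(x, ...) {
  if (x$n_epochs == 0L) { cat("TimingReport: no complete epochs\n"); return(invisible(x)) }
  cat(sprintf("TimingReport over %d epochs of %d samples (microseconds):\n",
              x$n_epochs, x$epoch_samples))
  cat(sprintf("  train %.1f +/- %.1f [%.1f, %.1f]\n",
              x$train["mean"], x$train["sd"], x$train["min"], x$train["max"]))
  cat(sprintf("  test  %.1f +/- %.1f [%.1f, %.1f]\n",
              x$test["mean"], x$test["sd"], x$test["min"], x$test["max"]))
  invisible(x)
}
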