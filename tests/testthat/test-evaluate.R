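test_that("contiguous allocation reproduces block sizes and partitions the record", {
  s <- allocateData(1000, c(0.3, 0.2, 0.5))
  expect_equal(lengths(list(s$estimation_idx, s$validation_idx, s$test_idx)),
               c(300L, 200L, 500L))
  expect_equal(s$estimation_idx[1], 1L)
  expect_equal(s$test_idx[500], 1000L)

  h <- allocateData(10, c(0.5, 0.5))
  expect_equal(h$estimation_idx, 1:5)
  expect_equal(h$test_idx, 6:10)
  expect_length(h$validation_idx, 0)

  for (N in c(10, 101, 997)) {
    for (scheme in c("contiguous", "interleaved")) {
      sp <- allocateData(N, c(0.3, 0.2, 0.5), scheme)
      all_idx <- c(sp$estimation_idx, sp$validation_idx, sp$test_idx)
      expect_equal(sort(all_idx), 1:N)
    }
  }
  expect_error(allocateData(100, c(0.6, 0.6)), "sum to 1")
})

test_that("metrics follow their definitions, including the adjusted penalty", {
  y <- c(1, 3, 2, 5, 4, 6, 8, 7)
  m <- computeMetrics(y, y, k = 2)
  expect_equal(c(m$r, m$R2, m$adjR2, m$RMSE), c(1, 1, 1, 0))

  m0 <- computeMetrics(y, rep(mean(y), 8), k = 1)
  expect_equal(m0$R2, 0)

  # direct evaluation of the adjustment at R2 = 0.9, N = 101, k = 10
  set.seed(1)
  yy <- rnorm(101)
  SST <- sum((yy - mean(yy))^2)
  resid <- rnorm(101); resid <- resid * sqrt(0.1 * SST / sum(resid^2))
  mm <- computeMetrics(yy, yy - resid, k = 10)
  expect_equal(mm$R2, 0.9, tolerance = 1e-12)
  expect_equal(mm$adjR2, 1 - 0.1 * 100 / 90, tolerance = 1e-12)

  expect_error(computeMetrics(rep(1, 5), rnorm(5), 1), "constant")
  expect_error(computeMetrics(1:4, 1:5, 1), "mismatch")
})

test_that("Bland-Altman summarises residual bias, limits and trend", {
  y <- c(1, 2, 3, 4)
  ba <- blandAltman(y, y + 2)
  expect_equal(c(ba$bias, ba$sd, ba$lower, ba$upper), c(2, 0, 2, 2))

  set.seed(33)
  a <- rnorm(200); b <- a + rnorm(200, 0.5, 0.3)
  bb <- blandAltman(a, b)
  r <- b - a
  expect_equal(bb$bias, mean(r))
  expect_equal(bb$sd, sd(r))
  expect_equal(bb$upper, mean(r) + sd(r))
  lm_or <- coef(lm(r ~ a))
  expect_equal(unname(bb$residual_regression["slope"]), unname(lm_or[2]),
               tolerance = 1e-9)
  wide <- blandAltman(a, b, sd_multiplier = 1.96)
  expect_equal(wide$upper, mean(r) + 1.96 * sd(r))

  envs <- toyEnvelopes(N = 150, M = 2)
  f <- forceFrom(envs, c(1, 2, 1), noise = 0.4, seed = 3)
  fit <- fitLogLinear(envs, signalMatrix(f, 100))
  expect_lt(abs(blandAltman(f, as.numeric(predictForce(fit, envs)))$bias), 1e-9)
})

test_that("bias t-test matches the analytic t distribution and its conventions", {
  y <- rnorm(10)
  expect_equal(biasTTest(y, y)$p_value, 1)

  r <- biasTTest(rep(0, 10), rep(1, 10))
  expect_equal(r$p_value, 0)

  set.seed(17)
  res <- rnorm(1000)
  out <- biasTTest(numeric(1000), res)
  tstat <- mean(res) / (sd(res) / sqrt(1000))
  p_or <- 2 * pt(-abs(tstat), 999)
  expect_equal(out$statistic, tstat, tolerance = 1e-9)
  expect_equal(out$p_value, p_or, tolerance = 1e-9)
})

test_that("repeated-measures ANOVA agrees with a hand-computed table", {
  scores <- matrix(c(0.90, 0.92, 0.91, 0.89, 0.93,
                     0.85, 0.88, 0.86, 0.84, 0.89,
                     0.80, 0.83, 0.81, 0.79, 0.84),
                   nrow = 5, dimnames = list(NULL, c("A", "B", "C")))
  out <- compareModelsRM(scores, reference = "A")
  # within-subject one-way ANOVA by explicit sums of squares
  gm <- mean(scores)
  ss_model <- 5 * sum((colMeans(scores) - gm)^2)
  ss_subj <- 3 * sum((rowMeans(scores) - gm)^2)
  ss_tot <- sum((scores - gm)^2)
  ss_err <- ss_tot - ss_model - ss_subj
  F_or <- (ss_model / 2) / (ss_err / 8)
  expect_equal(out$anova$statistic, F_or, tolerance = 1e-9)
  expect_equal(out$anova$df, c(2, 8))
  expect_equal(nrow(out$pairwise), 2)
  expect_true(all(out$pairwise$adj_p_value >= out$pairwise$p_value))
  expect_true(all(out$pairwise$adj_p_value <= 1))

  same <- matrix(rep(c(1, 2, 3, 4), 3), nrow = 4)
  identical_out <- compareModelsRM(same)
  expect_equal(identical_out$anova$statistic, 0)
  expect_equal(identical_out$anova$p_value, 1)

  two <- cbind(a = c(1, 2, 3), b = c(2, 3, 4))   # constant offset, no noise
  expect_lt(compareModelsRM(two)$pairwise$p_value, 1e-6)
  expect_error(compareModelsRM(matrix(c(1, NA, 2, 3), 2)), "complete")
})

test_that("Mann-Whitney U matches brute-force pair counting and exact enumeration", {
  out <- mannWhitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(out$statistic, 0)

  # identical groups: exact permutation p is 1
  expect_equal(mannWhitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  a <- c(1.2, 3.4, 2.2, 5.1); b <- c(2.0, 2.2, 4.4)
  u_brute <- sum(outer(a, b, function(x, y) (x > y) + 0.5 * (x == y)))
  expect_equal(mannWhitney(a, b)$statistic, u_brute)

  # exact p equals enumeration over all label assignments (ties included)
  vals <- c(a, b); n1 <- 4
  ranks <- rank(vals)
  combs <- combn(7, n1)
  sums <- apply(combs, 2, function(ix) sum(ranks[ix]))
  obs <- sum(ranks[1:n1])
  p_or <- min(1, 2 * min(mean(sums <= obs), mean(sums >= obs)))
  expect_equal(mannWhitney(a, b)$p_value, p_or)

  # tie-free case agrees with the classical exact distribution
  set.seed(2)
  x <- rnorm(6); y <- rnorm(7) + 1
  wt <- wilcox.test(x, y, exact = TRUE)
  expect_equal(mannWhitney(x, y)$statistic, unname(wt$statistic))
  expect_equal(mannWhitney(x, y)$p_value, wt$p.value, tolerance = 1e-12)

  # large samples: tie-corrected normal approximation stays close to the
  # classical implementation
  set.seed(4)
  xa <- rnorm(30); xb <- rnorm(30, 0.8)
  big <- mannWhitney(xa, xb)
  ref <- wilcox.test(xa, xb, exact = FALSE, correct = TRUE)
  expect_equal(big$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("ROC analysis obeys the rank identity and Youden conventions", {
  sc <- c(0.1, 0.2, 0.3, 0.8, 0.9, 0.95)
  lb <- c(0, 0, 0, 1, 1, 1)
  r <- rocYouden(sc, lb)
  expect_equal(r$auc, 1)
  expect_equal(r$youden, 1)

  sc2 <- c(3, 1, 4, 1.5, 5, 9, 2.6)
  lb2 <- c(0, 0, 1, 0, 1, 1, 0)
  r2 <- rocYouden(sc2, lb2)
  pos <- sc2[lb2 == 1]; neg <- sc2[lb2 == 0]
  auc_or <- mean(outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n)))
  expect_equal(r2$auc, auc_or)

  # AUC equals U/(n1 n2) from the Mann-Whitney statistic on the same data
  u <- mannWhitney(pos, neg)$statistic
  expect_equal(r2$auc, u / (length(pos) * length(neg)))

  # null scores: AUC near 1/2
  set.seed(5)
  sc3 <- rnorm(2000); lb3 <- sample(rep(0:1, 1000))
  expect_gt(rocYouden(sc3, lb3)$auc, 0.45)
  expect_lt(rocYouden(sc3, lb3)$auc, 0.55)

  expect_error(rocYouden(1:5, rep(1, 5)), "both classes")
})

test_that("ROC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  sc <- rnorm(60); lb <- as.integer(sc + rnorm(60) > 0)
  ours <- rocYouden(sc, lb)
  ref <- pROC::roc(lb, sc, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  best <- pROC::coords(ref, "best", best.method = "youden", transpose = FALSE)
  expect_equal(ours$sensitivity + ours$specificity,
               max(best$sensitivity + best$specificity), tolerance = 1e-12)
})

test_that("paired AUC comparison follows the placement-covariance construction", {
  set.seed(6)
  sc <- rnorm(40); lb <- rep(0:1, 20)
  r <- rocYouden(sc, lb)
  self <- compareAuc(r, r)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)

  # strong vs uninformative feature on the same subjects
  set.seed(7)
  lb2 <- rep(0:1, each = 100)
  good <- lb2 + rnorm(200, 0, 0.3)
  rand <- rnorm(200)
  out <- compareAuc(rocYouden(good, lb2), rocYouden(rand, lb2))
  expect_lt(out$p_value, 0.01)

  # hand-computed placement variance on a small fixture
  scA <- c(1, 2, 3, 4, 5, 6); scB <- c(2, 1, 4, 3, 6, 5); lbf <- c(0, 0, 0, 1, 1, 1)
  ra <- rocYouden(scA, lbf); rb <- rocYouden(scB, lbf)
  psi <- function(p, n) (p > n) + 0.5 * (p == n)
  v10 <- function(sc) sapply(sc[lbf == 1], function(p) mean(psi(p, sc[lbf == 0])))
  v01 <- function(sc) sapply(sc[lbf == 0], function(n) mean(psi(sc[lbf == 1], n)))
  var_or <- (var(v10(scA)) + var(v10(scB)) - 2 * cov(v10(scA), v10(scB))) / 3 +
            (var(v01(scA)) + var(v01(scB)) - 2 * cov(v01(scA), v01(scB))) / 3
  got <- compareAuc(ra, rb)
  expect_equal(got$variance, var_or, tolerance = 1e-12)

  expect_error(compareAuc(ra, rocYouden(c(1, 2, 3, 4), c(0, 0, 1, 1))), "paired")
})

test_that("paired AUC test agrees with an established DeLong implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  lb <- rep(0:1, each = 50)
  s1 <- lb + rnorm(100, 0, 0.8)
  s2 <- lb + rnorm(100, 0, 1.5)
  ours <- compareAuc(rocYouden(s1, lb), rocYouden(s2, lb))
  ref <- pROC::roc.test(pROC::roc(lb, s1, quiet = TRUE, direction = "<"),
                        pROC::roc(lb, s2, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("regression sample size follows the noncentral-F power convention", {
  expect_identical(regressionSampleSize(0.964, 5), 8L)
  expect_identical(regressionSampleSize(0.960, 11), 14L)
  # denominator df constraint: N is always at least k + 2
  for (R2 in c(0.3, 0.7, 0.95)) {
    for (k in c(1, 4, 9)) {
      expect_gte(regressionSampleSize(R2, k), k + 2L)
    }
  }
  expect_error(regressionSampleSize(0.001, 3, power = 0.999, max_n = 50),
               "not reachable")
})

test_that("timing harness slices epochs correctly and reports positive times", {
  fs <- 2048
  envs <- lapply(1:2, function(i)
    envelope(runif(fs * 2, 0.1, 0.8), fs, paste0("m", i)))
  f <- forceFrom(envs, c(1, 2, 1))
  rep_ <- timingHarness(function(e, y) fitLogLinear(e, signalMatrix(y, fs)),
                        function(m, e) predictForce(m, e),
                        envs, f, epoch_ms = 250)
  expect_equal(rep_$epoch_samples, 512L)
  expect_equal(rep_$n_epochs, 8L)
  expect_true(all(rep_$train >= 0))

  short <- timingHarness(function(e, y) NULL, function(m, e) NULL,
                         lapply(envs, function(e) envelope(e[1:100], fs, muscleId(e))),
                         f[1:100], epoch_ms = 250)
  expect_equal(short$n_epochs, 0L)
})

test_that("classical identity: squared correlation equals R2 for trained LS fits", {
  envs <- toyEnvelopes(N = 400, M = 3)
  f <- forceFrom(envs, c(1, 2, -1, 0.5), noise = 0.5, seed = 21)
  fit <- fitLogLinear(envs, signalMatrix(f, 100))
  pred <- as.numeric(predictForce(fit, envs))
  m <- computeMetrics(f, pred, k = 4)
  expect_equal(m$r^2, m$R2, tolerance = 1e-9)
  expect_lte(m$adjR2, m$R2)
})
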