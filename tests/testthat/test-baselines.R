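test_that("model structures evaluate to their closed forms", {
  fs <- 100
  e <- list(envelope(c(1, 4, 9), fs, "m1"))
  # power law: 2 * x^0.5
  expect_equal(evaluateModel("model2", c(2, 0.5), e), c(2, 4, 6))
  # zero exponent: e^0 = 1
  expect_equal(evaluateModel("model3", c(3, 0), e), rep(3, 3))
  e2 <- list(envelope(c(1, 2, 3), fs, "m1"), envelope(c(4, 5, 6), fs, "m2"))
  # identity affine structure sums the envelopes
  expect_equal(evaluateModel("model6", c(0, 1, 0, 1), e2), c(5, 7, 9))
  expect_error(evaluateModel("model2", c(1, 2, 3), e), "parameters")
})

test_that("trigonometric basis rows match direct evaluation", {
  E <- matrix(c(0, pi / 2), ncol = 1)
  B <- emgforce:::lipBasis("model8", E)
  expect_equal(B[1, ], c(1, 1, 0), tolerance = 1e-12)
  expect_equal(B[2, ], c(1, 0, 1), tolerance = 1e-12)
})

test_that("linearity holds exactly for LS families and fails for PSO families", {
  envs <- toyEnvelopes(N = 40, M = 2)
  for (fam in c("model1", "model5", "model6", "model8", "model9", "OLS")) {
    np <- emgforce:::nParams(fam, 2)
    set.seed(1)
    p1 <- rnorm(np); p2 <- rnorm(np)
    lhs <- evaluateModel(fam, p1 + p2, envs)
    rhs <- evaluateModel(fam, p1, envs) + evaluateModel(fam, p2, envs)
    # superposition up to the shared zero response (zero params give zero)
    z <- evaluateModel(fam, numeric(np), envs)
    expect_equal(lhs, rhs - z, tolerance = 1e-10)
  }
  for (fam in c("model2", "model3", "model4", "model7")) {
    np <- emgforce:::nParams(fam, 2)
    set.seed(2)
    p1 <- runif(np, 0.1, 1); p2 <- runif(np, 0.1, 1)
    z <- evaluateModel(fam, numeric(np), envs)
    lhs <- evaluateModel(fam, p1 + p2, envs)
    rhs <- evaluateModel(fam, p1, envs) + evaluateModel(fam, p2, envs)
    expect_gt(max(abs(lhs - (rhs - z))), 1e-6)
  }
})

test_that("LS families recover realizable targets and tolerate built-in collinearity", {
  envs <- toyEnvelopes(N = 300, M = 2)
  E <- sapply(envs, as.numeric)
  f_lin <- E %*% c(2, -1) + 0.5
  fit <- fitLipModel("OLS", envs, f_lin)
  expect_equal(fit$params, c(2, -1, 0.5), tolerance = 1e-8)

  f_sq <- as.numeric(E[, 1])^2
  fit5 <- fitLipModel("model5", envs, f_sq)
  pred <- evaluateModel("model5", fit5$params, envs)
  expect_lt(sum((pred - f_sq)^2) / sum((f_sq - mean(f_sq))^2), 1e-9)

  # model 1 duplicates its own column; the minimum-norm path absorbs it
  fit1 <- fitLipModel("model1", envs, f_lin)
  expect_identical(fit1$meta$solver_path, "pseudo-inverse")
  expect_equal(fit1$params[1], fit1$params[2], tolerance = 1e-8)
})

test_that("PSO finds the sphere minimum and is deterministic under a seed", {
  cfg <- psoConfig(4, seed = 42, lower = -5, upper = 5)
  obj <- function(x) sum(x^2)
  r1 <- psoOptimize(obj, cfg)
  expect_lt(r1$f_best, 1e-3)
  r2 <- psoOptimize(obj, cfg)
  expect_identical(r1$x_best, r2$x_best)
  expect_identical(r1$trace, r2$trace)
})

test_that("PSO on a convex objective approaches but never beats least squares", {
  set.seed(8)
  B <- matrix(rnorm(120 * 4), 120, 4); b <- rnorm(120)
  ls <- qr.solve(B, b)
  sse_ls <- sum((B %*% ls - b)^2)
  obj <- function(x) sum((B %*% x - b)^2)
  r <- psoOptimize(obj, psoConfig(4, seed = 3, lower = -10, upper = 10))
  expect_gte(r$f_best, sse_ls - 1e-9)
  expect_lt(r$f_best, sse_ls * 1.05)
})

test_that("multi-start PSO fitting selects on validation RMSE", {
  envs <- lapply(1:2, function(i)
    envelope(0.2 + 0.6 * abs(sin(2 * pi * seq_len(600) / 600 + i)), 100,
             paste0("m", i)))
  f <- 1.5 * as.numeric(envs[[1]])^0.8 + 1.5 * as.numeric(envs[[2]])^0.8
  split <- allocateData(600, c(0.3, 0.2, 0.5))
  pcfg <- psoConfig(4, seed = 5, n_restarts = 2, lower = c(-10, -5, -10, -5),
                    upper = c(10, 5, 10, 5))
  fit <- fitPsoModel("model2", envs, f, split, config = pcfg)
  expect_length(fit$meta$restarts, 2)
  vr <- vapply(fit$meta$restarts, `[[`, numeric(1), "validation_rmse")
  expect_identical(fit$meta$selected_restart, which.min(vr))
  pred <- evaluateModel("model2", fit$params, lapply(envs, function(e)
    envelope(e[split$test_idx], 100, muscleId(e))), fit$epsilon_floor)
  ft <- f[split$test_idx]
  expect_gt(1 - sum((pred - ft)^2) / sum((ft - mean(ft))^2), 0.9)

  one <- fitPsoModel("model2", envs, f, split,
                     config = utils::modifyList(pcfg, list(n_restarts = 1L)))
  expect_length(one$meta$restarts, 1)
})

test_that("ridge matches its closed-form oracle and its limits", {
  envs <- toyEnvelopes(N = 150, M = 3)
  E <- sapply(envs, as.numeric)
  set.seed(12)
  y <- E %*% c(1, -2, 0.5) + 3 + rnorm(150, 0, 0.1)

  r0 <- fitRidge(envs, y, lambda = 0)
  ols <- fitLipModel("OLS", envs, y)
  expect_equal(r0$params, ols$params, tolerance = 1e-9)

  rbig <- fitRidge(envs, y, lambda = 1e9)
  expect_lt(max(abs(rbig$params[1:3])), 1e-5)
  expect_equal(predictBaseline(rbig, envs), rep(mean(y), 150), tolerance = 1e-3)

  r <- fitRidge(envs, y, lambda = 0.01)
  X <- cbind(E, 1); D <- diag(c(1, 1, 1, 0))
  oracle <- solve(crossprod(X) + 0.01 * D, crossprod(X, y))
  expect_equal(r$params, as.numeric(oracle), tolerance = 1e-8)
})

test_that("linear SVR fits a realizable target and degrades gracefully", {
  envs <- toyEnvelopes(N = 400, M = 2)
  E <- sapply(envs, as.numeric)
  y <- as.numeric(E %*% c(2, -1)) + 0.5
  split <- allocateData(400, c(0.3, 0.2, 0.5), "interleaved")
  fit <- fitSvr(envs, y, split, cost_grid = 10^(0:3))
  pred <- predictBaseline(fit, lapply(envs, function(e)
    envelope(e[split$test_idx], 100, muscleId(e))))
  yt <- y[split$test_idx]
  expect_gt(1 - sum((pred - yt)^2) / sum((yt - mean(yt))^2), 0.999)

  expect_warning(cf <- fitSvr(envs, rep(2, 400), split), "constant")
  expect_equal(predictBaseline(cf, envs), rep(2, 400))

  direct <- fitSvr(envs, y, split, cost_grid = 10)   # grid of one: no tuning
  expect_true(all(is.na(direct$meta$cv_mse)) || length(direct$meta$cv_mse) == 1)
})

test_that("ANN learns a realizable mapping deterministically and stops early on noise", {
  envs <- toyEnvelopes(N = 500, M = 2)
  E <- sapply(envs, as.numeric)
  y <- as.numeric(E %*% c(2, 1)) - 0.5
  split <- allocateData(500, c(0.3, 0.2, 0.5), "interleaved")
  fit <- fitAnn(envs, y, split, seed = 6)
  idx <- split$test_idx
  pred <- predictBaseline(fit, lapply(envs, function(e)
    envelope(e[idx], 100, muscleId(e))))
  expect_gt(1 - sum((pred - y[idx])^2) / sum((y[idx] - mean(y[idx]))^2), 0.99)

  fit2 <- fitAnn(envs, y, split, seed = 6)
  expect_identical(fit$params, fit2$params)

  set.seed(99)
  noise <- rnorm(500)
  fitn <- fitAnn(envs, noise, split, seed = 6, max_epochs = 150)
  expect_lt(fitn$meta$epochs, 150)
})

test_that("fitted baselines never lose to the constant-mean predictor on training data", {
  cfg <- tinyConfig(seed = 13)
  ds <- makeDataset(cfg)
  envs <- ds$true_envelopes
  y <- as.numeric(unclass(ds$force))
  N <- length(y)
  split <- allocateData(N, c(0.3, 0.2, 0.5))
  eidx <- split$estimation_idx
  env_e <- emgforce:::subsetEnvelopes(envs, eidx)
  sse_mean <- sum((y[eidx] - mean(y[eidx]))^2)
  fams <- c("model6", "model9", "OLS")
  for (fam in fams) {
    fit <- fitLipModel(fam, env_e, y[eidx])
    sse <- sum((predictBaseline(fit, env_e) - y[eidx])^2)
    expect_lte(sse, sse_mean + 1e-9)
  }
  rf <- fitRidge(env_e, y[eidx])
  expect_lte(sum((predictBaseline(rf, env_e) - y[eidx])^2), sse_mean + 1e-9)
})
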