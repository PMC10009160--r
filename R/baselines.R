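# Thirteen comparison estimators of the EMG-force literature.
#
# Model structures 1-9 map a per-muscle envelope e to a force contribution and
# sum over muscles (parameters a..e per muscle):
#   1: a*e + b*e          5: a*e^4 + b*e^3 + c*e^2 + d*e + e5
#   2: a*e^b              6: a + b*e
#   3: a*exp(b*e)         7: e^a + exp(b - c*e)
#   4: a*e^b + c*e^d      8: a + b*cos(e) + c*sin(e)
#                         9: a + b*sin(e)
# 1, 5, 6, 8, 9 and OLS are linear in the parameters (convex, solved by least
# squares); 2, 3, 4, 7 are non-convex and fitted by particle swarm
# optimisation. OLS adds a single global intercept; ridge (RLS), linear SVR
# and a small Levenberg-Marquardt-trained feed-forward network complete the
# roster.

EXP_CLIP <- 1e12   # exponential families are clipped here to tame blow-up

.lipFamilies <- c("model1", "model5", "model6", "model8", "model9", "OLS")
.psoFamilies <- c("model2", "model3", "model4", "model7")

#' Specification of a comparison model family
#'
#' @param family one of `"model1"`..`"model9"`, `"OLS"`, `"RLS"`, `"SVR"`,
#'   `"ANN"`, `"proposed"`.
#' @return A list of class `ModelSpec` with the family name, its per-muscle
#'   parameter count and the fitting route (`LS`, `PSO`, `ridge`, `svr`,
#'   `ann`, or `loglinear-LS` for the proposed model).
#' @export
modelSpec <- function(family) {
  ppm <- c(model1 = 2L, model2 = 2L, model3 = 2L, model4 = 4L, model5 = 5L,
           model6 = 2L, model7 = 3L, model8 = 3L, model9 = 2L,
           OLS = 1L, RLS = 1L, SVR = 1L, ANN = NA_integer_, proposed = 1L)
  if (!family %in% names(ppm)) stop("unknown model family: ", family, call. = FALSE)
  fitting <- if (family %in% .lipFamilies) "LS"
             else if (family %in% .psoFamilies) "PSO"
             else switch(family, RLS = "ridge", SVR = "svr", ANN = "ann",
                         proposed = "loglinear-LS")
  structure(list(family = family, params_per_muscle = ppm[[family]],
                 fitting = fitting),
            class = "ModelSpec")
}

# envelope list -> N x M matrix, with ids
envMatrix <- function(envelopes) {
  stopifnot(is.list(envelopes), length(envelopes) >= 1L)
  N <- length(envelopes[[1L]])
  E <- vapply(envelopes, as.numeric, numeric(N))
  matrix(E, nrow = N)
}

# number of free parameters of a family for M muscles
nParams <- function(family, M) {
  s <- modelSpec(family)
  if (family %in% c("OLS", "RLS", "SVR")) M + 1L else s$params_per_muscle * M
}

#' Evaluate a model structure at given parameters
#'
#' Computes the estimated force TR(t) for one of the nine literature model
#' structures or OLS, at an explicit parameter vector. Parameters are laid
#' out muscle-major: all coefficients of muscle 1, then muscle 2, etc.; OLS
#' is `(c_1, ..., c_M, intercept)`. Power terms floor the envelope at
#' `epsilon_floor` (default `1e-8 * max(env)`) so `0^negative` cannot occur;
#' exponentials are clipped at `1e12`.
#'
#' @param family model family name (see [modelSpec()]).
#' @param params flat numeric parameter vector.
#' @param envelopes list of [envelope()]s.
#' @param epsilon_floor positive floor for power terms, or `NULL` for the
#'   relative default.
#' @return Numeric vector TR of length N.
#' @export
evaluateModel <- function(family, params, envelopes, epsilon_floor = NULL) {
  E <- envMatrix(envelopes)
  M <- ncol(E)
  np <- nParams(family, M)
  if (length(params) != np)
    stop(sprintf("family %s with %d muscle(s) needs %d parameters, got %d",
                 family, M, np, length(params)), call. = FALSE)
  if (is.null(epsilon_floor)) epsilon_floor <- max(1e-8 * max(E), 1e-300)
  Ef <- pmax(E, epsilon_floor)
  clipExp <- function(z) pmin(pmax(z, -EXP_CLIP), EXP_CLIP)
  TR <- numeric(nrow(E))
  if (family == "OLS") return(as.numeric(E %*% params[seq_len(M)]) + params[M + 1L])
  ppm <- modelSpec(family)$params_per_muscle
  overflow <- FALSE
  for (i in seq_len(M)) {
    p <- params[(i - 1L) * ppm + seq_len(ppm)]
    e <- E[, i]; ef <- Ef[, i]
    ti <- switch(family,
      model1 = p[1L] * e + p[2L] * e,
      model2 = p[1L] * ef^p[2L],
      model3 = p[1L] * exp(pmin(p[2L] * e, log(EXP_CLIP))),
      model4 = p[1L] * ef^p[2L] + p[3L] * ef^p[4L],
      model5 = p[1L] * e^4 + p[2L] * e^3 + p[3L] * e^2 + p[4L] * e + p[5L],
      model6 = p[1L] + p[2L] * e,
      model7 = ef^p[1L] + exp(pmin(p[2L] - p[3L] * e, log(EXP_CLIP))),
      model8 = p[1L] + p[2L] * cos(e) + p[3L] * sin(e),
      model9 = p[1L] + p[2L] * sin(e),
      stop("evaluateModel does not apply to family ", family, call. = FALSE))
    if (any(!is.finite(ti)) || any(abs(ti) > EXP_CLIP)) {
      overflow <- TRUE
      ti <- clipExp(ifelse(is.finite(ti), ti, sign(ti) * EXP_CLIP))
      ti[is.na(ti)] <- 0
    }
    TR <- TR + ti
  }
  if (overflow) warning(sprintf("%s overflowed and was clipped at %g", family, EXP_CLIP))
  TR
}

# basis matrix of a linear-in-the-parameters family; columns follow the
# muscle-major parameter layout, so basis %*% params == evaluateModel(...)
lipBasis <- function(family, E) {
  M <- ncol(E)
  one <- rep(1, nrow(E))
  cols <- switch(family,
    model1 = lapply(seq_len(M), function(i) cbind(E[, i], E[, i])),
    model5 = lapply(seq_len(M), function(i)
      cbind(E[, i]^4, E[, i]^3, E[, i]^2, E[, i], one)),
    model6 = lapply(seq_len(M), function(i) cbind(one, E[, i])),
    model8 = lapply(seq_len(M), function(i) cbind(one, cos(E[, i]), sin(E[, i]))),
    model9 = lapply(seq_len(M), function(i) cbind(one, sin(E[, i]))),
    OLS    = list(E, matrix(one, ncol = 1L)),
    stop(family, " is not linear in the parameters", call. = FALSE))
  B <- do.call(cbind, cols)
  dimnames(B) <- NULL
  B
}

#' Fit a linear-in-the-parameters comparison model
#'
#' Expands the envelopes into the family's basis and solves the least-squares
#' problem. Bases that are collinear by construction (model 1's duplicated
#' term; the repeated per-muscle intercepts of models 6, 8, 9) are resolved
#' by the minimum-norm pseudo-inverse path of [solveLeastSquares()].
#'
#' @param family one of `"model1"`, `"model5"`, `"model6"`, `"model8"`,
#'   `"model9"`, `"OLS"`.
#' @param envelopes list of [envelope()]s.
#' @param force one-channel [signalMatrix()] (or numeric vector).
#' @return A `BaselineFit` holding the flat parameter vector.
#' @export
fitLipModel <- function(family, envelopes, force) {
  if (!family %in% .lipFamilies)
    stop(family, " is not a least-squares family", call. = FALSE)
  E <- envMatrix(envelopes)
  b <- as.numeric(unclass(force))
  if (length(b) != nrow(E)) stop("envelopes and force lengths differ", call. = FALSE)
  B <- lipBasis(family, E)
  x <- solveLeastSquares(B, b)
  baselineFit(family, params = as.numeric(x),
              meta = list(solver_path = attr(x, "solver_path")))
}

#' PSO configuration
#'
#' Defaults follow the standard adaptive-neighbourhood configuration for this
#' problem class: `200 * n_weights` iterations, swarm of
#' `min(100, 10 * n_weights)`, minimum neighbourhood fraction 0.25,
#' self/social acceleration 1.49, ten restarts.
#'
#' @param n_weights number of parameters being optimised.
#' @param max_iter,swarm_size,min_neighborhood_fraction,self_adjustment,social_adjustment,n_restarts
#'   overrides of the defaults.
#' @param seed integer seed; every run is deterministic given it.
#' @param lower,upper parameter bounds, recycled to `n_weights`.
#' @return A list of class `PSOConfig`.
#' @export
psoConfig <- function(n_weights,
                      max_iter = 200L * n_weights,
                      swarm_size = min(100L, 10L * n_weights),
                      min_neighborhood_fraction = 0.25,
                      self_adjustment = 1.49,
                      social_adjustment = 1.49,
                      n_restarts = 10L,
                      seed = 1L,
                      lower = -10, upper = 10) {
  stopifnot(n_weights >= 1L, max_iter >= 1L, swarm_size >= 2L, n_restarts >= 1L)
  lower <- rep_len(lower, n_weights); upper <- rep_len(upper, n_weights)
  if (any(upper <= lower)) stop("bounds must satisfy lower < upper", call. = FALSE)
  structure(list(n_weights = as.integer(n_weights),
                 max_iter = as.integer(max_iter),
                 swarm_size = as.integer(swarm_size),
                 min_neighborhood_fraction = min_neighborhood_fraction,
                 self_adjustment = self_adjustment,
                 social_adjustment = social_adjustment,
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed),
                 lower = lower, upper = upper),
            class = "PSOConfig")
}

#' Particle swarm optimisation
#'
#' Global-best PSO with adaptive neighbourhood and inertia: each particle is
#' pulled toward its own best and the best of a random neighbourhood whose
#' size grows when the swarm stalls and resets to the minimum fraction on
#' improvement; inertia adapts in `[0.1, 1.1]`. Deterministic given
#' `config$seed`. Non-finite objective values are treated as `+1e100` so an
#' unbounded objective cannot poison the bookkeeping.
#'
#' @param objective function mapping a parameter vector to a scalar.
#' @param config a [psoConfig()] carrying bounds and budgets.
#' @return List with `x_best`, `f_best`, and `trace` (best value per
#'   iteration).
#' @export
psoOptimize <- function(objective, config) {
  stopifnot(inherits(config, "PSOConfig"))
  set.seed(config$seed)
  n <- config$n_weights; S <- config$swarm_size
  lo <- config$lower; hi <- config$upper; rng <- hi - lo
  c1 <- config$self_adjustment; c2 <- config$social_adjustment
  minN <- max(2L, ceiling(S * config$min_neighborhood_fraction))
  evalSafe <- function(x) {
    v <- objective(x)
    if (!is.finite(v)) 1e100 else v
  }
  X <- matrix(stats::runif(S * n, lo, hi), nrow = n)   # columns = particles
  V <- matrix(stats::runif(S * n, -rng, rng), nrow = n)
  P <- X
  pf <- apply(X, 2L, evalSafe)
  gbest <- which.min(pf); gx <- P[, gbest]; gf <- pf[gbest]
  W <- 1.1; stall <- 0L; Nsz <- minN
  trace <- numeric(config$max_iter)
  for (it in seq_len(config$max_iter)) {
    improved <- FALSE
    for (j in seq_len(S)) {
      nb <- sample.int(S, Nsz)            # random informers incl. possibly j
      lb <- nb[which.min(pf[nb])]
      u1 <- stats::runif(n); u2 <- stats::runif(n)
      V[, j] <- W * V[, j] + c1 * u1 * (P[, j] - X[, j]) +
                              c2 * u2 * (P[, lb] - X[, j])
      x <- X[, j] + V[, j]
      below <- x < lo; above <- x > hi
      x[below] <- lo[below]; x[above] <- hi[above]
      V[below | above, j] <- 0
      X[, j] <- x
      f <- evalSafe(x)
      if (f < pf[j]) { pf[j] <- f; P[, j] <- x }
      if (f < gf) { gf <- f; gx <- x; improved <- TRUE }
    }
    if (improved) {
      stall <- max(0L, stall - 1L); Nsz <- minN
    } else {
      stall <- stall + 1L; Nsz <- min(Nsz + minN, S)
    }
    if (stall < 2L) W <- min(2 * W, 1.1) else if (stall > 5L) W <- max(W / 2, 0.1)
    trace[it] <- gf
  }
  list(x_best = gx, f_best = gf, trace = trace)
}

#' Fit a non-convex model structure by multi-start PSO
#'
#' Minimises the estimation-set sum of squared errors of the family with
#' [psoOptimize()], restarted `config$n_restarts` times from different
#' seeds; among restarts, the parameter vector with the lowest
#' validation-set RMSE is returned (the stochastic optimiser is selected on
#' held-out data, not on its own training objective).
#'
#' @param family one of `"model2"`, `"model3"`, `"model4"`, `"model7"`.
#' @param envelopes list of [envelope()]s.
#' @param force measured force (one-channel `SignalMatrix` or vector).
#' @param split a [allocateData()] split providing `estimation_idx` and
#'   `validation_idx`.
#' @param config a [psoConfig()] for `nParams(family, M)` weights; `NULL`
#'   builds the default (exponent-type parameters bounded in `[-5, 5]`,
#'   others in `[-10, 10]`).
#' @param seed root seed used when `config` is `NULL`.
#' @return A `BaselineFit` with the winning parameters; metadata records each
#'   restart's estimation SSE and validation RMSE.
#' @export
fitPsoModel <- function(family, envelopes, force, split, config = NULL,
                        seed = 1L) {
  if (!family %in% .psoFamilies)
    stop(family, " is not a PSO-fitted family", call. = FALSE)
  E <- envMatrix(envelopes)
  b <- as.numeric(unclass(force))
  M <- ncol(E)
  np <- nParams(family, M)
  if (is.null(config)) {
    expo <- isExponentParam(family, M)
    config <- psoConfig(np, seed = as.integer(seed),
                        lower = ifelse(expo, -5, -10),
                        upper = ifelse(expo, 5, 10))
  }
  eidx <- split$estimation_idx; vidx <- split$validation_idx
  if (length(vidx) == 0L) vidx <- eidx   # degenerate split: select on estimation
  eps <- max(1e-8 * max(E), 1e-300)
  env_e <- lapply(seq_len(M), function(i) envelope(E[eidx, i], 1, paste0("m", i)))
  env_v <- lapply(seq_len(M), function(i) envelope(E[vidx, i], 1, paste0("m", i)))
  sseEst <- function(x) {
    r <- evaluateModel(family, x, env_e, epsilon_floor = eps) - b[eidx]
    sum(r * r)
  }
  best <- NULL
  meta <- list(restarts = list())
  for (k in seq_len(config$n_restarts)) {
    ck <- config; ck$seed <- config$seed + k - 1L
    res <- suppressWarnings(psoOptimize(sseEst, ck))
    pv <- suppressWarnings(evaluateModel(family, res$x_best, env_v, epsilon_floor = eps))
    vrmse <- sqrt(mean((pv - b[vidx])^2))
    meta$restarts[[k]] <- list(seed = ck$seed, sse = res$f_best,
                               validation_rmse = vrmse)
    if (is.null(best) || vrmse < best$vrmse)
      best <- list(x = res$x_best, vrmse = vrmse, restart = k, sse = res$f_best)
  }
  meta$selected_restart <- best$restart
  meta$validation_rmse <- best$vrmse
  baselineFit(family, params = best$x, meta = meta, epsilon_floor = eps)
}

# which parameters act as exponents (tighter default PSO bounds)
isExponentParam <- function(family, M) {
  per <- switch(family,
    model2 = c(FALSE, TRUE),
    model3 = c(FALSE, TRUE),
    model4 = c(FALSE, TRUE, FALSE, TRUE),
    model7 = c(TRUE, FALSE, FALSE),
    stop("no exponent map for ", family, call. = FALSE))
  rep(per, M)
}

#' Ridge (regularized least squares) baseline
#'
#' Closed-form ridge regression of force on the raw envelope matrix:
#' minimises `||Xw - y||^2 + lambda * ||w_slopes||^2`. The intercept is not
#' penalised, so the fit still recovers the force mean as `lambda` grows.
#'
#' @param envelopes list of [envelope()]s.
#' @param force measured force.
#' @param lambda nonnegative ridge penalty, default `0.01`.
#' @return A `BaselineFit` with parameters `(w_1..w_M, intercept)`.
#' @export
fitRidge <- function(envelopes, force, lambda = 0.01) {
  stopifnot(lambda >= 0)
  E <- envMatrix(envelopes)
  y <- as.numeric(unclass(force))
  X <- cbind(E, 1)
  D <- diag(c(rep(1, ncol(E)), 0))
  w <- solve(crossprod(X) + lambda * D, crossprod(X, y))
  baselineFit("RLS", params = as.numeric(w), meta = list(lambda = lambda))
}

#' Linear support-vector regression baseline
#'
#' Epsilon-SVR with a linear kernel on the raw envelope matrix; the cost
#' parameter is chosen by deterministic k-fold cross-validation over a
#' logarithmic grid on the estimation set, then the model is refit on the
#' whole estimation set at the winning cost.
#'
#' @param envelopes list of [envelope()]s.
#' @param force measured force.
#' @param split a [allocateData()] split; fitting and tuning use
#'   `estimation_idx` only.
#' @param cost_grid candidate costs, default `10^(-3:3)`.
#' @param folds number of CV folds, default 5.
#' @param epsilon width of the insensitive tube (on the scaled target),
#'   default 0.01 — tight, since the force target is low-noise after
#'   conditioning.
#' @return A `BaselineFit` with linearised parameters `(w_1..w_M, intercept)`
#'   (exact for the linear kernel); metadata records the CV table.
#' @export
fitSvr <- function(envelopes, force, split, cost_grid = 10^(-3:3),
                   folds = 5L, epsilon = 0.01) {
  E <- envMatrix(envelopes)
  y <- as.numeric(unclass(force))
  eidx <- split$estimation_idx
  Xe <- E[eidx, , drop = FALSE]; ye <- y[eidx]
  if (stats::sd(ye) == 0) {
    warning("constant force target; SVR falls back to a constant predictor")
    return(baselineFit("SVR", params = c(rep(0, ncol(E)), ye[1L]),
                       meta = list(constant_fallback = TRUE)))
  }
  cv_mse <- rep(NA_real_, length(cost_grid))
  if (length(cost_grid) > 1L) {
    fold_id <- rep_len(seq_len(folds), length(eidx))   # deterministic blocks
    for (ci in seq_along(cost_grid)) {
      errs <- vapply(seq_len(folds), function(f) {
        tr <- fold_id != f
        m <- e1071::svm(Xe[tr, , drop = FALSE], ye[tr], type = "eps-regression",
                        kernel = "linear", cost = cost_grid[ci],
                        epsilon = epsilon, scale = TRUE)
        mean((stats::predict(m, Xe[!tr, , drop = FALSE]) - ye[!tr])^2)
      }, numeric(1))
      cv_mse[ci] <- mean(errs)
    }
    cost <- cost_grid[which.min(cv_mse)]
  } else cost <- cost_grid[1L]
  m <- e1071::svm(Xe, ye, type = "eps-regression", kernel = "linear",
                  cost = cost, epsilon = epsilon, scale = TRUE)
  # linear kernel: fold the support-vector expansion and scaling into (w, b)
  w_scaled <- as.numeric(t(m$coefs) %*% m$SV)
  xs <- m$x.scale; ys <- m$y.scale
  w <- w_scaled / xs$`scaled:scale` * ys$`scaled:scale`
  b <- ys$`scaled:center` - ys$`scaled:scale` * m$rho -
       sum(w * xs$`scaled:center`)
  baselineFit("SVR", params = c(w, b),
              meta = list(cost = cost, cv_mse = cv_mse, cost_grid = cost_grid))
}

#' @export
print.BaselineFit <- function(x, ...) {
  cat(sprintf("BaselineFit: family %s, %d parameter(s)\n",
              x$family, length(x$params)))
  invisible(x)
}

baselineFit <- function(family, params, meta = list(), epsilon_floor = NULL,
                        extra = NULL) {
  structure(c(list(family = family, params = params,
                   epsilon_floor = epsilon_floor, meta = meta), extra),
            class = "BaselineFit")
}

#' Predict force from a fitted baseline
#'
#' @param fit a `BaselineFit` from one of the fitters.
#' @param envelopes list of [envelope()]s in the fitted muscle order.
#' @return Numeric vector of predicted force.
#' @export
predictBaseline <- function(fit, envelopes) {
  stopifnot(inherits(fit, "BaselineFit"))
  E <- envMatrix(envelopes)
  switch(fit$family,
    RLS = ,
    SVR = as.numeric(E %*% fit$params[seq_len(ncol(E))]) +
          fit$params[ncol(E) + 1L],
    ANN = annForward(fit, E),
    evaluateModel(fit$family, fit$params, envelopes,
                  epsilon_floor = fit$epsilon_floor))
}
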