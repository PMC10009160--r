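# Feed-forward network baseline: one hidden layer of tanh units, linear
# output, trained by damped Gauss-Newton (Levenberg-Marquardt) on the squared
# error with an analytic Jacobian. The damping term starts at 0.001 and is
# adapted each step: successful steps move the update toward pure
# Gauss-Newton, rejected steps toward gradient descent. Early stopping
# monitors the validation split.

annPack <- function(W1, b1, w2, b2) c(as.numeric(W1), b1, w2, b2)

annUnpack <- function(theta, d, H) {
  W1 <- matrix(theta[seq_len(H * d)], nrow = H)
  o <- H * d
  list(W1 = W1, b1 = theta[o + seq_len(H)],
       w2 = theta[o + H + seq_len(H)], b2 = theta[o + 2L * H + 1L])
}

# hidden activations and output for standardized inputs
annEval <- function(theta, X, d, H) {
  p <- annUnpack(theta, d, H)
  Z <- tanh(sweep(X %*% t(p$W1), 2L, p$b1, "+"))
  list(Z = Z, yhat = as.numeric(Z %*% p$w2) + p$b2)
}

# Jacobian of the residual vector wrt all parameters (N x P)
annJacobian <- function(theta, X, d, H) {
  p <- annUnpack(theta, d, H)
  Z <- tanh(sweep(X %*% t(p$W1), 2L, p$b1, "+"))
  dZ <- (1 - Z^2)                      # N x H
  N <- nrow(X)
  Jb1 <- sweep(dZ, 2L, p$w2, "*")      # d residual / d b1
  JW1 <- matrix(0, N, H * d)
  for (j in seq_len(d))
    JW1[, (j - 1L) * H + seq_len(H)] <- Jb1 * X[, j]
  cbind(JW1, Jb1, Z, rep(1, N))
}

#' Feed-forward neural-network baseline
#'
#' Trains a single-hidden-layer network (default 10 tanh units, linear
#' output) on the estimation split by Levenberg-Marquardt damped
#' Gauss-Newton, with the damping factor initialised at `0.001` and adapted
#' multiplicatively, and early stopping on the validation split (training
#' halts when validation error has not improved for `patience` epochs; the
#' best-validation parameters are kept). Inputs and target are standardized
#' with estimation-split statistics. If training diverges the fit restarts
#' from a fresh initialisation with heavier damping, at most three times.
#' Deterministic given `seed`.
#'
#' @param envelopes list of [envelope()]s.
#' @param force measured force.
#' @param split a [allocateData()] split with estimation and validation sets.
#' @param seed integer seed for the weight initialisation.
#' @param hidden number of hidden units, default 10.
#' @param max_epochs cap on LM iterations, default 150.
#' @param patience validation epochs without improvement before stopping.
#' @return A `BaselineFit` (family `"ANN"`) carrying the weights and the
#'   standardization constants; metadata records epochs run and the stopping
#'   reason.
#' @export
fitAnn <- function(envelopes, force, split, seed = 1L, hidden = 10L,
                   max_epochs = 150L, patience = 6L) {
  E <- envMatrix(envelopes)
  y <- as.numeric(unclass(force))
  eidx <- split$estimation_idx
  vidx <- split$validation_idx
  if (length(vidx) == 0L) vidx <- eidx
  d <- ncol(E); H <- as.integer(hidden)
  xc <- colMeans(E[eidx, , drop = FALSE])
  xs <- apply(E[eidx, , drop = FALSE], 2L, stats::sd); xs[xs == 0] <- 1
  yc <- mean(y[eidx]); ys <- stats::sd(y[eidx]); if (ys == 0) ys <- 1
  Xe <- sweep(sweep(E[eidx, , drop = FALSE], 2L, xc), 2L, xs, "/")
  Xv <- sweep(sweep(E[vidx, , drop = FALSE], 2L, xc), 2L, xs, "/")
  ye <- (y[eidx] - yc) / ys; yv <- (y[vidx] - yc) / ys
  P <- H * d + 2L * H + 1L

  trainOnce <- function(init_seed, mu0) {
    set.seed(init_seed)
    theta <- stats::runif(P, -0.5, 0.5)
    mu <- mu0
    sse <- sum((annEval(theta, Xe, d, H)$yhat - ye)^2)
    best <- list(theta = theta,
                 vmse = mean((annEval(theta, Xv, d, H)$yhat - yv)^2))
    stall_v <- 0L; epochs <- 0L; reason <- "max_epochs"
    for (ep in seq_len(max_epochs)) {
      epochs <- ep
      r <- annEval(theta, Xe, d, H)$yhat - ye
      J <- annJacobian(theta, Xe, d, H)
      g <- crossprod(J, r)
      Hm <- crossprod(J)
      accepted <- FALSE
      for (tries in 1:30) {
        step <- tryCatch(
          solve(Hm + mu * diag(diag(Hm) + 1e-8), g),
          error = function(e) NULL)
        if (!is.null(step)) {
          cand <- theta - as.numeric(step)
          sse_c <- sum((annEval(cand, Xe, d, H)$yhat - ye)^2)
          if (is.finite(sse_c) && sse_c < sse) {
            theta <- cand; sse <- sse_c
            mu <- max(mu / 10, 1e-12)
            accepted <- TRUE
            break
          }
        }
        mu <- mu * 10
        if (mu > 1e10) return(list(diverged = TRUE))
      }
      if (!accepted) { reason <- "no_descent"; break }
      vmse <- mean((annEval(theta, Xv, d, H)$yhat - yv)^2)
      if (vmse < best$vmse - 1e-12) {
        best <- list(theta = theta, vmse = vmse); stall_v <- 0L
      } else {
        stall_v <- stall_v + 1L
        if (stall_v >= patience) { reason <- "early_stop"; break }
      }
    }
    list(diverged = FALSE, theta = best$theta, vmse = best$vmse,
         epochs = epochs, reason = reason)
  }

  res <- NULL
  for (attempt in 0:3) {
    res <- trainOnce(as.integer(seed) + attempt, 0.001 * 100^attempt)
    if (!isTRUE(res$diverged)) break
  }
  if (isTRUE(res$diverged)) stop("ANN training diverged after 3 restarts", call. = FALSE)
  pars <- annUnpack(res$theta, d, H)
  baselineFit("ANN", params = res$theta,
              meta = list(epochs = res$epochs, stop_reason = res$reason,
                          validation_mse = res$vmse, hidden = H),
              extra = list(ann = list(W1 = pars$W1, b1 = pars$b1,
                                      w2 = pars$w2, b2 = pars$b2,
                                      x_center = xc, x_scale = xs,
                                      y_center = yc, y_scale = ys,
                                      d = d, H = H)))
}

# forward pass on raw envelope matrix (un-standardized)
annForward <- function(fit, E) {
  a <- fit$ann
  X <- sweep(sweep(E, 2L, a$x_center), 2L, a$x_scale, "/")
  Z <- tanh(sweep(X %*% t(a$W1), 2L, a$b1, "+"))
  (as.numeric(Z %*% a$w2) + a$b2) * a$y_scale + a$y_center
}
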