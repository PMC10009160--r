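#' Build the log-linear design matrix
#'
#' Assembles the least-squares system `A x = b` of the log-linear force model
#' f(t) = w0 + sum_i wi * ln(sEMG_i(t)): the first column of `A` is all ones
#' (intercept) and column `i + 1` is the natural log of muscle `i`'s envelope,
#' floored at `epsilon_floor` so that silent samples do not produce `-Inf`.
#'
#' @param envelopes list of [envelope()] objects, one per muscle, equal length.
#' @param force one-channel [signalMatrix()] of the measured force, same
#'   length and sampling rate as the envelopes.
#' @param epsilon_floor positive floor applied before the log. The default
#'   `NULL` uses `1e-8` times the global maximum envelope value, which keeps
#'   the floor unit-independent.
#' @return A list of class `DesignMatrix` with elements `A` (N x (M+1)), `b`
#'   (length N), `muscle_ids` and `epsilon_floor`.
#' @export
buildDesignMatrix <- function(envelopes, force, epsilon_floor = NULL) {
  if (!is.list(envelopes) || length(envelopes) < 1L)
    stop("`envelopes` must be a nonempty list of Envelope objects", call. = FALSE)
  if (!all(vapply(envelopes, inherits, logical(1), "Envelope")))
    stop("all elements of `envelopes` must be Envelope objects", call. = FALSE)
  b <- as.numeric(unclass(force))
  N <- length(b)
  lens <- vapply(envelopes, length, integer(1))
  if (any(lens != N))
    stop("envelopes and force must have the same number of samples", call. = FALSE)
  M <- length(envelopes)
  gmax <- max(vapply(envelopes, max, numeric(1)))
  if (is.null(epsilon_floor)) {
    epsilon_floor <- 1e-8 * gmax
    if (epsilon_floor <= 0) epsilon_floor <- 1e-8
  }
  if (epsilon_floor <= 0) stop("`epsilon_floor` must be positive", call. = FALSE)
  A <- matrix(1, nrow = N, ncol = M + 1L)
  for (i in seq_len(M)) {
    if (max(envelopes[[i]]) <= 0)
      warning(sprintf("envelope %d is identically zero; its log column is constant", i))
    A[, i + 1L] <- log(pmax(as.numeric(envelopes[[i]]), epsilon_floor))
  }
  if (N < M + 1L)
    warning("fewer samples than parameters: system is underdetermined")
  structure(list(A = A, b = b,
                 muscle_ids = vapply(envelopes, muscleId, character(1)),
                 epsilon_floor = epsilon_floor),
            class = "DesignMatrix")
}

#' Numerically stable least squares with SVD fallback
#'
#' Solves `min ||A x - b||^2`. Full-column-rank systems use a QR/triangular
#' solve (the normal-equation inverse is never formed). Rank-deficient
#' systems fall back to the Moore-Penrose pseudo-inverse via SVD, taking
#' reciprocals only of singular values above the conventional tolerance
#' `max(dim(A)) * max(sv) * eps`, which yields the minimum-norm minimizer.
#'
#' @param A numeric matrix, N x m.
#' @param b numeric vector of length N.
#' @return Numeric vector `x` with attribute `solver_path`, either
#'   `"normal-solve"` or `"pseudo-inverse"`.
#' @export
solveLeastSquares <- function(A, b) {
  if (!is.matrix(A) || length(b) != nrow(A))
    stop("`A` must be a matrix with nrow(A) == length(b)", call. = FALSE)
  if (nrow(A) == 0L || ncol(A) == 0L) stop("empty system", call. = FALSE)
  if (!all(is.finite(A)) || !all(is.finite(b)))
    stop("non-finite entries in the system", call. = FALSE)
  sv <- svd(A)
  tol <- max(dim(A)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (rank == ncol(A) && nrow(A) >= ncol(A)) {
    qrA <- qr(A)
    x <- as.numeric(qr.coef(qrA, b))
    attr(x, "solver_path") <- "normal-solve"
  } else {
    dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
    x <- as.numeric(sv$v %*% (dinv * crossprod(sv$u, b)))
    attr(x, "solver_path") <- "pseudo-inverse"
  }
  x
}

#' Condition number of a design matrix
#'
#' Ratio of the largest to the smallest singular value; `Inf` for
#' rank-deficient matrices. For any A this equals the square root of the
#' condition number of the Gram matrix A'A, which is why ill-conditioning
#' punishes the explicit normal-equation inverse twice as hard as a direct
#' solve on A.
#'
#' @param A numeric matrix.
#' @return A single number `>= 1` (possibly `Inf`).
#' @export
conditionNumber <- function(A) {
  if (!is.matrix(A) || length(A) == 0L) stop("`A` must be a nonempty matrix", call. = FALSE)
  d <- svd(A, nu = 0L, nv = 0L)$d
  tol <- max(dim(A)) * max(d) * .Machine$double.eps
  if (min(d) <= tol) Inf else max(d) / min(d)
}

#' Fit the convex log-linear force model
#'
#' Fits f(t) = w0 + sum_i wi * ln(sEMG_i(t)) by least squares on the
#' log-transformed envelope design matrix. Because the model is linear in its
#' parameters the problem is convex and the solution is the global minimum.
#'
#' @inheritParams buildDesignMatrix
#' @return A list of class `LogLinearModel`: `w0`, `w` (length M),
#'   `muscle_ids`, `epsilon_floor`, `condition_number`, `solver_path`.
#' @examples
#' fs <- 100
#' e1 <- envelope(seq(0.1, 1, length.out = 200), fs, "m1")
#' f  <- signalMatrix(2 + 3 * log(as.numeric(e1)), fs)
#' fit <- fitLogLinear(list(e1), f)
#' c(fit$w0, fit$w)   # recovers (2, 3)
#' @export
fitLogLinear <- function(envelopes, force, epsilon_floor = NULL) {
  dm <- buildDesignMatrix(envelopes, force, epsilon_floor)
  x <- solveLeastSquares(dm$A, dm$b)
  structure(list(w0 = x[1L], w = x[-1L],
                 muscle_ids = dm$muscle_ids,
                 epsilon_floor = dm$epsilon_floor,
                 condition_number = conditionNumber(dm$A),
                 solver_path = attr(x, "solver_path")),
            class = "LogLinearModel")
}

#' @export
print.LogLinearModel <- function(x, ...) {
  cat("Log-linear sEMG-force model\n")
  cat(sprintf("  w0 = %.6g\n", x$w0))
  for (i in seq_along(x$w))
    cat(sprintf("  w[%s] = %.6g\n", x$muscle_ids[i], x$w[i]))
  cat(sprintf("  condition number %.4g (%s)\n", x$condition_number, x$solver_path))
  invisible(x)
}

#' Predict force from envelopes
#'
#' Evaluates the fitted log-linear model on a set of envelopes (training or
#' new data). Envelope order must match the muscles the model was fit on.
#'
#' @param model a `LogLinearModel`.
#' @param envelopes list of [envelope()]s in the model's muscle order.
#' @return One-channel `SignalMatrix` of predicted force.
#' @export
predictForce <- function(model, envelopes) {
  if (!inherits(model, "LogLinearModel")) stop("`model` must be a LogLinearModel", call. = FALSE)
  ids <- vapply(envelopes, muscleId, character(1))
  if (length(ids) != length(model$muscle_ids) || !all(ids == model$muscle_ids))
    stop("envelope muscles do not match the model's muscles", call. = FALSE)
  N <- length(envelopes[[1L]])
  f <- rep(model$w0, N)
  for (i in seq_along(envelopes))
    f <- f + model$w[i] * log(pmax(as.numeric(envelopes[[i]]), model$epsilon_floor))
  signalMatrix(f, samplingRate(envelopes[[1L]]))
}

#' Serialize / restore a fitted log-linear model
#'
#' @param model a `LogLinearModel`.
#' @param path file path for the flat JSON representation.
#' @return `writeLogLinearModel` returns `path` invisibly;
#'   `readLogLinearModel` returns the restored `LogLinearModel`.
#' @export
writeLogLinearModel <- function(model, path) {
  jsonlite::write_json(
    list(muscle_ids = model$muscle_ids, w0 = model$w0, w = model$w,
         epsilon_floor = model$epsilon_floor,
         condition_number = model$condition_number,
         solver_path = model$solver_path),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeLogLinearModel
#' @export
readLogLinearModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(w0 = j$w0, w = as.numeric(j$w),
                 muscle_ids = as.character(j$muscle_ids),
                 epsilon_floor = j$epsilon_floor,
                 condition_number = j$condition_number,
                 solver_path = j$solver_path),
            class = "LogLinearModel")
}
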