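# ---- standardization ----------------------------------------------------------

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Standardize a train/test pair with training statistics
#'
#' Column means and population standard deviations are estimated on the
#' training split and applied to both splits, per variable, so the test split
#' never leaks into the estimates. Variables with zero training variance are
#' zeroed and flagged.
#'
#' @param train,test lists with elements `x` (target vector) and `Y`
#'   (trials x voxels matrix); `test` may be `NULL`.
#' @return list with standardized `train`, `test`, and `flagged` voxel
#'   indices.
#' @export
standardize_pair <- function(train, test = NULL) {
  Y <- as.matrix(train$Y)
  mu <- colMeans(Y)
  sdv <- sqrt(colMeans(sweep(Y, 2, mu)^2))
  flagged <- which(sdv < 1e-12)
  sdv[flagged] <- 1
  mx <- mean(train$x)
  sx <- pop_sd(train$x)
  if (sx < 1e-12) stop("zero-variance training target")
  std <- function(pair) {
    Ys <- sweep(sweep(as.matrix(pair$Y), 2, mu), 2, sdv, "/")
    Ys[, flagged] <- 0
    list(x = (pair$x - mx) / sx, Y = Ys)
  }
  out <- list(train = std(train), flagged = flagged)
  if (!is.null(test)) out$test <- std(test)
  out
}

# ---- encoding ------------------------------------------------------------------

#' Fit a univariate encoding model for one voxel
#'
#' Ordinary least squares of a voxel response on a single standardized
#' complexity value: `beta = (x'x)^-1 x'y`.
#'
#' @param x standardized target vector (length n).
#' @param y one voxel's standardized response vector (length n).
#' @return object of class `encoding_model` with field `beta`.
#' @export
fit_encoding <- function(x, y) {
  sxx <- sum(x^2)
  if (sxx == 0) stop("x'x is zero; cannot fit")
  structure(list(beta = sum(x * y) / sxx), class = "encoding_model")
}

#' Encoding betas for every voxel of an ROI
#'
#' @param x standardized target vector.
#' @param Y trials x voxels standardized response matrix.
#' @return numeric vector of per-voxel regression slopes.
#' @export
encode_roi <- function(x, Y) {
  sxx <- sum(x^2)
  if (sxx == 0) stop("x'x is zero; cannot fit")
  unname(drop(crossprod(as.matrix(Y), x))) / sxx
}

# ---- ridge machinery -----------------------------------------------------------

#' Effective degrees of freedom of a ridge fit
#'
#' `sum_j d_j^2 / (d_j^2 + lambda)` over the nonzero singular values `d_j` of
#' the design matrix; the trace of the ridge hat matrix.
#'
#' @param singular_values singular values of the (standardized) design.
#' @param lambda ridge penalty, `>= 0`.
#' @return scalar effective degrees of freedom.
#' @export
edf_of_lambda <- function(singular_values, lambda) {
  if (lambda < 0) stop("lambda must be non-negative")
  d2 <- singular_values[singular_values > 0]^2
  sum(d2 / (d2 + lambda))
}

#' Grid of effective-degrees-of-freedom targets
#'
#' 100 linearly spaced values between 0.1 and `min(n, q) - 0.1`, the
#' parameterization in which the ridge penalty is searched.
#'
#' @param n training trials.
#' @param q voxels.
#' @param length grid size.
#' @return numeric vector of df targets.
#' @export
edf_grid <- function(n, q, length = 100) {
  m <- min(n, q)
  if (m <= 0.2) stop("min(n, q) too small for the df grid")
  seq(0.1, m - 0.1, length.out = length)
}

#' Solve the ridge penalty attaining a target effective df
#'
#' Newton's method on `edf(lambda) - target`, warm-startable and safeguarded
#' by bisection on a bracketing interval, so convergence holds even for
#' ill-conditioned spectra.
#'
#' @param singular_values singular values of the design.
#' @param target_df requested effective degrees of freedom, in
#'   `(0, rank)`.
#' @param init optional warm start for lambda.
#' @param tol convergence tolerance on `|edf(lambda) - target_df|`.
#' @return scalar `lambda >= 0`.
#' @export
solve_lambda <- function(singular_values, target_df, init = NULL,
                         tol = 1e-8) {
  d2 <- singular_values[singular_values > 1e-12]^2
  rank <- length(d2)
  if (target_df <= 0 || target_df >= rank)
    stop("target_df must lie strictly between 0 and the rank (", rank, ")")
  g <- function(l) sum(d2 / (d2 + l)) - target_df
  gp <- function(l) -sum(d2 / (d2 + l)^2)
  lo <- 0; hi <- max(d2) * (rank / target_df)
  while (g(hi) > 0) hi <- hi * 10
  lambda <- if (!is.null(init) && init > lo && init < hi) init
            else max(d2) * (rank - target_df) / target_df
  for (iter in 1:200) {
    val <- g(lambda)
    if (abs(val) < tol) return(lambda)
    if (val > 0) lo <- lambda else hi <- lambda
    step <- lambda - val / gp(lambda)
    lambda <- if (step > lo && step < hi) step else (lo + hi) / 2
  }
  lambda
}

#' Leave-one-out error of a ridge decoder
#'
#' Mean squared leave-one-out prediction error on the training set, computed
#' with the exact closed-form shortcut `e_i / (1 - h_ii)` where `h_ii` are
#' the diagonal entries of the ridge hat matrix.
#'
#' @param Y trials x voxels standardized training responses (or a precomputed
#'   `svd(Y)` via `sv`).
#' @param x standardized training targets.
#' @param lambda ridge penalty.
#' @param sv optional `svd(Y)` result, to avoid re-decomposition.
#' @return scalar mean squared LOO error.
#' @export
loo_error <- function(Y, x, lambda, sv = NULL) {
  if (is.null(sv)) sv <- svd(as.matrix(Y))
  keep <- sv$d > 1e-12
  U <- sv$u[, keep, drop = FALSE]
  w <- sv$d[keep]^2 / (sv$d[keep]^2 + lambda)
  pred <- U %*% (w * drop(crossprod(U, x)))
  hii <- drop((U^2) %*% w)
  if (any(hii >= 1 - 1e-12))
    stop("leverage ~ 1 at trial ", which(hii >= 1 - 1e-12)[1],
         "; LOO undefined")
  mean(((x - pred) / (1 - hii))^2)
}

#' Fit a multivariate ridge decoding model for an ROI
#'
#' `beta = (Y'Y + lambda I)^-1 Y' x`, with the penalty chosen by grid search:
#' effective-df targets from [edf_grid()] are converted to penalties by
#' [solve_lambda()] (targets at or above the rank of `Y` map to the
#' least-squares limit `lambda = 0`), and the penalty minimizing the
#' leave-one-out error is selected, ties broken toward the larger penalty.
#'
#' @param Y trials x voxels standardized training responses.
#' @param x standardized training targets.
#' @param grid_length number of df targets.
#' @param sv optional precomputed `svd(Y)`.
#' @return object of class `decoding_model`: `beta`, `lambda`, chosen `edf`,
#'   the search `grid` (df, lambda, loo), and the training spectrum `d`.
#' @export
fit_decoding <- function(Y, x, grid_length = 100, sv = NULL) {
  Y <- as.matrix(Y)
  if (all(Y == 0)) stop("degenerate response matrix (all zeros)")
  if (is.null(sv)) sv <- svd(Y)
  d <- sv$d
  rank <- sum(d > 1e-12)
  targets <- edf_grid(nrow(Y), ncol(Y), grid_length)
  lambdas <- numeric(length(targets))
  init <- NULL
  for (i in seq_along(targets)) {
    if (targets[i] >= rank - 1e-8) {
      lambdas[i] <- 0
    } else {
      lambdas[i] <- solve_lambda(d, targets[i], init = init)
      init <- lambdas[i]
    }
  }
  loo <- vapply(lambdas, function(l) loo_error(Y, x, l, sv = sv), numeric(1))
  best <- which(loo <= min(loo) + 1e-15)
  best <- best[which.max(lambdas[best])]        # ties toward larger lambda
  lambda <- lambdas[best]
  keep <- d > 1e-12
  shrink <- d[keep] / (d[keep]^2 + lambda)
  beta <- drop(sv$v[, keep, drop = FALSE] %*%
                 (shrink * drop(crossprod(sv$u[, keep, drop = FALSE], x))))
  structure(list(beta = beta, lambda = lambda,
                 edf = edf_of_lambda(d, lambda),
                 grid = data.frame(df = targets, lambda = lambdas, loo = loo),
                 d = d),
            class = "decoding_model")
}

# ---- validation ----------------------------------------------------------------

pearson_or_zero <- function(truth, pred) {
  if (pop_sd(pred) < 1e-12 || pop_sd(truth) < 1e-12)
    return(structure(0, flagged = TRUE))
  stats::cor(truth, pred)
}

#' Predict from a fitted model
#' @param object a `decoding_model`.
#' @param Y test trials x voxels matrix.
#' @param ... unused.
#' @return predicted target vector.
#' @export
predict.decoding_model <- function(object, Y, ...) {
  drop(as.matrix(Y) %*% object$beta)
}

#' @rdname predict.decoding_model
#' @param x test target vector (the encoding predictor).
#' @export
predict.encoding_model <- function(object, x, ...) object$beta * x

#' Validate a model on a held-out test pair
#'
#' Pearson correlation between ground truths and predictions on the test set.
#' Zero-variance predictions score `r = 0` with a `flagged` attribute.
#'
#' @param model an `encoding_model` or `decoding_model`.
#' @param truth ground-truth vector on the test set (the target `x` for
#'   decoding; the voxel response `y` for encoding).
#' @param input test-set model input (`Y` for decoding; `x` for encoding).
#' @return list with `r` and `predictions`.
#' @export
evaluate <- function(model, truth, input) {
  pred <- if (inherits(model, "decoding_model")) predict(model, input)
          else predict(model, input)
  r <- pearson_or_zero(truth, pred)
  list(r = as.numeric(r), predictions = pred,
       flagged = isTRUE(attr(r, "flagged")))
}
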