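# ---- Procrustes transforms ----------------------------------------------------

#' Construct a Procrustes transform
#'
#' Maps row vectors x to `(scale * x + translation) %*% rotation`: uniform
#' scaling first, then translation, then rotation, the composition order of
#' the package's conventions.
#'
#' @param rotation orthogonal d x d matrix (applied to row vectors on the
#'   right).
#' @param scale positive scalar.
#' @param translation length-d vector.
#' @return object of class `procrustes_transform`.
#' @export
procrustes_transform <- function(rotation, scale = 1, translation = NULL) {
  rotation <- as.matrix(rotation)
  d <- nrow(rotation)
  if (is.null(translation)) translation <- numeric(d)
  if (scale <= 0) stop("scale must be positive")
  if (max(abs(crossprod(rotation) - diag(d))) > 1e-8)
    stop("rotation must be orthogonal")
  structure(list(rotation = rotation, scale = scale,
                 translation = as.numeric(translation)),
            class = "procrustes_transform")
}

#' Apply a Procrustes transform to a configuration
#'
#' @param data trials x d numeric matrix (rows are points).
#' @param transform a `procrustes_transform`.
#' @return transformed trials x d matrix.
#' @export
apply_transform <- function(data, transform) {
  data <- as.matrix(data)
  if (ncol(data) != nrow(transform$rotation))
    stop("dimension mismatch between data and transform")
  sweep(data * transform$scale, 2, -transform$translation) %*%
    transform$rotation
}

#' Root-sum-square (Procrustes) distance between two configurations
#'
#' @param a,b equal-shape numeric matrices.
#' @return square root of the sum of squared entrywise differences.
#' @export
procrustes_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  sqrt(sum((a - b)^2))
}

#' Fit the Procrustes transform aligning one configuration to another
#'
#' Solves the orthogonal Procrustes problem with uniform scaling and
#' translation on column-mean-centered data, minimizing the root-sum-square
#' distance between the transformed source and the target. Orthogonal matrices
#' (including reflections) are allowed, as in standard hyperalignment
#' practice.
#'
#' @param source,target trials x d matrices over the same trials.
#' @param scaling if `FALSE`, fix the scale at 1.
#' @return a `procrustes_transform` such that
#'   `apply_transform(source, fit)` best approximates `target`.
#' @export
procrustes_fit <- function(source, target, scaling = TRUE) {
  A <- as.matrix(source); B <- as.matrix(target)
  if (!all(dim(A) == dim(B))) stop("source and target must have equal shape")
  if (nrow(A) < 2) stop("need at least 2 trials")
  mu_a <- colMeans(A); mu_b <- colMeans(B)
  Ac <- sweep(A, 2, mu_a); Bc <- sweep(B, 2, mu_b)
  ssA <- sum(Ac^2)
  if (ssA < 1e-24) stop("degenerate source: all rows identical")
  sv <- svd(crossprod(Ac, Bc))
  R <- sv$u %*% t(sv$v)
  s <- if (scaling) sum(sv$d) / ssA else 1
  if (s <= 0) s <- 1e-12
  # standard map: x -> s x R + t_std;  package order: (s x + t) R
  t_std <- mu_b - s * drop(mu_a %*% R)
  procrustes_transform(R, s, drop(t_std %*% t(R)))
}

# ---- common space -------------------------------------------------------------

#' Zero-pad a response matrix to a target voxel dimensionality
#'
#' @param rm a `response_matrix` with `q <= d`.
#' @param d target dimensionality.
#' @return padded `response_matrix`; `original_q` records the input width.
#' @export
pad_to_dimension <- function(rm, d) {
  if (rm$q > d) stop("cannot pad: matrix wider than target dimension")
  if (rm$q == d) return(rm)
  data <- cbind(rm$data, matrix(0, rm$n, d - rm$q))
  response_matrix(data, rm$subject, rm$roi, rm$split, rm$trial_ids,
                  original_q = rm$original_q)
}

#' Build a common representational space across subjects
#'
#' Iterative Procrustes hyperalignment: the common space is initialized from
#' the training data of the subject with the most voxels (other subjects are
#' zero-padded to that dimensionality); each iteration transforms every
#' subject to the common space, averages the aligned data across subjects,
#' and reassigns the average as the common space. Iteration stops after
#' `iterations` rounds or when the mean residual improves by less than `tol`.
#'
#' @param datasets list of training `response_matrix` objects over the same
#'   trials (one per subject).
#' @param iterations maximum number of refinement iterations.
#' @param scaling allow uniform scaling in the Procrustes fits.
#' @param tol early-stopping tolerance on the mean residual improvement.
#' @return object of class `common_space`: dimensionality `d`, the common
#'   matrix, per-subject `procrustes_transform`s fitted to the final space,
#'   and the per-iteration mean residual log.
#' @export
hyperalign <- function(datasets, iterations = 2, scaling = TRUE, tol = 1e-6) {
  if (!length(datasets)) stop("need at least one subject")
  ns <- vapply(datasets, function(x) x$n, numeric(1))
  if (length(unique(ns)) != 1)
    stop("trial-count mismatch across subjects: ", paste(ns, collapse = ", "))
  qs <- vapply(datasets, function(x) x$q, numeric(1))
  d <- max(qs)
  ref <- which.max(qs)                      # ties broken by subject order
  padded <- lapply(datasets, pad_to_dimension, d = d)
  subjects <- vapply(datasets, function(x) x$subject, character(1))
  common <- padded[[ref]]$data
  log <- numeric(0)
  prev <- Inf
  for (it in seq_len(max(iterations, 1))) {
    aligned <- vector("list", length(padded))
    resid <- numeric(length(padded))
    for (i in seq_along(padded)) {
      tf <- procrustes_fit(padded[[i]]$data, common, scaling = scaling)
      aligned[[i]] <- apply_transform(padded[[i]]$data, tf)
      resid[i] <- procrustes_distance(aligned[[i]], common)
    }
    common <- Reduce(`+`, aligned) / length(aligned)
    log <- c(log, mean(resid))
    if (it > 1 && prev - mean(resid) < tol) break
    prev <- mean(resid)
  }
  transforms <- lapply(padded, function(p)
    procrustes_fit(p$data, common, scaling = scaling))
  names(transforms) <- subjects
  structure(list(d = d, common = common, transforms = transforms,
                 subjects = subjects, reference = subjects[ref],
                 original_q = stats::setNames(qs, subjects),
                 residual_log = log, roi = datasets[[1]]$roi),
            class = "common_space")
}

#' @export
print.common_space <- function(x, ...) {
  cat(sprintf("common_space: d = %d over %d subjects (ref %s); residuals: %s\n",
              x$d, length(x$subjects), x$reference,
              paste(signif(x$residual_log, 4), collapse = " -> ")))
  invisible(x)
}

#' Project subjects into a common space and average
#'
#' Transforms each subject's (zero-padded) train and test data with its fitted
#' transform and averages elementwise across subjects, yielding the mean
#' hyperaligned response matrices the downstream models are fit on.
#'
#' @param train,test lists of `response_matrix` objects, one per subject, in
#'   the same subject order; `test` may be `NULL`.
#' @param cs a `common_space` containing a transform for every subject.
#' @return list with mean hyperaligned `train` and (if given) `test`
#'   `response_matrix` objects, subject id `"SH"`.
#' @export
project <- function(train, test = NULL, cs) {
  avg <- function(lst, split) {
    acc <- NULL
    for (rm in lst) {
      tf <- cs$transforms[[rm$subject]]
      if (is.null(tf)) stop("subject missing from common space: ", rm$subject)
      x <- apply_transform(pad_to_dimension(rm, cs$d)$data, tf)
      acc <- if (is.null(acc)) x else acc + x
    }
    response_matrix(acc / length(lst), subject = "SH", roi = cs$roi,
                    split = split, trial_ids = lst[[1]]$trial_ids)
  }
  out <- list(train = avg(train, "train"))
  if (!is.null(test)) out$test <- avg(test, "test")
  out
}
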