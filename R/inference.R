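# ---- permutation significance --------------------------------------------------

#' Permutation test of a model's validation correlation
#'
#' The order of the ground truths is shuffled independently within the
#' training and test sets, the model is refit and rescored, and this is
#' repeated `reps` times. The chance level is the mean null `r`; the p-value
#' is the plain fraction of null `r` values greater than or equal to the
#' observed `r` (it can be exactly 0). Set `add_one = TRUE` for the
#' `(b+1)/(m+1)` convention instead.
#'
#' @param fit_and_score function `(train, test) -> r` fitting on `train` and
#'   returning the test-set validation correlation; `train` and `test` are
#'   lists carrying the target vector in `$x`.
#' @param train,test the training and test inputs handed to `fit_and_score`.
#' @param reps number of permutations.
#' @param seed RNG seed (the test is deterministic given it).
#' @param add_one use the small-sample `(b+1)/(m+1)` p-value.
#' @return object of class `permutation_null`: `observed`, `null` (vector),
#'   `chance`, `p`, `n_excluded` non-finite nulls.
#' @export
permutation_test <- function(fit_and_score, train, test, reps = 1000,
                             seed = 1, add_one = FALSE) {
  if (reps < 1) stop("reps must be >= 1")
  observed <- fit_and_score(train, test)
  null_r <- numeric(reps)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  for (i in seq_len(reps)) {
    tr <- train; te <- test
    tr$x <- sample(tr$x)
    te$x <- sample(te$x)
    null_r[i] <- fit_and_score(tr, te)
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  bad <- !is.finite(null_r)
  null_r <- null_r[!bad]
  p <- if (add_one) (sum(null_r >= observed) + 1) / (length(null_r) + 1)
       else mean(null_r >= observed)
  structure(list(observed = observed, null = null_r,
                 chance = mean(null_r), p = p, n_excluded = sum(bad)),
            class = "permutation_null")
}

#' Bootstrap standard error of a validation correlation
#'
#' Test trials are resampled with replacement, the correlation between
#' truths and predictions is recomputed per resample, and the standard
#' deviation of the resampled correlations is returned. Degenerate resamples
#' (zero variance) are redrawn, up to a retry cap.
#'
#' @param truths,predictions equal-length numeric vectors from the test set.
#' @param reps bootstrap iterations.
#' @param seed RNG seed.
#' @param max_retries redraw cap per degenerate resample.
#' @return scalar bootstrap SEM.
#' @export
bootstrap_sem <- function(truths, predictions, reps = 1000, seed = 1,
                          max_retries = 100) {
  n <- length(truths)
  if (n < 3) stop("need at least 3 test trials")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  rs <- numeric(reps)
  for (i in seq_len(reps)) {
    for (try in seq_len(max_retries)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (pop_sd(truths[idx]) > 1e-12 && pop_sd(predictions[idx]) > 1e-12) {
        rs[i] <- stats::cor(truths[idx], predictions[idx])
        break
      }
      if (try == max_retries) rs[i] <- NA_real_
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  stats::sd(rs[is.finite(rs)])
}

# ---- masks and summaries --------------------------------------------------------

#' Dual-threshold significance mask
#'
#' Per-voxel indicators at the 0.05 and 0.001 levels (rejection at
#' `p <= threshold`); the stricter mask is always nested in the looser one.
#'
#' @param p numeric vector of per-voxel p-values.
#' @return list of logical vectors `p05` and `p001`.
#' @export
significance_mask <- function(p) {
  list(p05 = p <= 0.05, p001 = p <= 0.001)
}

#' Venn-cell overlap fractions of three significance masks
#'
#' Partitions the union of significant voxels across three measures into the
#' seven membership cells of the Venn diagram and reports each cell's
#' fraction of the union.
#'
#' @param masks named list of three logical vectors over the same voxels.
#' @return named numeric vector over cells (e.g. `"A"`, `"A&B"`,
#'   `"A&B&C"`), summing to 1; all-`NA` with `n_union = 0` attribute when
#'   the union is empty.
#' @export
overlap_fractions <- function(masks) {
  stopifnot(length(masks) == 3)
  if (is.null(names(masks))) names(masks) <- c("A", "B", "C")
  len <- unique(vapply(masks, length, integer(1)))
  if (length(len) != 1) stop("masks must cover the same voxels")
  nm <- names(masks)
  cells <- list(c(1), c(2), c(3), c(1, 2), c(1, 3), c(2, 3), c(1, 2, 3))
  labels <- vapply(cells, function(cc) paste(nm[cc], collapse = "&"),
                   character(1))
  member <- vapply(masks, as.logical, logical(len))
  if (is.null(dim(member))) member <- matrix(member, nrow = len)
  union_n <- sum(rowSums(member) > 0)
  out <- stats::setNames(rep(NA_real_, 7), labels)
  attr(out, "n_union") <- union_n
  if (union_n == 0) return(out)
  for (i in seq_along(cells)) {
    inset <- rowSums(member[, cells[[i]], drop = FALSE]) == length(cells[[i]])
    outset <- if (length(cells[[i]]) == 3) rep(FALSE, len)
              else rowSums(member[, -cells[[i]], drop = FALSE]) > 0
    out[i] <- sum(inset & !outset) / union_n
  }
  out
}

#' Sensitivity summary over significant voxels
#'
#' Over the significant voxels of one ROI/measure: mean absolute encoding
#' slope, percentage of positive slopes, and mean absolute normalized slope
#' `|beta / r|` (voxels with `|r|` below `r_floor` are excluded from the
#' normalized mean and counted).
#'
#' @param betas per-voxel encoding slopes.
#' @param rs per-voxel validation correlations.
#' @param mask logical significance mask.
#' @param r_floor exclusion threshold on `|r|` for the normalized slope.
#' @return list `mean_abs_beta`, `pct_positive`, `mean_abs_beta_over_r`,
#'   `n_sig`, `n_excluded`; `NULL` (with a message) when the mask is empty.
#' @export
sensitivity_summary <- function(betas, rs, mask, r_floor = 1e-8) {
  if (!any(mask)) {
    message("empty significance mask; ROI omitted from sensitivity summary")
    return(NULL)
  }
  b <- betas[mask]; r <- rs[mask]
  ok <- abs(r) >= r_floor
  list(mean_abs_beta = mean(abs(b)),
       pct_positive = 100 * mean(b > 0),
       mean_abs_beta_over_r = if (any(ok)) mean(abs(b[ok] / r[ok]))
                              else NA_real_,
       n_sig = sum(mask), n_excluded = sum(!ok))
}
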