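# ---- response containers -----------------------------------------------------

#' Construct a trial-by-voxel response matrix
#'
#' @param data numeric trials x voxels matrix.
#' @param subject subject identifier.
#' @param roi ROI label.
#' @param split `"train"` or `"test"`.
#' @param trial_ids optional trial identifiers.
#' @param original_q original voxel count before any zero padding.
#' @return object of class `response_matrix`.
#' @export
response_matrix <- function(data, subject = "S1", roi = "ROI", split = "train",
                            trial_ids = NULL, original_q = ncol(data)) {
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop("response matrix contains non-finite values")
  if (is.null(trial_ids)) trial_ids <- seq_len(nrow(data))
  structure(list(data = data, n = nrow(data), q = ncol(data),
                 subject = subject, roi = roi, split = split,
                 trial_ids = trial_ids, original_q = original_q),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("response_matrix: %d trials x %d voxels (%s, %s, %s split)\n",
              x$n, x$q, x$subject, x$roi, x$split))
  invisible(x)
}

# ---- preprocessing -----------------------------------------------------------

#' Linearly detrend and standardize a run along time
#'
#' Per voxel: the least-squares line over time is removed, then the series is
#' z-scored along time (population variance convention). Voxels with zero
#' variance after detrending are set to all zeros and reported in the
#' `flagged` attribute.
#'
#' @param run numeric time x voxel matrix.
#' @return matrix of the same shape; attribute `flagged` lists zero-variance
#'   voxel columns.
#' @export
detrend_standardize <- function(run) {
  run <- as.matrix(run)
  nt <- nrow(run)
  if (nt < 3) stop("need at least 3 time points")
  t0 <- seq_len(nt) - (nt + 1) / 2                 # centered time
  denom <- sum(t0^2)
  slope <- colSums(run * t0) / denom
  res <- run - rep(colMeans(run), each = nt) - outer(t0, slope)
  sdv <- sqrt(colMeans(res^2))
  flagged <- which(sdv < 1e-12)
  sdv[flagged] <- 1
  out <- res / rep(sdv, each = nt)
  out[, flagged] <- 0
  attr(out, "flagged") <- flagged
  out
}

#' Trial response for a 3 s TR design (one row per trial)
#'
#' Shifts the trial window by one TR (3 s), crops to the first 3 TRs (9 s) and
#' averages along time, giving one value per voxel per trial.
#'
#' @param trial time x voxel matrix for one trial, rows at TR resolution
#'   starting at stimulus onset (0-based TR indexing).
#' @param shift_TR TRs to skip after onset.
#' @param crop_TR TRs to average.
#' @return numeric vector, one value per voxel.
#' @export
trial_average_exp1 <- function(trial, shift_TR = 1, crop_TR = 3) {
  trial <- as.matrix(trial)
  if (nrow(trial) < shift_TR + crop_TR)
    stop("trial too short: need at least ", shift_TR + crop_TR, " TRs")
  colMeans(trial[(shift_TR + 1):(shift_TR + crop_TR), , drop = FALSE])
}

#' Trial response windows for a 0.735 s TR design (28 rows per trial)
#'
#' Shifts the trial window by `shift_TR` TRs, crops to `crop_TR` TRs and takes
#' a moving average with a 12-TR window and 1-TR hop. The final full window is
#' dropped so a 40-TR crop yields exactly 28 time points, aligning one-to-one
#' with the 28-point sliding-window stimulus feature series.
#'
#' @param trial time x voxel matrix for one trial, rows at TR resolution
#'   starting at stimulus onset.
#' @param shift_TR,crop_TR,window_TR,hop_TR windowing parameters in TRs.
#' @return (windows x voxels) matrix; 28 rows under the defaults.
#' @export
trial_windows_exp2 <- function(trial, shift_TR = 4, crop_TR = 40,
                               window_TR = 12, hop_TR = 1) {
  trial <- as.matrix(trial)
  if (nrow(trial) < shift_TR + crop_TR)
    stop("trial too short: need at least ", shift_TR + crop_TR, " TRs")
  if (crop_TR <= window_TR) stop("crop must exceed the window length")
  seg <- trial[(shift_TR + 1):(shift_TR + crop_TR), , drop = FALSE]
  # starts s = 0, hop, ... while s + window < crop (strict), so the window
  # ending exactly at the crop boundary is dropped: 28 windows for 40 TRs
  n_win <- (crop_TR - window_TR - 1L) %/% hop_TR + 1L
  out <- matrix(0, n_win, ncol(trial))
  for (i in seq_len(n_win)) {
    st <- (i - 1) * hop_TR + 1
    out[i, ] <- colMeans(seg[st:(st + window_TR - 1), , drop = FALSE])
  }
  out
}

# ---- I/O ----------------------------------------------------------------------

#' Write a response matrix as tab-separated text
#'
#' Metadata travels in `#`-prefixed header lines; the table has `trial_id`
#' plus one column per voxel.
#'
#' @param rm a `response_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(rm, path) {
  con <- file(path, "w"); on.exit(close(con))
  meta <- c(subject = rm$subject, roi = rm$roi, split = rm$split,
            original_q = rm$original_q)
  writeLines(sprintf("# %s: %s", names(meta), meta), con)
  df <- data.frame(trial_id = rm$trial_ids, rm$data, check.names = FALSE)
  colnames(df) <- c("trial_id", paste0("v", seq_len(rm$q)))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a response matrix written by [write_responses()]
#' @param path input path.
#' @return a `response_matrix`.
#' @export
read_responses <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- list()
  for (l in lines[meta_lines]) {
    kv <- sub("^#\\s*", "", l)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:\\s*", "", kv))
  }
  body <- lines[setdiff(seq_along(lines), meta_lines)]
  if (length(body) < 1) stop("no table in ", path)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "trial_id") stop("malformed header in ", path)
  if (length(body) < 2) stop("empty response table (0 trials) in ", path)
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  ncols <- length(header)
  mat <- matrix(NA_real_, length(rows), ncols - 1L)
  ids <- character(length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != ncols)
      stop(sprintf("ragged row at line %d of %s", i + 1L + length(meta_lines),
                   path))
    ids[i] <- r[1]
    vals <- suppressWarnings(as.numeric(r[-1]))
    if (any(is.na(vals))) {
      bad <- which(is.na(vals))[1]
      stop(sprintf("non-numeric cell at line %d, column %s of %s",
                   i + 1L + length(meta_lines), header[bad + 1L], path))
    }
    mat[i, ] <- vals
  }
  response_matrix(mat, subject = meta$subject %||% "S1",
                  roi = meta$roi %||% "ROI",
                  split = meta$split %||% "train", trial_ids = ids,
                  original_q = as.integer(meta$original_q %||% ncol(mat)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
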