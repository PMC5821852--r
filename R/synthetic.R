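# ---- synthetic stimuli ---------------------------------------------------------
#
# The generators emulate the statistical structure the analysis assumes: images
# whose clutter (number of random shapes) drives the complexity measures over a
# wide range, music-like clips with a controllable event rate, voxel responses
# that are noisy linear functions of standardized complexity with region-wise
# slope magnitudes and sign mixtures, and subjects that are rotated, scaled and
# translated copies of a common response space. They make no claim to match the
# image or music corpora the measures were designed for.

#' Generate synthetic cluttered images
#'
#' Each image is a smooth low-frequency background with `k` random antialiased
#' discs composited on top, `k` drawn uniformly from `clutter_range`. More
#' shapes mean more edges and less compressible rasters, so the gradient and
#' PNG measures increase with `k`.
#'
#' @param n number of images.
#' @param clutter_range integer range for the shape count `k`.
#' @param size image side length in pixels.
#' @param noise_sd pixel noise added to the background, in intensity units.
#' @param seed RNG seed.
#' @return list with `images` (list of size x size x 3 arrays, 0--255) and
#'   `clutter` (integer vector of planted `k`).
#' @export
gen_images <- function(n, clutter_range = c(0, 50), size = 256, noise_sd = 2,
                       seed = 1) {
  set.seed(seed)
  xs <- matrix(rep(seq_len(size), size), size, size)
  ys <- t(xs)
  images <- vector("list", n)
  clutter <- sample(clutter_range[1]:clutter_range[2], n, replace = TRUE)
  for (i in seq_len(n)) {
    ph <- stats::runif(4, 0, 2 * pi)
    base <- 128 + 40 * sin(2 * pi * xs / size + ph[1]) *
      cos(2 * pi * ys / size + ph[2]) +
      20 * sin(4 * pi * (xs + ys) / (2 * size) + ph[3])
    img <- array(0, c(size, size, 3))
    tint <- stats::runif(3, 0.8, 1.2)
    for (ch in 1:3) img[, , ch] <- base * tint[ch]
    k <- clutter[i]
    if (k > 0) {
      for (s in seq_len(k)) {
        cx <- stats::runif(1, 1, size); cy <- stats::runif(1, 1, size)
        r0 <- stats::runif(1, 6, 32)
        col <- stats::runif(3, 0, 255)
        dist <- sqrt((xs - cx)^2 + (ys - cy)^2)
        alpha <- pmin(pmax((r0 - dist) / 1.5, 0), 1)
        for (ch in 1:3)
          img[, , ch] <- img[, , ch] * (1 - alpha) + col[ch] * alpha
      }
    }
    # sensor-style noise added after compositing, uniform across clutter
    if (noise_sd > 0)
      img <- img + array(stats::rnorm(size * size * 3, 0, noise_sd),
                         c(size, size, 3))
    img[img < 0] <- 0; img[img > 255] <- 255
    images[[i]] <- round(img)
  }
  list(images = images, clutter = clutter)
}

# Refractory Poisson onset times on (0, duration): events closer than
# `refractory` to the previously kept event are dropped, so clicks do not
# overlap within the onset detector's resolution.
poisson_onsets <- function(rate, duration, refractory = 0.06) {
  if (rate <= 0) return(numeric(0))
  t <- cumsum(stats::rexp(ceiling(rate * duration * 3 + 20), rate))
  t <- t[t < duration]
  if (!length(t)) return(numeric(0))
  kept <- t[1]
  for (ti in t[-1]) if (ti - kept[length(kept)] >= refractory)
    kept <- c(kept, ti)
  kept
}

#' Generate synthetic music-like clips
#'
#' Tone bursts (random carrier frequency, exponentially decaying envelope) at
#' refractory-Poisson onset times, plus white noise. Event rate drives the
#' event-density measure; noise level drives the codec-size measures.
#'
#' @param n number of clips.
#' @param rate_range event-rate range in Hz.
#' @param duration clip duration in seconds.
#' @param sample_rate sampling rate in Hz.
#' @param noise_sd white-noise standard deviation (waveform units).
#' @param seed RNG seed.
#' @return list with `clips` (list of `audio_clip`), `rates` (planted event
#'   rate per clip) and `onsets` (list of realized onset times).
#' @export
gen_audio <- function(n, rate_range = c(1, 8), duration = 29,
                      sample_rate = 16000, noise_sd = 0.02, seed = 1) {
  set.seed(seed)
  clips <- vector("list", n)
  onsets <- vector("list", n)
  rates <- stats::runif(n, rate_range[1], rate_range[2])
  n_samp <- round(duration * sample_rate)
  tt <- (seq_len(n_samp) - 1) / sample_rate
  for (i in seq_len(n)) {
    x <- if (noise_sd > 0) stats::rnorm(n_samp, 0, noise_sd) else numeric(n_samp)
    on <- poisson_onsets(rates[i], duration)
    for (t0 in on) {
      f <- stats::runif(1, 200, 2000)
      i0 <- floor(t0 * sample_rate) + 1
      len <- min(round(0.08 * sample_rate), n_samp - i0 + 1)
      if (len < 2) next
      tb <- tt[seq_len(len)]
      x[i0:(i0 + len - 1)] <- x[i0:(i0 + len - 1)] +
        0.6 * exp(-tb / 0.02) * sin(2 * pi * f * tb)
    }
    clips[[i]] <- audio_clip(pmax(pmin(x, 1), -1), sample_rate)
    onsets[[i]] <- on
  }
  list(clips = clips, rates = rates, onsets = onsets)
}

# ---- synthetic responses -------------------------------------------------------

#' Plant per-voxel complexity slopes for simulated ROIs
#'
#' Slope magnitudes are drawn around each ROI's nominal magnitude (uniform
#' within +/- 25%) and flipped negative with the configured fraction,
#' emulating the mixture of complexity- and simplicity-preferring voxels.
#'
#' @param rois named list; each element a list with `q` (voxels), `slope`
#'   (nominal magnitude), `neg_frac` (fraction of negative slopes).
#' @param seed RNG seed.
#' @return named list of slope vectors.
#' @export
plant_slopes <- function(rois, seed = 1) {
  set.seed(seed)
  out <- lapply(rois, function(cfg) {
    mag <- cfg$slope * stats::runif(cfg$q, 0.75, 1.25)
    sign <- ifelse(stats::runif(cfg$q) < cfg$neg_frac, -1, 1)
    mag * sign
  })
  names(out) <- names(rois)
  out
}

#' Generate voxel responses as noisy linear functions of complexity
#'
#' `y_v = s_v * x + e`, `e ~ N(0, noise_sd)`, per voxel, for one split of one
#' simulated ROI.
#'
#' @param x standardized complexity values (one per trial).
#' @param slopes planted per-voxel slope vector from [plant_slopes()].
#' @param noise_sd response noise standard deviation.
#' @param seed RNG seed.
#' @param roi,split,subject metadata for the returned matrix.
#' @return a `response_matrix`.
#' @export
gen_responses <- function(x, slopes, noise_sd = 1, seed = 1, roi = "ROI",
                          split = "train", subject = "COMMON") {
  set.seed(seed)
  n <- length(x); q <- length(slopes)
  Y <- outer(x, slopes) + if (noise_sd > 0)
    matrix(stats::rnorm(n * q, 0, noise_sd), n, q) else 0
  response_matrix(Y, subject = subject, roi = roi, split = split)
}

#' Generate subjects as transformed copies of a common response space
#'
#' Each subject is the common data mapped by a random orthogonal rotation, a
#' positive uniform scale and a translation, optionally truncated to fewer
#' voxels, plus independent Gaussian noise — the generative inverse of
#' hyperalignment.
#'
#' @param common a `response_matrix` holding the common-space data.
#' @param n_subjects number of subjects.
#' @param noise_sd independent noise per subject.
#' @param truncate_q optional integer vector (length `n_subjects`) of voxel
#'   counts to keep per subject.
#' @param seed RNG seed.
#' @return list with `subjects` (list of `response_matrix`) and `transforms`
#'   (the planted `procrustes_transform`s).
#' @export
gen_subjects <- function(common, n_subjects, noise_sd = 0, truncate_q = NULL,
                         seed = 1) {
  if (n_subjects < 1) stop("need at least one subject")
  set.seed(seed)
  d <- common$q
  subjects <- vector("list", n_subjects)
  transforms <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    QR <- qr(matrix(stats::rnorm(d * d), d, d))
    R <- qr.Q(QR) %*% diag(sign(diag(qr.R(QR))), d)
    tf <- procrustes_transform(R, stats::runif(1, 0.5, 2),
                               stats::rnorm(d, 0, 1))
    X <- apply_transform(common$data, tf)
    if (noise_sd > 0)
      X <- X + matrix(stats::rnorm(length(X), 0, noise_sd), nrow(X))
    qi <- if (is.null(truncate_q)) d else truncate_q[i]
    X <- X[, seq_len(qi), drop = FALSE]
    subjects[[i]] <- response_matrix(X, subject = paste0("S", i),
                                     roi = common$roi, split = common$split,
                                     original_q = qi)
    transforms[[i]] <- tf
  }
  list(subjects = subjects, transforms = transforms)
}

# ---- stimulus selection by tag clustering ---------------------------------------

#' Select train/test stimuli by agglomerative tag clustering
#'
#' Stimuli are clustered on their binary tag vectors with correlation distance
#' (1 - Pearson correlation) and complete linkage into `k` clusters. Within
#' each cluster, members are ranked by within-cluster similarity (mean Pearson
#' correlation with the other members; ties broken by stimulus order): the top
#' member goes to the test set, the next `per_cluster_train` to the training
#' set.
#'
#' @param tags stimulus x tag binary matrix (no all-zero rows).
#' @param k number of clusters.
#' @param per_cluster_train training stimuli per cluster.
#' @return data.frame `stimulus, cluster, similarity, assignment` with
#'   assignment in `test`, `train`, `unused`.
#' @export
cluster_select_stimuli <- function(tags, k = 16, per_cluster_train = 8) {
  tags <- as.matrix(tags)
  if (nrow(tags) < k) stop("need at least k stimuli")
  if (any(rowSums(tags != 0) == 0)) stop("all-zero stimulus rows not allowed")
  C <- suppressWarnings(stats::cor(t(tags)))
  C[!is.finite(C)] <- 0
  D <- stats::as.dist(1 - C)
  cl <- stats::cutree(stats::hclust(D, method = "complete"), k = k)
  n <- nrow(tags)
  sim <- numeric(n)
  for (i in seq_len(n)) {
    others <- which(cl == cl[i] & seq_len(n) != i)
    sim[i] <- if (length(others)) mean(C[i, others]) else 1
  }
  assignment <- rep("unused", n)
  for (g in seq_len(k)) {
    members <- which(cl == g)
    ranked <- members[order(-sim[members], members)]
    assignment[ranked[1]] <- "test"
    n_train <- min(per_cluster_train, length(ranked) - 1L)
    if (n_train < per_cluster_train && length(ranked) > 1)
      warning(sprintf("cluster %d has only %d training candidates", g, n_train))
    if (n_train > 0)
      assignment[ranked[2:(1 + n_train)]] <- "train"
  }
  ids <- if (!is.null(rownames(tags))) rownames(tags)
         else as.character(seq_len(n))
  data.frame(stimulus = ids, cluster = cl, similarity = sim,
             assignment = assignment, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Generate a tag matrix with planted blocks
#'
#' Each of `k` clusters gets a random non-constant binary tag prototype and
#' `per_cluster` identical copies of it — the degenerate geometry in which
#' correct clustering is fully determined.
#'
#' @param k clusters.
#' @param per_cluster stimuli per cluster.
#' @param n_tags tag count.
#' @param p tag activation probability in prototypes.
#' @param seed RNG seed.
#' @return list with `tags` (matrix) and `blocks` (planted cluster labels).
#' @export
gen_tag_matrix <- function(k = 16, per_cluster = 9, n_tags = 136, p = 0.3,
                           seed = 1) {
  set.seed(seed)
  repeat {
    protos <- matrix(stats::rbinom(k * n_tags, 1, p), k, n_tags)
    ok <- all(rowSums(protos) > 0) && all(rowSums(protos) < n_tags) &&
      !anyDuplicated(apply(protos, 1, paste, collapse = ""))
    if (ok) break
  }
  tags <- protos[rep(seq_len(k), each = per_cluster), ]
  list(tags = tags, blocks = rep(seq_len(k), each = per_cluster))
}
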