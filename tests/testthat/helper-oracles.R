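# Independent naive-loop oracles the fast implementations are checked against.

# Direct transcription of the mean-max-gradient definition: per pixel, per
# channel, central differences with replicated borders, explicit loops.
naive_gradient_complexity <- function(lab) {
  h <- dim(lab)[1]; w <- dim(lab)[2]
  tot <- 0
  for (x in 1:h) for (y in 1:w) {
    best <- 0
    for (ch in 1:3) {
      S <- lab[, , ch]
      gx <- (S[x, min(y + 1, w)] - S[x, max(y - 1, 1)]) / 2
      gy <- (S[min(x + 1, h), y] - S[max(x - 1, 1), y]) / 2
      best <- max(best, sqrt(gx^2 + gy^2))
    }
    tot <- tot + best
  }
  tot / (h * w)
}

# Direct transcription of the self-similarity definition over a pyramid.
naive_self_similarity <- function(pyr) {
  L2 <- pyr$levels[[3]]; L3 <- pyr$levels[[4]]
  sums <- numeric(pyr$bins)
  for (f in seq_len(pyr$bins)) {
    acc <- 0
    for (x in 1:8) for (y in 1:8) {
      p <- L2[ceiling(x / 2), ceiling(y / 2), f]
      c3 <- L3[x, y, f]
      acc <- acc + if (p < c3) p else c3
    }
    sums[f] <- acc
  }
  s <- sort(sums)
  (s[length(s) / 2] + s[length(s) / 2 + 1]) / 2
}

# Direct (non-separable) Lanczos-3 resampler evaluated pixel by pixel.
naive_lanczos_resize <- function(plane, n_out, a = 3) {
  n_in_r <- nrow(plane); n_in_c <- ncol(plane)
  lk <- function(x) {
    if (abs(x) >= a) return(0)
    if (x == 0) return(1)
    a * sin(pi * x) * sin(pi * x / a) / (pi^2 * x^2)
  }
  out <- matrix(0, n_out, n_out)
  for (i in 1:n_out) for (j in 1:n_out) {
    sr <- n_out / n_in_r; sc <- n_out / n_in_c
    cr <- (i - 0.5) / sr + 0.5; ccn <- (j - 0.5) / sc + 0.5
    supr <- if (sr < 1) a / sr else a
    supc <- if (sc < 1) a / sc else a
    acc <- 0; wsum <- 0
    for (r in floor(cr - supr):ceiling(cr + supr)) {
      xr <- cr - r; if (sr < 1) xr <- xr * sr
      wr <- lk(xr)
      if (wr == 0) next
      for (cc in floor(ccn - supc):ceiling(ccn + supc)) {
        xc <- ccn - cc; if (sc < 1) xc <- xc * sc
        wc <- lk(xc)
        if (wc == 0) next
        v <- plane[min(max(r, 1), n_in_r), min(max(cc, 1), n_in_c)]
        acc <- acc + wr * wc * v
        wsum <- wsum + wr * wc
      }
    }
    out[i, j] <- acc / wsum
  }
  out
}

# Per-voxel least-squares line removal then z-scoring, via lm().
naive_detrend_standardize <- function(run) {
  nt <- nrow(run)
  tv <- seq_len(nt)
  out <- run
  for (v in seq_len(ncol(run))) {
    res <- stats::residuals(stats::lm(run[, v] ~ tv))
    out[, v] <- res / sqrt(mean(res^2))
  }
  out
}

# Moving average over the pinned window set, explicit loops.
naive_trial_windows <- function(trial, shift, crop, window, hop) {
  seg <- trial[(shift + 1):(shift + crop), , drop = FALSE]
  starts <- seq(0, crop - window, by = hop)
  starts <- starts[starts + window < crop]
  out <- matrix(0, length(starts), ncol(trial))
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1):(starts[i] + window)
    for (v in seq_len(ncol(trial))) out[i, v] <- mean(seg[idx, v])
  }
  out
}

# Explicit leave-one-out refit of the ridge decoder.
naive_loo_error <- function(Y, x, lambda) {
  n <- nrow(Y)
  errs <- numeric(n)
  for (i in seq_len(n)) {
    Yi <- Y[-i, , drop = FALSE]; xi <- x[-i]
    beta <- solve(crossprod(Yi) + lambda * diag(ncol(Y)), crossprod(Yi, xi))
    errs[i] <- (x[i] - drop(Y[i, , drop = FALSE] %*% beta))^2
  }
  mean(errs)
}

# Scalar root bracketing for the ridge penalty at a df target.
bisect_lambda <- function(d, target, hi = 1e8) {
  g <- function(l) sum(d^2 / (d^2 + l)) - target
  stats::uniroot(g, c(0, hi), tol = 1e-12)$root
}

# Hand Pearson correlation.
naive_pearson <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# Random Lab-like image: smooth plus noise, on the Lab scale.
random_lab <- function(h, w, seed = 1) {
  set.seed(seed)
  arr <- array(0, c(h, w, 3))
  arr[, , 1] <- matrix(stats::runif(h * w, 0, 100), h, w)
  arr[, , 2] <- matrix(stats::runif(h * w, -60, 60), h, w)
  arr[, , 3] <- matrix(stats::runif(h * w, -60, 60), h, w)
  arr
}
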