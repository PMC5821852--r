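# ---- image container helpers -------------------------------------------------

as_rgb_array <- function(img) {
  if (is.null(dim(img))) stop("image must be a matrix or H x W x 3 array")
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (length(dim(img)) != 3L || !dim(img)[3] %in% c(1L, 3L))
    stop("image must have 1 or 3 channels")
  if (dim(img)[3] == 1L) img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  if (any(dim(img)[1:2] == 0L)) stop("empty image")
  storage.mode(img) <- "double"
  img
}

# Lanczos kernel, a = 3
lanczos_kernel <- function(x, a = 3) {
  y <- numeric(length(x))
  nz <- abs(x) < a & x != 0
  y[x == 0] <- 1
  xi <- x[nz]
  y[nz] <- a * sin(pi * xi) * sin(pi * xi / a) / (pi^2 * xi^2)
  y
}

# Row-resampling weight matrix mapping n_in samples to n_out, with the kernel
# widened by the scale factor when downsampling (antialiasing) and source
# indices clamped to the border (edge replication).
lanczos_weights <- function(n_in, n_out, a = 3) {
  scale <- n_out / n_in
  support <- if (scale < 1) a / scale else a
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    center <- (i - 0.5) / scale + 0.5            # 1-based source coordinate
    lo <- floor(center - support)
    hi <- ceiling(center + support)
    idx <- lo:hi
    x <- center - idx
    if (scale < 1) x <- x * scale
    w <- lanczos_kernel(x, a)
    keep <- w != 0
    idx <- pmin(pmax(idx[keep], 1L), n_in)
    w <- w[keep]
    w <- w / sum(w)
    for (k in seq_along(idx)) W[i, idx[k]] <- W[i, idx[k]] + w[k]
  }
  W
}

#' Preprocess an image for complexity measurement
#'
#' Resizes an RGB image to a square raster (256 x 256 by default) with
#' separable Lanczos-3 resampling, replicating a single-channel input to three
#' channels first. Intensities are kept on the 0--255 scale and rounded to
#' integers, matching what a lossless encoder would subsequently see.
#'
#' @param img numeric matrix (grayscale) or H x W x 3 array with intensities
#'   in \[0, 255\].
#' @param size output side length in pixels.
#' @return a `size` x `size` x 3 integer-valued array.
#' @export
preprocess_image <- function(img, size = 256) {
  img <- as_rgb_array(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (h == size && w == size) {
    out <- round(img)
  } else {
    Wr <- lanczos_weights(h, size)
    Wc <- lanczos_weights(w, size)
    out <- array(0, c(size, size, 3L))
    for (ch in 1:3) out[, , ch] <- Wr %*% img[, , ch] %*% t(Wc)
    out <- round(out)
  }
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

#' Convert an RGB image to CIE L*a*b*
#'
#' Uses sRGB primaries with the D65 white point, the de facto convention for
#' photographic material. Input intensities are on \[0, 255\].
#'
#' @param img H x W x 3 array of sRGB intensities in \[0, 255\].
#' @return H x W x 3 array with L*, a*, b* planes.
#' @export
rgb_to_lab <- function(img) {
  img <- as_rgb_array(img)
  d <- dim(img)
  px <- matrix(img, ncol = 3L) / 255
  lab <- grDevices::convertColor(px, from = "sRGB", to = "Lab")
  array(lab, c(d[1], d[2], 3L))
}

# Central differences with replicated borders, per plane.
# Returns list(gx, gy): gx differentiates along columns (x), gy along rows (y).
central_gradient <- function(S) {
  h <- nrow(S); w <- ncol(S)
  Spad_c <- cbind(S[, 1], S, S[, w])
  Spad_r <- rbind(S[1, ], S, S[h, ])
  gx <- (Spad_c[, 3:(w + 2)] - Spad_c[, 1:w]) / 2
  gy <- (Spad_r[3:(h + 2), ] - Spad_r[1:h, ]) / 2
  list(gx = gx, gy = gy)
}

#' Mean maximum magnitude gradient complexity
#'
#' The maximum rate of change across the L*, a*, b* planes, averaged over
#' pixels: for each pixel the gradient magnitude is computed per channel
#' (central differences, borders replicated), the maximum over the three
#' channels is taken, and the result is the mean over all pixels. Units are
#' Lab units per pixel.
#'
#' @param lab H x W x 3 Lab array from [rgb_to_lab()].
#' @return scalar complexity value.
#' @export
gradient_complexity <- function(lab) {
  stopifnot(length(dim(lab)) == 3L, dim(lab)[3] == 3L)
  mag <- array(0, dim(lab))
  for (ch in 1:3) {
    g <- central_gradient(lab[, , ch])
    mag[, , ch] <- sqrt(g$gx^2 + g$gy^2)
  }
  mean(pmax(mag[, , 1], mag[, , 2], mag[, , 3]))
}

#' PNG compressed-size complexity
#'
#' Losslessly encodes the RGB image with libpng (via the \pkg{png} package,
#' default compression) and returns the encoded size in bytes — a practical
#' surrogate for the Kolmogorov complexity of the raster.
#'
#' @param img H x W x 3 array with intensities in \[0, 255\].
#' @return integer byte count.
#' @export
png_complexity <- function(img) {
  img <- as_rgb_array(img)
  raw <- png::writePNG(img / 255, target = raw())
  length(raw)
}

#' Pyramid histogram of oriented gradients over the Lab image
#'
#' At each pyramid level `l` the image is divided into a `2^l` x `2^l` grid;
#' every region accumulates a 16-bin histogram of gradient orientations over
#' \[-pi, pi), weighted by gradient magnitude. Per pixel the Lab channel with
#' the largest gradient magnitude supplies both orientation and weight,
#' mirroring the max-over-channel convention of the gradient measure. Each
#' region histogram is L1-normalized; regions with zero gradient mass stay
#' all-zero.
#'
#' @param lab H x W x 3 Lab array.
#' @param levels highest pyramid level (level 0 is the whole image).
#' @param bins number of orientation bins.
#' @return object of class `phog_pyramid`: list of `levels + 1` arrays, level
#'   `l` having dimension `2^l` x `2^l` x `bins`.
#' @export
compute_phog <- function(lab, levels = 3, bins = 16) {
  stopifnot(length(dim(lab)) == 3L, dim(lab)[3] == 3L)
  if (bins <= 0) stop("bins must be positive")
  if (levels < 0) stop("levels must be non-negative")
  h <- dim(lab)[1]; w <- dim(lab)[2]
  gx <- array(0, c(h, w, 3L)); gy <- gx; mag <- gx
  for (ch in 1:3) {
    g <- central_gradient(lab[, , ch])
    gx[, , ch] <- g$gx; gy[, , ch] <- g$gy
    mag[, , ch] <- sqrt(g$gx^2 + g$gy^2)
  }
  best <- apply(mag, c(1, 2), which.max)
  sel <- cbind(seq_len(h * w), as.vector(best))
  pick <- function(a) matrix(a, ncol = 3L)[sel]
  m <- matrix(pick(mag), h, w)
  theta <- atan2(pick(gy), pick(gx))          # (-pi, pi]
  theta[theta >= pi] <- -pi                   # wrap to [-pi, pi)
  bin <- pmin(floor((theta + pi) / (2 * pi) * bins) + 1L, bins)
  pyr <- vector("list", levels + 1L)
  for (l in 0:levels) {
    g <- 2L^l
    rix <- pmin(ceiling(row(m) / (h / g)), g)
    cix <- pmin(ceiling(col(m) / (w / g)), g)
    H <- array(0, c(g, g, bins))
    # linear index into the g x g x bins array
    lin <- as.vector(rix) + (as.vector(cix) - 1L) * g +
      (as.vector(bin) - 1L) * g * g
    acc <- rowsum(as.vector(m), lin)
    H[as.integer(rownames(acc))] <- acc[, 1]
    for (r in 1:g) for (cc in 1:g) {
      s <- sum(H[r, cc, ])
      if (s > 0) H[r, cc, ] <- H[r, cc, ] / s
    }
    pyr[[l + 1L]] <- H
  }
  structure(list(levels = pyr, bins = bins), class = "phog_pyramid")
}

#' Self-similarity complexity from a PHOG pyramid
#'
#' For each orientation bin `f`, sums over the 8 x 8 level-3 grid the minimum
#' of the level-3 histogram value and its level-2 parent region's value
#' (histogram intersection), then returns the median over the 16 per-bin sums
#' (mean of the two middle order statistics). Bounded by \[0, 64\] under
#' per-region L1 normalization; a pyramid of uniform histograms gives 4.
#'
#' @param pyr `phog_pyramid` with levels 2 and 3 present.
#' @return scalar self-similarity value.
#' @export
self_similarity <- function(pyr) {
  if (!inherits(pyr, "phog_pyramid") || length(pyr$levels) < 4L)
    stop("pyramid must contain levels 0..3")
  L2 <- pyr$levels[[3L]]; L3 <- pyr$levels[[4L]]
  bins <- pyr$bins
  s <- numeric(bins)
  for (f in seq_len(bins)) {
    tot <- 0
    for (x in 1:8) for (y in 1:8)
      tot <- tot + min(L2[ceiling(x / 2), ceiling(y / 2), f], L3[x, y, f])
    s[f] <- tot
  }
  stats::median(s)
}

#' All three visual complexity measures for one image
#'
#' Convenience wrapper: preprocesses, converts to Lab, and returns the
#' gradient, PNG-size, and self-similarity measures.
#'
#' @param img raw image (matrix or H x W x 3 array, intensities 0--255).
#' @param size preprocessing side length.
#' @return named numeric vector `c(gradient, png_bytes, self_similarity)`.
#' @export
visual_complexity <- function(img, size = 256) {
  pp <- preprocess_image(img, size = size)
  lab <- rgb_to_lab(pp)
  c(gradient = gradient_complexity(lab),
    png_bytes = png_complexity(pp),
    self_similarity = self_similarity(compute_phog(lab)))
}

#' Batch visual complexity table
#'
#' @param images list of images (arrays) or character vector of PNG paths.
#' @param ids stimulus identifiers; defaults to names or indices.
#' @param size preprocessing side length.
#' @return data.frame with columns `stimulus_id`, `gradient`, `png_bytes`,
#'   `self_similarity`; attribute `encoder` records the pinned PNG encoder.
#' @export
visual_complexity_table <- function(images, ids = NULL, size = 256) {
  if (is.character(images)) {
    paths <- images
    if (is.null(ids)) ids <- basename(paths)
    images <- lapply(paths, function(p) png::readPNG(p) * 255)
  }
  if (is.null(ids)) ids <- if (!is.null(names(images))) names(images)
                           else as.character(seq_along(images))
  vals <- t(vapply(images, visual_complexity, numeric(3), size = size))
  out <- data.frame(stimulus_id = ids, gradient = vals[, 1],
                    png_bytes = vals[, 2], self_similarity = vals[, 3],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "encoder") <- "libpng (R png package, default compression)"
  out
}
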