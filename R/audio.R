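# ---- audio container ---------------------------------------------------------

#' Construct an audio clip
#'
#' @param samples numeric vector (mono) or samples x channels matrix; values
#'   nominally in \[-1, 1\]. Multi-channel input is downmixed by channel mean.
#' @param rate sampling rate in Hz.
#' @return object of class `audio_clip` with fields `samples`, `rate`,
#'   `duration` (seconds).
#' @export
audio_clip <- function(samples, rate = 16000) {
  if (is.matrix(samples)) samples <- rowMeans(samples)
  samples <- as.numeric(samples)
  if (rate <= 0) stop("rate must be positive")
  structure(list(samples = samples, rate = rate,
                 duration = length(samples) / rate),
            class = "audio_clip")
}

#' Resample a clip to a target rate (linear interpolation)
#' @param clip an `audio_clip`.
#' @param rate target rate in Hz.
#' @return resampled `audio_clip`.
#' @export
resample_clip <- function(clip, rate = 16000) {
  if (clip$rate == rate) return(clip)
  n_out <- round(clip$duration * rate)
  t_out <- (seq_len(n_out) - 1) / rate
  t_in <- (seq_along(clip$samples) - 1) / clip$rate
  audio_clip(stats::approx(t_in, clip$samples, xout = t_out, rule = 2)$y, rate)
}

#' Sliding analysis windows over a clip
#'
#' Windows start at multiples of the hop and are emitted only while they fit
#' entirely inside the clip: `floor((duration - window)/hop) + 1` windows. The
#' default window of 8.82 s with a 0.735 s hop yields 28 windows on a 29 s
#' clip, aligning one-to-one with the trial-level fMRI windows.
#'
#' @param clip an `audio_clip`.
#' @param window window length in seconds.
#' @param hop hop between window starts in seconds.
#' @return list of `audio_clip` windows.
#' @export
sliding_windows <- function(clip, window = 8.82, hop = 0.735) {
  if (hop <= 0 || hop > window) stop("require 0 < hop <= window")
  wn <- round(window * clip$rate)
  hn <- round(hop * clip$rate)
  n <- length(clip$samples)
  if (wn > n) stop("window longer than clip")
  k <- (n - wn) %/% hn
  lapply(0:k, function(i)
    audio_clip(clip$samples[(i * hn + 1):(i * hn + wn)], clip$rate))
}

# ---- codecs ------------------------------------------------------------------

quantize_pcm16 <- function(x) as.integer(round(pmax(pmin(x, 1), -1) * 32767))

# Rice code length in bits for integer residuals at parameter k
rice_bits <- function(res, k) {
  u <- ifelse(res >= 0, 2 * as.numeric(res), -2 * as.numeric(res) - 1)
  sum(floor(u / 2^k)) + length(u) * (k + 1)
}

best_rice_bits <- function(res) {
  u_mean <- mean(abs(as.numeric(res))) * 2 + 1
  k0 <- max(0L, floor(log2(u_mean)))
  min(vapply(max(0L, k0 - 1L):(k0 + 1L), function(k) rice_bits(res, k),
             numeric(1)))
}

#' Lossless codec size of a clip
#'
#' Size in bytes of the clip encoded with the package's lossless audio codec:
#' 16-bit PCM quantization, 4096-sample frames, fixed linear predictors of
#' order 0--3 (the best per frame), and Rice coding of the residuals with a
#' per-frame parameter. A surrogate for the Kolmogorov complexity of the
#' waveform; compare sizes only across clips encoded with the same settings.
#'
#' @param clip an `audio_clip` (mono; use [audio_clip()] to downmix).
#' @param frame frame length in samples.
#' @return integer byte count.
#' @export
flac_complexity <- function(clip, frame = 4096) {
  s <- quantize_pcm16(clip$samples)
  n <- length(s)
  if (n == 0) stop("empty clip")
  starts <- seq(1L, n, by = frame)
  bits <- 0
  for (st in starts) {
    fr <- as.numeric(s[st:min(st + frame - 1L, n)])
    cand <- numeric(4)
    res <- fr
    for (ord in 0:3) {
      cand[ord + 1] <- best_rice_bits(res) + ord * 17   # warm-up samples
      if (length(res) > 1) res <- diff(res) else break
    }
    bits <- bits + min(cand, na.rm = TRUE) + 16         # frame header
  }
  as.integer(ceiling(bits / 8) + 64)                    # stream header
}

#' Lossy codec size of a clip
#'
#' Size in bytes under the package's lossy transform codec: 1024-sample
#' frames, discrete Fourier transform, uniform quantization of the (one-sided)
#' spectrum with a step set by the quality parameter, and DEFLATE entropy
#' coding of the quantized coefficients. Higher quality means a finer step and
#' larger files; sizes are comparable only at a fixed quality.
#'
#' @param clip an `audio_clip`.
#' @param quality integer 0--10; default 5 (mid-scale).
#' @param frame frame length in samples.
#' @return integer byte count.
#' @export
ogg_complexity <- function(clip, quality = 5, frame = 1024) {
  if (quality < 0 || quality > 10) stop("quality must be in [0, 10]")
  s <- as.numeric(quantize_pcm16(clip$samples))
  n <- length(s)
  if (n == 0) stop("empty clip")
  pad <- (frame - n %% frame) %% frame
  s <- c(s, numeric(pad))
  M <- matrix(s, nrow = frame)
  sp <- stats::mvfft(M)[seq_len(frame / 2 + 1), , drop = FALSE]
  step <- 2^(14 - quality)
  q <- c(round(Re(sp) / step), round(Im(sp) / step))
  bytes <- memCompress(writeBin(as.integer(q), raw(), size = 4L), type = "gzip")
  as.integer(length(bytes) + 58)                        # container header
}

# ---- onsets ------------------------------------------------------------------

#' Detect note/percussive onsets in a clip
#'
#' Spectral-flux novelty with noise robustness: magnitude STFT (Hann window,
#' 32 ms frames, 8 ms hop), bin magnitudes pooled into frequency bands,
#' whitened by each band's clip-wide median and log-compressed, then
#' half-wave-rectified frame differences are summed over bands and lightly
#' smoothed. Peaks must exceed both a local median adaptive threshold and a
#' global robust noise floor, must be the maximum within the minimum
#' inter-onset radius, and surviving peaks are pruned greedily (strongest
#' first) to the minimum gap.
#'
#' @param clip an `audio_clip`.
#' @param frame STFT frame length in samples.
#' @param hop STFT hop in samples.
#' @param min_gap minimum inter-onset interval in seconds.
#' @param delta absolute novelty floor as a fraction of the novelty maximum.
#' @param nband number of frequency bands pooled before the flux.
#' @return increasing numeric vector of onset times in seconds.
#' @export
detect_onsets <- function(clip, frame = 512, hop = 128, min_gap = 0.05,
                          delta = 0.05, nband = 32) {
  x <- clip$samples
  n <- length(x)
  if (n < frame) x <- c(x, numeric(frame - n))
  starts <- seq(1L, max(length(x) - frame + 1L, 1L), by = hop)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(frame - 1)) / (frame - 1))
  M <- vapply(starts, function(st) x[st:(st + frame - 1L)] * win,
              numeric(frame))
  spec <- Mod(stats::mvfft(M)[2:(frame / 2 + 1), , drop = FALSE])  # no DC
  if (max(spec) <= 0) return(numeric(0))
  nb <- nrow(spec) %/% nband
  B <- rowsum(spec, rep(seq_len(nband), each = nb)[seq_len(nrow(spec))]) / nb
  ref <- apply(B, 1, stats::median)
  B <- log1p(B / pmax(ref, 1e-6 * max(B)))
  nt <- ncol(B)
  if (nt < 2) return(numeric(0))
  flux <- c(0, colSums(pmax(B[, -1, drop = FALSE] -
                              B[, -nt, drop = FALSE], 0)))
  if (max(flux) <= 0) return(numeric(0))
  k <- min(3L, length(flux))
  flux <- stats::filter(flux, rep(1 / k, k), sides = 2)
  flux[is.na(flux)] <- 0
  flux <- as.numeric(flux)
  L <- max(1L, round(0.3 * clip$rate / hop))
  thr <- vapply(seq_along(flux), function(t) {
    w <- flux[max(1, t - L):min(length(flux), t + L)]
    stats::median(w) + 2 * stats::mad(w)
  }, numeric(1))
  noise_floor <- stats::median(flux) + 4.5 * stats::mad(flux)
  gap_frames <- min_gap * clip$rate / hop
  is_peak <- flux > pmax(thr, noise_floor, delta * max(flux))
  gf <- ceiling(gap_frames)
  for (t in seq_along(flux)) {
    if (is_peak[t]) {
      lo <- max(1, t - gf); hi <- min(length(flux), t + gf)
      if (flux[t] < max(flux[lo:hi])) is_peak[t] <- FALSE
    }
  }
  cand <- which(is_peak)
  if (!length(cand)) return(numeric(0))
  # greedy minimum-gap suppression, strongest peak first
  ord <- cand[order(-flux[cand])]
  keep <- integer(0)
  for (t in ord)
    if (!length(keep) || all(abs(keep - t) >= gap_frames)) keep <- c(keep, t)
  times <- (sort(keep) - 1) * hop / clip$rate
  times[times <= clip$duration]
}

#' Event density of a clip
#'
#' Mean rate of detected onsets: onset count divided by clip duration, in Hz.
#'
#' @param clip an `audio_clip`.
#' @param ... passed to [detect_onsets()].
#' @return scalar rate in Hz.
#' @export
event_density <- function(clip, ...) {
  if (clip$duration <= 0) stop("zero-duration clip")
  length(detect_onsets(clip, ...)) / clip$duration
}

# ---- series extraction -------------------------------------------------------

#' Sliding-window complexity series for a clip
#'
#' Applies one auditory complexity measure to every sliding window of the
#' clip. With the default 8.82 s window and 0.735 s hop a 29 s clip yields a
#' 28-point series per measure.
#'
#' @param clip an `audio_clip`.
#' @param measure one of `"flac"`, `"ogg"`, `"event_density"`.
#' @param window,hop window spec in seconds.
#' @param ... passed to the underlying measure.
#' @return object of class `complexity_series`: list with `measure`, `values`,
#'   `window`, `hop`.
#' @export
extract_series <- function(clip, measure = c("flac", "ogg", "event_density"),
                           window = 8.82, hop = 0.735, ...) {
  measure <- match.arg(measure)
  fn <- switch(measure,
               flac = flac_complexity,
               ogg = ogg_complexity,
               event_density = event_density)
  wins <- sliding_windows(clip, window, hop)
  structure(list(measure = measure,
                 values = vapply(wins, fn, numeric(1), ...),
                 window = window, hop = hop),
            class = "complexity_series")
}

#' Batch auditory complexity table (long format)
#'
#' @param clips list of `audio_clip` objects.
#' @param ids stimulus identifiers.
#' @param window,hop window spec in seconds.
#' @return data.frame `stimulus_id, window_index, measure, value`.
#' @export
audio_complexity_table <- function(clips, ids = NULL, window = 8.82,
                                   hop = 0.735) {
  if (is.null(ids)) ids <- if (!is.null(names(clips))) names(clips)
                           else as.character(seq_along(clips))
  rows <- list()
  for (i in seq_along(clips)) {
    for (m in c("flac", "ogg", "event_density")) {
      s <- extract_series(clips[[i]], m, window, hop)
      rows[[length(rows) + 1L]] <- data.frame(
        stimulus_id = ids[i], window_index = seq_along(s$values),
        measure = m, value = s$values, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# ---- WAV I/O (16-bit PCM) ----------------------------------------------------

#' Read a 16-bit PCM WAV file
#' @param path file path.
#' @return an `audio_clip` (multi-channel input downmixed to mono).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  rate <- NULL; channels <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, 2, endian = "little")
      channels <- fmt[2]
      rate <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))
      invisible(readBin(con, "integer", 1, 2, endian = "little"))
      bits <- readBin(con, "integer", 1, 2, endian = "little")
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
      if (fmt[1] != 1L || bits != 16L)
        stop("only 16-bit PCM WAV is supported")
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", sz / 2, 2, signed = TRUE,
                         endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
  if (is.null(samples) || is.null(rate)) stop("malformed WAV file: ", path)
  x <- samples / 32768
  if (channels > 1) x <- rowMeans(matrix(x, ncol = channels, byrow = TRUE))
  audio_clip(x, rate)
}

#' Write a clip as a 16-bit PCM mono WAV file
#' @param clip an `audio_clip`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  s <- quantize_pcm16(clip$samples)
  con <- file(path, "wb"); on.exit(close(con))
  data_sz <- 2L * length(s)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")         # PCM, mono
  writeBin(as.integer(clip$rate), con, 4, endian = "little")
  writeBin(as.integer(clip$rate * 2L), con, 4, endian = "little")
  writeBin(c(2L, 16L), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_sz, con, 4, endian = "little")
  writeBin(s, con, 2, endian = "little")
  invisible(path)
}
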