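# Pulse feature extraction: conventional A/H/W parameters and the deepest
# dyadic Haar coefficients that the real-time signal processing operates on.

#' Haar wavelet coefficients of one pulse
#'
#' Orthonormal dyadic Haar transform of the waveform, keeping the deepest
#' level whose atoms span 16 samples. For each block b of 16 consecutive
#' samples the detail coefficient is
#' \deqn{c_b = (\sum \textrm{first 8} - \sum \textrm{last 8}) / 4,}
#' i.e. the inner product with the orthonormal Haar atom (+1/4 over the first
#' eight samples, -1/4 over the last eight). An 80-sample trigger window
#' therefore yields exactly 5 coefficients per channel, the feature space the
#' sort decision operates in. The same-level approximation (scaling)
#' coefficients, `(sum of 16)/4`, are available via `type`.
#'
#' @param waveform numeric vector whose length is a multiple of 16.
#' @param type `"detail"` (default) or `"approximation"`.
#' @return numeric vector of `length(waveform)/16` coefficients, ordered by
#'   time position within the window.
#' @examples
#' haar_coefficients(rep(1, 80))  # constants have vanishing detail: 0 0 0 0 0
#' @export
haar_coefficients <- function(waveform, type = c("detail", "approximation")) {
  type <- match.arg(type)
  n <- length(waveform)
  if (n == 0 || n %% 16 != 0) {
    stop("haar_coefficients: waveform length (", n,
         ") must be a positive multiple of 16; no silent padding", call. = FALSE)
  }
  blocks <- matrix(waveform, nrow = 16)
  if (type == "detail") {
    (colSums(blocks[1:8, , drop = FALSE]) -
       colSums(blocks[9:16, , drop = FALSE])) / 4
  } else {
    colSums(blocks) / 4
  }
}

#' Streaming Haar coefficients of a continuous sample stream
#'
#' Emits one coefficient per 16 consecutive samples starting at `offset`,
#' emulating a transform running continuously on the incoming data stream
#' with an adjustable time offset. On any window aligned with batch block
#' boundaries the output equals [haar_coefficients()] of that window.
#'
#' @param samples numeric vector, the sample stream.
#' @param offset alignment offset in samples, in `[0, 16)`.
#' @param type passed to the per-block computation, see [haar_coefficients()].
#' @return numeric vector of `floor((length(samples) - offset)/16)`
#'   coefficients (empty when the stream is shorter than `16 + offset`).
#' @export
streaming_haar <- function(samples, offset = 0L, type = c("detail", "approximation")) {
  type <- match.arg(type)
  offset <- as.integer(offset)
  if (offset < 0L || offset >= 16L) stop("offset must lie in [0, 16)", call. = FALSE)
  usable <- length(samples) - offset
  n_blocks <- usable %/% 16L
  if (n_blocks <= 0L) return(numeric(0))
  x <- samples[(offset + 1L):(offset + 16L * n_blocks)]
  haar_coefficients(x, type = type)
}

#' Area, height and width of one pulse
#'
#' The conventional per-event scalar parameters, computed on the
#' baseline-subtracted waveform: area A is the sum of positive samples,
#' height H the maximum sample, and width W the number of samples above 50%
#' of H. The baseline defaults to the median of the first and last 4 samples
#' of the window (the pulse is centred, so the window edges see baseline
#' only). An all-baseline waveform yields A = H = W = 0; a purely
#' negative-going (extinction) pulse yields A = 0, H = 0 and W = 0 as well —
#' width is only defined for positive-going pulses.
#'
#' @param waveform numeric vector.
#' @param baseline_estimate baseline level; `NULL` (default) estimates it
#'   from the window edges.
#' @return named numeric vector `c(A=, H=, W=)`.
#' @examples
#' compute_ahw(c(0, 1, 2, 3, 4, 3, 2, 1, 0), baseline_estimate = 0)
#' # A = 16, H = 4, W = 3
#' @export
compute_ahw <- function(waveform, baseline_estimate = NULL) {
  n <- length(waveform)
  if (n < 1) stop("empty waveform", call. = FALSE)
  if (is.null(baseline_estimate)) {
    edge <- min(4L, n %/% 2)
    baseline_estimate <- if (edge > 0) {
      stats::median(c(waveform[seq_len(edge)], waveform[(n - edge + 1L):n]))
    } else waveform[1]
  }
  v <- waveform - baseline_estimate
  h <- max(v)
  if (h <= 0) return(c(A = 0, H = max(0, h), W = 0))
  c(A = sum(pmax(v, 0)), H = h, W = sum(v > h / 2))
}

#' Wavelet feature matrix of a stream
#'
#' Applies [haar_coefficients()] per channel to every event.
#'
#' @param stream a `pulse_stream`.
#' @param type passed to [haar_coefficients()].
#' @return numeric matrix, `n_events x (n_channels * n_coeff)`; columns are
#'   named `<channel>.c<i>` with `i` in `0..n_coeff-1` ordered by time
#'   position, grouped by channel.
#' @export
wavelet_features <- function(stream, type = c("detail", "approximation")) {
  stopifnot(inherits(stream, "pulse_stream"))
  type <- match.arg(type)
  n <- n_events(stream)
  n_ch <- stream$optics$n_channels
  n_s <- stream$optics$n_samples
  nc <- n_s %/% 16L
  if (n_s %% 16L != 0L) {
    stop("window of ", n_s, " samples is not a multiple of 16", call. = FALSE)
  }
  out <- matrix(0, n, n_ch * nc)
  colnames(out) <- as.vector(vapply(stream$optics$channel_names, function(ch)
    paste0(ch, ".c", 0:(nc - 1)), character(nc)))
  for (ch in seq_len(n_ch)) {
    # vectorized over events: each row reshaped into 16-sample blocks
    w <- stream$waveforms[, ch, , drop = FALSE]
    dim(w) <- c(n, n_s)
    cols <- (ch - 1L) * nc + seq_len(nc)
    for (b in seq_len(nc)) {
      s <- (b - 1L) * 16L
      if (type == "detail") {
        out[, cols[b]] <- (rowSums(w[, s + 1:8, drop = FALSE]) -
                             rowSums(w[, s + 9:16, drop = FALSE])) / 4
      } else {
        out[, cols[b]] <- rowSums(w[, s + 1:16, drop = FALSE]) / 4
      }
    }
  }
  out
}

#' A/H/W feature table of a stream
#'
#' Per-event area, height and width for every channel, plus any stain
#' intensities carried by the stream. This is the table exported to FCS
#' list-mode files.
#'
#' @param stream a `pulse_stream`.
#' @return data.frame with columns `<channel>.A`, `<channel>.H`,
#'   `<channel>.W` per channel and `stain1`, `stain2` when present.
#' @export
ahw_features <- function(stream) {
  stopifnot(inherits(stream, "pulse_stream"))
  n <- n_events(stream)
  chn <- stream$optics$channel_names
  out <- vector("list", length(chn))
  for (ch in seq_along(chn)) {
    m <- t(apply(stream$waveforms[, ch, , drop = FALSE], 1,
                 function(row) compute_ahw(as.numeric(row))))
    if (n == 0) m <- matrix(0, 0, 3, dimnames = list(NULL, c("A", "H", "W")))
    colnames(m) <- paste0(chn[ch], ".", c("A", "H", "W"))
    out[[ch]] <- m
  }
  df <- as.data.frame(do.call(cbind, out))
  if (!is.null(stream$stains)) df <- cbind(df, as.data.frame(stream$stains))
  df
}
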