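#' STFT configuration
#'
#' @param window_seconds Window length in seconds (default 0.2 s: 72
#'   samples at 360 Hz, 100 at 500 Hz).
#' @param hop_seconds Frame increment in seconds (default 0.01 s: 4 samples
#'   at 360 Hz, 5 at 500 Hz).
#' @param kaiser_alpha Kaiser shape parameter alpha (the window argument is
#'   `pi * alpha`); 0 gives a rectangular window. Default 3.
#' @param magnitude_mode `"linear"` or `"log"` (`log1p` of the linear
#'   magnitude).
#' @return An object of class `stft_config`.
#' @export
stft_config <- function(window_seconds = 0.2, hop_seconds = 0.01,
                        kaiser_alpha = 3,
                        magnitude_mode = c("linear", "log")) {
  magnitude_mode <- match.arg(magnitude_mode)
  if (!(window_seconds > hop_seconds && hop_seconds > 0)) {
    stop("need window_seconds > hop_seconds > 0")
  }
  if (kaiser_alpha < 0) stop("kaiser_alpha must be >= 0")
  structure(list(window_seconds = window_seconds, hop_seconds = hop_seconds,
                 kaiser_alpha = kaiser_alpha,
                 magnitude_mode = magnitude_mode),
            class = "stft_config")
}

#' Kaiser window weights
#'
#' `w(n) = I0(pi * alpha * sqrt(1 - (2n/(N-1) - 1)^2)) / I0(pi * alpha)`
#' for `0 <= n <= N-1`, where `I0` is the zeroth-order modified Bessel
#' function of the first kind. Symmetric, peak value 1 at the centre;
#' `alpha = 0` collapses to the rectangular window.
#'
#' @param N Window length in samples (>= 1).
#' @param alpha Shape parameter (>= 0).
#' @return Numeric vector of `N` weights.
#' @export
kaiser_window <- function(N, alpha) {
  if (N < 1) stop("window length must be >= 1")
  if (N == 1) return(1)
  n <- 0:(N - 1)
  arg <- 1 - (2 * n / (N - 1) - 1)^2
  arg[arg < 0] <- 0
  besselI(pi * alpha * sqrt(arg), 0) / besselI(pi * alpha, 0)
}

#' Kaiser-window magnitude STFT spectrogram
#'
#' Frames of `round(window_seconds * fs)` samples advance by
#' `round(hop_seconds * fs)` samples; each frame is tapered with the Kaiser
#' window and transformed with an N-point DFT (N = window length). All N
#' magnitude bins are kept as rows (so conjugate-symmetric rows are
#' retained, matching the square frame height), frames as columns; the
#' segment itself is never zero-padded, so the frame count is
#' `floor((L - window) / hop) + 1`.
#'
#' @param segment Numeric vector of length >= one window.
#' @param sampling_rate Sampling rate in Hz used to convert the second
#'   based window/hop to samples (adaptive-layout segments use their
#'   nominal 500 Hz).
#' @param cfg An [stft_config()].
#' @param onesided Keep only bins `0..floor(N/2)` (off by default).
#' @return A numeric matrix of class `spectrogram` with attributes
#'   `window_len`, `hop` and `sampling_rate`.
#' @export
stft_spectrogram <- function(segment, sampling_rate, cfg = stft_config(),
                             onesided = FALSE) {
  win <- round(cfg$window_seconds * sampling_rate)
  hop <- round(cfg$hop_seconds * sampling_rate)
  if (hop < 1) stop("hop shorter than one sample")
  L <- length(segment)
  if (L < win) stop("segment shorter than one window")
  n_frames <- floor((L - win) / hop) + 1
  w <- kaiser_window(win, cfg$kaiser_alpha)
  starts <- (seq_len(n_frames) - 1) * hop
  frames <- vapply(starts, function(s) segment[(s + 1):(s + win)] * w,
                   numeric(win))
  mag <- abs(stats::mvfft(frames))
  if (onesided) mag <- mag[seq_len(floor(win / 2) + 1), , drop = FALSE]
  if (cfg$magnitude_mode == "log") mag <- log1p(mag)
  structure(mag, window_len = win, hop = hop, sampling_rate = sampling_rate,
            class = c("spectrogram", class(mag)))
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram: %d frequency bins x %d frames (window %d, hop %d)>\n",
              nrow(x), ncol(x), attr(x, "window_len"), attr(x, "hop")))
  invisible(x)
}
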