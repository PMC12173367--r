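#' Paired dual-scale beat sample
#'
#' One labelled heartbeat represented at two temporal scales: a
#' single-cycle window and a three-cycle window, both centered on the same
#' R-peak. In fixed mode (360 Hz layout) the windows are 288 and 864
#' samples; in adaptive mode both are resized to the configured targets
#' (400 and 1200 by default).
#'
#' @param single_cycle,three_cycle Numeric segment vectors.
#' @param center_r 0-based R-peak index in the source record.
#' @param label Beat-class label.
#' @param soft_label Optional probability vector over classes (used by
#'   Mixup-generated samples).
#' @return An object of class `dual_sample`.
#' @export
dual_sample <- function(single_cycle, three_cycle, center_r, label,
                        soft_label = NULL) {
  structure(list(single_cycle = as.numeric(single_cycle),
                 three_cycle = as.numeric(three_cycle),
                 center_r = center_r, label = label,
                 soft_label = soft_label),
            class = "dual_sample")
}

#' Fixed-length dual-scale crop around one R-peak
#'
#' Takes 143 samples left and 144 right of the R-peak for the single-cycle
#' window (288 samples, R included in the left count) and 431 left / 432
#' right for the three-cycle window (864 samples). The single-cycle window
#' is by construction the central third of the three-cycle window.
#'
#' @param signal Numeric vector.
#' @param r_index 0-based R-peak index.
#' @return List with `single` and `three`, or `NULL` when the three-cycle
#'   window does not fit inside the signal (the beat is skipped upstream).
#' @export
crop_fixed <- function(signal, r_index) {
  n <- length(signal)
  if (r_index - 431 < 0 || r_index + 432 >= n) return(NULL)
  list(single = signal[(r_index - 143):(r_index + 144) + 1],
       three = signal[(r_index - 431):(r_index + 432) + 1])
}

#' Cycle length in samples from heart rate and sampling rate
#'
#' `Ns = 60 / Hr * Sr`: the expected number of samples per cardiac cycle.
#'
#' @param heart_rate_bpm Heart rate in beats per minute (> 0).
#' @param sampling_rate Sampling rate in Hz.
#' @return Cycle length in samples (a real number; callers round).
#' @export
adaptive_cycle_length <- function(heart_rate_bpm, sampling_rate) {
  if (heart_rate_bpm <= 0) stop("heart rate must be positive")
  60 / heart_rate_bpm * sampling_rate
}

#' Heart-rate-adaptive dual-scale crop
#'
#' Takes `round(Ns/2)` samples on each side for the single-cycle window and
#' `round(3*Ns/2)` on each side for the three-cycle window (round-half-up;
#' the R sample occupies the left half-count), centred on the R-peak.
#'
#' @param signal Numeric vector.
#' @param r_index 0-based R-peak index.
#' @param Ns Cycle length in samples (see [adaptive_cycle_length()]).
#' @return List with `single` (length `2*round(Ns/2)`) and `three` (length
#'   `2*round(3*Ns/2)`), or `NULL` when the three-cycle window does not fit.
#' @export
crop_adaptive <- function(signal, r_index, Ns) {
  if (Ns < 8) stop("degenerate cycle length")
  n <- length(signal)
  h1 <- round_half_up(Ns / 2)
  h3 <- round_half_up(3 * Ns / 2)
  if (r_index - h3 + 1 < 0 || r_index + h3 >= n) return(NULL)
  list(single = signal[(r_index - h1 + 1):(r_index + h1) + 1],
       three = signal[(r_index - h3 + 1):(r_index + h3) + 1])
}

# Cubic-convolution (Keys, a = -0.5) interpolation weights from n_in
# samples onto n_out positions with endpoint alignment and clamped border
# samples. Returns the dense n_out x n_in weight matrix; resampling is
# `M %*% x`. The kernel reproduces constants exactly and linear ramps away
# from the borders, and integer-aligned mappings reduce to the identity.
cubic_kernel <- function(x) {
  ax <- abs(x)
  ifelse(ax <= 1, 1.5 * ax^3 - 2.5 * ax^2 + 1,
         ifelse(ax < 2, -0.5 * ax^3 + 2.5 * ax^2 - 4 * ax + 2, 0))
}

cubic_resize_matrix <- function(n_in, n_out) {
  if (n_in < 4) stop("need at least 4 samples for cubic interpolation")
  if (n_out < 1) stop("target length must be >= 1")
  M <- matrix(0, n_out, n_in)
  u <- if (n_out == 1) (n_in - 1) / 2 else (0:(n_out - 1)) * (n_in - 1) / (n_out - 1)
  base <- floor(u)
  for (k in -1:2) {
    src <- base + k
    wgt <- cubic_kernel(u - src)
    src <- pmin(pmax(src, 0), n_in - 1)
    for (i in seq_len(n_out)) {
      if (wgt[i] != 0) M[i, src[i] + 1] <- M[i, src[i] + 1] + wgt[i]
    }
  }
  M
}

#' Resample a 1-D segment with bicubic (cubic-convolution) interpolation
#'
#' The segment is treated as a 1 x N image and resampled with the standard
#' cubic-convolution kernel (a = -0.5). Constants are reproduced exactly;
#' an identity-length resize returns the input.
#'
#' @param segment Numeric vector of length >= 4.
#' @param target_len Output length (>= 4).
#' @return Numeric vector of length `target_len`.
#' @export
resize_1d <- function(segment, target_len) {
  if (length(segment) < 4) stop("segment too short for cubic interpolation")
  if (target_len < 4) stop("target length must be >= 4")
  as.numeric(cubic_resize_matrix(length(segment), target_len) %*% segment)
}

#' Build paired dual-scale samples for every labelled beat of a record
#'
#' Fixed mode uses the 288/864-sample windows of the 360 Hz layout.
#' Adaptive mode estimates the record's heart rate from the median R-R
#' interval, crops `Ns`-dependent windows and resizes them to
#' `resize_targets` with bicubic interpolation. Beats whose three-cycle
#' window falls outside the record are skipped; the count of skipped beats
#' is attached as the `n_skipped` attribute.
#'
#' @param record An [ecg_record()] with `r_peaks` and `beat_labels` (or a
#'   record-level `rhythm` attribute for adaptive CSV data).
#' @param mode `"fixed"` or `"adaptive"`.
#' @param resize_targets Adaptive-mode output lengths, default `c(400, 1200)`.
#' @return List of [dual_sample()] objects with attribute `n_skipped`.
#' @export
build_samples <- function(record, mode = c("fixed", "adaptive"),
                          resize_targets = c(400, 1200)) {
  mode <- match.arg(mode)
  stopifnot(inherits(record, "ecg_record"))
  peaks <- record$r_peaks
  if (is.null(peaks) || length(peaks) == 0) {
    out <- list()
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  labels <- record$beat_labels
  if (is.null(labels)) {
    rhythm <- attr(record, "rhythm")
    if (is.null(rhythm) || is.na(rhythm)) stop("record has no beat labels")
    labels <- rep(rhythm, length(peaks))
  }
  x <- record$samples
  out <- vector("list", length(peaks))
  skipped <- 0L
  if (mode == "adaptive") {
    if (length(peaks) < 2) stop("adaptive mode needs >= 2 R-peaks")
    hr <- 60 * record$sampling_rate / median(diff(peaks))
    Ns <- adaptive_cycle_length(hr, record$sampling_rate)
  }
  for (i in seq_along(peaks)) {
    cr <- if (mode == "fixed") {
      crop_fixed(x, peaks[i])
    } else {
      crop_adaptive(x, peaks[i], Ns)
    }
    if (is.null(cr)) {
      skipped <- skipped + 1L
      next
    }
    if (mode == "adaptive") {
      cr$single <- resize_1d(cr$single, resize_targets[1])
      cr$three <- resize_1d(cr$three, resize_targets[2])
    }
    out[[i]] <- dual_sample(cr$single, cr$three, peaks[i], labels[i])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  attr(out, "n_skipped") <- skipped
  out
}
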