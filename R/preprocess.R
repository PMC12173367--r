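#' Denoising configuration
#'
#' @param wavelet_name Wavelet family; `"db4"` (Daubechies, 4 vanishing
#'   moments) is the only built-in.
#' @param levels Decomposition depth (default 8).
#' @param threshold_rule `"sure"` (Stein's unbiased risk estimate, soft
#'   thresholding, per level) or `"universal"`.
#' @param baseline_window_frac Running-median window as a fraction of the
#'   sampling rate (default 0.30, i.e. 108 samples at 360 Hz).
#' @return An object of class `denoise_config`.
#' @export
denoise_config <- function(wavelet_name = "db4", levels = 8,
                           threshold_rule = c("sure", "universal"),
                           baseline_window_frac = 0.30) {
  threshold_rule <- match.arg(threshold_rule)
  if (levels < 1) stop("levels must be >= 1")
  if (baseline_window_frac <= 0 || baseline_window_frac >= 1) {
    stop("baseline_window_frac must lie in (0, 1)")
  }
  if (wavelet_name != "db4") stop("only the db4 wavelet is built in")
  structure(list(wavelet_name = wavelet_name, levels = as.integer(levels),
                 threshold_rule = threshold_rule,
                 baseline_window_frac = baseline_window_frac),
            class = "denoise_config")
}

# Daubechies-4 orthonormal scaling filter; the wavelet filter is its
# quadrature mirror. Periodized filter bank => an orthogonal transform with
# exact reconstruction for even lengths.
db4_lo <- c(0.2303778133088552, 0.7148465705525415, 0.6308807679295904,
            -0.0279837694169839, -0.1870348117188811, 0.0308413818359870,
            0.0328830116669829, -0.0105974017849973)
db4_hi <- rev(db4_lo) * c(1, -1, 1, -1, 1, -1, 1, -1)

dwt_step <- function(x, filt) {
  n <- length(x)
  out <- numeric(n / 2)
  k2 <- 2 * (seq_len(n / 2) - 1)
  for (m in seq_along(filt)) {
    out <- out + filt[m] * x[(k2 + m - 1) %% n + 1]
  }
  out
}

idwt_step <- function(a, d, lo, hi) {
  n <- 2 * length(a)
  x <- numeric(n)
  k2 <- 2 * (seq_along(a) - 1)
  for (m in seq_along(lo)) {
    idx <- (k2 + m - 1) %% n + 1
    x[idx] <- x[idx] + lo[m] * a + hi[m] * d
  }
  x
}

# Periodized multilevel DWT. Returns approx at the deepest level plus the
# detail bands, finest first.
dwt_db4 <- function(x, levels) {
  details <- vector("list", levels)
  cur <- x
  for (j in seq_len(levels)) {
    details[[j]] <- dwt_step(cur, db4_hi)
    cur <- dwt_step(cur, db4_lo)
  }
  list(approx = cur, details = details)
}

idwt_db4 <- function(decomp) {
  cur <- decomp$approx
  for (j in rev(seq_along(decomp$details))) {
    cur <- idwt_step(cur, decomp$details[[j]], db4_lo, db4_hi)
  }
  cur
}

# SURE threshold for soft shrinkage of ~N(0,1) data (the rigorous-SURE
# rule): minimise the unbiased risk estimate over thresholds at the data
# magnitudes.
sure_threshold <- function(x) {
  n <- length(x)
  if (n == 0) return(0)
  s <- sort(x^2)
  cs <- cumsum(s)
  k <- seq_len(n)
  risk <- (n - 2 * k + cs + (n - k) * s) / n
  sqrt(s[which.min(risk)])
}

soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

#' Wavelet-threshold denoising
#'
#' Eight-level (by default) periodized db4 decomposition with per-level
#' soft thresholding of the detail bands; thresholds are selected by
#' Stein's unbiased risk estimate with the noise scale taken from the
#' median absolute deviation of the finest detail band. Approximation
#' coefficients pass through untouched, so slow baseline content is left
#' for the median filter.
#'
#' @param signal Numeric vector.
#' @param cfg A [denoise_config()].
#' @return Denoised signal, same length as the input.
#' @export
wavelet_denoise <- function(signal, cfg = denoise_config()) {
  if (length(signal) == 0) stop("empty signal")
  n <- length(signal)
  levels <- cfg$levels
  if (n < 2^levels) {
    levels <- max(1L, floor(log2(n)) - 2L)
    warning("signal shorter than 2^levels; reducing to ", levels, " levels")
  }
  block <- 2^levels
  n_pad <- ceiling(n / block) * block
  x <- if (n_pad > n) {
    pad <- n_pad - n
    c(signal, signal[n - seq_len(pad) + 1])   # symmetric extension
  } else signal
  dec <- dwt_db4(x, levels)
  sigma <- median(abs(dec$details[[1]])) / 0.6745
  if (sigma > 0) {
    for (j in seq_len(levels)) {
      d <- dec$details[[j]]
      thr <- if (cfg$threshold_rule == "sure") {
        sigma * sure_threshold(d / sigma)
      } else {
        sigma * sqrt(2 * log(length(d)))
      }
      dec$details[[j]] <- soft_threshold(d, thr)
    }
  }
  idwt_db4(dec)[seq_len(n)]
}

#' Baseline-wander removal by running-median subtraction
#'
#' Subtracts a centered running median whose window is a fraction of the
#' sampling rate (0.30 by default: 108 samples at 360 Hz). Even windows are
#' supported; edges use reflect padding. A constant signal maps to zero.
#'
#' @param signal Numeric vector.
#' @param sampling_rate Sampling frequency in Hz.
#' @param cfg A [denoise_config()].
#' @return Signal minus its running median, same length.
#' @export
remove_baseline <- function(signal, sampling_rate, cfg = denoise_config()) {
  window <- round(cfg$baseline_window_frac * sampling_rate)
  if (window < 3) stop("baseline window must be >= 3 samples")
  if (window > length(signal)) stop("baseline window longer than signal")
  signal - cpp_running_median(signal, as.integer(window))
}

#' R-peak detection (Pan-Tompkins style)
#'
#' Band-pass (5-15 Hz), differentiate, square, integrate over a 150 ms
#' centered window, pick integration peaks with an adaptive signal/noise
#' threshold, then refine each detection to the largest absolute deflection
#' of the input within +/-75 ms. A 0.2 s refractory period is enforced.
#' Intended for signals already denoised and baseline-corrected; annotated
#' datasets should use their annotations instead.
#'
#' @param signal Numeric vector (a denoised single lead).
#' @param sampling_rate Sampling frequency in Hz.
#' @return Integer vector of 0-based R-peak indices (possibly empty).
#' @export
detect_r_peaks <- function(signal, sampling_rate) {
  n <- length(signal)
  if (n == 0 || max(abs(signal)) < 1e-9) return(integer(0))
  if (n < 2 * sampling_rate) stop("need at least 2 s of signal")
  ny <- sampling_rate / 2
  bp <- signal::butter(2, c(5, 15) / ny, type = "pass")
  filtered <- signal::filtfilt(bp, signal)
  deriv <- c(0, diff(filtered))
  sq <- deriv^2
  w <- max(3L, round(0.15 * sampling_rate))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  # compress the dynamic range so low-amplitude beat classes survive the
  # adaptive threshold alongside large ones
  integ <- sqrt(integ)
  # candidate local maxima, >= 0.2 s apart (keep the larger on conflict)
  refr <- as.integer(round(0.2 * sampling_rate))
  is_pk <- which(diff(sign(diff(integ))) < 0) + 1L
  is_pk <- is_pk[integ[is_pk] > 0]
  if (length(is_pk) == 0) return(integer(0))
  is_pk <- is_pk[order(integ[is_pk], decreasing = TRUE)]
  keep <- logical(0)
  sel <- integer(0)
  for (p in is_pk) {
    if (all(abs(sel - p) >= refr)) sel <- c(sel, p)
  }
  sel <- sort(sel)
  # adaptive two-level thresholding over candidates in time order
  spki <- max(integ[seq_len(min(n, 2 * sampling_rate))]) * 0.8
  npki <- mean(integ[seq_len(min(n, 2 * sampling_rate))]) * 0.5
  peaks <- integer(0)
  cand_thr <- numeric(length(sel))
  accepted <- logical(length(sel))
  for (k in seq_along(sel)) {
    p <- sel[k]
    thr <- npki + 0.25 * (spki - npki)
    cand_thr[k] <- thr
    if (integ[p] > thr) {
      peaks <- c(peaks, p)
      accepted[k] <- TRUE
      spki <- 0.125 * integ[p] + 0.875 * spki
    } else {
      npki <- 0.125 * integ[p] + 0.875 * npki
    }
  }
  if (length(peaks) == 0) return(integer(0))
  # search-back: re-examine long R-R gaps at half threshold
  if (length(peaks) >= 3) {
    repeat {
      peaks <- sel[accepted]
      med_rr <- median(diff(peaks))
      changed <- FALSE
      bounds <- c(0L, peaks, n)
      for (g in which(diff(bounds) > 1.66 * med_rr)) {
        inside <- which(!accepted & sel > bounds[g] & sel < bounds[g + 1])
        inside <- inside[integ[sel[inside]] > cand_thr[inside] / 2]
        if (length(inside) > 0) {
          best <- inside[which.max(integ[sel[inside]])]
          accepted[best] <- TRUE
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    peaks <- sel[accepted]
  }
  # refine to the strongest deflection of the input near each detection
  half <- as.integer(round(0.075 * sampling_rate))
  refined <- vapply(peaks, function(p) {
    lo <- max(1L, p - half)
    hi <- min(n, p + half)
    lo + which.max(abs(signal[lo:hi])) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # final refractory pass on refined indices
  out <- integer(0)
  for (p in refined) {
    if (length(out) == 0 || p - out[length(out)] >= refr) {
      out <- c(out, p)
    } else if (abs(signal[p]) > abs(signal[out[length(out)]])) {
      out[length(out)] <- p
    }
  }
  as.integer(out - 1L)   # 0-based
}
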