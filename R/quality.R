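#' Signal-quality thresholds
#'
#' The exclusion rules applied before feature extraction. Defaults are the
#' device-calibrated constants of the development device and are exposed
#' because they depend on the sensor's units and sampling rate:
#' a window is rejected when it touches the saturation ceiling, when more
#' than \code{missing_max} of its samples are missing, when any
#' overlapping 1-s accelerometer window has weighted-sd motion score
#' above \code{acc_threshold}, when the spectral mass above
#' \code{hf_cutoff} exceeds \code{hf_ratio_max} of the total, or when the
#' segment's peak heights satisfy all three sharp-peak ratio conditions.
#' Pulse intervals shorter than \code{min_ppi_s} (= 60/200 s, i.e. above
#' 200 beats/min) are invalid.
#'
#' @param missing_max maximal tolerated missing-sample fraction (strictly
#'   greater rejects).
#' @param acc_w weights of the per-axis accelerometer sds in the motion
#'   score.
#' @param acc_threshold motion-score rejection threshold (strictly greater
#'   rejects), device units.
#' @param hf_cutoff high-frequency cutoff, Hz.
#' @param hf_ratio_max maximal tolerated spectral ratio above the cutoff
#'   (strictly greater rejects).
#' @param sharp_max_ratio,sharp_iqr_ratio,sharp_mean_ratio sharp-peak
#'   thresholds on max/median, IQR/median and mean/median peak height
#'   (all three at-or-above rejects).
#' @param min_ppi_s minimal valid pulse-to-pulse interval, seconds.
#' @return An object of class \code{"quality_thresholds"}.
#' @export
quality_thresholds <- function(missing_max = 0.05,
                               acc_w = c(0.57, 0.58, 0.57),
                               acc_threshold = 23.12,
                               hf_cutoff = 30, hf_ratio_max = 0.5,
                               sharp_max_ratio = 4.5,
                               sharp_iqr_ratio = 2.15,
                               sharp_mean_ratio = 1.3,
                               min_ppi_s = 60 / 200) {
  stopifnot(missing_max > 0, missing_max < 1, length(acc_w) == 3,
            all(acc_w > 0), acc_threshold > 0, hf_cutoff > 0,
            hf_ratio_max > 0, min_ppi_s > 0)
  structure(list(missing_max = missing_max, acc_w = acc_w,
                 acc_threshold = acc_threshold, hf_cutoff = hf_cutoff,
                 hf_ratio_max = hf_ratio_max,
                 sharp_max_ratio = sharp_max_ratio,
                 sharp_iqr_ratio = sharp_iqr_ratio,
                 sharp_mean_ratio = sharp_mean_ratio,
                 min_ppi_s = min_ppi_s),
            class = "quality_thresholds")
}

#' Saturation check
#'
#' TRUE iff any finite sample in the window equals the saturation ceiling
#' (clipping). Missing samples are the business of
#' \code{\link{missing_fraction}} and do not trigger this flag.
#'
#' @param window numeric samples (NA = missing).
#' @param saturation_value clipping ceiling, same units.
#' @return logical flag.
#' @export
check_saturation <- function(window, saturation_value) {
  if (length(window) == 0) stop("empty window", call. = FALSE)
  any(window == saturation_value, na.rm = TRUE)
}

#' Missing-sample fraction of a window
#'
#' @param window numeric samples (NA = missing).
#' @return fraction of missing samples in [0, 1]; reject when strictly
#'   above the \code{missing_max} threshold (5\% default: 256 missing of a
#'   5120-sample 10-s window at 512 Hz is still kept).
#' @export
missing_fraction <- function(window) {
  if (length(window) == 0) stop("empty window", call. = FALSE)
  mean(is.na(window))
}

#' Accelerometer motion score of a 1-s window
#'
#' Weighted sum of the per-axis sample standard deviations,
#' \code{0.57 sd(ax) + 0.58 sd(ay) + 0.57 sd(az)}; wrist movement is
#' declared when the score strictly exceeds the device threshold
#' (default 23.12).
#'
#' @param ax,ay,az per-axis samples over ~1 s (equal lengths, >= 2).
#' @param w the three axis weights.
#' @return numeric score.
#' @export
motion_score <- function(ax, ay, az, w = c(0.57, 0.58, 0.57)) {
  if (length(ax) != length(ay) || length(ay) != length(az))
    stop("axis length mismatch", call. = FALSE)
  if (length(ax) < 2) stop("need >= 2 samples per axis", call. = FALSE)
  w[1] * sd(ax) + w[2] * sd(ay) + w[3] * sd(az)
}

#' Motion scores over consecutive 1-s accelerometer windows
#'
#' @param acc an \code{"acc_record"}.
#' @param thresholds a \code{\link{quality_thresholds}}.
#' @return data frame \code{start_s}, \code{end_s}, \code{score},
#'   \code{flag} (score strictly above threshold) for each full
#'   non-overlapping 1-s window.
#' @export
motion_flags <- function(acc, thresholds = quality_thresholds()) {
  stopifnot(inherits(acc, "acc_record"))
  n <- length(acc$ax)
  wlen <- round(acc$fs)
  n_win <- n %/% wlen
  if (n_win < 1) stop("recording shorter than 1 s", call. = FALSE)
  out <- data.frame(start_s = (seq_len(n_win) - 1L) * wlen / acc$fs)
  out$end_s <- out$start_s + wlen / acc$fs
  out$score <- vapply(seq_len(n_win), function(k) {
    idx <- ((k - 1L) * wlen + 1L):(k * wlen)
    motion_score(acc$ax[idx], acc$ay[idx], acc$az[idx], thresholds$acc_w)
  }, numeric(1))
  out$flag <- out$score > thresholds$acc_threshold
  out
}

#' High-frequency spectral ratio of a smoothed window
#'
#' Ratio of summed FFT magnitudes at frequencies strictly above the
#' cutoff to the total over all positive-frequency bins (DC excluded).
#' Windows whose ratio strictly exceeds the threshold are rejected as
#' noise; at sampling rates where the cutoff is at or beyond Nyquist the
#' rule is inapplicable and \code{NA} is returned (callers must treat
#' this as "rule not evaluated", not as a pass of a computed ratio).
#'
#' @param window numeric samples; interior missing samples are linearly
#'   interpolated before the transform.
#' @param fs sampling rate, Hz.
#' @param cutoff cutoff frequency, Hz (default 30).
#' @return ratio in [0, 1], or NA if \code{fs <= 2 * cutoff}.
#' @export
hf_noise_ratio <- function(window, fs, cutoff = 30) {
  if (length(window) == 0) stop("empty window", call. = FALSE)
  if (fs <= 2 * cutoff) return(NA_real_)
  x <- interpolate_missing(window)
  if (all(is.na(x))) return(NA_real_)
  x <- x - mean(x)
  n <- length(x)
  mag <- Mod(fft(x))
  k <- seq_len(floor(n / 2))          # positive-frequency bins, DC excluded
  freq <- k * fs / n
  tot <- sum(mag[k + 1L])
  if (tot == 0) return(0)
  sum(mag[k + 1L][freq > cutoff]) / tot
}

# Linear interpolation over interior NA runs; leading/trailing NAs take
# the nearest finite value. All-NA input returned unchanged.
interpolate_missing <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- which(!is.na(x))
  if (length(ok) == 0) return(x)
  approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
}

#' Sharp-peak exclusion rule
#'
#' A segment's smoothed PPG is rejected as having an "extremely sharp
#' peak" when all three conditions hold on its peak heights:
#' max/median >= 4.5, IQR/median >= 2.15 and mean/median >= 1.3
#' (conjunction). Quartiles use the linear-interpolation convention
#' (\code{quantile} type 7). A non-positive median marks a degenerate
#' signal and rejects outright.
#'
#' @param heights peak heights of one segment (>= 3).
#' @param thresholds a \code{\link{quality_thresholds}}.
#' @return logical flag (TRUE = reject).
#' @export
sharp_peak_flag <- function(heights, thresholds = quality_thresholds()) {
  if (length(heights) < 3) stop("need >= 3 peak heights", call. = FALSE)
  med <- median(heights)
  if (!is.finite(med) || med <= 0) return(TRUE)
  (max(heights) / med >= thresholds$sharp_max_ratio) &&
    (IQR(heights) / med >= thresholds$sharp_iqr_ratio) &&
    (mean(heights) / med >= thresholds$sharp_mean_ratio)
}
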