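#' Smoothing-spline parameters
#'
#' The two conditioning stages are penalized cubic smoothing splines whose
#' penalties are tuned so the trace of the smoother matrix hits a target
#' effective degrees of freedom: a low-df fit (default 10 per 10-s window)
#' captures baseline wander and is subtracted, and a high-df fit (default
#' 100) is kept as the denoised signal. Windows are processed
#' non-overlapping with \code{edge_s} seconds of context fitted and
#' discarded on each side to suppress boundary artifacts.
#'
#' @param df_baseline effective df of the baseline-wander fit.
#' @param df_denoise effective df of the denoising fit.
#' @param window_s processing window length, seconds.
#' @param edge_s fitted-and-discarded context on each side, seconds.
#' @return An object of class \code{"spline_params"}.
#' @export
spline_params <- function(df_baseline = 10, df_denoise = 100,
                          window_s = 10, edge_s = 1) {
  stopifnot(df_baseline > 1, df_denoise > df_baseline,
            window_s > 0, edge_s >= 0)
  structure(list(df_baseline = df_baseline, df_denoise = df_denoise,
                 window_s = window_s, edge_s = edge_s),
            class = "spline_params")
}

# One spline fit at a target effective df, tolerant of missing samples.
# Returns fitted values at every index (NA where the input was missing).
fit_spline_df <- function(x, df) {
  idx <- seq_along(x)
  ok <- which(!is.na(x))
  out <- rep(NA_real_, length(x))
  if (length(ok) <= df + 2) return(out)  # cannot reach the target df
  nknots <- min(length(ok), as.integer(ceiling(2.5 * df)) + 6L)
  fit <- smooth.spline(idx[ok], x[ok], df = df, nknots = nknots,
                       cv = FALSE, keep.data = FALSE)
  out[ok] <- predict(fit, idx[ok])$y
  out
}

#' Remove baseline wander from a PPG window
#'
#' Subtracts a low-df smoothing-spline fit (effective degrees of freedom
#' \code{params$df_baseline}, tolerance about 0.5) from the window; the
#' residual retains the pulsatile content while slow wander is removed.
#' Missing samples stay missing.
#'
#' @param window numeric samples of one processing window (NA = missing).
#' @param params a \code{\link{spline_params}}.
#' @return detrended samples, same length.
#' @export
remove_baseline <- function(window, params = spline_params()) {
  stopifnot(inherits(params, "spline_params"))
  if (sum(!is.na(window)) <= params$df_baseline + 2)
    stop("window too short for baseline removal", call. = FALSE)
  window - fit_spline_df(window, params$df_baseline)
}

#' Denoise a detrended PPG window
#'
#' Returns the high-df smoothing-spline fit itself (effective degrees of
#' freedom \code{params$df_denoise}) as the conditioned signal; high
#' frequency noise lands in the discarded residual. The output variance
#' never exceeds the input variance.
#'
#' @inheritParams remove_baseline
#' @return smoothed samples, same length.
#' @export
denoise <- function(window, params = spline_params()) {
  stopifnot(inherits(params, "spline_params"))
  if (sum(!is.na(window)) <= params$df_denoise + 2)
    stop("window too short for denoising", call. = FALSE)
  fit_spline_df(window, params$df_denoise)
}

#' Condition a PPG record and assess per-window quality
#'
#' Splits the record into non-overlapping windows of
#' \code{params$window_s} seconds, evaluates the window-level quality
#' rules (saturation, missing fraction, high-frequency spectral ratio),
#' and runs baseline removal and denoising per window (with edge context
#' discarded). Windows too short to support the denoising df — in
#' practice only a trailing remainder — are flagged and left unprocessed.
#'
#' @param ppg a \code{"ppg_record"}.
#' @param params a \code{\link{spline_params}}.
#' @param thresholds a \code{\link{quality_thresholds}}.
#' @return A list of class \code{"processed_ppg"} with
#'   \describe{
#'     \item{samples}{conditioned signal (NA where missing or
#'       unprocessed)}
#'     \item{detrended}{baseline-removed signal before denoising (used
#'       for sub-sample peak-time refinement)}
#'     \item{fs}{sampling rate}
#'     \item{windows}{data frame: \code{start_s}, \code{end_s},
#'       \code{saturated}, \code{missing_frac}, \code{missing_exceeded},
#'       \code{hf_ratio}, \code{hf_applicable}, \code{hf_noise},
#'       \code{too_short}, \code{flagged}}
#'   }
#' @export
preprocess_ppg <- function(ppg, params = spline_params(),
                           thresholds = quality_thresholds()) {
  stopifnot(inherits(ppg, "ppg_record"))
  x <- ppg$samples
  n <- length(x)
  fs <- ppg$fs
  wlen <- round(params$window_s * fs)
  elen <- round(params$edge_s * fs)
  n_win <- ceiling(n / wlen)
  # a short trailing remainder (< half a window) merges into the last
  # full window instead of being fitted on its own
  if (n_win > 1 && n - (n_win - 1L) * wlen < wlen / 2) n_win <- n_win - 1L
  out <- rep(NA_real_, n)
  out_det <- rep(NA_real_, n)
  win <- data.frame(start_s = (seq_len(n_win) - 1L) * wlen / fs)
  win$end_s <- pmin(win$start_s + wlen / fs, n / fs)
  win$end_s[n_win] <- n / fs
  win$saturated <- FALSE
  win$missing_frac <- NA_real_
  win$missing_exceeded <- FALSE
  win$hf_ratio <- NA_real_
  win$hf_applicable <- fs > 2 * thresholds$hf_cutoff
  win$hf_noise <- FALSE
  win$too_short <- FALSE

  for (k in seq_len(n_win)) {
    i0 <- (k - 1L) * wlen + 1L
    i1 <- if (k == n_win) n else min(k * wlen, n)
    core <- x[i0:i1]
    win$saturated[k] <- check_saturation(core, ppg$saturation_value)
    win$missing_frac[k] <- missing_fraction(core)
    win$missing_exceeded[k] <- win$missing_frac[k] > thresholds$missing_max
    # fit with edge context, keep the core
    j0 <- max(1L, i0 - elen)
    j1 <- min(n, i1 + elen)
    ext <- x[j0:j1]
    if (sum(!is.na(ext)) <= params$df_denoise + 2) {
      win$too_short[k] <- TRUE
      next
    }
    det <- remove_baseline(ext, params)
    sm <- denoise(det, params)
    core_idx <- (i0 - j0 + 1L):(i0 - j0 + 1L + (i1 - i0))
    out[i0:i1] <- sm[core_idx]
    out_det[i0:i1] <- det[core_idx]
    if (win$hf_applicable[k]) {
      # evaluated on the detrended (pre-denoise) signal: after the
      # high-df smooth the noise this rule screens for is already gone
      r <- hf_noise_ratio(out_det[i0:i1], fs, thresholds$hf_cutoff)
      win$hf_ratio[k] <- r
      # strict ">" with an epsilon guard so a ratio of exactly 0.5 is
      # kept regardless of floating-point representation
      win$hf_noise[k] <- isTRUE(r > thresholds$hf_ratio_max + 1e-12)
    }
  }
  win$flagged <- win$saturated | win$missing_exceeded | win$hf_noise |
    win$too_short
  structure(list(samples = out, detrended = out_det, fs = fs,
                 windows = win),
            class = "processed_ppg")
}

#' @export
print.processed_ppg <- function(x, ...) {
  cat(sprintf("<processed_ppg %.1f s @ %g Hz, %d/%d window(s) flagged>\n",
              length(x$samples) / x$fs, x$fs, sum(x$windows$flagged),
              nrow(x$windows)))
  invisible(x)
}
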