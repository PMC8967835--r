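#' Detect pulse peaks on a conditioned PPG signal
#'
#' Local maxima of the conditioned signal, retained greedily in
#' decreasing-height order subject to a minimal pairwise spacing. The
#' spacing is specified in seconds (default 50 samples at the 512 Hz
#' development rate, ~0.098 s) and converted through \code{fs}, so
#' behaviour is rate-invariant. The signal may contain missing runs
#' (\code{NA}); detection runs independently on each contiguous finite
#' run. Because the conditioned signal is detrended (zero-mean wander),
#' candidate maxima must exceed \code{min_height} (default 0, the
#' detrended zero line), which suppresses ripple maxima in the
#' inter-pulse troughs.
#'
#' When \code{x} is a \code{"processed_ppg"}, each candidate peak is
#' refined to the local maximum of the baseline-removed (pre-denoise)
#' signal within half the minimal spacing — two-stage detection: the
#' heavily smoothed signal locates beats robustly, the detrended signal
#' restores the sharp peak apex that smoothing displaces.
#'
#' @param x conditioned samples (a \code{"processed_ppg"} or numeric
#'   vector).
#' @param fs sampling rate, Hz (taken from the record if \code{x} is a
#'   \code{"processed_ppg"}).
#' @param min_distance_s minimal peak spacing, seconds.
#' @param min_height minimal peak height, signal units.
#' @param min_height_frac candidates below this fraction of the median
#'   candidate height are discarded (suppresses residual smoothing
#'   ripple at signal edges; 0 disables). Must stay well below the
#'   relative amplitude of attenuated ectopic pulses (~0.5).
#' @return A \code{"beat_series"}: list with \code{peak_times} (s,
#'   strictly increasing), \code{peak_indices} (1-based sample index),
#'   \code{peak_heights}, \code{fs}.
#' @export
detect_peaks <- function(x, fs = NULL, min_distance_s = 50 / 512,
                         min_height = 0, min_height_frac = 0.2) {
  refine_on <- NULL
  if (inherits(x, "processed_ppg")) {
    fs <- x$fs
    refine_on <- x$detrended
    x <- x$samples
  }
  if (is.null(fs) || fs <= 0) stop("fs must be supplied and > 0", call. = FALSE)
  if (length(x) == 0) stop("empty signal", call. = FALSE)
  min_dist <- max(1L, round(min_distance_s * fs))

  # contiguous finite runs
  finite <- !is.na(x)
  runs <- rle(finite)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  idx_all <- integer(0)
  for (r in which(runs$values)) {
    seg <- x[starts[r]:ends[r]]
    if (length(seg) < 3) next
    pk <- pracma::findpeaks(seg, minpeakdistance = min_dist,
                            minpeakheight = min_height)
    if (is.null(pk)) next
    idx_all <- c(idx_all, starts[r] - 1L + pk[, 2])
  }
  idx_all <- sort(idx_all)
  if (min_height_frac > 0 && length(idx_all) > 0) {
    h <- x[idx_all]
    idx_all <- idx_all[h >= min_height_frac * median(h)]
  }
  if (!is.null(refine_on) && length(idx_all) > 0) {
    half <- max(1L, floor(min_dist / 2))
    n <- length(refine_on)
    idx_all <- vapply(idx_all, function(i) {
      j0 <- max(1L, i - half); j1 <- min(n, i + half)
      seg <- refine_on[j0:j1]
      if (all(is.na(seg))) return(as.integer(i))
      as.integer(j0 + which.max(seg) - 1L)
    }, integer(1))
    idx_all <- sort(unique(idx_all))
    x <- refine_on
  }
  times <- (idx_all - 1L) / fs
  if (!is.null(refine_on) && length(idx_all) > 0) {
    # sub-sample apex interpolation: the detrended pulse is band-limited
    # far below Nyquist even at 128 Hz, so a local spline through the
    # samples around the apex recovers the continuous-time peak position
    # nearly rate-independently
    half <- 3L
    delta <- vapply(idx_all, function(i) {
      j0 <- max(1L, i - half); j1 <- min(length(x), i + half)
      y <- x[j0:j1]
      if (anyNA(y) || length(y) < 4) return(0)
      fine <- seq(j0, j1, by = 1 / 64)
      yy <- stats::spline(j0:j1, y, xout = fine, method = "fmm")$y
      max(-1, min(1, fine[which.max(yy)] - i))
    }, numeric(1))
    times <- times + delta / fs
  }
  structure(list(peak_times = times,
                 peak_indices = idx_all,
                 peak_heights = x[idx_all],
                 fs = fs),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series: %d peaks @ %g Hz>\n",
              length(x$peak_times), x$fs))
  invisible(x)
}

#' Pulse-to-pulse intervals from a beat series
#'
#' Successive peak-time differences, with a validity mask: an interval is
#' invalid when shorter than \code{min_ppi_s} (default 60/200 s — a
#' heart rate above 200 beats/min is physiologically implausible and
#' indicates a detection artifact). Invalid intervals later discard
#' their whole containing segment rather than being deleted in place,
#' which would corrupt successive-difference statistics.
#'
#' @param beats a \code{"beat_series"} with >= 2 peaks.
#' @param min_ppi_s minimal valid interval, seconds.
#' @return data frame: \code{ppi_s}, \code{start_time_s} (time of the
#'   interval's opening peak), \code{valid}.
#' @export
to_ppis <- function(beats, min_ppi_s = 60 / 200) {
  stopifnot(inherits(beats, "beat_series"))
  if (length(beats$peak_times) < 2) stop("need >= 2 peaks", call. = FALSE)
  ppi <- diff(beats$peak_times)
  data.frame(ppi_s = ppi,
             start_time_s = beats$peak_times[-length(beats$peak_times)],
             valid = ppi >= min_ppi_s)
}

#' Split pulse intervals into labeled N-beat segments
#'
#' Consecutive, non-overlapping blocks of \code{n_beats} intervals; the
#' trailing remainder is discarded. Each segment must be fully contained
#' in a single annotation interval (half-open \code{[start_s, end_s)});
#' segments straddling a rhythm boundary or not covered by any
#' annotation are discarded. Segments are further discarded when they
#' contain an invalid interval, overlap a flagged PPG quality window or a
#' flagged 1-s motion window, or trip the sharp-peak rule on their peak
#' heights. Every discarded segment carries its reason codes.
#'
#' @param beats a \code{"beat_series"}.
#' @param annotations data frame \code{start_s}, \code{end_s},
#'   \code{label}.
#' @param n_beats intervals per segment (N; 10, 25, 40 or 80 in the
#'   study design, any value >= 2 accepted).
#' @param patient_id identifier attached to every segment.
#' @param quality optional \code{windows} data frame of
#'   \code{\link{preprocess_ppg}}.
#' @param motion optional data frame of \code{\link{motion_flags}}.
#' @param thresholds a \code{\link{quality_thresholds}}.
#' @return A \code{"ppi_segments"} object: list with \code{segments}
#'   (list of kept segments, each with \code{ppis}, \code{heights},
#'   \code{start_time}, \code{end_time}, \code{label}, \code{patient_id},
#'   \code{n_beats}) and \code{log} (one row per candidate segment:
#'   \code{start_s}, \code{end_s}, \code{label}, \code{kept},
#'   \code{reason}).
#' @export
segment_ppis <- function(beats, annotations, n_beats = 25,
                         patient_id = "P000", quality = NULL, motion = NULL,
                         thresholds = quality_thresholds()) {
  stopifnot(inherits(beats, "beat_series"), n_beats >= 2)
  if (is.null(annotations) || nrow(annotations) == 0)
    stop("no annotations", call. = FALSE)
  ppis <- to_ppis(beats, thresholds$min_ppi_s)
  n <- nrow(ppis)
  n_seg <- n %/% n_beats
  segments <- list()
  log <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    label = character(0), kept = logical(0),
                    reason = character(0))
  if (n_seg >= 1) {
    for (s in seq_len(n_seg)) {
      i0 <- (s - 1L) * n_beats + 1L
      i1 <- s * n_beats
      seg_ppis <- ppis$ppi_s[i0:i1]
      t_start <- beats$peak_times[i0]
      t_end <- beats$peak_times[i1 + 1L]
      heights <- beats$peak_heights[i0:(i1 + 1L)]
      covering <- which(annotations$start_s <= t_start &
                          annotations$end_s >= t_end)
      reasons <- character(0)
      label <- NA_character_
      if (length(covering) == 0) {
        straddles <- any(annotations$start_s < t_end &
                           annotations$end_s > t_start)
        reasons <- c(reasons, if (straddles) "mixed-label" else "unannotated")
      } else {
        label <- annotations$label[covering[1]]
      }
      if (any(seg_ppis < thresholds$min_ppi_s))
        reasons <- c(reasons, "invalid-ppi")
      if (!is.null(quality)) {
        ovl <- quality$flagged & quality$start_s < t_end &
          quality$end_s > t_start
        if (any(ovl)) reasons <- c(reasons, "quality-window")
      }
      if (!is.null(motion)) {
        ovl <- motion$flag & motion$start_s < t_end & motion$end_s > t_start
        if (any(ovl)) reasons <- c(reasons, "motion")
      }
      if (sharp_peak_flag(heights, thresholds))
        reasons <- c(reasons, "sharp-peak")
      kept <- length(reasons) == 0
      log <- rbind(log, data.frame(start_s = t_start, end_s = t_end,
                                   label = label, kept = kept,
                                   reason = paste(reasons, collapse = ";")))
      if (kept) {
        segments[[length(segments) + 1L]] <-
          list(patient_id = patient_id, n_beats = as.integer(n_beats),
               ppis = seg_ppis, heights = heights,
               start_time = t_start, end_time = t_end, label = label)
      }
    }
  }
  n_rem <- n - n_seg * n_beats
  if (n_rem > 0) {
    log <- rbind(log, data.frame(
      start_s = beats$peak_times[n_seg * n_beats + 1L],
      end_s = beats$peak_times[n + 1L],
      label = NA_character_, kept = FALSE, reason = "remainder"))
  }
  structure(list(segments = segments, log = log,
                 n_ppis_total = n,
                 n_ppis_remainder = n_rem),
            class = "ppi_segments")
}

#' @export
print.ppi_segments <- function(x, ...) {
  cat(sprintf("<ppi_segments: %d kept / %d candidate segment(s)>\n",
              length(x$segments), nrow(x$log)))
  invisible(x)
}
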