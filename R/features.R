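# Per-segment feature panel. All interval features are heart-rate-robust:
# they depend on the spread/shape of the PPI distribution, not its mean.

#' Standard deviation of the pulse intervals
#'
#' Sample standard deviation (n-1 denominator) of the N intervals of one
#' segment, seconds.
#'
#' @param ppis interval vector, N >= 2.
#' @return numeric, seconds.
#' @export
ppi_sd <- function(ppis) {
  if (length(ppis) < 2) stop("need >= 2 intervals", call. = FALSE)
  sd(ppis)
}

#' Root mean squared successive differences of the pulse intervals
#'
#' @param ppis interval vector, N >= 3.
#' @return numeric, seconds.
#' @export
ppi_rmssd <- function(ppis) {
  if (length(ppis) < 3) stop("need >= 3 intervals", call. = FALSE)
  rmssd(ppis)
}

#' Shannon entropy of the interval histogram
#'
#' \eqn{-\sum_b P_b \log P_b} (natural log) over \code{bins} equal-width
#' bins spanning the segment's own interval range; \eqn{P_b} is the
#' fraction of intervals in bin b, and empty bins contribute zero. With
#' all intervals equal there is a single occupied bin and the entropy is
#' 0 by convention. Because the bin grid follows the per-segment range,
#' the entropy is invariant to rescaling all intervals (heart-rate
#' robustness).
#'
#' @param ppis interval vector, N >= 2.
#' @param bins number of histogram bins (10, 100 and 1000 in the feature
#'   panel).
#' @return entropy in nats, >= 0.
#' @export
shannon_entropy <- function(ppis, bins) {
  if (length(ppis) < 2) stop("need >= 2 intervals", call. = FALSE)
  stopifnot(bins >= 1)
  rng <- range(ppis)
  if (rng[1] == rng[2]) return(0)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  cnt <- tabulate(pmin(bins, findInterval(ppis, edges, left.open = FALSE)),
                  nbins = bins)
  p <- cnt / length(ppis)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Dominant spectral frequency of the conditioned PPG segment
#'
#' Frequency (Hz) of the maximal FFT magnitude of the detrended PPG
#' samples over the segment's time span, searched in the physiological
#' band [0.5, 3.5] Hz (30-210 beats/min), DC excluded. This is an
#' estimate of the mean heart rate over the segment and is therefore not
#' itself heart-rate-robust; it enters the model only through its
#' three-segment rolling SD.
#'
#' @param segment_ppg conditioned samples covering the segment (NA
#'   tolerated, interpolated).
#' @param fs sampling rate, Hz.
#' @param band search band, Hz.
#' @return list with \code{freq} (Hz) and \code{low_confidence} (TRUE
#'   when the in-band maximum does not dominate the out-of-band
#'   spectrum, e.g. for noise-only input).
#' @export
max_fft <- function(segment_ppg, fs, band = c(0.5, 3.5)) {
  n <- length(segment_ppg)
  if (n < 4) stop("segment window too short", call. = FALSE)
  x <- interpolate_missing(segment_ppg)
  x <- x - mean(x)
  mag <- Mod(fft(x))
  k <- seq_len(floor(n / 2))
  freq <- k * fs / n
  magp <- mag[k + 1L]
  in_band <- freq >= band[1] & freq <= band[2]
  if (!any(in_band)) stop("window shorter than the search band resolution",
                          call. = FALSE)
  i <- which.max(ifelse(in_band, magp, -Inf))
  # a genuine cardiac line towers over the spectral floor; the maximum of
  # a flat (noise-only) magnitude spectrum stays within a few multiples
  # of its median
  list(freq = freq[i],
       low_confidence = magp[i] < 5 * stats::median(magp))
}

#' Rolling three-segment statistics
#'
#' For a segment and its two closest subsequent segments (same patient,
#' same contiguous rhythm block): SD3 = mean of the three per-segment
#' SDs; RMSSD3 = sample SD of the three RMSSDs; MaxFFTSD3 = sample SD of
#' the three dominant frequencies. Aggregating three short segments
#' keeps the recording time short while stabilising the estimates.
#'
#' @param sds,rmssds,maxffts numeric vectors of length 3 (current segment
#'   first).
#' @return named list \code{sd3}, \code{rmssd3}, \code{maxfftsd3}.
#' @export
rolling_features <- function(sds, rmssds, maxffts) {
  stopifnot(length(sds) == 3, length(rmssds) == 3, length(maxffts) == 3)
  list(sd3 = mean(sds), rmssd3 = sd(rmssds), maxfftsd3 = sd(maxffts))
}

#' Pulse-morphology features from peak heights
#'
#' Peak heights are first divided by their segment median (the quality
#' rules are median-ratio based and this makes the features invariant to
#' the optical gain), then SD, RMSSD and IQR are computed
#' (linear-interpolation quartiles).
#'
#' @param heights peak heights of one segment (>= 3, positive median).
#' @param normalize divide by the median first (default TRUE).
#' @return named list \code{ph_sd}, \code{ph_rmssd}, \code{ph_iqr}.
#' @export
peak_height_features <- function(heights, normalize = TRUE) {
  if (length(heights) < 3) stop("need >= 3 heights", call. = FALSE)
  med <- median(heights)
  if (normalize) {
    if (!is.finite(med) || med <= 0) stop("non-positive height median",
                                          call. = FALSE)
    heights <- heights / med
  }
  list(ph_sd = sd(heights), ph_rmssd = rmssd(heights),
       ph_iqr = IQR(heights))
}

# Biased (divide-by-N) normalized autocovariance at lags 1..lag_max.
# Zero-variance input returns zeros by convention.
acf_values <- function(x, lag_max) {
  n <- length(x)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) return(rep(0, lag_max))
  vapply(seq_len(lag_max), function(k) {
    sum(xc[1:(n - k)] * xc[(k + 1):n]) / denom
  }, numeric(1))
}

#' Autocorrelation features of the peak heights
#'
#' Normalized autocorrelation of the segment's peak heights at lags
#' 1..floor(N/2); the features are the SD, RMSSD and IQR of that ACF
#' sequence and the SD of its first differences (Diff SD). In sinus
#' rhythm consecutive pulse amplitudes are strongly correlated and the
#' ACF sequence decays smoothly; in AF it collapses toward zero.
#' Zero-variance heights give all-zero features by convention.
#'
#' @param heights peak heights (>= 4).
#' @return named list \code{acf_sd}, \code{acf_rmssd}, \code{acf_iqr},
#'   \code{acf_diffsd}.
#' @export
acf_height_features <- function(heights) {
  if (length(heights) < 4) stop("need >= 4 heights", call. = FALSE)
  a <- acf_values(heights, max(2L, length(heights) %/% 2L))
  if (all(a == 0))
    return(list(acf_sd = 0, acf_rmssd = 0, acf_iqr = 0, acf_diffsd = 0))
  list(acf_sd = sd(a), acf_rmssd = rmssd(a), acf_iqr = IQR(a),
       acf_diffsd = sd(diff(a)))
}

#' Ectopy-oriented interval features
#'
#' Aimed at "regularly abnormal" rhythms (bigeminy and other premature
#' complexes) that mimic AF in plain variability:
#' \describe{
#'   \item{lag1_acf, lag2_acf}{normalized autocorrelation of the interval
#'     sequence at lags 1 and 2 (0 for zero-variance segments). Strict
#'     short-long alternation gives lag-1 near -1 and lag-2 near +1,
#'     whereas AF intervals are serially uncorrelated.}
#'   \item{dip_p}{p-value of Hartigan's dip test of unimodality: the
#'     bigeminy interval distribution is bimodal (small p), AF and SR
#'     unimodal.}
#'   \item{even_sd, odd_sd}{sample SD of the even-/odd-position intervals
#'     (1-based): near zero under strict alternation despite a large
#'     overall SD.}
#' }
#'
#' @param ppis interval vector (N >= 6).
#' @return named list \code{lag1_acf}, \code{lag2_acf}, \code{dip_p},
#'   \code{even_sd}, \code{odd_sd}.
#' @export
extended_features <- function(ppis) {
  if (length(ppis) < 6) stop("need >= 6 intervals", call. = FALSE)
  a <- acf_values(ppis, 2L)
  idx <- seq_along(ppis)
  list(lag1_acf = a[1], lag2_acf = a[2],
       dip_p = dip_test(ppis)$p_value,
       even_sd = sd(ppis[idx %% 2 == 0]),
       odd_sd = sd(ppis[idx %% 2 == 1]))
}

# Canonical feature column sets.
base8_features <- function() c("ppi_sd", "ppi_rmssd", "se10", "se100",
                               "se1000", "sd3", "rmssd3", "maxfftsd3")
morph_features <- function() c("ph_sd", "ph_rmssd", "ph_iqr", "acf_sd",
                               "acf_rmssd", "acf_iqr", "acf_diffsd")
ext_features <- function() c("lag1_acf", "lag2_acf", "dip_p", "even_sd",
                             "odd_sd")

#' Feature columns of a named feature set
#'
#' @param feature_set \code{"base8"} (the 8 model features),
#'   \code{"base8+extended"} (plus the 5 ectopy features) or \code{"all"}
#'   (8 + MaxFFT + 7 morphological + 5 extended = 21).
#' @return character vector of column names.
#' @export
feature_columns <- function(feature_set = c("base8", "base8+extended",
                                            "all")) {
  feature_set <- match.arg(feature_set)
  switch(feature_set,
         base8 = base8_features(),
         `base8+extended` = c(base8_features(), ext_features()),
         all = c(base8_features(), "maxfft", morph_features(),
                 ext_features()))
}

#' Build the per-segment feature table
#'
#' One row per segment that has two subsequent same-patient, same-rhythm
#' block neighbours (required by the rolling features; the trailing two
#' segments of every block are dropped from model input). MaxFFT is
#' always computed — it feeds MaxFFTSD3 — but is only exposed as a
#' column in the \code{"all"} set, mirroring its exclusion by feature
#' selection.
#'
#' @param segs a \code{"ppi_segments"} object (or list of segment lists).
#' @param processed the \code{"processed_ppg"} the segments came from
#'   (needed for MaxFFT); may be NULL, in which case MaxFFT and
#'   MaxFFTSD3 are computed from the interval sequence's reciprocal mean
#'   rate — only appropriate for interval-only simulations.
#' @param feature_set see \code{\link{feature_columns}}.
#' @return data frame: \code{patient_id}, \code{start_time},
#'   \code{label}, feature columns.
#' @export
build_feature_table <- function(segs, processed = NULL,
                                feature_set = c("base8", "base8+extended",
                                                "all")) {
  feature_set <- match.arg(feature_set)
  segments <- if (inherits(segs, "ppi_segments")) segs$segments else segs
  if (length(segments) == 0) stop("empty segment list", call. = FALSE)
  per <- lapply(segments, function(s) {
    ent <- vapply(c(10, 100, 1000), function(b) shannon_entropy(s$ppis, b),
                  numeric(1))
    mf <- if (!is.null(processed)) {
      i0 <- max(1L, floor(s$start_time * processed$fs) + 1L)
      i1 <- min(length(processed$samples),
                ceiling(s$end_time * processed$fs) + 1L)
      max_fft(processed$samples[i0:i1], processed$fs)$freq
    } else 1 / mean(s$ppis)
    ph <- peak_height_features(s$heights)
    ac <- acf_height_features(s$heights)
    ex <- extended_features(s$ppis)
    c(list(patient_id = s$patient_id, start_time = s$start_time,
           label = s$label,
           ppi_sd = ppi_sd(s$ppis), ppi_rmssd = ppi_rmssd(s$ppis),
           se10 = ent[1], se100 = ent[2], se1000 = ent[3],
           maxfft = mf), ph, ac, ex)
  })
  df <- do.call(rbind, lapply(per, function(p) as.data.frame(p)))
  # rolling features within (patient, contiguous block): segments are
  # in temporal order per patient; block identity = label runs.
  df <- df[order(df$patient_id, df$start_time), , drop = FALSE]
  df$block <- NA_character_
  for (pid in unique(df$patient_id)) {
    i <- which(df$patient_id == pid)
    runs <- cumsum(c(1L, as.integer(df$label[i][-1] !=
                                      df$label[i][-length(i)])))
    df$block[i] <- paste(pid, runs)
  }
  df$sd3 <- NA_real_; df$rmssd3 <- NA_real_; df$maxfftsd3 <- NA_real_
  for (b in unique(df$block)) {
    rows <- which(df$block == b)
    if (length(rows) < 3) next
    for (j in seq_len(length(rows) - 2L)) {
      i <- rows[j]; trio <- rows[j:(j + 2L)]
      rf <- rolling_features(df$ppi_sd[trio], df$ppi_rmssd[trio],
                             df$maxfft[trio])
      df$sd3[i] <- rf$sd3; df$rmssd3[i] <- rf$rmssd3
      df$maxfftsd3[i] <- rf$maxfftsd3
    }
  }
  df <- df[!is.na(df$sd3), , drop = FALSE]
  keep <- c("patient_id", "start_time", "label", feature_columns(feature_set))
  rownames(df) <- NULL
  df[, keep, drop = FALSE]
}
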