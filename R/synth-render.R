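#' Render a PPG waveform from an interval sequence
#'
#' Places one pulse template per beat at the cumulative beat times implied
#' by \code{rr}, scales each by its amplitude factor, and adds the artifact
#' layers of \code{noise}: sinusoidal baseline wander, white noise, motion
#' corruption, clipping at the saturation ceiling, and sample dropouts
#' (missing samples, \code{NA}).
#'
#' The pulse template is an asymmetric Gaussian (fast upstroke, slow decay)
#' plus a small, delayed dicrotic bump, with all widths scaled to
#' \code{min(rr)/2} so consecutive pulses stay resolved at high heart
#' rates. The waveform maximum of a clean pulse coincides with the beat
#' time.
#'
#' @param rr interval sequence (seconds), e.g. from
#'   \code{\link{gen_rr_sequence}}; \code{n} intervals imply \code{n + 1}
#'   beats.
#' @param fs sampling rate, Hz (512 native, 128 for the reduced-rate
#'   configuration; any positive value accepted).
#' @param noise a \code{\link{noise_spec}}.
#' @param amp_factors per-beat pulse amplitude factors (length
#'   \code{length(rr) + 1}); defaults to the \code{amp_factors} attribute
#'   of \code{rr}, else all 1.
#' @param amp_rr_coupling strength of the pulse-amplitude dependence on
#'   the preceding interval (longer diastolic filling gives a larger
#'   pulse — the pulse-deficit physiology that makes AF pulse amplitudes
#'   variable). The per-beat factor is
#'   \code{1 + amp_rr_coupling * (rr_prev - mean(rr)) / mean(rr)},
#'   clamped to [0.4, 1.6]; 0 disables.
#' @param pulse_amp nominal pulse amplitude, signal units.
#' @param pad_s quiet padding before the first and after the last beat, s.
#' @param seed integer seed for the noise layers.
#' @return A \code{"ppg_record"}: list with \code{samples} (NA = missing),
#'   \code{fs}, \code{saturation_value}, \code{start_time} and
#'   \code{truth_beats} (exact beat times, seconds).
#' @examples
#' rr <- gen_rr_sequence(rhythm_spec("SR"), 10, seed = 1)
#' rec <- render_ppg(rr, fs = 128,
#'                   noise = noise_spec(baseline_amp = 0, white_sd = 0,
#'                                      dropout_fraction = 0))
#' @export
render_ppg <- function(rr, fs = 512, noise = noise_spec(),
                       amp_factors = NULL, amp_rr_coupling = 0.4,
                       pulse_amp = 1, pad_s = 1, seed = 1L) {
  if (length(rr) < 1L || any(rr <= 0)) stop("rr must be positive and non-empty",
                                            call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0", call. = FALSE)
  stopifnot(inherits(noise, "noise_spec"))
  amp_factors <- amp_factors %||% attr(rr, "amp_factors") %||%
    rep(1, length(rr) + 1L)
  stopifnot(length(amp_factors) == length(rr) + 1L)
  if (amp_rr_coupling > 0) {
    prev_rr <- c(rr[1], rr)              # first beat: no preceding interval
    fill <- 1 + amp_rr_coupling * (prev_rr - mean(rr)) / mean(rr)
    amp_factors <- amp_factors * pmin(1.6, pmax(0.4, fill))
  }

  beat_times <- pad_s + cumsum(c(0, as.numeric(rr)))
  duration <- beat_times[length(beat_times)] + pad_s
  n <- floor(duration * fs) + 1L
  t <- (seq_len(n) - 1L) / fs

  w <- min(rr) / 2                       # template width scale, s
  # mild upstroke/decay asymmetry: strong asymmetry would bias the
  # post-smoothing argmax away from the true beat time
  sig_up <- 0.13 * w; sig_dn <- 0.16 * w
  dic_amp <- 0.12; dic_mu <- 0.35 * w; dic_sd <- 0.12 * w
  span <- 4 * sig_dn + dic_mu + 3 * dic_sd

  x <- numeric(n)
  for (b in seq_along(beat_times)) {
    tb <- beat_times[b]
    i0 <- max(1L, floor((tb - 4 * sig_up) * fs) + 1L)
    i1 <- min(n, ceiling((tb + span) * fs) + 1L)
    idx <- i0:i1
    dt <- t[idx] - tb
    pulse <- ifelse(dt < 0, exp(-dt^2 / (2 * sig_up^2)),
                    exp(-dt^2 / (2 * sig_dn^2))) +
      dic_amp * exp(-(dt - dic_mu)^2 / (2 * dic_sd^2))
    x[idx] <- x[idx] + pulse_amp * amp_factors[b] * pulse
  }

  x <- with_seed(seed, {
    phase <- runif(1, 0, 2 * pi)
    y <- x + noise$baseline_amp * sin(2 * pi * noise$baseline_freq * t + phase)
    if (noise$white_sd > 0) y <- y + rnorm(n, 0, noise$white_sd)
    ep <- noise$motion_episodes
    if (nrow(ep) > 0) {
      for (k in seq_len(nrow(ep))) {
        in_ep <- t >= ep$start_s[k] & t < ep$start_s[k] + ep$duration_s[k]
        if (any(in_ep) && ep$ppg_sd[k] > 0)
          y[in_ep] <- y[in_ep] + rnorm(sum(in_ep), 0, ep$ppg_sd[k])
      }
    }
    y <- pmin(y, noise$saturation_value)
    if (noise$dropout_fraction > 0) {
      drop <- runif(n) < noise$dropout_fraction
      y[drop] <- NA_real_
    }
    y
  })

  structure(list(samples = x, fs = fs,
                 saturation_value = noise$saturation_value,
                 start_time = 0, truth_beats = beat_times),
            class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record %.1f s @ %g Hz, %d beats, %.2f%% missing>\n",
              length(x$samples) / x$fs, x$fs,
              length(x$truth_beats),
              100 * mean(is.na(x$samples))))
  invisible(x)
}

#' Render a triaxial accelerometer recording
#'
#' Gravity-offset baseline per axis plus Gaussian noise at
#' \code{quiet_sd}; inside each motion episode the per-axis sd is raised
#' to the episode's \code{acc_sd}. Units follow the device's arbitrary
#' calibration (the motion-score threshold of
#' \code{\link{quality_thresholds}} is expressed in the same units).
#'
#' @param duration_s recording length, seconds (> 0).
#' @param fs sampling rate, Hz (device default 100).
#' @param motion_episodes data frame with \code{start_s},
#'   \code{duration_s}, \code{acc_sd} (extra columns ignored), or NULL.
#' @param quiet_sd per-axis sd outside episodes.
#' @param seed integer seed.
#' @return An \code{"acc_record"}: list with \code{ax}, \code{ay},
#'   \code{az}, \code{fs}.
#' @export
render_acc <- function(duration_s, fs = 100, motion_episodes = NULL,
                       quiet_sd = 1, seed = 1L) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be > 0", call. = FALSE)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  g <- c(0, 0, 9.81)
  with_seed(seed, {
    axes <- lapply(1:3, function(a) {
      y <- g[a] + rnorm(n, 0, quiet_sd)
      if (!is.null(motion_episodes) && nrow(motion_episodes) > 0) {
        for (k in seq_len(nrow(motion_episodes))) {
          in_ep <- t >= motion_episodes$start_s[k] &
            t < motion_episodes$start_s[k] + motion_episodes$duration_s[k]
          if (any(in_ep))
            y[in_ep] <- g[a] + rnorm(sum(in_ep), 0, motion_episodes$acc_sd[k])
        }
      }
      y
    })
    structure(list(ax = axes[[1]], ay = axes[[2]], az = axes[[3]], fs = fs),
              class = "acc_record")
  })
}

#' @export
print.acc_record <- function(x, ...) {
  cat(sprintf("<acc_record %.1f s @ %g Hz>\n", length(x$ax) / x$fs, x$fs))
  invisible(x)
}
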