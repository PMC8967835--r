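#' Rhythm specification for the interval simulator
#'
#' Describes the statistical structure of one cardiac rhythm for
#' \code{\link{gen_rr_sequence}}. Four rhythm kinds are modelled:
#' \describe{
#'   \item{SR}{sinus rhythm: base interval 60/\code{mean_rate} s with a
#'     sinusoidal respiratory modulation (\code{rsa_amp}, \code{rsa_freq})
#'     and i.i.d. Gaussian jitter (\code{jitter_sd}).}
#'   \item{AF}{atrial fibrillation: irregularly-irregular, i.i.d. intervals
#'     from a Gaussian with sd \code{af_sd}, truncated below at 0.25 s.}
#'   \item{PVC_BIGEMINY}{ventricular ectopy: a fraction
#'     \code{ectopy_burden} of beats are premature ventricular complexes,
#'     each replacing two normal intervals by a fixed
#'     (\code{coupling}, \code{compensatory_pause}) pair; the ectopic pulse
#'     amplitude is attenuated by \code{pvc_amp_factor} (pulse deficit).
#'     At burden 0.5 this is strict bigeminy: short-long alternation.}
#'   \item{PAC}{atrial ectopy: each beat is premature with probability
#'     \code{ectopy_burden}; a premature interval is the normal interval
#'     scaled by U(0.4, 0.7) and is followed by a partial (non-fully
#'     compensatory) pause returning half of the advanced time.}
#' }
#'
#' @param kind one of \code{"SR"}, \code{"AF"}, \code{"PVC_BIGEMINY"},
#'   \code{"PAC"}.
#' @param mean_rate mean heart rate, beats/min, in [30, 200].
#' @param jitter_sd sd of Gaussian interval jitter, seconds (SR and the
#'   sinus background of ectopic rhythms).
#' @param rsa_amp,rsa_freq amplitude (s) and frequency (Hz) of respiratory
#'   sinus arrhythmia modulation (SR).
#' @param af_sd sd of the AF interval distribution, seconds.
#' @param coupling,compensatory_pause PVC coupling interval and
#'   post-ectopic pause, seconds.
#' @param ectopy_burden fraction of beats that are ectopic, in [0, 0.5].
#' @param pvc_amp_factor multiplicative pulse-amplitude attenuation of
#'   ectopic beats, in (0, 1].
#' @param background_ectopy fraction of sporadic premature beats in SR
#'   (the AF-clinic population is rarely free of isolated premature
#'   complexes; occasional short-long interval pairs also reproduce the
#'   outlier-driven drop in sinus-rhythm interval entropy seen in real
#'   recordings).
#' @return An object of class \code{"rhythm_spec"}.
#' @examples
#' rhythm_spec("AF", mean_rate = 90, af_sd = 0.2)
#' @export
rhythm_spec <- function(kind = c("SR", "AF", "PVC_BIGEMINY", "PAC"),
                        mean_rate = 75,
                        jitter_sd = 0.02,
                        rsa_amp = 0.02, rsa_freq = 0.25,
                        af_sd = 0.2,
                        coupling = 0.6, compensatory_pause = 1.2,
                        ectopy_burden = 0.5,
                        pvc_amp_factor = 0.5,
                        background_ectopy = 0.02) {
  kind <- match.arg(kind)
  stop_if_not_scalar_number(mean_rate, "mean_rate", 30, 200)
  stop_if_not_scalar_number(jitter_sd, "jitter_sd", 0)
  stop_if_not_scalar_number(rsa_amp, "rsa_amp", 0)
  stop_if_not_scalar_number(rsa_freq, "rsa_freq", 0)
  stop_if_not_scalar_number(af_sd, "af_sd", 0)
  stop_if_not_scalar_number(coupling, "coupling", 1e-9)
  stop_if_not_scalar_number(compensatory_pause, "compensatory_pause", 1e-9)
  stop_if_not_scalar_number(ectopy_burden, "ectopy_burden", 0, 0.5)
  stop_if_not_scalar_number(pvc_amp_factor, "pvc_amp_factor", 1e-9, 1)
  stop_if_not_scalar_number(background_ectopy, "background_ectopy", 0, 0.5)
  structure(list(kind = kind, mean_rate = mean_rate, jitter_sd = jitter_sd,
                 rsa_amp = rsa_amp, rsa_freq = rsa_freq, af_sd = af_sd,
                 coupling = coupling, compensatory_pause = compensatory_pause,
                 ectopy_burden = ectopy_burden,
                 pvc_amp_factor = pvc_amp_factor,
                 background_ectopy = background_ectopy),
            class = "rhythm_spec")
}

#' @export
print.rhythm_spec <- function(x, ...) {
  cat(sprintf("<rhythm_spec %s, %.0f bpm>\n", x$kind, x$mean_rate))
  invisible(x)
}

#' Noise and artifact specification for the PPG renderer
#'
#' Controls the artifact plumbing of \code{\link{render_ppg}} and
#' \code{\link{render_acc}}: sinusoidal baseline wander, additive white
#' noise, motion episodes (corrupting the PPG and raising accelerometer
#' variance simultaneously), amplitude clipping at a saturation ceiling,
#' and random sample dropouts (missing samples, stored as \code{NA}).
#'
#' @param baseline_amp,baseline_freq baseline wander amplitude (signal
#'   units) and frequency (Hz).
#' @param white_sd sd of additive white noise, signal units.
#' @param motion_episodes data frame with columns \code{start_s},
#'   \code{duration_s}, \code{acc_sd}, \code{ppg_sd}: episodes of wrist
#'   motion. \code{acc_sd} is the per-axis accelerometer sd inside the
#'   episode; \code{ppg_sd} the sd of the PPG corruption added.
#' @param saturation_value clipping ceiling, signal units.
#' @param dropout_fraction fraction of samples replaced by the missing
#'   sentinel, in [0, 1).
#' @return An object of class \code{"noise_spec"}.
#' @export
noise_spec <- function(baseline_amp = 0.3, baseline_freq = 0.2,
                       white_sd = 0.02,
                       motion_episodes = NULL,
                       saturation_value = 2.5,
                       dropout_fraction = 0.005) {
  stop_if_not_scalar_number(baseline_amp, "baseline_amp", 0)
  stop_if_not_scalar_number(baseline_freq, "baseline_freq", 0)
  stop_if_not_scalar_number(white_sd, "white_sd", 0)
  stop_if_not_scalar_number(saturation_value, "saturation_value", 0)
  stop_if_not_scalar_number(dropout_fraction, "dropout_fraction", 0, 1 - 1e-12)
  if (is.null(motion_episodes)) {
    motion_episodes <- data.frame(start_s = numeric(0), duration_s = numeric(0),
                                  acc_sd = numeric(0), ppg_sd = numeric(0))
  }
  stopifnot(is.data.frame(motion_episodes),
            all(c("start_s", "duration_s", "acc_sd", "ppg_sd") %in%
                  names(motion_episodes)))
  structure(list(baseline_amp = baseline_amp, baseline_freq = baseline_freq,
                 white_sd = white_sd, motion_episodes = motion_episodes,
                 saturation_value = saturation_value,
                 dropout_fraction = dropout_fraction),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf(
    "<noise_spec baseline %.2f@%.2fHz, white sd %.3f, %d motion episode(s), sat %.2f, dropout %.3f>\n",
    x$baseline_amp, x$baseline_freq, x$white_sd, nrow(x$motion_episodes),
    x$saturation_value, x$dropout_fraction))
  invisible(x)
}

#' Generate a pulse-to-pulse (RR-like) interval sequence
#'
#' Draws \code{n_beats} consecutive inter-beat intervals under the rhythm
#' model in \code{spec}. The ectopic rhythms additionally record which
#' beats are ectopic and the per-beat pulse-amplitude factors used by
#' \code{\link{render_ppg}}; a sequence of \code{n_beats} intervals implies
#' \code{n_beats + 1} beats.
#'
#' @param spec a \code{\link{rhythm_spec}}.
#' @param n_beats number of intervals to generate (>= 2).
#' @param seed integer seed; identical (spec, n_beats, seed) give identical
#'   output.
#' @return Numeric vector of intervals (seconds) with attributes
#'   \code{amp_factors} (length \code{n_beats + 1}) and \code{ectopic}
#'   (logical, per beat).
#' @examples
#' rr <- gen_rr_sequence(rhythm_spec("SR", mean_rate = 60, jitter_sd = 0,
#'                                   rsa_amp = 0, background_ectopy = 0),
#'                       10, seed = 1)
#' stopifnot(all(rr == 1))
#' @export
gen_rr_sequence <- function(spec, n_beats, seed = 1L) {
  stopifnot(inherits(spec, "rhythm_spec"))
  if (!is.numeric(n_beats) || length(n_beats) != 1L || n_beats < 2)
    stop("n_beats must be >= 2", call. = FALSE)
  n <- as.integer(n_beats)
  base <- 60 / spec$mean_rate
  with_seed(seed, {
    rr <- switch(spec$kind,
      SR = {
        t_prev <- cumsum(c(0, rep(base, n - 1L)))  # nominal beat times
        rr0 <- base + spec$rsa_amp * sin(2 * pi * spec$rsa_freq * t_prev) +
          rnorm(n, 0, spec$jitter_sd)
        if (spec$background_ectopy > 0)
          insert_premature(rr0, spec$background_ectopy)
        else rr0
      },
      AF = rtruncnorm_low(n, mean = base, sd = spec$af_sd, lower = 0.25),
      PVC_BIGEMINY = rr_bigeminy(spec, n, base),
      PAC = rr_pac(spec, n, base),
      stop("unknown rhythm kind", call. = FALSE))
    rr <- pmax(rr, 0.2)  # physiological floor for non-AF jitter tails
    if (is.null(attr(rr, "amp_factors"))) {
      attr(rr, "amp_factors") <- rep(1, n + 1L)
      attr(rr, "ectopic") <- rep(FALSE, n + 1L)
    }
    rr
  })
}

# Truncated-below Gaussian sampler via inverse-CDF (exact, vectorized).
rtruncnorm_low <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(pmax(mean, lower), n))
  p_lo <- pnorm(lower, mean, sd)
  qnorm(p_lo + runif(n) * (1 - p_lo), mean, sd)
}

# Bigeminy / interpolated PVCs: each ectopic event replaces two normal
# intervals with a fixed (coupling, compensatory pause) pair. Burden 0.5
# gives strict alternation; sub-maximal burdens place events at random
# non-adjacent positions (runs of bigeminy interrupted by sinus runs, as
# in real recordings).
rr_bigeminy <- function(spec, n, base) {
  rr <- base + rnorm(n, 0, spec$jitter_sd)
  ect <- rep(FALSE, n + 1L)
  n_events <- floor(spec$ectopy_burden * n)
  if (n_events > 0) {
    if (n_events >= floor((n - 1L) / 2)) {
      slots <- seq(1L, n - 1L, by = 2L)     # maximal burden: strict alternation
    } else {
      cand <- sample(seq_len(n - 1L))
      slots <- integer(0)
      for (i in cand) {
        if (length(slots) >= n_events) break
        if (!any(abs(slots - i) < 2L)) slots <- c(slots, i)
      }
      slots <- sort(slots)
    }
    for (i in slots) {
      # coupling intervals and pauses vary beat to beat in real ectopy;
      # scaled from the sinus jitter so the noise-free case stays exact
      rr[i] <- spec$coupling + rnorm(1, 0, 2.5 * spec$jitter_sd)
      rr[i + 1L] <- spec$compensatory_pause + rnorm(1, 0, 2.5 * spec$jitter_sd)
      ect[i + 1L] <- TRUE  # the beat ending the coupling interval is the PVC
    }
  }
  amp <- ifelse(ect, spec$pvc_amp_factor, 1)
  structure(rr, amp_factors = amp, ectopic = ect)
}

# Premature-beat insertion: interval i shortened by U(0.4, 0.7), interval
# i+1 lengthened by half the advanced time (partial compensatory pause).
insert_premature <- function(rr, burden) {
  n <- length(rr)
  ect <- rep(FALSE, n + 1L)
  early <- which(rbinom(n - 1L, 1L, burden) == 1L)
  early <- early[c(TRUE, diff(early) >= 2L)]
  for (i in early) {
    u <- runif(1, 0.4, 0.7)
    advanced <- rr[i] * (1 - u)
    rr[i] <- rr[i] * u
    rr[i + 1L] <- rr[i + 1L] + 0.5 * advanced
    ect[i + 1L] <- TRUE
  }
  structure(rr, amp_factors = rep(1, n + 1L), ectopic = ect)
}

# Sporadic premature atrial beats over a sinus background.
rr_pac <- function(spec, n, base) {
  rr <- base + rnorm(n, 0, spec$jitter_sd)
  insert_premature(rr, spec$ectopy_burden)
}
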