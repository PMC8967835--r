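#' Assemble a recording from per-rhythm blocks
#'
#' Internal worker for \code{\link{make_dataset}}: concatenates one
#' interval sequence per rhythm block, renders PPG and ACC over the full
#' duration, and books half-open annotation intervals \code{[start, end)}.
#'
#' @keywords internal
#' @noRd
simulate_recording <- function(patient_id, blocks, noise, fs_ppg, fs_acc,
                               quiet_acc_sd, seed) {
  stopifnot(nrow(blocks) >= 1)
  rr_all <- numeric(0)
  amp_all <- 1            # amplitude factor of the very first beat
  ann <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    label = character(0))
  t_cursor <- 0
  for (b in seq_len(nrow(blocks))) {
    spec <- blocks$spec[[b]]
    n_beats <- ceiling(blocks$duration_s[b] * spec$mean_rate / 60)
    rr <- gen_rr_sequence(spec, n_beats, seed = derive_seed(seed, b))
    amp <- attr(rr, "amp_factors")
    rr_all <- c(rr_all, as.numeric(rr))
    # first beat of a block coincides with last beat of the previous one;
    # keep the previous beat's amplitude, append the rest.
    amp_all <- c(amp_all, amp[-1L])
    block_dur <- sum(rr)
    lab <- blocks$label[b]
    ann <- rbind(ann, data.frame(start_s = t_cursor,
                                 end_s = t_cursor + block_dur,
                                 label = lab))
    t_cursor <- t_cursor + block_dur
  }
  pad_s <- 1
  ppg <- render_ppg(rr_all, fs = fs_ppg, noise = noise,
                    amp_factors = amp_all, pad_s = pad_s,
                    seed = derive_seed(seed, 101L))
  ann$start_s <- ann$start_s + pad_s
  ann$end_s <- ann$end_s + pad_s
  dur <- length(ppg$samples) / ppg$fs
  acc <- render_acc(dur, fs = fs_acc,
                    motion_episodes = noise$motion_episodes,
                    quiet_sd = quiet_acc_sd,
                    seed = derive_seed(seed, 202L))
  structure(list(patient_id = patient_id, ppg = ppg, acc = acc,
                 annotations = ann, truth_beats = ppg$truth_beats),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording %s: %.0f s PPG @ %g Hz, %d annotation block(s): %s>\n",
              x$patient_id, length(x$ppg$samples) / x$ppg$fs, x$ppg$fs,
              nrow(x$annotations),
              paste(x$annotations$label, collapse = "+")))
  invisible(x)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study design the detector targets: each patient
#' contributes contiguous blocks of AF and sinus rhythm, recorded
#' continuously for several minutes per rhythm, with mild baseline wander,
#' white noise and occasional dropouts. Per-patient heart rates are drawn
#' uniformly from \code{sr_rate_range} / \code{af_rate_range}.
#'
#' @param n_patients number of simulated patients.
#' @param block_plan data frame with columns \code{kind} (rhythm kind per
#'   \code{\link{rhythm_spec}}) and \code{duration_s}; one row per
#'   contiguous rhythm block, rendered in order for every patient.
#' @param noise a \code{\link{noise_spec}} shared by all patients.
#' @param fs_ppg PPG sampling rate, Hz (512 or 128 typical).
#' @param fs_acc accelerometer sampling rate, Hz.
#' @param sr_rate_range,af_rate_range per-patient mean heart-rate ranges,
#'   beats/min.
#'
#' Per-patient heterogeneity: \code{jitter_sd}, \code{af_sd} and
#' \code{background_ectopy} may each be a length-2 range from which one
#' value per patient is drawn (a scalar fixes the value for the whole
#' cohort). A clinical cohort is heterogeneous in exactly these axes —
#' some AF is comparatively regular, some sinus rhythm carries frequent
#' premature beats — and that heterogeneity, not the class means, is
#' what keeps the classification benchmark off the ceiling.
#' @param jitter_sd,rsa_amp,rsa_freq,af_sd,ectopy_burden,pvc_amp_factor
#'   rhythm parameters forwarded to \code{\link{rhythm_spec}}.
#' @param pvc_burden_range per-patient PVC burden range for bigeminy
#'   blocks; each patient's burden is drawn uniformly from it,
#'   emulating the wide burden spread of a premature-complex ablation
#'   cohort (roughly 20 +/- 14 percent). Set both ends to 0.5 for
#'   strict bigeminy in every patient.
#' @param pac_burden premature-beat fraction for PAC blocks.
#' @param background_ectopy sporadic premature-beat fraction inside SR
#'   blocks.
#' @param quiet_acc_sd accelerometer per-axis sd outside motion episodes.
#' @return An object of class \code{"dataset_config"}.
#' @export
dataset_config <- function(n_patients = 40,
                           block_plan = data.frame(
                             kind = c("AF", "SR"),
                             duration_s = c(240, 240)),
                           noise = noise_spec(),
                           fs_ppg = 512, fs_acc = 100,
                           sr_rate_range = c(55, 90),
                           af_rate_range = c(70, 110),
                           jitter_sd = c(0.015, 0.05),
                           rsa_amp = 0.02, rsa_freq = 0.25,
                           af_sd = c(0.12, 0.28),
                           ectopy_burden = 0.5, pvc_amp_factor = 0.5,
                           pvc_burden_range = c(0.15, 0.45),
                           pac_burden = 0.13,
                           background_ectopy = c(0, 0.05),
                           quiet_acc_sd = 1) {
  stopifnot(n_patients >= 1, nrow(block_plan) >= 1,
            all(c("kind", "duration_s") %in% names(block_plan)))
  structure(list(n_patients = as.integer(n_patients),
                 block_plan = block_plan, noise = noise,
                 fs_ppg = fs_ppg, fs_acc = fs_acc,
                 sr_rate_range = sr_rate_range,
                 af_rate_range = af_rate_range,
                 jitter_sd = jitter_sd, rsa_amp = rsa_amp,
                 rsa_freq = rsa_freq, af_sd = af_sd,
                 ectopy_burden = ectopy_burden,
                 pvc_amp_factor = pvc_amp_factor,
                 pvc_burden_range = pvc_burden_range,
                 pac_burden = pac_burden,
                 background_ectopy = background_ectopy,
                 quiet_acc_sd = quiet_acc_sd),
            class = "dataset_config")
}

#' Generate a synthetic multi-patient PPG/ACC dataset
#'
#' Simulates \code{config$n_patients} recordings, each with the annotated
#' rhythm blocks of \code{config$block_plan}. Per-patient seeds are
#' derived reproducibly from \code{seed}: identical (config, seed) give
#' bit-identical datasets.
#'
#' @param config a \code{\link{dataset_config}}.
#' @param seed master integer seed.
#' @return List of \code{"recording"} objects (class \code{"ppg_dataset"}).
#' @examples
#' ds <- make_dataset(dataset_config(
#'   n_patients = 2,
#'   block_plan = data.frame(kind = c("AF", "SR"), duration_s = c(60, 60)),
#'   fs_ppg = 128), seed = 7)
#' length(ds)
#' @export
make_dataset <- function(config = dataset_config(), seed = 1L) {
  stopifnot(inherits(config, "dataset_config"))
  recs <- lapply(seq_len(config$n_patients), function(p) {
    pseed <- derive_seed(seed, p * 1000L)
    draw <- function(rng) if (length(rng) == 2) runif(1, rng[1], rng[2])
                          else rng[1]
    rates <- with_seed(pseed, list(
      sr = runif(1, config$sr_rate_range[1], config$sr_rate_range[2]),
      af = runif(1, config$af_rate_range[1], config$af_rate_range[2]),
      pvc = runif(1, config$pvc_burden_range[1],
                  config$pvc_burden_range[2]),
      jitter = draw(config$jitter_sd),
      af_sd = draw(config$af_sd),
      bg_ect = draw(config$background_ectopy)))
    specs <- lapply(seq_len(nrow(config$block_plan)), function(b) {
      kind <- config$block_plan$kind[b]
      rate <- if (kind == "AF") rates$af else rates$sr
      rhythm_spec(kind, mean_rate = rate,
                  jitter_sd = rates$jitter,
                  rsa_amp = config$rsa_amp, rsa_freq = config$rsa_freq,
                  af_sd = rates$af_sd,
                  ectopy_burden = if (kind == "PAC") config$pac_burden
                                  else if (kind == "PVC_BIGEMINY") rates$pvc
                                  else config$ectopy_burden,
                  pvc_amp_factor = config$pvc_amp_factor,
                  background_ectopy = rates$bg_ect)
    })
    blocks <- data.frame(label = config$block_plan$kind,
                         duration_s = config$block_plan$duration_s)
    # segment labels collapse PVC_BIGEMINY -> PVC for annotation bookkeeping
    blocks$label <- ifelse(blocks$label == "PVC_BIGEMINY", "PVC", blocks$label)
    blocks$spec <- specs
    simulate_recording(sprintf("P%03d", p), blocks, config$noise,
                       config$fs_ppg, config$fs_acc, config$quiet_acc_sd,
                       seed = derive_seed(pseed, 1L))
  })
  structure(recs, class = "ppg_dataset")
}

#' @export
print.ppg_dataset <- function(x, ...) {
  cat(sprintf("<ppg_dataset: %d recording(s)>\n", length(x)))
  invisible(x)
}
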