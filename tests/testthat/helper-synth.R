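# Small fixture builders shared across test files.

quiet_noise <- function(...) {
  noise_spec(baseline_amp = 0, white_sd = 0, dropout_fraction = 0, ...)
}

tiny_cohort <- function(n_patients = 6, af_s = 120, sr_s = 120,
                        fs_ppg = 128, pvc_s = 0, seed = 1) {
  kinds <- c("AF", "SR", if (pvc_s > 0) "PVC_BIGEMINY")
  durs <- c(af_s, sr_s, if (pvc_s > 0) pvc_s)
  make_dataset(dataset_config(
    n_patients = n_patients,
    block_plan = data.frame(kind = kinds, duration_s = durs),
    fs_ppg = fs_ppg), seed = seed)
}

# A clean rendered recording with known beats.
clean_recording <- function(kind = "SR", n_beats = 30, rate = 70,
                            fs = 512, seed = 1) {
  spec <- rhythm_spec(kind, mean_rate = rate)
  rr <- gen_rr_sequence(spec, n_beats, seed = seed)
  render_ppg(rr, fs = fs, noise = quiet_noise(), seed = seed)
}

# Random per-segment fixtures (interval + height vectors) across rhythm
# kinds, for feature-oracle comparisons.
random_segment <- function(seed, n = 25) {
  kind <- c("SR", "AF", "PVC_BIGEMINY", "PAC")[1 + seed %% 4]
  spec <- rhythm_spec(kind, mean_rate = 60 + (seed * 7) %% 50)
  ppis <- as.numeric(gen_rr_sequence(spec, n, seed = seed))
  heights <- withr_seed(seed + 1000, {
    base <- 0.8 + 0.3 * stats::runif(n + 1)
    pmax(0.05, base + stats::rnorm(n + 1, 0, 0.05))
  })
  list(ppis = ppis, heights = heights, kind = kind)
}

# local seed scope without depending on withr
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}
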