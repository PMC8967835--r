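test_that("degenerate noise-free sinus rhythm gives exactly constant intervals", {
  rr <- gen_rr_sequence(rhythm_spec("SR", mean_rate = 60, jitter_sd = 0,
                                    rsa_amp = 0, background_ectopy = 0),
                        10, seed = 1)
  expect_equal(as.numeric(rr), rep(1, 10))
})

test_that("AF interval spread matches its generating distribution", {
  rr <- gen_rr_sequence(rhythm_spec("AF", mean_rate = 75, af_sd = 0.2),
                        1000, seed = 42)
  expect_gt(sd(rr), 0.18)
  expect_lt(sd(rr), 0.22)
  expect_true(all(rr >= 0.25))
})

test_that("full-burden bigeminy strictly alternates coupling and pause", {
  rr <- gen_rr_sequence(rhythm_spec("PVC_BIGEMINY", mean_rate = 75,
                                    jitter_sd = 0, coupling = 0.6,
                                    compensatory_pause = 1.2,
                                    ectopy_burden = 0.5),
                        10, seed = 1)
  expect_equal(as.numeric(rr), rep(c(0.6, 1.2), 5))
  expect_equal(attr(rr, "amp_factors")[attr(rr, "ectopic")],
               rep(0.5, sum(attr(rr, "ectopic"))))
})

test_that("interval generation is deterministic and rejects bad input", {
  spec <- rhythm_spec("AF")
  expect_identical(gen_rr_sequence(spec, 50, seed = 9),
                   gen_rr_sequence(spec, 50, seed = 9))
  expect_error(gen_rr_sequence(spec, 1), "n_beats")
  expect_error(rhythm_spec("SR", mean_rate = 500), "mean_rate")
})

test_that("rendered pulses peak at the true beat times", {
  rr <- gen_rr_sequence(rhythm_spec("SR", mean_rate = 72), 10, seed = 2)
  rec <- render_ppg(rr, fs = 512, noise = quiet_noise(), seed = 2)
  # every truth beat has the local argmax within 1 sample
  for (tb in rec$truth_beats) {
    i <- round(tb * 512) + 1L
    win <- rec$samples[(i - 30):(i + 30)]
    expect_lte(abs(which.max(win) - 31), 1)
  }
  # interval bookkeeping: truth beats reproduce the intervals exactly
  expect_equal(diff(rec$truth_beats), as.numeric(rr), tolerance = 1e-12)
  expect_equal(sum(rr), rec$truth_beats[length(rr) + 1] - rec$truth_beats[1],
               tolerance = 1e-9)
})

test_that("saturation clips and dropouts hit their configured fraction", {
  rr <- gen_rr_sequence(rhythm_spec("SR"), 20, seed = 3)
  sat <- 0.8   # below the ~1.1 max template amplitude
  rec <- render_ppg(rr, fs = 256,
                    noise = noise_spec(baseline_amp = 0, white_sd = 0,
                                       saturation_value = sat,
                                       dropout_fraction = 0), seed = 3)
  expect_true(any(rec$samples == sat, na.rm = TRUE))
  expect_true(all(rec$samples <= sat, na.rm = TRUE))

  rec2 <- render_ppg(rr, fs = 256,
                     noise = noise_spec(dropout_fraction = 0.1), seed = 3)
  expect_lt(abs(mean(is.na(rec2$samples)) - 0.1), 0.01)
})

test_that("accelerometer rendering honours duration and motion episodes", {
  acc <- render_acc(60, fs = 100, quiet_sd = 1, seed = 1)
  expect_equal(length(acc$ax), 6000)
  mf <- motion_flags(acc)
  expect_true(all(mf$score < 23.12))

  ep <- data.frame(start_s = 20, duration_s = 5, acc_sd = 30, ppg_sd = 0)
  acc2 <- render_acc(60, fs = 100, motion_episodes = ep, quiet_sd = 1,
                     seed = 1)
  mf2 <- motion_flags(acc2)
  inside <- mf2$start_s >= 20 & mf2$end_s <= 25
  expect_true(all(mf2$score[inside] > 23.12))
  expect_true(all(mf2$score[!inside] < 23.12))
})

test_that("AF interval spread exceeds sinus spread in nearly every draw", {
  af <- rhythm_spec("AF", af_sd = 0.2)
  sr <- rhythm_spec("SR", jitter_sd = 0.02)
  wins <- vapply(1:100, function(s) {
    sd(gen_rr_sequence(af, 25, seed = s)) >
      sd(gen_rr_sequence(sr, 25, seed = s + 5000))
  }, logical(1))
  expect_gte(mean(wins), 0.99)
})

test_that("bigeminy intervals are more bimodal than sinus intervals", {
  bg <- rhythm_spec("PVC_BIGEMINY")
  sr <- rhythm_spec("SR")
  for (s in 1:10) {
    expect_gt(dip_statistic(gen_rr_sequence(bg, 25, seed = s)),
              dip_statistic(gen_rr_sequence(sr, 25, seed = s)))
  }
})

test_that("dataset builder books annotations and is bit-reproducible", {
  cfg <- dataset_config(n_patients = 2,
                        block_plan = data.frame(kind = c("AF", "SR"),
                                                duration_s = c(120, 120)),
                        fs_ppg = 128)
  ds <- make_dataset(cfg, seed = 7)
  expect_length(ds, 2)
  ann <- do.call(rbind, lapply(ds, `[[`, "annotations"))
  expect_equal(nrow(ann), 4)
  expect_equal(ann$label, rep(c("AF", "SR"), 2))
  # blocks tile the recording without overlap
  for (rec in ds) {
    a <- rec$annotations
    expect_true(all(a$end_s[-nrow(a)] <= a$start_s[-1] + 1e-9))
    expect_lte(max(a$end_s), length(rec$ppg$samples) / rec$ppg$fs)
  }
  ds2 <- make_dataset(cfg, seed = 7)
  expect_identical(ds, ds2)
})
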