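test_that("peak detection honours height and spacing rules", {
  expect_length(detect_peaks(rep(1, 1000), fs = 512)$peak_times, 0)

  # two candidate maxima 0.05 s apart: only the taller is retained
  x <- rep(0, 1000)
  x[300] <- 1.0
  x[300 + 26] <- 0.8                  # 26 samples ~ 0.05 s at 512 Hz
  bt <- detect_peaks(x, fs = 512, min_height_frac = 0)
  expect_equal(bt$peak_indices, 300L)

  expect_error(detect_peaks(numeric(0), fs = 512), "empty")
})

test_that("clean simulated beats are recovered exactly", {
  rec <- clean_recording("SR", n_beats = 10, rate = 70, seed = 6)
  pr <- preprocess_ppg(rec)
  bt <- detect_peaks(pr)
  expect_length(bt$peak_times, 11)
  expect_true(all(abs(bt$peak_times - rec$truth_beats) < 0.020))
  expect_true(all(diff(bt$peak_times) > 0))
})

test_that("interval extraction flags implausibly short intervals", {
  mk_beats <- function(idx, fs) {
    structure(list(peak_times = (idx - 1) / fs, peak_indices = idx,
                   peak_heights = rep(1, length(idx)), fs = fs),
              class = "beat_series")
  }
  p <- to_ppis(mk_beats(c(1, 513, 1025), 512))
  expect_equal(p$ppi_s, c(1, 1))
  expect_true(all(p$valid))

  p2 <- to_ppis(mk_beats(c(1, 129, 641), 512))   # 0.25 s then 1 s
  expect_equal(p2$valid, c(FALSE, TRUE))

  p3 <- to_ppis(mk_beats(c(1, 65), 128))         # 0.5 s at 128 Hz
  expect_true(p3$valid)
  expect_error(to_ppis(mk_beats(5, 512)), "2 peaks")
})

test_that("segmentation splits, labels and discards with reasons", {
  fs <- 512
  times <- cumsum(c(1, rep(0.8, 100)))           # 100 intervals
  beats <- structure(list(peak_times = times,
                          peak_indices = round(times * fs) + 1L,
                          peak_heights = rep(1, length(times)), fs = fs),
                     class = "beat_series")
  ann <- data.frame(start_s = 0, end_s = 100, label = "AF")
  segs <- segment_ppis(beats, ann, n_beats = 25)
  expect_length(segs$segments, 4)
  expect_true(all(vapply(segs$segments, `[[`, "", "label") == "AF"))

  # 30 intervals at N = 25: one segment plus discarded remainder
  beats30 <- structure(list(peak_times = times[1:31],
                            peak_indices = round(times[1:31] * fs) + 1L,
                            peak_heights = rep(1, 31), fs = fs),
                       class = "beat_series")
  segs30 <- segment_ppis(beats30, ann, n_beats = 25)
  expect_length(segs30$segments, 1)
  expect_equal(segs30$n_ppis_remainder, 5)
  expect_true("remainder" %in% segs30$log$reason)

  # a segment straddling a rhythm boundary is discarded as mixed
  ann2 <- data.frame(start_s = c(0, 10), end_s = c(10, 100),
                     label = c("AF", "SR"))
  segs2 <- segment_ppis(beats, ann2, n_beats = 25)
  expect_true("mixed-label" %in% segs2$log$reason)

  # conservation: every candidate segment is kept or discarded with reason
  expect_true(all(segs2$log$kept | nzchar(segs2$log$reason)))
  n_candidates <- sum(segs2$log$reason != "remainder")
  expect_equal(n_candidates * 25 + segs2$n_ppis_remainder,
               segs2$n_ppis_total)
  expect_error(segment_ppis(beats, NULL, 25), "annotations")
})

test_that("intervals agree across 512 and 128 Hz renderings", {
  rr <- gen_rr_sequence(rhythm_spec("AF", mean_rate = 80), 30, seed = 13)
  for (fs in c(512, 128)) {
    rec <- render_ppg(rr, fs = fs, noise = quiet_noise(), seed = 13)
    pr <- preprocess_ppg(rec)
    bt <- detect_peaks(pr)
    expect_length(bt$peak_times, 31)
    assign(paste0("ppi", fs), diff(bt$peak_times))
  }
  expect_true(all(abs(ppi512 - ppi128) <= 1 / 128 + 1e-9))
})

test_that("zero-noise beat recovery is exact across rhythms and rates", {
  for (s in 1:10) {
    kind <- c("SR", "AF", "PAC")[1 + s %% 3]
    rec <- clean_recording(kind, n_beats = 25,
                           rate = 55 + 5 * s, fs = 512, seed = s)
    bt <- detect_peaks(preprocess_ppg(rec))
    expect_length(bt$peak_times, length(rec$truth_beats))
    expect_lt(max(abs(bt$peak_times - rec$truth_beats)), 1 / 512)
  }
})
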