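test_that("saturation flag fires only on clipped finite samples", {
  expect_false(check_saturation(c(0.1, 0.5, 0.9), 1.0))
  expect_true(check_saturation(c(0.1, 1.0, 0.9), 1.0))
  expect_false(check_saturation(rep(NA_real_, 10), 1.0))
  expect_error(check_saturation(numeric(0), 1.0), "empty")
})

test_that("missing-data rule keeps the 5% boundary and drops above it", {
  w <- rep(0, 5120)
  w[1:256] <- NA                       # exactly 5% of a 10-s 512 Hz window
  expect_equal(missing_fraction(w), 0.05)
  expect_false(missing_fraction(w) > quality_thresholds()$missing_max)
  w[257] <- NA
  expect_true(missing_fraction(w) > quality_thresholds()$missing_max)
  expect_equal(missing_fraction(rep(0, 100)), 0)
})

test_that("motion score applies the printed axis weights", {
  z <- as.numeric(scale(rnorm(100)))    # sample sd exactly 1
  expect_equal(motion_score(20 * z, 20 * z, 20 * z), 34.4,
               tolerance = 1e-9)
  expect_gt(34.4, quality_thresholds()$acc_threshold)
  expect_equal(motion_score(10 * z, 10 * z, 10 * z), 17.2,
               tolerance = 1e-9)
  expect_lt(17.2, quality_thresholds()$acc_threshold)
  expect_equal(motion_score(rep(1, 50), rep(2, 50), rep(3, 50)), 0)
  expect_error(motion_score(1:10, 1:9, 1:10), "mismatch")
})

test_that("baseline removal captures slow wander and passes pulse content", {
  p <- spline_params()
  expect_true(all(abs(remove_baseline(rep(2.5, 5120), p)) < 1e-6))

  t <- (0:5119) / 512
  slow <- sin(2 * pi * 0.1 * t)
  res <- remove_baseline(slow, p)
  expect_lt(sqrt(mean(res^2)) / sqrt(mean(slow^2)), 0.05)

  pulse <- sin(2 * pi * 1.2 * t)
  res2 <- remove_baseline(pulse, p)
  expect_gte(var(res2) / var(pulse), 0.8)
  expect_lt(abs(mean(res2)), 0.01)

  expect_error(remove_baseline(rep(1, 8), p), "short")
})

test_that("denoising returns the smooth fit and never adds variance", {
  p <- spline_params()
  expect_equal(denoise(rep(1.5, 5120), p), rep(1.5, 5120), tolerance = 1e-8)

  noise <- withr_seed(1, rnorm(5120))
  sm <- denoise(noise, p)
  expect_lt(var(sm) / var(noise), 0.10)

  t <- (0:5119) / 512
  pulse <- sin(2 * pi * 1.2 * t)
  expect_gt(cor(pulse, denoise(pulse, p)), 0.99)
  expect_lte(var(denoise(pulse, p)), var(pulse) * (1 + 1e-9))
})

test_that("repeated conditioning contracts instead of drifting", {
  # a fixed-df penalized fit re-shrinks mid-band harmonics on every
  # pass, so strict idempotence cannot hold; the second pass must
  # change far less than the first and never amplify
  rec <- clean_recording("AF", n_beats = 20, fs = 256, seed = 4)
  p <- spline_params()
  x <- rec$samples
  f1 <- denoise(remove_baseline(x, p), p)
  f2 <- denoise(remove_baseline(f1, p), p)
  rms <- function(v) sqrt(mean(v^2))
  expect_lte(rms(f2), rms(f1) * (1 + 1e-9))
  expect_lt(abs(rms(f2) - rms(f1)) / rms(f1), 0.15)
  expect_lt(abs(rms(f2) - rms(f1)), abs(rms(f1) - rms(x - mean(x))))
  expect_gt(cor(f1, f2), 0.95)
})

test_that("high-frequency ratio separates clean and noisy spectra", {
  t <- (0:5119) / 512
  expect_lt(hf_noise_ratio(sin(2 * pi * 1 * t), 512), 0.01)
  expect_gt(hf_noise_ratio(sin(2 * pi * 40 * t), 512), 0.99)
  both <- sin(2 * pi * 1 * t) + sin(2 * pi * 40 * t)
  r <- hf_noise_ratio(both, 512)
  expect_equal(r, 0.5, tolerance = 1e-6)
  expect_false(isTRUE(r > quality_thresholds()$hf_ratio_max + 1e-12))
  # below 2x the cutoff the rule is inapplicable, not silently passed
  expect_true(is.na(hf_noise_ratio(sin(2 * pi * 1 * t[1:500]), 50)))
})

test_that("sharp-peak rule is a strict conjunction of the three ratios", {
  expect_false(sharp_peak_flag(rep(1, 5)))
  expect_true(sharp_peak_flag(c(1, 1, 1, 10, 10)))
  expect_false(sharp_peak_flag(c(1, 1, 1, 1, 10)))   # IQR/med = 0
  expect_true(sharp_peak_flag(c(-1, 0, 1)))          # non-positive median
  expect_error(sharp_peak_flag(c(1, 2)), "3")
})

test_that("window gating flags carry one reason each and are reproducible", {
  rr <- gen_rr_sequence(rhythm_spec("SR"), 90, seed = 11)
  rec <- render_ppg(rr, fs = 128,
                    noise = noise_spec(dropout_fraction = 0.2), seed = 11)
  pr <- preprocess_ppg(rec)
  expect_true(any(pr$windows$missing_exceeded))
  expect_true(all(pr$windows$flagged ==
                    (pr$windows$saturated | pr$windows$missing_exceeded |
                       pr$windows$hf_noise | pr$windows$too_short)))
  pr2 <- preprocess_ppg(rec)
  expect_identical(pr$windows, pr2$windows)
})
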