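test_that("interval SD and RMSSD match hand computations", {
  expect_equal(ppi_sd(rep(0.8, 10)), 0)
  expect_equal(ppi_rmssd(rep(0.8, 10)), 0)
  expect_equal(ppi_sd(c(0.8, 1.0, 1.2)), 0.2)
  expect_equal(ppi_rmssd(c(1.0, 1.1, 1.0)), 0.1)
  expect_error(ppi_sd(1), "2")
  expect_error(ppi_rmssd(c(1, 2)), "3")
})

test_that("interval entropy has its closed-form values", {
  expect_equal(shannon_entropy(rep(0.9, 25), 1000), 0)
  # 25 values in 25 distinct bins of 1000: uniform over 25 -> ln 25
  x <- seq(0.5, 1.5, length.out = 25)
  expect_equal(shannon_entropy(x, 1000), log(25), tolerance = 1e-9)
  # half the mass in each of two bins of 10 -> ln 2
  y <- c(rep(0.6, 10), rep(1.2, 10))
  expect_equal(shannon_entropy(y, 10), log(2), tolerance = 1e-12)
})

test_that("dominant frequency lands on the spectral line", {
  fs <- 128
  t <- (0:(20 * fs - 1)) / fs
  r <- max_fft(sin(2 * pi * 1.2 * t), fs)
  expect_equal(r$freq, 1.2, tolerance = fs / length(t) + 1e-9)
  expect_false(r$low_confidence)

  noise <- withr_seed(3, rnorm(length(t)))
  rn <- max_fft(noise, fs)
  expect_gte(rn$freq, 0.5)
  expect_lte(rn$freq, 3.5)
  expect_true(rn$low_confidence)
})

test_that("rolling three-segment statistics follow their definitions", {
  r <- rolling_features(c(0.2, 0.2, 0.2), c(0.1, 0.1, 0.1), c(1, 1, 1))
  expect_equal(r, list(sd3 = 0.2, rmssd3 = 0, maxfftsd3 = 0))
  expect_equal(rolling_features(c(0.1, 0.2, 0.3), 1:3, 1:3)$sd3, 0.2)
  expect_equal(rolling_features(1:3, 1:3, c(1.0, 1.2, 1.4))$maxfftsd3,
               sd(c(1.0, 1.2, 1.4)))
})

test_that("peak-height morphology is median-normalized and scale invariant", {
  expect_equal(peak_height_features(rep(2, 10)),
               list(ph_sd = 0, ph_rmssd = 0, ph_iqr = 0))
  h <- withr_seed(4, runif(11, 0.5, 1.5))
  expect_equal(peak_height_features(h), peak_height_features(2 * h),
               tolerance = 1e-12)
  alt <- rep(c(1, 2), 5)
  got <- peak_height_features(alt)
  norm <- alt / o_median(alt)
  expect_equal(got$ph_sd, o_sd(norm), tolerance = 1e-12)
  expect_equal(got$ph_rmssd, o_rmssd(norm), tolerance = 1e-12)
  expect_equal(got$ph_iqr, o_iqr(norm), tolerance = 1e-12)
  expect_error(peak_height_features(c(-1, -2, 0)), "median")
})

test_that("height autocorrelation features respond to serial structure", {
  expect_equal(acf_height_features(rep(1, 26)),
               list(acf_sd = 0, acf_rmssd = 0, acf_iqr = 0, acf_diffsd = 0))
  alt <- rep(c(1, 2), 13)
  af <- acf_height_features(alt)
  a <- vapply(1:13, function(k) o_acf(alt, k), numeric(1))
  expect_equal(a[1], -25 / 26, tolerance = 1e-9)   # biased lag-1 of alternation
  expect_gt(af$acf_sd, 0.7)
  # i.i.d. heights: ACF values live in the white-noise band
  inside <- unlist(lapply(1:20, function(s) {
    h <- withr_seed(s + 300, rnorm(80, 1, 0.1))
    abs(ppgaf:::acf_values(h, 40)) < 2 / sqrt(80)
  }))
  expect_gte(mean(inside), 0.9)
})

test_that("ectopy features isolate regular alternation from irregularity", {
  expect_equal(extended_features(rep(0.8, 10))[c("lag1_acf", "even_sd",
                                                 "odd_sd")],
               list(lag1_acf = 0, even_sd = 0, odd_sd = 0))
  big <- rep(c(0.6, 1.2), length.out = 25)
  ex <- extended_features(big)
  expect_equal(ex$even_sd, 0)
  expect_equal(ex$odd_sd, 0)
  expect_equal(ppi_sd(big), o_sd(big), tolerance = 1e-12)
  expect_gt(ppi_sd(big), 0.29)
  expect_lt(ex$lag1_acf, -0.9)
  expect_lt(ex$dip_p, 0.05)
  # serially independent unimodal intervals: no alternation, no bimodality
  ok <- vapply(1:10, function(s) {
    u <- withr_seed(s + 800, runif(1000, 0.5, 1.5))
    e <- extended_features(u)
    abs(e$lag1_acf) < 0.1 && e$dip_p > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("interval features are heart-rate robust", {
  x <- as.numeric(gen_rr_sequence(rhythm_spec("AF"), 25, seed = 21))
  for (c_ in c(0.5, 2)) {
    expect_equal(ppi_sd(c_ * x), c_ * ppi_sd(x), tolerance = 1e-12)
    expect_equal(ppi_rmssd(c_ * x), c_ * ppi_rmssd(x), tolerance = 1e-12)
    for (B in c(10, 100, 1000))
      expect_equal(shannon_entropy(c_ * x, B), shannon_entropy(x, B),
                   tolerance = 1e-9)
    e1 <- extended_features(x); e2 <- extended_features(c_ * x)
    expect_equal(e2$lag1_acf, e1$lag1_acf, tolerance = 1e-9)
    expect_equal(e2$lag2_acf, e1$lag2_acf, tolerance = 1e-9)
    expect_equal(e2$dip_p, e1$dip_p)
    expect_equal(e2$even_sd, c_ * e1$even_sd, tolerance = 1e-12)
    expect_equal(e2$odd_sd, c_ * e1$odd_sd, tolerance = 1e-12)
  }
})

test_that("feature table applies rolling-window bookkeeping and schemas", {
  seg <- function(t, label = "AF") {
    ppis <- as.numeric(gen_rr_sequence(rhythm_spec(label), 25,
                                       seed = round(t)))
    list(patient_id = "P1", n_beats = 25L, ppis = ppis,
         heights = withr_seed(round(t), runif(26, 0.8, 1.2)),
         start_time = t, end_time = t + sum(ppis), label = label)
  }
  segs <- lapply(c(0, 20, 40, 60), seg)
  ft <- build_feature_table(segs, NULL, "base8")
  expect_equal(nrow(ft), 2)           # trailing two lack rolling successors
  expect_setequal(setdiff(names(ft), c("patient_id", "start_time", "label")),
                  feature_columns("base8"))
  expect_length(feature_columns("base8"), 8)
  expect_length(feature_columns("all"), 21)
  ft_all <- build_feature_table(segs, NULL, "all")
  expect_equal(ncol(ft_all), 3 + 21)
  expect_error(build_feature_table(list(), NULL), "empty")
})

test_that("feature contrasts on the default cohort point the expected way", {
  ds <- make_dataset(dataset_config(
    n_patients = 6,
    block_plan = data.frame(kind = c("AF", "SR"), duration_s = c(200, 200)),
    fs_ppg = 128), seed = 2)
  ft <- dataset_features(ds, 25, "all")
  rep_ <- univariate_report(ft)
  m <- function(f) rep_[rep_$feature == f, ]
  af_higher <- c("ppi_sd", "ppi_rmssd", "se10", "se100", "se1000", "sd3",
                 "maxfftsd3", "ph_sd", "ph_rmssd", "ph_iqr")
  for (f in af_higher) expect_gt(m(f)$mean_a, m(f)$mean_b, label = f)
  af_lower <- c("rmssd3", "acf_sd", "acf_rmssd", "acf_iqr", "acf_diffsd")
  for (f in af_lower) expect_lt(m(f)$mean_a, m(f)$mean_b, label = f)
})
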