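# IP branch: artifact removal, breath detection, SQI and timing
# features with the 5-MAD cascade.

test_that("amplitude-artifact removal interpolates flagged samples", {
  x <- rep(10, 50); x[20] <- 25
  out <- remove_amplitude_artifacts(impedance_trace(x, 16))
  expect_equal(out$samples[20], 10)
  expect_identical(which(out$interpolated), 20L)

  # 6 is above 0.5 * median(10): untouched
  x2 <- rep(10, 50); x2[20] <- 6
  out2 <- remove_amplitude_artifacts(impedance_trace(x2, 16))
  expect_equal(out2$samples, x2)
  expect_false(any(out2$interpolated))

  expect_error(remove_amplitude_artifacts(impedance_trace(c(9, 9), 16)),
               "3 samples")
  expect_error(remove_amplitude_artifacts(
    impedance_trace(c(1, 100, 1, 100), 16)), "anchor")
})

test_that("artifact interpolation fraction matches the implanted event", {
  plan <- breath_plan(1, 2, artifacts = data.frame(
    onset = 30, duration = 2, scale = 2), seed = 3)
  ip <- generate_ip(plan, 16, 120)
  out <- remove_amplitude_artifacts(ip$trace)
  expect_lt(abs(mean(out$interpolated) - 2 / 120), 2 / (16 * 120))
})

test_that("breath detection recovers sinusoid periods", {
  fs <- 100
  t <- seq(0, 64, 1 / fs)
  seg <- detect_breaths(impedance_trace(sin(2 * pi * 0.25 * t), fs))
  expect_true(nrow(seg) %in% c(15, 16))
  ibi <- seg$breath_end - seg$insp_onset
  expect_true(all(abs(ibi - 4) <= 1 / fs + 1e-9))

  # period below the minimum peak distance: merged, never < 0.67 s
  seg2 <- detect_breaths(impedance_trace(sin(2 * pi * 2 * t), fs))
  expect_true(all(seg2$breath_end - seg2$insp_onset >= 0.67))

  # featureless input: empty segmentation
  expect_equal(nrow(detect_breaths(impedance_trace(rep(1, 3200), fs))), 0)
})

test_that("detected onsets track ground truth on clean recordings", {
  plan <- jittered_plan(20, 120, seed = 8)
  ip <- generate_ip(plan, 16, 120)
  feats <- run_ip_branch(ip$trace)
  feats <- feats[!feats$outlier, ]
  tru <- match_truth(feats, ip$truth)
  expect_true(all(abs(feats$insp_onset - tru$insp_onset) < 0.1))
})

test_that("signal quality passes clean breathing and fails noise", {
  plan <- jittered_plan(20, 96, seed = 9)
  ip <- generate_ip(plan, 16, 96)
  tr <- resample_to_100hz(ip$trace)
  ipf <- bandpass_ip(tr)
  seg <- assess_signal_quality(ipf, detect_breaths(ipf, raw = tr))
  expect_true(all(seg$quality_ok))

  # second half replaced by white noise
  x <- ip$trace$samples
  set.seed(10)
  x[(length(x) %/% 2):length(x)] <-
    400 + stats::rnorm(length(x) - length(x) %/% 2 + 1, 0, 0.5)
  tr2 <- resample_to_100hz(impedance_trace(x, 16))
  ipf2 <- bandpass_ip(tr2)
  seg2 <- assess_signal_quality(ipf2, detect_breaths(ipf2, raw = tr2))
  noisy <- seg2$insp_onset > 56
  expect_true(sum(noisy) > 0)
  expect_true(all(!seg2$quality_ok[noisy]))

  # alternating 2 s / 4 s IBIs: duration CoV 0.47 > 0.3, all fail
  fs <- 100
  breaths <- rep(c(2, 4), 20)
  tt <- seq(0, sum(breaths), 1 / fs)
  on <- c(0, cumsum(breaths))
  phase <- numeric(length(tt))
  idx <- findInterval(tt, on, rightmost.closed = TRUE)
  idx[idx > length(breaths)] <- length(breaths)
  phase <- (tt - on[idx]) / breaths[idx]
  xalt <- -cos(2 * pi * phase)
  tra <- impedance_trace(xalt, fs)
  sega <- assess_signal_quality(tra, detect_breaths(tra))
  expect_true(all(!sega$quality_ok))
})

test_that("raising the correlation threshold never adds good breaths", {
  plan <- jittered_plan(25, 96, jitter_cv = 0.08, noise_sd = 0.05,
                        seed = 11)
  ip <- generate_ip(plan, 16, 96)
  tr <- resample_to_100hz(ip$trace)
  ipf <- bandpass_ip(tr)
  seg <- detect_breaths(ipf, raw = tr)
  counts <- vapply(c(0.5, 0.7, 0.9, 0.99), function(th)
    sum(assess_signal_quality(ipf, seg, corr_threshold = th)$quality_ok),
    0)
  expect_true(all(diff(counts) <= 0))
})

test_that("timing features are exact arithmetic on the fiducials", {
  seg <- data.frame(breath_id = 1:2,
                    insp_onset = c(0, 3), exp_onset = c(1, 4.5),
                    breath_end = c(3, 6), quality_ok = TRUE,
                    outlier = FALSE)
  f <- extract_timing_features(seg)
  expect_equal(f$Ti, c(1, 1.5))
  expect_equal(f$Te, c(2, 1.5))
  expect_equal(f$IBI, c(3, 3))
  expect_equal(f$RR, c(20, 20))
  expect_equal(f$TeTi, c(2, 1))
  expect_equal(f$TiIBI, c(1 / 3, 0.5))

  bad <- seg; bad$exp_onset[1] <- -1
  expect_error(extract_timing_features(bad), "increasing")
})

test_that("timing MAD filter flags gross errors, zero-spread included", {
  base <- data.frame(breath_id = 1:31, insp_onset = (0:30) * 3,
                     RR = 20, Ti = 1, Te = 2, IBI = 3, TeTi = 2,
                     TiIBI = 1 / 3, quality_ok = TRUE, outlier = FALSE)
  base$Ti[16] <- 2  # doubled Ti among identical breaths
  out <- remove_timing_outliers(base)
  expect_identical(which(out$outlier), 16L)

  base$Ti[16] <- 1
  expect_false(any(remove_timing_outliers(base)$outlier))
})

test_that("implanted 10x Ti errors are caught at >= 95% / <= 2% FP", {
  set.seed(12)
  n <- 600
  ti <- stats::rlnorm(n, log(1), 0.06)
  te <- stats::rlnorm(n, log(1.3), 0.06)
  implant <- sort(sample(n, 18))  # 3%
  ti[implant] <- ti[implant] * 10
  ibi <- ti + te
  feats <- data.frame(breath_id = seq_len(n), insp_onset = cumsum(ibi),
                      RR = 60 / ibi, Ti = ti, Te = te, IBI = ibi,
                      TeTi = te / ti, TiIBI = ti / ibi,
                      quality_ok = TRUE, outlier = FALSE)
  out <- remove_timing_outliers(feats)
  sens <- mean(out$outlier[implant])
  fp <- mean(out$outlier[-implant])
  expect_gte(sens, 0.95)
  expect_lte(fp, 0.02)
})
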