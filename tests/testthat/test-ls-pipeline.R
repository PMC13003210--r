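# Lung-sound branch: phase segmentation, subband SIs, acoustic outlier
# filter and multimodal matching.

test_that("phase segmentation is exact index arithmetic", {
  au <- audio_trace(numeric(16000), 4000)
  seg <- data.frame(breath_id = 1L, insp_onset = 0, exp_onset = 1,
                    breath_end = 3, quality_ok = TRUE, outlier = FALSE)
  ph <- segment_phases(au, seg)
  expect_equal(ph$start_sample, c(1L, 4001L))
  expect_equal(ph$end_sample, c(4001L, 12001L))
  expect_equal(diff(c(ph$start_sample[1], ph$end_sample[1])), 4000)

  # no good breaths: empty
  seg$quality_ok <- FALSE
  expect_equal(nrow(segment_phases(au, seg)), 0)

  # breath past the audio end is dropped with a message
  seg2 <- data.frame(breath_id = 1:2, insp_onset = c(0, 2),
                     exp_onset = c(1, 3), breath_end = c(2, 7),
                     quality_ok = TRUE, outlier = FALSE)
  expect_message(ph2 <- segment_phases(au, seg2), "past the audio end")
  expect_equal(unique(ph2$breath_id), 1L)
})

test_that("subband SIs localize tones and partition to one", {
  fs <- 4000
  t <- seq(0, 1, 1 / fs)
  for (f in c(150, 400, 650, 900)) {
    si <- compute_phase_si(sin(2 * pi * f * t), fs)
    sis <- unlist(si[1, 1:4])
    bands <- si_band_edges()
    b <- which(f >= bands[, 1] & f < pmax(bands[, 2], bands[, 1] + 1))
    expect_gte(sis[b], 0.95)
    expect_equal(sum(sis), 1, tolerance = 1e-9)
  }

  # white noise restricted to 100-1000 Hz: SIs ~ bandwidth fractions
  set.seed(13)
  nz <- mmbreath:::shaped_noise(2 * fs, fs, c(100, 1000))
  si_n <- unlist(compute_phase_si(nz, fs)[1, 1:4])
  expect_true(all(abs(si_n - c(200, 200, 300, 200) / 900) < 0.05))

  # shorter than one 64-ms window: marked missing
  expect_true(is.na(compute_phase_si(numeric(100), fs)$raw_intensity))
})

test_that("normalized SIs are scale-invariant; raw intensity is not", {
  set.seed(14)
  fs <- 4000
  x <- mmbreath:::shaped_noise(fs, fs, c(100, 1000))
  a <- compute_phase_si(x, fs)
  b <- compute_phase_si(3.7 * x, fs)
  expect_equal(unlist(a[1, 1:4]), unlist(b[1, 1:4]), tolerance = 1e-12)
  expect_equal(b$raw_intensity / a$raw_intensity, 3.7^2,
               tolerance = 1e-9)
})

test_that("an expiratory wheeze shifts expiratory SIs as expected", {
  plan <- breath_plan(1.2, 1.8, seed = 15)
  ip <- generate_ip(plan, 16, 60)
  base_spec <- acoustic_spec(seed = 16)
  wz_spec <- acoustic_spec(wheezes = data.frame(
    freq = 600, phase = "expiration", snr_db = 6), seed = 16)
  seg <- data.frame(breath_id = ip$truth$breath_id,
                    insp_onset = ip$truth$insp_onset,
                    exp_onset = ip$truth$exp_onset,
                    breath_end = ip$truth$breath_end,
                    quality_ok = TRUE, outlier = FALSE)
  si_for <- function(spec) {
    au <- generate_lung_sound(ip$truth, spec, 60)
    au <- bandpass_audio(au)
    ac <- compute_breath_acoustics(au, segment_phases(au, seg))
    e <- ac[ac$phase == "expiration", ]
    c(lo = stats::median(e$si_100_300), hi = stats::median(e$si_500_800))
  }
  base <- si_for(base_spec)
  wz <- si_for(wz_spec)
  expect_gt(wz["hi"], base["hi"])
  expect_lt(wz["lo"], base["lo"])
})

test_that("acoustic MAD filter flags implanted loud breaths", {
  mk <- function(intensity) {
    lapply(seq_along(intensity), function(i) data.frame(
      breath_id = i, phase = c("inspiration", "expiration"),
      si_100_300 = 0.7, si_300_500 = 0.15, si_500_800 = 0.1,
      si_800_1000 = 0.05,
      raw_intensity = intensity[i] * c(0.6, 0.4),
      breath_intensity = intensity[i], outlier = FALSE))
  }
  ints <- rep(1, 40); ints[25] <- 20
  ac <- do.call(rbind, mk(ints))
  out <- remove_acoustic_outliers(ac)
  expect_identical(unique(out$breath_id[out$outlier]), 25L)

  ac2 <- do.call(rbind, mk(rep(1, 40)))
  expect_false(any(remove_acoustic_outliers(ac2)$outlier))
})

test_that("cough-like bursts are flagged through the full audio path", {
  plan <- jittered_plan(20, 150, seed = 17)
  ip <- generate_ip(plan, 16, 150)
  au <- generate_lung_sound(ip$truth, acoustic_spec(seed = 18), 150)
  tru <- ip$truth
  set.seed(19)
  implant <- sort(sample(5:(nrow(tru) - 5), max(2, round(0.05 * nrow(tru)))))
  x <- au$samples
  for (k in implant) {
    i0 <- round(tru$exp_onset[k] * au$fs); i1 <- i0 + round(0.3 * au$fs)
    x[i0:i1] <- x[i0:i1] + 0.5 * stats::rnorm(i1 - i0 + 1)
  }
  au2 <- bandpass_audio(audio_trace(x, au$fs))
  seg <- data.frame(breath_id = tru$breath_id,
                    insp_onset = tru$insp_onset,
                    exp_onset = tru$exp_onset,
                    breath_end = tru$breath_end,
                    quality_ok = TRUE, outlier = FALSE)
  ac <- remove_acoustic_outliers(
    compute_breath_acoustics(au2, segment_phases(au2, seg)))
  flagged <- unique(ac$breath_id[ac$outlier])
  expect_gte(mean(implant %in% flagged), 0.9)
  clean <- setdiff(tru$breath_id, implant)
  expect_lte(mean(clean %in% flagged), 0.02)
})

test_that("multimodal matching is an inner join with 13 features", {
  timing <- data.frame(breath_id = 1:10, insp_onset = (1:10) * 3,
                       RR = 20, Ti = 1, Te = 2, IBI = 3, TeTi = 2,
                       TiIBI = 1 / 3, quality_ok = TRUE, outlier = FALSE)
  ac <- do.call(rbind, lapply(1:10, function(i) data.frame(
    breath_id = i, phase = c("inspiration", "expiration"),
    si_100_300 = 0.7, si_300_500 = 0.15, si_500_800 = 0.1,
    si_800_1000 = 0.05, raw_intensity = 1, breath_intensity = 2,
    outlier = FALSE)))
  mm <- match_multimodal_breaths(timing, ac)
  expect_equal(nrow(mm), 10)
  expect_setequal(setdiff(names(mm), c("breath_id", "insp_onset")),
                  multimodal_feature_names())
  expect_length(multimodal_feature_names(), 13)

  # breath failing only the acoustic filter is absent
  ac$outlier[ac$breath_id == 4] <- TRUE
  expect_false(4 %in% match_multimodal_breaths(timing, ac)$breath_id)

  # disjoint sets: empty, with a message
  timing2 <- timing; timing2$breath_id <- 101:110
  expect_message(mm2 <- match_multimodal_breaths(timing2, ac),
                 "no breaths")
  expect_equal(nrow(mm2), 0)
})
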