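# Synthetic recording generator: quasi-periodic impedance-pneumography
# (IP) traces with known breath timings, phase-locked band-limited
# lung-sound audio, and whole labeled cohorts. Every downstream stage of
# the pipeline is validated against the ground truth these functions
# emit.

#' Describe the breaths of a synthetic impedance recording
#'
#' The impedance waveform rises over each inspiration and falls over each
#' expiration as raised-cosine half-cycles of unequal half-periods; the
#' pipeline itself never depends on this exact shape.
#'
#' @param ti,te inspiration / expiration durations in seconds (vectors,
#'   recycled to cover the requested duration).
#' @param amplitude peak-to-trough respiratory excursion (ohm). The
#'   physical excursion amplitude is treated as a free parameter.
#' @param baseline_ohm static transthoracic impedance level (ohm).
#' @param drift_amplitude amplitude of a slow sinusoidal baseline drift
#'   (ohm); `drift_period_s` its period.
#' @param noise_sd standard deviation of additive Gaussian noise (ohm).
#' @param artifacts data frame with columns `onset`, `duration`
#'   (seconds) and `scale`: transient events that multiply the local
#'   signal, emulating loosened-lead movement artifacts.
#' @param seed integer seed making generation reproducible.
#' @return object of class `breath_plan`.
#' @export
breath_plan <- function(ti, te, amplitude = 1, baseline_ohm = 400,
                        drift_amplitude = 0, drift_period_s = 60,
                        noise_sd = 0, artifacts = NULL, seed = 1L) {
  if (any(ti <= 0) || any(te <= 0)) stop("Ti and Te must be positive")
  if (any(amplitude <= 0)) stop("amplitudes must be positive")
  if (!is.null(artifacts)) {
    stopifnot(all(c("onset", "duration", "scale") %in% names(artifacts)))
    if (any(artifacts$scale == 1)) stop("artifact scale must differ from 1")
  }
  structure(list(ti = ti, te = te, amplitude = amplitude,
                 baseline_ohm = baseline_ohm,
                 drift_amplitude = drift_amplitude,
                 drift_period_s = drift_period_s,
                 noise_sd = noise_sd, artifacts = artifacts,
                 seed = as.integer(seed)),
            class = "breath_plan")
}

#' Generate a synthetic impedance-pneumography trace
#'
#' @param plan a [breath_plan()].
#' @param fs sampling rate in Hz (16 Hz emulates the wearable's raw
#'   bioimpedance stream).
#' @param duration_s recording length in seconds; must cover at least
#'   three breaths.
#' @return list with `trace` (an [impedance_trace()]) and `truth`, a
#'   data frame of per-breath ground truth (`insp_onset`, `exp_onset`,
#'   `breath_end`, `ti`, `te`, `ibi`, `rr`).
#' @export
generate_ip <- function(plan, fs = 16, duration_s = 300) {
  stopifnot(inherits(plan, "breath_plan"))
  if (!is.numeric(fs) || fs < 16) stop("`fs` must be at least 16 Hz")
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("`duration_s` must be positive")
  nb_guess <- ceiling(duration_s / min(plan$ti + plan$te)) + 2
  ti <- rep_len(plan$ti, nb_guess)
  te <- rep_len(plan$te, nb_guess)
  amp <- rep_len(plan$amplitude, nb_guess)
  onsets <- c(0, cumsum(ti + te))[seq_len(nb_guess)]
  keep <- onsets + ti + te <= duration_s
  if (sum(keep) < 3) stop("duration must cover at least 3 breaths")
  ti <- ti[keep]; te <- te[keep]; amp <- amp[keep]; onsets <- onsets[keep]
  truth <- data.frame(
    breath_id = seq_along(onsets),
    insp_onset = onsets, exp_onset = onsets + ti,
    breath_end = onsets + ti + te,
    ti = ti, te = te, ibi = ti + te, rr = 60 / (ti + te))

  t <- seq(0, duration_s, by = 1 / fs)
  x <- numeric(length(t))
  idx <- findInterval(t, onsets)
  inside <- idx >= 1 & t < onsets[pmin(idx, length(onsets))] +
    ti[pmin(idx, length(onsets))] + te[pmin(idx, length(onsets))]
  ii <- pmax(idx, 1)
  rel <- t - onsets[ii]
  rise <- rel < ti[ii]
  x[inside & rise] <- (amp[ii] * (1 - cos(pi * rel / ti[ii])) / 2)[inside & rise]
  fall <- !rise
  x[inside & fall] <-
    (amp[ii] * (1 + cos(pi * (rel - ti[ii]) / te[ii])) / 2)[inside & fall]
  x <- x + plan$baseline_ohm
  if (plan$drift_amplitude != 0)
    x <- x + plan$drift_amplitude * sin(2 * pi * t / plan$drift_period_s)
  if (plan$noise_sd > 0)
    x <- x + with_seed(plan$seed, stats::rnorm(length(t), 0, plan$noise_sd))
  if (!is.null(plan$artifacts)) {
    for (j in seq_len(nrow(plan$artifacts))) {
      a <- plan$artifacts[j, ]
      sel <- t >= a$onset & t < a$onset + a$duration
      x[sel] <- x[sel] * a$scale
    }
  }
  list(trace = impedance_trace(x, fs), truth = truth)
}

#' Describe the acoustic content of a synthetic lung-sound recording
#'
#' Breath sounds are modeled as band-limited Gaussian noise whose
#' envelope is gated by the breathing phase (normal lung sounds are
#' inspiration-dominant), optionally with tonal wheeze components and
#' per-phase subband spectral shaping.
#'
#' @param base_noise_band numeric length-2, noise band in Hz.
#' @param base_level RMS amplitude of expiratory noise (normalized
#'   units); 0 gives silence.
#' @param inspiration_gain_db inspiratory gain relative to expiration in
#'   dB (+6 dB means 4x the power).
#' @param wheezes data frame with columns `freq` (Hz), `phase`
#'   (`"inspiration"`/`"expiration"`) and `snr_db` (tone power relative
#'   to the same-phase noise power).
#' @param band_weights_insp,band_weights_exp optional length-4 vectors of
#'   relative spectral power over the canonical subbands 100-300,
#'   300-500, 500-800 and 800-1000 Hz, used to shape each phase's noise
#'   spectrum (normalized internally). `NULL` gives a flat spectrum over
#'   `base_noise_band`.
#' @param fs audio sampling rate (Hz).
#' @param seed integer seed.
#' @return object of class `acoustic_spec`.
#' @export
acoustic_spec <- function(base_noise_band = c(100, 1000), base_level = 0.05,
                          inspiration_gain_db = 6, wheezes = NULL,
                          band_weights_insp = NULL, band_weights_exp = NULL,
                          fs = 4000, seed = 1L) {
  stopifnot(length(base_noise_band) == 2, base_noise_band[1] > 0,
            is.finite(inspiration_gain_db))
  if (base_noise_band[2] >= fs / 2)
    stop("noise band must lie below the Nyquist frequency")
  if (!is.null(wheezes)) {
    stopifnot(all(c("freq", "phase", "snr_db") %in% names(wheezes)))
    if (any(wheezes$freq >= fs / 2))
      stop("wheeze frequency at or above Nyquist")
    if (!all(wheezes$phase %in% c("inspiration", "expiration")))
      stop("wheeze phase must be 'inspiration' or 'expiration'")
  }
  for (w in list(band_weights_insp, band_weights_exp))
    if (!is.null(w)) stopifnot(length(w) == 4, all(w >= 0), sum(w) > 0)
  structure(list(base_noise_band = base_noise_band, base_level = base_level,
                 inspiration_gain_db = inspiration_gain_db,
                 wheezes = wheezes,
                 band_weights_insp = band_weights_insp,
                 band_weights_exp = band_weights_exp,
                 fs = fs, seed = as.integer(seed)),
            class = "acoustic_spec")
}

# Spectrally shaped unit-RMS Gaussian noise. `weights` spreads power
# over the four canonical subbands; NULL gives a flat band.
shaped_noise <- function(n, fs, band, weights = NULL) {
  n_out <- n
  n <- stats::nextn(n, c(2, 3, 5))  # keep the FFT length smooth
  x <- stats::rnorm(n)
  sp <- stats::fft(x)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)  # mirror for the negative-frequency half
  gain <- numeric(n)
  if (is.null(weights)) {
    gain[freq >= band[1] & freq <= band[2]] <- 1
  } else {
    bands <- si_band_edges()
    w <- weights / sum(weights)
    for (b in seq_len(4)) {
      sel <- freq >= bands[b, 1] & freq < bands[b, 2]
      if (b == 4) sel <- freq >= bands[b, 1] & freq <= bands[b, 2]
      gain[sel] <- sqrt(w[b] / (bands[b, 2] - bands[b, 1]))
    }
  }
  y <- Re(stats::fft(sp * gain, inverse = TRUE))[seq_len(n_out)] / n
  r <- sqrt(mean(y^2))
  if (r > 0) y / r else y
}

# Phase masks (inspiration, expiration) over the audio time grid with
# raised-cosine cross-fades at phase boundaries to avoid clicks.
phase_masks <- function(t, truth, ramp_s = 0.05) {
  m_i <- numeric(length(t))
  for (j in seq_len(nrow(truth))) {
    b <- truth[j, ]
    m_i <- m_i + ramp_box(t, b$insp_onset, b$exp_onset, ramp_s)
  }
  m_i <- pmin(m_i, 1)
  list(insp = m_i, exp = 1 - m_i)
}

# Smooth indicator of [a, b) with half-cosine edges of width `ramp`.
ramp_box <- function(t, a, b, ramp) {
  up <- (t - (a - ramp / 2)) / ramp
  dn <- ((b + ramp / 2) - t) / ramp
  pmax(0, pmin(1, up, dn))
}

#' Generate phase-locked synthetic lung-sound audio
#'
#' @param truth ground-truth breath table from [generate_ip()].
#' @param spec an [acoustic_spec()].
#' @param duration_s audio length in seconds.
#' @return an [audio_trace()] sampled at `spec$fs`.
#' @export
generate_lung_sound <- function(truth, spec, duration_s) {
  stopifnot(inherits(spec, "acoustic_spec"))
  if (max(truth$breath_end) > duration_s + 1e-9)
    warning("ground truth extends past the requested audio duration")
  fs <- spec$fs
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  g <- 10^(spec$inspiration_gain_db / 20)
  masks <- phase_masks(t, truth)
  out <- with_seed(spec$seed, {
    y <- numeric(n)
    if (spec$base_level > 0) {
      same_shape <- is.null(spec$band_weights_insp) &&
        is.null(spec$band_weights_exp)
      if (same_shape) {
        nz <- shaped_noise(n, fs, spec$base_noise_band)
        y <- spec$base_level * (masks$exp + g * masks$insp) * nz
      } else {
        ni <- shaped_noise(n, fs, spec$base_noise_band, spec$band_weights_insp)
        ne <- shaped_noise(n, fs, spec$base_noise_band, spec$band_weights_exp)
        y <- spec$base_level * (g * masks$insp * ni + masks$exp * ne)
      }
    }
    if (!is.null(spec$wheezes)) {
      for (j in seq_len(nrow(spec$wheezes))) {
        wz <- spec$wheezes[j, ]
        lvl <- spec$base_level * (if (wz$phase == "inspiration") g else 1)
        if (lvl == 0) lvl <- 0.05  # audible tone even over silence
        a <- sqrt(2 * lvl^2 * 10^(wz$snr_db / 10))
        mask <- if (wz$phase == "inspiration") masks$insp else masks$exp
        ph <- stats::runif(1, 0, 2 * pi)
        y <- y + a * mask * sin(2 * pi * wz$freq * t + ph)
      }
    }
    y
  })
  audio_trace(out, fs)
}
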