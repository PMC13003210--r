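# Whole-cohort simulation: labeled multimodal recordings whose
# group-level feature distributions mimic an acute-asthma admission
# (T1), pre-discharge (T2) and healthy-control contrast. Patients carry
# a persistent participant effect so T1/T2 recordings are genuinely
# paired.

#' Feature targets for one simulated group
#'
#' @param rr_bpm target median respiratory rate (breaths/min).
#' @param ti_ibi target inspiratory duty cycle Ti/IBI.
#' @param si_insp,si_exp length-4 relative spectral power targets over
#'   the subbands 100-300/300-500/500-800/800-1000 Hz for the
#'   inspiratory and expiratory phase (normalized internally).
#' @param inspiration_gain_db inspiratory acoustic gain (dB).
#' @return object of class `group_profile`.
#' @export
group_profile <- function(rr_bpm, ti_ibi, si_insp, si_exp,
                          inspiration_gain_db = 6) {
  if (rr_bpm <= 0) stop("respiratory-rate target must be positive")
  if (ti_ibi <= 0 || ti_ibi >= 1) stop("ti_ibi must lie in (0, 1)")
  stopifnot(length(si_insp) == 4, length(si_exp) == 4,
            all(si_insp >= 0), all(si_exp >= 0))
  structure(list(rr_bpm = rr_bpm, ti_ibi = ti_ibi,
                 si_insp = si_insp / sum(si_insp),
                 si_exp = si_exp / sum(si_exp),
                 inspiration_gain_db = inspiration_gain_db),
            class = "group_profile")
}

#' Built-in group profiles for the acute-asthma contrast
#'
#' Median feature targets for an admission-like (T1), pre-discharge-like
#' (T2) and healthy-control-like group: tachypneic breathing with
#' low-frequency-dominant (wheeze-like) spectra at admission, slower
#' breathing with a flatter lung-sound spectrum and longer relative
#' expiration in controls, and T2 intermediate.
#'
#' @return named list of [group_profile()] objects (`T1`, `T2`,
#'   `control`).
#' @export
asthma_cohort_profiles <- function() {
  list(
    T1 = group_profile(35.04, 0.48,
                       si_insp = c(0.820, 0.100, 0.062, 0.021),
                       si_exp  = c(0.806, 0.112, 0.063, 0.024)),
    T2 = group_profile(32.34, 0.47,
                       si_insp = c(0.757, 0.123, 0.075, 0.034),
                       si_exp  = c(0.768, 0.124, 0.077, 0.028)),
    control = group_profile(22.37, 0.41,
                            si_insp = c(0.678, 0.155, 0.121, 0.045),
                            si_exp  = c(0.695, 0.155, 0.116, 0.044)))
}

#' Describe a synthetic cohort
#'
#' @param groups named list; each element is a list with `n` (group
#'   size), `profile` (a [group_profile()]) and `time_point`
#'   (`"T1"`, `"T2"` or `"single"`). Groups named `T1`/`T2` share
#'   participant identities (first `n` patients each), making paired
#'   analyses meaningful.
#' @param duration_s length of each recording (seconds).
#' @param subject_rr_cv,subject_si_sd between-participant lognormal
#'   variability of the RR target and log-scale variability of the
#'   subband weights.
#' @param breath_jitter_cv within-recording breath-to-breath timing
#'   jitter (coefficient of variation).
#' @param noise_sd_ohm,drift_amplitude_ohm impedance noise and baseline
#'   drift.
#' @param seed integer master seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, duration_s = 180, subject_rr_cv = 0.06,
                        subject_si_sd = 0.10, breath_jitter_cv = 0.03,
                        noise_sd_ohm = 0.02, drift_amplitude_ohm = 0.3,
                        seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)))
  for (g in groups) {
    if (!is.numeric(g$n) || g$n < 1) stop("group sizes must be >= 1")
    if (!inherits(g$profile, "group_profile"))
      stop("each group needs a `group_profile`")
  }
  structure(list(groups = groups, duration_s = duration_s,
                 subject_rr_cv = subject_rr_cv,
                 subject_si_sd = subject_si_sd,
                 breath_jitter_cv = breath_jitter_cv,
                 noise_sd_ohm = noise_sd_ohm,
                 drift_amplitude_ohm = drift_amplitude_ohm,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Convenience spec for the built-in asthma-contrast cohort
#'
#' @param n_t1,n_t2,n_control group sizes (matched-cohort-like defaults).
#' @param duration_s recording length in seconds.
#' @param seed integer master seed.
#' @export
asthma_cohort_spec <- function(n_t1 = 10, n_t2 = 7, n_control = 9,
                               duration_s = 180, seed = 1L) {
  pr <- asthma_cohort_profiles()
  cohort_spec(groups = list(
    T1 = list(n = n_t1, profile = pr$T1, time_point = "T1"),
    T2 = list(n = n_t2, profile = pr$T2, time_point = "T2"),
    control = list(n = n_control, profile = pr$control,
                   time_point = "single")),
    duration_s = duration_s, seed = seed)
}

#' Generate a labeled synthetic cohort of multimodal recordings
#'
#' @param spec a [cohort_spec()].
#' @return list of recordings; each has `id`, `participant_id`, `group`
#'   (`patient`/`control`), `time_point`, `bioz` (an
#'   [impedance_trace()]), `audio` (an [audio_trace()]) and `truth`.
#'   The manifest data frame is attached as attribute `"manifest"`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  recs <- list()
  manifest <- NULL
  # patient participant effects persist across T1/T2 groups
  patient_groups <- names(spec$groups)[names(spec$groups) %in% c("T1", "T2")]
  n_patients <- if (length(patient_groups))
    max(vapply(spec$groups[patient_groups], function(g) g$n, 0)) else 0
  subj_effect <- function(subj_seed) with_seed(subj_seed, list(
    rr_mult = exp(stats::rnorm(1, 0, spec$subject_rr_cv)),
    ti_shift = stats::rnorm(1, 0, 0.012),
    si_log_i = stats::rnorm(4, 0, spec$subject_si_sd),
    si_log_e = stats::rnorm(4, 0, spec$subject_si_sd)))
  k <- 0L
  for (gname in names(spec$groups)) {
    g <- spec$groups[[gname]]
    is_patient <- gname %in% c("T1", "T2")
    for (i in seq_len(g$n)) {
      k <- k + 1L
      pid <- if (is_patient) sprintf("P%02d", i) else sprintf("C%02d", i)
      # deterministic per-(participant, time point) seeds below 2^31
      subj_seed <- (spec$seed * 977L + (if (is_patient) i else 500L + i)) %%
        .Machine$integer.max
      rec_seed <- (spec$seed * 7919L + k * 131L) %% .Machine$integer.max
      eff <- subj_effect(subj_seed)
      pr <- g$profile
      pars <- with_seed(rec_seed, {
        rr <- pr$rr_bpm * eff$rr_mult * exp(stats::rnorm(1, 0, 0.03))
        ti_ibi <- min(0.9, max(0.1,
          pr$ti_ibi + eff$ti_shift + stats::rnorm(1, 0, 0.008)))
        wi <- pr$si_insp * exp(eff$si_log_i + stats::rnorm(4, 0, 0.04))
        we <- pr$si_exp * exp(eff$si_log_e + stats::rnorm(4, 0, 0.04))
        ibi <- 60 / rr
        nb <- ceiling(spec$duration_s / ibi) + 2
        jit <- exp(stats::rnorm(nb, 0, spec$breath_jitter_cv))
        list(ti = ibi * ti_ibi * jit,
             te = ibi * (1 - ti_ibi) * rep_len(rev(jit), nb),
             wi = wi / sum(wi), we = we / sum(we))
      })
      plan <- breath_plan(pars$ti, pars$te, amplitude = 1,
                          drift_amplitude = spec$drift_amplitude_ohm,
                          noise_sd = spec$noise_sd_ohm,
                          seed = rec_seed)
      ip <- generate_ip(plan, fs = 16, duration_s = spec$duration_s)
      aspec <- acoustic_spec(base_level = 0.05,
                             inspiration_gain_db = pr$inspiration_gain_db,
                             band_weights_insp = pars$wi,
                             band_weights_exp = pars$we,
                             seed = (rec_seed + 1L) %% .Machine$integer.max)
      audio <- generate_lung_sound(ip$truth, aspec, spec$duration_s)
      rid <- sprintf("%s_%s", pid, g$time_point)
      recs[[rid]] <- list(id = rid, participant_id = pid,
                          group = if (is_patient) "patient" else "control",
                          time_point = g$time_point,
                          bioz = ip$trace, audio = audio,
                          truth = ip$truth)
      manifest <- rbind(manifest, data.frame(
        id = rid, participant_id = pid,
        group = if (is_patient) "patient" else "control",
        time_point = g$time_point, duration_s = spec$duration_s,
        stringsAsFactors = FALSE))
    }
  }
  attr(recs, "manifest") <- manifest
  recs
}
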