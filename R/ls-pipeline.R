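# Lung-sound branch: audio conditioning, IP-driven breathing-phase
# segmentation, phase-specific subband spectral integrated intensities
# (SIs) and the acoustic outlier filter.

#' Canonical SI subband edges
#'
#' The four subbands 100-300, 300-500, 500-800 and 800-1000 Hz form an
#' exact partition of 100-1000 Hz: each band is half-open \[low, high)
#' except the last, which closes at 1000 Hz. This makes the four
#' normalized SIs of any phase sum to exactly one.
#'
#' @return 4x2 matrix of band edges in Hz.
#' @export
si_band_edges <- function() {
  matrix(c(100, 300, 300, 500, 500, 800, 800, 1000),
         ncol = 2, byrow = TRUE,
         dimnames = list(c("100_300", "300_500", "500_800", "800_1000"),
                         c("low", "high")))
}

#' Resample lung-sound audio
#'
#' FIR-antialiased resampling to the processing rate (4 kHz by default;
#' raw wearable audio is nominally 46.875 kHz).
#'
#' @param audio an [audio_trace()].
#' @param target_hz output rate.
#' @param allow_upsample permit `target_hz` above the input rate.
#' @return resampled [audio_trace()].
#' @export
resample_audio <- function(audio, target_hz = 4000,
                           allow_upsample = FALSE) {
  stopifnot(inherits(audio, "audio_trace"))
  if (target_hz > audio$fs && !allow_upsample)
    stop("refusing to upsample audio (set allow_upsample = TRUE)")
  if (target_hz == audio$fs) return(audio)
  r <- fir_resample(audio$samples, audio$fs, target_hz)
  audio_trace(r$samples, r$fs, audio$channel)
}

#' Band-pass filter lung-sound audio
#'
#' Zero-phase FIR band-pass, 100-1000 Hz by default: the low cutoff
#' suppresses heart-sound interference, the high cutoff suppresses
#' speech/room noise while keeping normal and adventitious breath-sound
#' energy.
#'
#' @param audio an [audio_trace()].
#' @param low,high band edges in Hz.
#' @param atten_db stopband attenuation (dB).
#' @return filtered [audio_trace()].
#' @export
bandpass_audio <- function(audio, low = 100, high = 1000,
                           atten_db = 60) {
  stopifnot(inherits(audio, "audio_trace"))
  if (high >= audio$fs / 2) stop("high edge must be below Nyquist")
  n <- kaiser_order(atten_db, 0.5 * low, audio$fs)
  h <- fir_design(n, c(low, high), audio$fs, "kaiser",
                  kaiser_beta(atten_db))
  audio_trace(fir_filter_zerophase(audio$samples, h), audio$fs,
              audio$channel)
}

#' Segment audio into breathing phases using IP-derived timings
#'
#' For each good-quality, non-outlier breath, the inspiration interval
#' is \[inspiration onset, expiration onset) and the expiration interval
#' \[expiration onset, breath end), converted to half-open audio sample
#' index ranges. Audio and segmentation are assumed to share a clock.
#'
#' @param audio an [audio_trace()].
#' @param seg breath segmentation (quality/outlier flags respected; set
#'   `all_breaths = TRUE` to ignore the flags).
#' @param all_breaths include breaths failing upstream filters.
#' @return data frame: `breath_id`, `phase`, `start_sample`,
#'   `end_sample` (1-based, half-open \[start, end)).
#' @export
segment_phases <- function(audio, seg, all_breaths = FALSE) {
  stopifnot(inherits(audio, "audio_trace"))
  n <- length(audio$samples); fs <- audio$fs
  use <- if (all_breaths) rep(TRUE, nrow(seg)) else
    !is.na(seg$quality_ok) & seg$quality_ok & !seg$outlier
  s <- seg[use, , drop = FALSE]
  if (nrow(s) == 0)
    return(data.frame(breath_id = integer(0), phase = character(0),
                      start_sample = integer(0), end_sample = integer(0)))
  out <- data.frame(
    breath_id = rep(s$breath_id, each = 2),
    phase = rep(c("inspiration", "expiration"), nrow(s)),
    start_sample = as.integer(rbind(round(s$insp_onset * fs),
                                    round(s$exp_onset * fs))) + 1L,
    end_sample = as.integer(rbind(round(s$exp_onset * fs),
                                  round(s$breath_end * fs))) + 1L)
  dropped <- unique(out$breath_id[out$end_sample > n + 1L])
  if (length(dropped)) {
    message(sprintf("dropping %d breath(s) extending past the audio end",
                    length(dropped)))
    out <- out[!out$breath_id %in% dropped, , drop = FALSE]
  }
  out
}

#' Normalized subband spectral integrated intensities of one segment
#'
#' PSD estimates are computed over 64-ms Hamming windows with 75%
#' overlap (modified periodograms). Each window's PSD is normalized to 1
#' by its maximum, integrated (rectangle rule over FFT bins, bins
#' assigned to bands by centre frequency) over each subband and divided
#' by the integral over 100-1000 Hz; the per-window SIs are then
#' averaged across the segment's windows. `raw_intensity` is the
#' unnormalized cumulative 100-1000 Hz PSD integral summed over windows.
#'
#' @param samples audio samples of one breathing-phase segment.
#' @param fs sampling rate (Hz).
#' @param win_ms analysis window in milliseconds.
#' @param overlap fractional window overlap.
#' @return one-row data frame `si_100_300 ... si_800_1000`,
#'   `raw_intensity`, `n_windows`; `NA` SIs when the segment is shorter
#'   than one analysis window or has no in-band energy.
#' @export
compute_phase_si <- function(samples, fs = 4000, win_ms = 64,
                             overlap = 0.75) {
  nwin <- round(win_ms / 1000 * fs)
  hop <- max(1L, round(nwin * (1 - overlap)))
  st <- stft_psd(samples, fs, nwin, hop)
  empty <- data.frame(si_100_300 = NA_real_, si_300_500 = NA_real_,
                      si_500_800 = NA_real_, si_800_1000 = NA_real_,
                      raw_intensity = NA_real_, n_windows = 0L)
  if (st$nframes == 0) return(empty)
  bands <- si_band_edges()
  df <- st$freq[2] - st$freq[1]
  total_sel <- st$freq >= 100 & st$freq <= 1000
  band_sel <- lapply(seq_len(4), function(b) {
    if (b == 4) st$freq >= bands[b, 1] & st$freq <= bands[b, 2]
    else st$freq >= bands[b, 1] & st$freq < bands[b, 2]
  })
  pk <- apply(st$psd, 2, max)
  valid <- pk > 0
  if (!any(valid)) return(empty)
  pn <- sweep(st$psd[, valid, drop = FALSE], 2, pk[valid], "/")
  tot <- colSums(pn[total_sel, , drop = FALSE]) * df
  si <- vapply(band_sel, function(sel)
    mean(colSums(pn[sel, , drop = FALSE]) * df / tot), numeric(1))
  raw <- sum(colSums(st$psd[total_sel, , drop = FALSE]) * df)
  data.frame(si_100_300 = si[1], si_300_500 = si[2],
             si_500_800 = si[3], si_800_1000 = si[4],
             raw_intensity = raw, n_windows = sum(valid))
}

#' Phase-contextualized acoustic features for every segmented breath
#'
#' @param audio conditioned [audio_trace()].
#' @param phases phase table from [segment_phases()].
#' @param win_ms,overlap PSD analysis window parameters.
#' @return `phase_acoustics` data frame: one row per (breath, phase)
#'   with the four SIs, the phase `raw_intensity`, the breath-level
#'   `breath_intensity` (both phases combined) and an `outlier` flag.
#' @export
compute_breath_acoustics <- function(audio, phases, win_ms = 64,
                                     overlap = 0.75) {
  stopifnot(inherits(audio, "audio_trace"))
  if (nrow(phases) == 0)
    return(cbind(phases[, c("breath_id", "phase")],
                 si_100_300 = numeric(0), si_300_500 = numeric(0),
                 si_500_800 = numeric(0), si_800_1000 = numeric(0),
                 raw_intensity = numeric(0), breath_intensity = numeric(0),
                 outlier = logical(0)))
  rows <- lapply(seq_len(nrow(phases)), function(i) {
    p <- phases[i, ]
    seg <- audio$samples[p$start_sample:(p$end_sample - 1L)]
    cbind(p[, c("breath_id", "phase")],
          compute_phase_si(seg, audio$fs, win_ms, overlap))
  })
  out <- do.call(rbind, rows)
  short <- unique(out$breath_id[is.na(out$raw_intensity)])
  if (length(short))
    message(sprintf("%d phase segment(s) shorter than one PSD window; breaths dropped", length(short)))
  out <- out[!out$breath_id %in% short, , drop = FALSE]
  bi <- tapply(out$raw_intensity, out$breath_id, sum)
  out$breath_intensity <- as.numeric(bi[as.character(out$breath_id)])
  out$outlier <- FALSE
  rownames(out) <- NULL
  out
}

#' Flag acoustically outlying breaths with a sliding MAD filter
#'
#' Operates on the three unnormalized cumulative intensities (breath
#' level, inspiratory, expiratory): a breath is an outlier when any of
#' them deviates more than `k` MADs from the median of its centered
#' 30-breath window.
#'
#' @param acoustics output of [compute_breath_acoustics()].
#' @param k MAD multiplier (4 by convention for the acoustic cascade).
#' @param window window length in breaths.
#' @param scaled use the 1.4826-scaled MAD.
#' @return `acoustics` with `outlier` filled in.
#' @export
remove_acoustic_outliers <- function(acoustics, k = 4, window = 30,
                                     scaled = TRUE) {
  if (nrow(acoustics) == 0) return(acoustics)
  ids <- unique(acoustics$breath_id)
  insp <- acoustics[acoustics$phase == "inspiration", ]
  expi <- acoustics[acoustics$phase == "expiration", ]
  s_b <- acoustics$breath_intensity[match(ids, acoustics$breath_id)]
  s_i <- insp$raw_intensity[match(ids, insp$breath_id)]
  s_e <- expi$raw_intensity[match(ids, expi$breath_id)]
  fl <- mad_outlier_flags(s_b, k, window, scaled) |
    mad_outlier_flags(s_i, k, window, scaled) |
    mad_outlier_flags(s_e, k, window, scaled)
  acoustics$outlier <- fl[match(acoustics$breath_id, ids)]
  acoustics
}

#' Join timing and acoustic features into the multimodal breath table
#'
#' Inner join on breath identity of breaths surviving both the
#' timing-feature filters (quality + 5-MAD) and the acoustic 4-MAD
#' filter; each row carries the 13-feature multimodal vector: 5 timing
#' features and 4 SIs for each breathing phase.
#'
#' @param timing timing features (after [remove_timing_outliers()]).
#' @param acoustics phase acoustics (after [remove_acoustic_outliers()]).
#' @return data frame with `breath_id`, `insp_onset` and the 13 feature
#'   columns `RR, Ti, Te, TeTi, TiIBI, SI100_300_I, ... SI800_1000_E`.
#' @export
match_multimodal_breaths <- function(timing, acoustics) {
  tok <- timing[!timing$outlier &
                  (!is.na(timing$quality_ok) & timing$quality_ok),
                , drop = FALSE]
  aok <- acoustics[!acoustics$outlier, , drop = FALSE]
  insp <- aok[aok$phase == "inspiration", ]
  expi <- aok[aok$phase == "expiration", ]
  ids <- intersect(intersect(tok$breath_id, insp$breath_id),
                   expi$breath_id)
  if (length(ids) == 0) {
    message("no breaths survive both pipelines; empty multimodal table")
  }
  ti <- tok[match(ids, tok$breath_id), ]
  ii <- insp[match(ids, insp$breath_id), ]
  ee <- expi[match(ids, expi$breath_id), ]
  out <- data.frame(
    breath_id = ids, insp_onset = ti$insp_onset,
    RR = ti$RR, Ti = ti$Ti, Te = ti$Te, TeTi = ti$TeTi, TiIBI = ti$TiIBI,
    SI100_300_I = ii$si_100_300, SI300_500_I = ii$si_300_500,
    SI500_800_I = ii$si_500_800, SI800_1000_I = ii$si_800_1000,
    SI100_300_E = ee$si_100_300, SI300_500_E = ee$si_300_500,
    SI500_800_E = ee$si_500_800, SI800_1000_E = ee$si_800_1000)
  rownames(out) <- NULL
  out
}

#' Names of the 13 multimodal features
#' @export
multimodal_feature_names <- function() {
  c("RR", "Ti", "Te", "TeTi", "TiIBI",
    "SI100_300_I", "SI300_500_I", "SI500_800_I", "SI800_1000_I",
    "SI100_300_E", "SI300_500_E", "SI500_800_E", "SI800_1000_E")
}
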