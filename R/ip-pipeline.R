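# Impedance-pneumography branch: conditioning, breath detection,
# signal-quality assessment and per-breath respiratory timing features.
#
# Breath fiducials follow the standard IP convention: impedance rises on
# inhalation, so an interbreath interval (IBI) runs trough-to-trough
# with the intervening peak marking the inspiration-to-expiration
# transition. This makes Ti + Te = IBI exact by construction.

#' Resample an impedance trace to the processing rate
#'
#' FIR-antialiased resampling to 100 Hz (the raw wearable stream is
#' 16 Hz).
#'
#' @param trace an [impedance_trace()].
#' @param target_hz output rate, default 100 Hz.
#' @return resampled [impedance_trace()].
#' @export
resample_to_100hz <- function(trace, target_hz = 100) {
  stopifnot(inherits(trace, "impedance_trace"))
  if (length(trace$samples) < 2) stop("trace too short to resample")
  r <- fir_resample(trace$samples, trace$fs, target_hz)
  impedance_trace(r$samples, r$fs, trace$excitation_khz)
}

#' Remove transient amplitude artifacts from a bioimpedance trace
#'
#' Samples above `hi` times or below `lo` times the whole-recording
#' median (computed before any replacement) are removed and refilled by
#' linear interpolation between the nearest surviving samples; flagged
#' runs touching the recording edges are extended from the nearest
#' surviving value. Such transients typically come from movement briefly
#' loosening an electrode lead.
#'
#' @param trace an [impedance_trace()].
#' @param hi,lo multiplicative thresholds on the recording median.
#' @return an [impedance_trace()] with `interpolated` marking
#'   replacements.
#' @export
remove_amplitude_artifacts <- function(trace, hi = 1.5, lo = 0.5) {
  stopifnot(inherits(trace, "impedance_trace"))
  x <- trace$samples
  if (length(x) < 3) stop("trace must have at least 3 samples")
  med <- stats::median(x)
  bad <- x > hi * med | x < lo * med
  if (all(bad)) stop("all samples flagged as artifacts; no anchor points")
  if (any(bad)) {
    good <- which(!bad)
    x[bad] <- stats::approx(good, x[good], xout = which(bad),
                            rule = 2)$y
  }
  impedance_trace(x, trace$fs, trace$excitation_khz,
                  interpolated = bad | trace$interpolated)
}

#' Band-pass filter the respiratory impedance signal
#'
#' Zero-phase Kaiser-window FIR band-pass in the respiratory band
#' (nominally 0.1-1 Hz, i.e. 6-60 breaths/min). The upper edge can be
#' raised to 1.4 Hz for recordings with a clear dominant frequency above
#' 1 Hz; values outside \[1.0, 1.4\] are executed with a warning.
#'
#' @param trace an [impedance_trace()] (conditioned, 100 Hz).
#' @param f_lo,f_hi band edges in Hz.
#' @param atten_db stopband attenuation (dB).
#' @return filtered [impedance_trace()] (zero-mean).
#' @export
bandpass_ip <- function(trace, f_lo = 0.1, f_hi = 1.0, atten_db = 50) {
  stopifnot(inherits(trace, "impedance_trace"))
  if (f_lo >= f_hi || f_hi >= trace$fs / 2)
    stop("need f_lo < f_hi < fs/2")
  if (f_hi < 1.0 || f_hi > 1.4)
    warning(sprintf("upper band edge %.2f Hz outside the nominal [1.0, 1.4] Hz range", f_hi))
  # transition width trades stopband sharpness against kernel length
  # (and hence edge-transient extent); 1.5 f_lo keeps the stopband edge
  # strictly above DC while halving the ringing time of a tight design
  n <- kaiser_order(atten_db, 1.5 * f_lo, trace$fs)
  n <- min(n, 2 * floor((length(trace$samples) - 1) / 2) + 1)
  h <- fir_design(n, c(f_lo, f_hi), trace$fs, "kaiser",
                  kaiser_beta(atten_db))
  y <- fir_filter_zerophase(trace$samples - mean(trace$samples), h)
  impedance_trace(y, trace$fs, trace$excitation_khz, trace$interpolated)
}

# Local maxima of x with a minimum separation, enforced greedily from
# the largest candidate down; candidates below `min_height` are ignored
# (suppresses filter-ripple microstructure on breath slopes).
find_peaks <- function(x, min_dist, min_height = -Inf) {
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1
  cand <- cand[x[cand] >= min_height]
  if (length(cand) == 0) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= min_dist)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Detect breaths in a filtered impedance-pneumography signal
#'
#' Peaks (end-inspiration) are detected on 32-second windows advanced so
#' consecutive windows overlap by 2 seconds, with a minimum inter-peak
#' distance of 0.67 s (capping detectable rates at 89.55 breaths/min).
#' Window-level peak sets are merged by deduplicating peaks closer than
#' `dedup_s` (below half the minimum IBI, so distinct breaths cannot
#' collide), the minimum distance is re-enforced globally, and breath
#' boundaries are placed at the signal minima between consecutive peaks.
#'
#' @param ip filtered [impedance_trace()].
#' @param win_s analysis window length (s).
#' @param overlap_s overlap between consecutive windows (s).
#' @param min_peak_dist_s minimum distance between breath peaks (s).
#' @param dedup_s peak deduplication tolerance when merging windows (s).
#' @param raw optional conditioned pre-bandpass [impedance_trace()] on
#'   the same grid: each detected extremum is then refined to the local
#'   extremum of a lightly low-passed copy, recovering phase-transition
#'   timing that the narrow respiratory band-pass smears on asymmetric
#'   breaths.
#' @return `breath_segmentation` data frame: `breath_id`, `insp_onset`,
#'   `exp_onset`, `breath_end` (seconds), `quality_ok`, `outlier`.
#' @export
detect_breaths <- function(ip, win_s = 32, overlap_s = 2,
                           min_peak_dist_s = 0.67, dedup_s = 0.25,
                           raw = NULL) {
  stopifnot(inherits(ip, "impedance_trace"))
  x <- ip$samples; fs <- ip$fs; n <- length(x)
  dur <- n / fs
  advance <- win_s - overlap_s
  starts <- if (dur <= win_s) 0 else seq(0, dur - win_s, by = advance)
  if (dur > win_s && max(starts) + win_s < dur)
    starts <- c(starts, dur - win_s)
  min_dist <- round(min_peak_dist_s * fs)
  peaks <- integer(0)
  for (s in starts) {
    i0 <- floor(s * fs) + 1
    i1 <- min(n, ceiling((s + win_s) * fs))
    xw <- x[i0:i1]
    # peaks must rise meaningfully above the window's signal level; the
    # band-passed signal is zero-mean so breath peaks are positive
    thr <- 0.1 * stats::quantile(abs(xw), 0.95)
    p <- find_peaks(xw, min_dist, min_height = thr) + i0 - 1
    peaks <- c(peaks, p)
  }
  peaks <- sort(unique(peaks))
  if (length(peaks) == 0) return(empty_segmentation())
  # deduplicate across window overlaps: cluster peaks closer than dedup_s
  dedup <- round(dedup_s * fs)
  grp <- cumsum(c(1, diff(peaks) > dedup))
  peaks <- vapply(split(peaks, grp),
                  function(g) g[which.max(x[g])], numeric(1))
  # re-enforce the global minimum distance
  peaks <- peaks[order(x[peaks], decreasing = TRUE)]
  keep <- integer(0)
  for (i in peaks) {
    if (!length(keep) || all(abs(keep - i) >= min_dist)) keep <- c(keep, i)
  }
  peaks <- sort(keep)
  if (length(peaks) < 2) return(empty_segmentation())
  troughs <- integer(0)
  for (j in seq_len(length(peaks) - 1)) {
    seg <- (peaks[j] + 1):(peaks[j + 1] - 1)
    troughs <- c(troughs, seg[which.min(x[seg])])
  }
  # leading/trailing boundary minima (kept only when strictly interior)
  if (peaks[1] > 2) {
    seg <- 1:(peaks[1] - 1)
    i_min <- seg[which.min(x[seg])]
    if (i_min > 1) troughs <- c(i_min, troughs)
  }
  if (peaks[length(peaks)] < n - 1) {
    seg <- (peaks[length(peaks)] + 1):n
    i_min <- seg[which.min(x[seg])]
    if (i_min < n) troughs <- c(troughs, i_min)
  }
  troughs <- sort(troughs)
  if (length(troughs) < 2) return(empty_segmentation())
  if (!is.null(raw)) {
    # boundary troughs (no peak on one side) cannot be refined -- the
    # adjacent signal is featureless baseline -- so the breaths leaning
    # on them are dropped rather than emitted with degraded timing
    two_sided <- troughs > min(peaks) & troughs < max(peaks)
    ref <- refine_extrema(raw, peaks, troughs[two_sided])
    peaks <- ref$peaks; troughs <- ref$troughs
  }
  rows <- list()
  for (j in seq_len(length(troughs) - 1)) {
    inside <- peaks[peaks > troughs[j] & peaks < troughs[j + 1]]
    if (length(inside) == 0) next
    pk <- inside[which.max(x[round(inside)])]
    rows[[length(rows) + 1]] <- c(troughs[j], pk, troughs[j + 1])
  }
  if (!length(rows)) return(empty_segmentation())
  m <- do.call(rbind, rows)
  # the minimum peak distance caps the detectable rate; enforce it on
  # the emitted trough-to-trough IBIs too (guards edge fragments)
  m <- m[(m[, 3] - m[, 1]) / fs >= min_peak_dist_s, , drop = FALSE]
  if (!nrow(m)) return(empty_segmentation())
  data.frame(breath_id = seq_len(nrow(m)),
             insp_onset = (m[, 1] - 1) / fs,
             exp_onset = (m[, 2] - 1) / fs,
             breath_end = (m[, 3] - 1) / fs,
             quality_ok = NA, outlier = FALSE)
}

# Refine detected extrema on the conditioned pre-bandpass signal.
#
# The respiratory band-pass smears phase-transition timing on
# asymmetric breaths (harmonic truncation shifts peaks), so each
# extremum is re-estimated by least-squares fitting a hinged two-sided
# parabola -- separate curvatures left and right of a shared vertex --
# over a window of +/- 25% of the gap to the neighbouring opposite
# extrema. A single symmetric parabola is biased toward the flatter
# side when inspiratory and expiratory curvatures differ; the hinge
# model is not, and the wide window averages sample noise out on the
# flat extrema of slow breaths.
refine_extrema <- function(raw, peaks, troughs, wfrac = 0.25) {
  stopifnot(inherits(raw, "impedance_trace"))
  xs <- raw$samples
  n <- length(xs)
  snap <- function(idx, others, maximize) {
    vapply(idx, function(i) {
      # leading/trailing extrema have no opposite extremum on one side;
      # the signal there is featureless (baseline), so the hinge model
      # is unconstrained -- keep the detected position
      if (!any(others < i) || !any(others > i)) return(as.numeric(i))
      g_lo <- i - max(others[others < i])
      g_hi <- min(others[others > i]) - i
      w <- round(wfrac * min(g_lo, g_hi))
      if (!is.finite(w) || w < 5) return(as.numeric(i))
      a <- max(1, i - w); b <- min(n, i + w)
      hinge_vertex(xs[a:b], maximize) + a - 1
    }, numeric(1))
  }
  list(peaks = snap(peaks, troughs, TRUE),
       troughs = snap(troughs, peaks, FALSE))
}

# Least-squares hinged-parabola vertex: scan candidate vertex positions,
# fitting x(t) = x0 + cL (t-v)^2 [t<v] + cR (t-v)^2 [t>=v] for each, and
# return the candidate (1-based, within the segment) minimizing the
# residual sum of squares with admissible curvature signs.
hinge_vertex <- function(seg, maximize) {
  if (maximize) seg <- -seg
  m <- length(seg)
  ctr <- (m + 1) / 2
  # keep candidates away from the window edges, where one hinge arm has
  # too few points to constrain its curvature
  cand <- seq(max(3, ceiling(ctr - 0.6 * (ctr - 1))),
              min(m - 2, floor(ctr + 0.6 * (ctr - 1))))
  t <- seq_len(m)
  rss <- rep(NA_real_, length(cand))
  for (k in seq_along(cand)) {
    v <- cand[k]
    dl <- pmin(t - v, 0)^2
    dr <- pmax(t - v, 0)^2
    fit <- stats::lm.fit(cbind(1, dl, dr), seg)
    cf <- fit$coefficients
    if (any(is.na(cf)) || cf[2] <= 0 || cf[3] <= 0) next
    rss[k] <- sum(fit$residuals^2)
  }
  if (all(is.na(rss))) return(which.min(seg))
  k <- which.min(rss)
  v <- cand[k]
  # sub-sample polish: parabolic interpolation of the RSS minimum
  if (k > 1 && k < length(rss) && !is.na(rss[k - 1]) && !is.na(rss[k + 1])) {
    den <- rss[k - 1] - 2 * rss[k] + rss[k + 1]
    if (den > 0) {
      d <- 0.5 * (rss[k - 1] - rss[k + 1]) / den
      v <- v + max(-0.5, min(0.5, d))
    }
  }
  v
}

empty_segmentation <- function() {
  data.frame(breath_id = integer(0), insp_onset = numeric(0),
             exp_onset = numeric(0), breath_end = numeric(0),
             quality_ok = logical(0), outlier = logical(0))
}

#' Assess per-breath signal quality (template-correlation SQI)
#'
#' Quality is evaluated on 32-second windows with 75% overlap (8-s hop).
#' Within each window all fully contained breaths are linearly
#' time-normalized to the window's median IBI length and averaged into a
#' breath template. The window passes when (a) the coefficient of
#' variation of breath durations is at most `cov_threshold`, (b) the
#' mean Pearson correlation of the normalized breaths against the
#' template exceeds `corr_threshold`, and (c) detected breaths cover at
#' least `coverage` of the window. A breath is good if it lies in at
#' least one passing window; windows with fewer than 2 breaths fail.
#'
#' @param ip filtered [impedance_trace()] used for detection.
#' @param seg segmentation from [detect_breaths()].
#' @param win_s window length (s); `hop_s` window hop (s).
#' @param cov_threshold coefficient-of-variation threshold on breath
#'   durations.
#' @param corr_threshold template-correlation threshold.
#' @param coverage minimum fraction of the window covered by breaths.
#' @return segmentation with `quality_ok` filled in.
#' @export
assess_signal_quality <- function(ip, seg, win_s = 32, hop_s = 8,
                                  cov_threshold = 0.3,
                                  corr_threshold = 0.7, coverage = 0.6) {
  stopifnot(inherits(ip, "impedance_trace"))
  if (nrow(seg) == 0) return(seg)
  x <- ip$samples; fs <- ip$fs
  dur <- length(x) / fs
  win_len <- min(win_s, dur)
  starts <- if (dur <= win_s) 0 else seq(0, dur - win_s, by = hop_s)
  ok <- rep(FALSE, nrow(seg))
  ibi <- seg$breath_end - seg$insp_onset
  for (s in starts) {
    inside <- which(seg$insp_onset >= s - 1e-9 &
                      seg$breath_end <= s + win_len + 1e-9)
    if (length(inside) < 2) next
    durs <- ibi[inside]
    if (stats::sd(durs) / mean(durs) > cov_threshold) next
    if (sum(durs) < coverage * win_len) next
    len <- max(4L, round(stats::median(durs) * fs))
    mat <- vapply(inside, function(b) {
      i0 <- floor(seg$insp_onset[b] * fs) + 1
      i1 <- max(i0 + 1, floor(seg$breath_end[b] * fs))
      stats::approx(seq(i0, i1), x[i0:i1], n = len)$y
    }, numeric(len))
    template <- rowMeans(mat)
    if (stats::sd(template) == 0) next
    cors <- apply(mat, 2, function(col)
      if (stats::sd(col) == 0) 0 else stats::cor(col, template))
    if (mean(cors) > corr_threshold) ok[inside] <- TRUE
  }
  seg$quality_ok <- ok
  seg
}

#' Per-breath respiratory timing features
#'
#' For each good-quality breath: Ti (inspiration time), Te (expiration
#' time), IBI = Ti + Te, RR = 60/IBI (breaths/min), Te:Ti and the
#' inspiratory duty cycle Ti/IBI.
#'
#' @param seg quality-flagged segmentation.
#' @param keep_all also emit rows for breaths failing quality control
#'   (flagged, excluded downstream).
#' @return `timing_features` data frame.
#' @export
extract_timing_features <- function(seg, keep_all = FALSE) {
  if (nrow(seg) > 0 &&
      any(seg$exp_onset <= seg$insp_onset | seg$breath_end <= seg$exp_onset))
    stop("segmentation onsets must be strictly increasing within breaths")
  use <- if (keep_all) rep(TRUE, nrow(seg)) else
    !is.na(seg$quality_ok) & seg$quality_ok
  s <- seg[use, , drop = FALSE]
  ti <- s$exp_onset - s$insp_onset
  te <- s$breath_end - s$exp_onset
  ibi <- ti + te
  data.frame(breath_id = s$breath_id, insp_onset = s$insp_onset,
             RR = 60 / ibi, Ti = ti, Te = te, IBI = ibi,
             TeTi = te / ti, TiIBI = ti / ibi,
             quality_ok = s$quality_ok, outlier = s$outlier)
}

#' Flag timing-feature outliers with a sliding MAD filter
#'
#' A breath is an outlier when any of RR, Ti or Te deviates more than
#' `k` (scaled) MADs from the median of its centered 30-breath window.
#'
#' @param feats timing features from [extract_timing_features()].
#' @param k MAD multiplier (5 by convention for the timing cascade).
#' @param window window length in breaths.
#' @param scaled use the 1.4826-scaled MAD.
#' @return features with the `outlier` column filled in.
#' @export
remove_timing_outliers <- function(feats, k = 5, window = 30,
                                   scaled = TRUE) {
  if (nrow(feats) == 0) return(feats)
  fl <- mad_outlier_flags(feats$RR, k, window, scaled) |
    mad_outlier_flags(feats$Ti, k, window, scaled) |
    mad_outlier_flags(feats$Te, k, window, scaled)
  feats$outlier <- fl
  feats
}
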