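# Feature time-series generation: windowed averaging of the per-breath
# multimodal features plus the final window-level outlier stage.

#' Windowed feature time series from the multimodal breath table
#'
#' Features are averaged over 32-second windows with 75% overlap (8-s
#' hop) to mitigate breath-by-breath variability. A breath belongs to a
#' window when its inspiration onset falls inside it; windows containing
#' no breaths are emitted as `NA` (filled later by the interpolation
#' stage).
#'
#' @param breaths multimodal breath table from
#'   [match_multimodal_breaths()] (needs `insp_onset`).
#' @param duration_s recording duration (defaults to the last onset).
#' @param win_s window length (s); `overlap` fractional overlap.
#' @return `feature_timeseries` data frame: `window_start`, the 13
#'   feature columns, and per-feature `interpolated.*` flags.
#' @export
build_timeseries <- function(breaths, duration_s = NULL, win_s = 32,
                             overlap = 0.75) {
  feats <- intersect(multimodal_feature_names(), names(breaths))
  hop <- win_s * (1 - overlap)
  if (nrow(breaths) == 0)
    return(data.frame(window_start = numeric(0)))
  if (is.null(duration_s)) duration_s <- max(breaths$insp_onset) + 1e-9
  starts <- seq(0, max(0, duration_s - win_s), by = hop)
  if (length(starts) == 0) starts <- 0
  rows <- lapply(starts, function(s) {
    sel <- breaths$insp_onset >= s & breaths$insp_onset < s + win_s
    v <- if (any(sel)) colMeans(breaths[sel, feats, drop = FALSE])
    else stats::setNames(rep(NA_real_, length(feats)), feats)
    as.data.frame(as.list(v))
  })
  out <- cbind(window_start = starts, do.call(rbind, rows))
  for (f in feats) out[[paste0("interpolated.", f)]] <- is.na(out[[f]])
  # windows empty of breaths are filled by interpolation over window index
  for (f in feats) out[[f]] <- interp_fill(out[[f]])
  rownames(out) <- NULL
  out
}

# Linear interpolation over index with nearest-value edge extension.
interp_fill <- function(x) {
  bad <- is.na(x)
  if (!any(bad) || all(bad)) return(x)
  idx <- which(!bad)
  if (length(idx) == 1) {
    x[bad] <- x[idx]
    return(x)
  }
  x[bad] <- stats::approx(idx, x[idx], xout = which(bad), rule = 2)$y
  x
}

#' Remove outlying window averages from a feature time series
#'
#' Per feature (independently), window means deviating more than `k`
#' MADs from the whole-series median are removed and refilled by linear
#' interpolation over window index, with edge values extended from the
#' nearest surviving window; refilled windows are flagged in the
#' per-feature `interpolated.*` columns.
#'
#' @param series output of [build_timeseries()].
#' @param k MAD multiplier.
#' @param scaled use the 1.4826-scaled MAD.
#' @return cleaned series.
#' @export
remove_window_outliers <- function(series, k = 5, scaled = TRUE) {
  feats <- intersect(multimodal_feature_names(), names(series))
  if (nrow(series) == 0) return(series)
  for (f in feats) {
    x <- series[[f]]
    med <- stats::median(x, na.rm = TRUE)
    s <- mad_robust(x, scaled)
    dev <- abs(x - med)
    bad <- if (s == 0) dev > 0 else dev > k * s
    bad[is.na(bad)] <- TRUE
    if (all(bad)) stop(sprintf("all windows outlying for feature %s", f))
    if (any(bad)) {
      x[bad] <- NA
      series[[f]] <- interp_fill(x)
      flag <- paste0("interpolated.", f)
      series[[flag]] <- series[[flag]] | bad
    }
  }
  series
}
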