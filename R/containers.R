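# Lightweight S3 containers for the two signal modalities plus shared
# robust-statistics helpers used by every outlier cascade.

#' Construct an impedance trace
#'
#' @param samples impedance samples (ohm).
#' @param fs sampling rate (Hz).
#' @param excitation_khz excitation frequency of the bioimpedance channel
#'   (the 150 kHz channel carries the respiratory signal).
#' @param interpolated logical mask, `TRUE` where samples were replaced
#'   by interpolation.
#' @return object of class `impedance_trace`.
#' @export
impedance_trace <- function(samples, fs, excitation_khz = 150,
                            interpolated = NULL) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("`fs` must be a single positive number")
  if (length(samples) == 0) stop("empty impedance trace")
  if (is.null(interpolated)) interpolated <- rep(FALSE, length(samples))
  if (length(interpolated) != length(samples))
    stop("interpolation mask length must equal the number of samples")
  structure(list(samples = samples, fs = fs,
                 excitation_khz = excitation_khz,
                 interpolated = as.logical(interpolated)),
            class = "impedance_trace")
}

#' @export
print.impedance_trace <- function(x, ...) {
  cat(sprintf("<impedance_trace> %d samples @ %g Hz (%g kHz excitation), %.1f s, %.3f%% interpolated\n",
              length(x$samples), x$fs, x$excitation_khz,
              length(x$samples) / x$fs, 100 * mean(x$interpolated)))
  invisible(x)
}

#' Construct an audio trace
#'
#' @param samples audio samples (normalized amplitude).
#' @param fs sampling rate (Hz).
#' @param channel auscultation channel label.
#' @return object of class `audio_trace`.
#' @export
audio_trace <- function(samples, fs, channel = "anterior-right") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("`fs` must be a single positive number")
  if (any(!is.finite(samples))) stop("audio samples must be finite")
  structure(list(samples = samples, fs = fs, channel = channel),
            class = "audio_trace")
}

#' @export
print.audio_trace <- function(x, ...) {
  cat(sprintf("<audio_trace> %d samples @ %g Hz (%.1f s), channel %s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$channel))
  invisible(x)
}

#' Scaled median absolute deviation
#'
#' MAD with the 1.4826 Gaussian-consistency factor by default, matching
#' the robust outlier tooling of common numerical environments; set
#' `scaled = FALSE` for the raw median absolute deviation.
#'
#' @param x numeric vector.
#' @param scaled apply the 1.4826 consistency constant.
#' @export
mad_robust <- function(x, scaled = TRUE) {
  stats::mad(x, constant = if (scaled) 1.4826 else 1, na.rm = TRUE)
}

#' Sliding-window MAD outlier flags
#'
#' For each observation, the median and MAD are computed over a centered
#' window of `window` observations (truncated at the edges); the
#' observation is flagged when its absolute deviation from the window
#' median exceeds `k` window MADs. When the window MAD is zero, any
#' nonzero deviation is flagged (zero-spread convention).
#'
#' @param x numeric vector.
#' @param k MAD multiplier.
#' @param window window length in observations.
#' @param scaled use scaled MAD (see [mad_robust()]).
#' @return logical vector of outlier flags.
#' @export
mad_outlier_flags <- function(x, k, window = 30, scaled = TRUE) {
  n <- length(x)
  if (n == 0) return(logical(0))
  half <- window %/% 2
  flags <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half)
    hi <- min(n, lo + window - 1)
    lo <- max(1, hi - window + 1)
    w <- x[lo:hi]
    med <- stats::median(w, na.rm = TRUE)
    s <- mad_robust(w, scaled)
    dev <- abs(x[i] - med)
    flags[i] <- if (s == 0) isTRUE(dev > 0) else isTRUE(dev > k * s)
  }
  flags
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
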