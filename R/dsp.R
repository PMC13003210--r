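# Windowed-sinc FIR design, zero-phase filtering and FIR-antialiased
# resampling. Implemented here because no DSP package ships with the
# analysis environment; the designs are the textbook Kaiser/Hamming
# windowed-sinc constructions.

#' Kaiser window
#'
#' @param n window length (number of taps).
#' @param beta Kaiser shape parameter; larger values trade transition
#'   width for stopband attenuation (beta ~ 6 gives ~ 60 dB).
#' @return numeric vector of length `n`.
#' @keywords internal
kaiser_window <- function(n, beta) {
  stopifnot(n >= 1, beta >= 0)
  m <- n - 1
  k <- seq_len(n) - 1
  x <- beta * sqrt(pmax(0, 1 - ((2 * k - m) / m)^2))
  if (n == 1) return(1)
  besselI(x, 0) / besselI(beta, 0)
}

#' Hamming window
#' @param n window length.
#' @keywords internal
hamming_window <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# Kaiser design rule: taps needed for a given attenuation (dB) and
# transition width (Hz) at sampling rate fs. Returns an odd tap count so
# the filter has an integer group delay (type-I linear phase).
kaiser_order <- function(atten_db, transition_hz, fs) {
  dw <- 2 * pi * transition_hz / fs
  n <- ceiling((atten_db - 8) / (2.285 * dw)) + 1
  if (n %% 2 == 0) n <- n + 1
  as.integer(n)
}

kaiser_beta <- function(atten_db) {
  if (atten_db > 50) {
    0.1102 * (atten_db - 8.7)
  } else if (atten_db >= 21) {
    0.5842 * (atten_db - 21)^0.4 + 0.07886 * (atten_db - 21)
  } else {
    0
  }
}

#' Design a linear-phase FIR filter by the windowed-sinc method
#'
#' @param n odd number of taps.
#' @param fc cutoff frequency in Hz (length 1 for low-pass, length 2 for
#'   band-pass).
#' @param fs sampling rate in Hz.
#' @param window `"kaiser"` or `"hamming"`.
#' @param beta Kaiser beta (ignored for Hamming).
#' @return numeric vector of `n` filter taps.
#' @keywords internal
fir_design <- function(n, fc, fs, window = c("kaiser", "hamming"), beta = 6) {
  window <- match.arg(window)
  stopifnot(n %% 2 == 1, all(fc > 0), all(fc < fs / 2))
  m <- (n - 1) / 2
  k <- -m:m
  sinc <- function(f) {
    x <- 2 * f / fs
    ifelse(k == 0, x, sin(pi * x * k) / (pi * k))
  }
  h <- if (length(fc) == 1) sinc(fc) else sinc(fc[2]) - sinc(fc[1])
  w <- if (window == "kaiser") kaiser_window(n, beta) else hamming_window(n)
  h <- h * w
  # unit gain at the band centre (or DC for low-pass)
  f0 <- if (length(fc) == 1) 0 else sqrt(prod(fc))
  g <- sum(h * cos(2 * pi * f0 * k / fs))
  h / g
}

#' Zero-phase FIR filtering
#'
#' Applies an odd-length linear-phase FIR filter and removes its group
#' delay, so filtered events keep their original timing. The input is
#' reflection-padded by half the filter length at each end to suppress
#' edge transients.
#'
#' @param x numeric signal.
#' @param h odd-length FIR taps.
#' @return filtered signal, same length as `x`.
#' @keywords internal
fir_filter_zerophase <- function(x, h) {
  n <- length(h)
  stopifnot(n %% 2 == 1)
  m <- (n - 1) / 2
  lx <- length(x)
  pad <- min(m, lx - 1)
  # symmetric reflection: value-continuous and amplitude-preserving, so
  # narrowband edge transients stay bounded by the local signal level
  left <- x[seq(pad + 1, 2, by = -1)]
  right <- x[seq(lx - 1, lx - pad, by = -1)]
  xp <- c(left, x, right)
  y <- convolve_full(xp, h)
  y[(m + pad + 1):(m + pad + lx)]
}

# Full linear convolution via FFT, zero-padded to a 2-3-5-smooth length
# (R's mixed-radix FFT degrades badly on awkward lengths).
convolve_full <- function(x, h) {
  n <- length(x) + length(h) - 1
  nf <- stats::nextn(n, c(2, 3, 5))
  xf <- stats::fft(c(x, numeric(nf - length(x))))
  hf <- stats::fft(c(h, numeric(nf - length(h))))
  Re(stats::fft(xf * hf, inverse = TRUE))[seq_len(n)] / nf
}

#' Resample a signal with FIR antialiasing
#'
#' Upsampling uses zero-stuffing by the rational factor's numerator, a
#' zero-phase Kaiser FIR interpolation low-pass, and decimation by the
#' denominator; downsampling uses a zero-phase Kaiser antialiasing
#' low-pass below the new Nyquist followed by linear interpolation onto
#' the target grid (the "linear resampling with an FIR antialiasing
#' low-pass filter" recipe).
#'
#' @param x numeric signal.
#' @param fs_in,fs_out input/output sampling rates (Hz).
#' @param atten_db stopband attenuation of the antialiasing filter.
#' @return list with `samples` and `fs`.
#' @keywords internal
fir_resample <- function(x, fs_in, fs_out, atten_db = 60) {
  stopifnot(fs_in > 0, fs_out > 0, length(x) >= 2)
  if (fs_out == fs_in) return(list(samples = x, fs = fs_out))
  # work on the zero-mean signal: a large DC offset would otherwise leak
  # through the stopband at the imaging frequencies and ride on the
  # output as spurious ripple comparable to small physiological signals
  mu <- mean(x)
  x <- x - mu
  add_mu <- function(r) { r$samples <- r$samples + mu; r }
  frac <- rational_ratio(fs_out, fs_in)
  if (fs_out > fs_in && !is.null(frac) && frac[1] <= 64) {
    l <- frac[1]; m <- frac[2]
    fs_up <- fs_in * l
    xs <- numeric(length(x) * l)
    xs[seq(1, length(xs), by = l)] <- x * l
    n <- kaiser_order(atten_db, 0.1 * fs_in, fs_up)
    h <- fir_design(n, fs_in / 2, fs_up, "kaiser", kaiser_beta(atten_db))
    y <- fir_filter_zerophase(xs, h)
    return(add_mu(list(samples = y[seq(1, length(y), by = m)],
                       fs = fs_out)))
  }
  # downsampling: transition band just under the new Nyquist
  nyq <- min(fs_out, fs_in) / 2
  n <- kaiser_order(atten_db, 0.1 * nyq, fs_in)
  n <- min(n, 2 * floor((length(x) - 1) / 2) + 1)
  h <- fir_design(n, 0.95 * nyq, fs_in, "kaiser", kaiser_beta(atten_db))
  xf <- fir_filter_zerophase(x, h)
  t_in <- (seq_along(x) - 1) / fs_in
  t_out <- seq(0, t_in[length(t_in)], by = 1 / fs_out)
  add_mu(list(samples = stats::approx(t_in, xf, xout = t_out, rule = 2)$y,
              fs = fs_out))
}

# Small-integer rational approximation of fs_out/fs_in (NULL if the
# rates are not commensurate at 1e-6 precision).
rational_ratio <- function(fs_out, fs_in, max_den = 10000) {
  r <- fs_out / fs_in
  for (m in seq_len(max_den)) {
    l <- r * m
    if (abs(l - round(l)) < 1e-6) return(c(as.integer(round(l)), m))
  }
  NULL
}

#' Short-time power spectral density matrix
#'
#' Frames a signal into fixed-length windows with the given hop, applies
#' a Hamming taper and returns the one-sided modified periodogram of each
#' frame (power per Hz, window-power normalized).
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param nwin frame length in samples.
#' @param hop hop in samples.
#' @return list with `psd` (bins x frames matrix), `freq` (bin centre
#'   frequencies, Hz) and `nframes`.
#' @keywords internal
stft_psd <- function(x, fs, nwin, hop) {
  lx <- length(x)
  if (lx < nwin) return(list(psd = NULL, freq = NULL, nframes = 0L))
  starts <- seq(1, lx - nwin + 1, by = hop)
  w <- hamming_window(nwin)
  u <- sum(w^2)
  frames <- vapply(starts, function(s) x[s:(s + nwin - 1)] * w,
                   numeric(nwin))
  sp <- stats::mvfft(frames)
  nb <- nwin %/% 2 + 1
  p <- (Mod(sp[seq_len(nb), , drop = FALSE])^2) / (fs * u)
  # one-sided: double everything except DC (and Nyquist for even nwin)
  if (nb > 2) {
    dbl <- 2:(nb - if (nwin %% 2 == 0) 1 else 0)
    p[dbl, ] <- 2 * p[dbl, ]
  }
  list(psd = p, freq = (seq_len(nb) - 1) * fs / nwin,
       nframes = length(starts))
}

#' Amplitude of one frequency component of a signal
#'
#' Single-bin discrete Fourier projection; used throughout the tests to
#' measure pass/stopband behaviour.
#'
#' @param x signal, `fs` sampling rate, `f` frequency (Hz).
#' @keywords internal
tone_amplitude <- function(x, fs, f) {
  t <- (seq_along(x) - 1) / fs
  2 * Mod(mean(x * exp(-2i * pi * f * t)))
}
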