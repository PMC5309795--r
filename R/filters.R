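# FIR design and zero-phase filtering.
#
# Band-pass filtering throughout the package uses linear-phase least-squares
# FIR filters applied forward and backward (two-way), so the net group delay
# is zero and narrow-band phase estimates are undistorted. Filter length
# follows the cycles rule: length = ceil(cycles * fs / low_edge) samples,
# with cycles = 4 by default.

# Least-squares linear-phase (type I) FIR design on a dense frequency grid.
# `bands` is a matrix with rows (f_lo, f_hi, amp_lo, amp_hi, weight) in Hz;
# frequencies not covered by any band are transition regions (unweighted).
firls_design <- function(n_taps, fs, bands) {
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1L  # force odd (type I)
  M <- (n_taps - 1L) %/% 2L
  if (M > 1500L) {
    # the dense-grid least-squares system becomes unwieldy for very long
    # filters (sub-Hz edges); fall back to frequency-sampling with a Hamming
    # window, which matches the least-squares response to within the ripple
    return(.fir_freqsamp(n_taps, fs, bands))
  }
  ngrid <- max(512L, 16L * n_taps)
  f <- seq(0, fs / 2, length.out = ngrid)
  D <- rep(NA_real_, ngrid)
  W <- rep(0, ngrid)
  for (i in seq_len(nrow(bands))) {
    sel <- f >= bands[i, 1] & f <= bands[i, 2]
    D[sel] <- bands[i, 3] +
      (bands[i, 4] - bands[i, 3]) *
        (f[sel] - bands[i, 1]) / max(bands[i, 2] - bands[i, 1], .Machine$double.eps)
    W[sel] <- bands[i, 5]
  }
  keep <- W > 0
  fk <- f[keep]; Dk <- D[keep]; Wk <- sqrt(W[keep])
  # amplitude response A(f) = a0 + 2 * sum_k a_k cos(2 pi f k / fs)
  C <- cbind(1, 2 * cos(outer(2 * pi * fk / fs, seq_len(M))))
  a <- qr.solve(C * Wk, Dk * Wk)
  h <- c(rev(a[-1]), a[1], a[-1])
  h
}

# frequency-sampling linear-phase design: inverse DFT of the desired
# amplitude response (transition regions interpolated linearly), windowed
.fir_freqsamp <- function(n_taps, fs, bands) {
  ngrid <- nextn(4L * n_taps, 2)
  f <- seq(0, fs / 2, length.out = ngrid + 1L)
  D <- rep(NA_real_, length(f))
  for (i in seq_len(nrow(bands))) {
    sel <- f >= bands[i, 1] & f <= bands[i, 2]
    D[sel] <- bands[i, 3] +
      (bands[i, 4] - bands[i, 3]) *
        (f[sel] - bands[i, 1]) / max(bands[i, 2] - bands[i, 1], .Machine$double.eps)
  }
  D <- approx(f[!is.na(D)], D[!is.na(D)], xout = f, rule = 2)$y
  full <- c(D, rev(D[2:ngrid]))  # two-sided spectrum, zero phase
  h_full <- Re(fft(full, inverse = TRUE)) / length(full)
  M <- (n_taps - 1L) %/% 2L
  h <- c(h_full[(M + 1L):2], h_full[1L], h_full[2:(M + 1L)])
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n_taps) - 1) / (n_taps - 1))
  h * w
}

# filter length from the cycles rule
fir_length <- function(fs, low_hz, cycles = 4) {
  n <- as.integer(ceiling(cycles * fs / low_hz))
  if (n %% 2 == 0) n <- n + 1L
  n
}

# full linear convolution via FFT
conv_fft <- function(x, h) {
  L <- length(x) + length(h) - 1L
  N <- nextn(L, 2)
  X <- fft(c(x, numeric(N - length(x))))
  H <- fft(c(h, numeric(N - length(h))))
  Re(fft(X * H, inverse = TRUE))[seq_len(L)] / N
}

# zero-phase (forward-backward) FIR filtering with reflective edge padding.
# For a symmetric kernel the two passes equal one centred convolution with
# the kernel's self-convolution, which is what is computed here.
fir_filtfilt <- function(x, h) {
  n <- length(x)
  nh <- length(h)
  npad <- min(n - 1L, 3L * nh)
  left <- 2 * x[1] - x[(npad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - npad)]
  xp <- c(left, x, right)
  g <- conv_fft(h, h)            # length 2*nh - 1, delay nh - 1 samples
  y <- conv_fft(xp, g)
  y[(nh - 1L + npad) + seq_len(n)]
}

#' Design a band-pass FIR filter
#'
#' Linear-phase least-squares design with transition bands of 15% of each
#' edge, mirroring common electrophysiology practice.
#'
#' @param fs sampling rate (Hz).
#' @param low_hz,high_hz pass-band edges (Hz), `0 < low < high < fs/2`.
#' @param cycles filter-length rule: length = ceil(cycles * fs / low_hz).
#' @param trans fractional transition bandwidth (default 0.15).
#' @param method `"window"` (windowed frequency sampling; flatter pass band
#'   at the cycles-rule length, the default) or `"ls"` (dense-grid least
#'   squares).
#' @return numeric vector of filter taps (odd length, symmetric).
#' @export
design_bandpass <- function(fs, low_hz, high_hz, cycles = 4, trans = 0.15,
                            method = c("window", "ls")) {
  method <- match.arg(method)
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2")
  }
  n <- fir_length(fs, low_hz, cycles)
  f1 <- max(low_hz * (1 - trans), 0)
  f2 <- min(high_hz * (1 + trans), fs / 2)
  bands <- rbind(
    c(0, f1, 0, 0, 1),
    c(low_hz, high_hz, 1, 1, 10),
    c(f2, fs / 2, 0, 0, 1)
  )
  if (f1 <= 0) bands <- bands[-1, , drop = FALSE]
  if (f2 >= fs / 2) bands <- bands[-nrow(bands), , drop = FALSE]
  if (method == "window") .fir_freqsamp(n, fs, bands)
  else firls_design(n, fs, bands)
}

#' Zero-phase band-pass filter
#'
#' Two-way (forward-backward) least-squares FIR band-pass. Accepts a numeric
#' vector, a matrix (channels x samples, filtered per row), or an
#' [lfp_recording].
#'
#' @param x signal(s) to filter.
#' @param low_hz,high_hz band edges in Hz.
#' @param fs sampling rate; taken from the recording when `x` is one.
#' @param cycles filter-length rule (default 4 cycles of the low edge).
#' @return object of the same shape/class as `x`.
#' @export
bandpass_fir <- function(x, low_hz, high_hz, fs = NULL, cycles = 4) {
  if (inherits(x, "lfp_recording")) {
    x$data <- bandpass_fir(x$data, low_hz, high_hz, fs = x$fs, cycles = cycles)
    return(x)
  }
  if (is.null(fs)) stop("fs is required for plain numeric input")
  h <- design_bandpass(fs, low_hz, high_hz, cycles = cycles)
  if (is.matrix(x)) {
    t(apply(x, 1L, fir_filtfilt, h = h))
  } else {
    fir_filtfilt(as.numeric(x), h)
  }
}

#' Zero-phase low-pass filter
#'
#' @inheritParams bandpass_fir
#' @param high_hz cut-off frequency in Hz.
#' @export
lowpass_fir <- function(x, high_hz, fs = NULL, cycles = 4) {
  if (inherits(x, "lfp_recording")) {
    x$data <- lowpass_fir(x$data, high_hz, fs = x$fs, cycles = cycles)
    return(x)
  }
  if (is.null(fs)) stop("fs is required for plain numeric input")
  n <- fir_length(fs, high_hz, cycles)
  f2 <- min(high_hz * 1.15, fs / 2)
  bands <- rbind(c(0, high_hz, 1, 1, 1), c(f2, fs / 2, 0, 0, 1))
  if (f2 >= fs / 2) bands <- bands[1, , drop = FALSE]
  h <- .fir_freqsamp(n, fs, bands)
  if (is.matrix(x)) t(apply(x, 1L, fir_filtfilt, h = h))
  else fir_filtfilt(as.numeric(x), h)
}

#' Resample a recording to a new rate
#'
#' Polyphase anti-aliased resampling (via [signal::resample]); used for the
#' acquisition-to-analysis (e.g. 5 kHz to 2 kHz) and Granger (250 Hz) stages.
#'
#' @param rec an [lfp_recording] (or numeric vector with `fs` given).
#' @param fs_new target sampling rate in Hz.
#' @param fs original sampling rate when `rec` is a plain vector.
#' @return resampled object of the same class.
#' @export
resample_recording <- function(rec, fs_new, fs = NULL) {
  ratio <- if (inherits(rec, "lfp_recording")) fs_new / rec$fs else fs_new / fs
  frac <- .ratio_to_pq(ratio)
  resample1 <- function(x) as.numeric(signal::resample(x, frac[1], frac[2]))
  if (inherits(rec, "lfp_recording")) {
    dat <- t(apply(rec$data, 1L, resample1))
    rec$data <- dat
    rec$fs <- fs_new
    if (!is.null(rec$events)) attr(rec$events, "fs") <- fs_new
    return(rec)
  }
  resample1(as.numeric(rec))
}

.ratio_to_pq <- function(ratio, max_den = 1000L) {
  # small rational approximation of the resampling ratio
  for (q in seq_len(max_den)) {
    p <- ratio * q
    if (abs(p - round(p)) < 1e-9) return(c(as.integer(round(p)), q))
  }
  stop("resampling ratio is not a small rational number")
}
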