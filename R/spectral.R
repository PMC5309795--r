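# Spectral estimation: Welch PSD, power-law slope, subject-specific band
# selection, adaptive filter-bank Hilbert decomposition, high-gamma envelope
# spectra.

#' Welch power spectral density
#'
#' Averaged modified periodograms with a Hamming taper, 1 s windows and 50%
#' overlap by default. The one-sided density integrates to the signal
#' variance (within taper correction).
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param window_s window length in seconds.
#' @param overlap fractional window overlap.
#' @return data frame of class `power_spectrum` with columns `freq` (Hz) and
#'   `power` (units^2/Hz).
#' @export
welch_psd <- function(x, fs, window_s = 1, overlap = 0.5) {
  x <- as.numeric(x)
  nwin <- round(window_s * fs)
  if (length(x) < 2 * nwin) stop("signal shorter than two Welch windows")
  hop <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, length(x) - nwin + 1L, by = hop)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(nwin) - 1) / (nwin - 1))  # Hamming
  U <- sum(w^2)
  acc <- numeric(nwin)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(fft(seg))^2
  }
  acc <- acc / (length(starts) * fs * U)
  half <- floor(nwin / 2) + 1L
  p <- acc[seq_len(half)]
  # one-sided: double everything except DC (and Nyquist when nwin is even)
  dbl <- 2:(half - if (nwin %% 2 == 0) 1L else 0L)
  p[dbl] <- 2 * p[dbl]
  out <- data.frame(freq = (seq_len(half) - 1L) * fs / nwin, power = p)
  class(out) <- c("power_spectrum", "data.frame")
  attr(out, "fs") <- fs
  attr(out, "window_s") <- window_s
  attr(out, "overlap") <- overlap
  out
}

#' Fit the aperiodic (power-law) background of a spectrum
#'
#' Ordinary least squares of transformed power on frequency over a fit
#' range. Both fit spaces are computed: the semi-log fit (log-power on linear
#' frequency) gives the regression slope `beta`, and the log-log fit gives
#' the exponent `chi` of the power law `P ~ f^(-chi)`.
#'
#' @param psd a [welch_psd()] result (or data frame with `freq`, `power`).
#' @param fit_range_hz frequency range used for the fit (default 2-80 Hz).
#' @return list of class `slope_fit` with `beta`, `intercept`, `residuals`,
#'   `chi`, `chi_intercept`, `freq` and per-space fitted log-power curves.
#' @export
fit_powerlaw <- function(psd, fit_range_hz = c(2, 80)) {
  sel <- psd$freq >= fit_range_hz[1] & psd$freq <= fit_range_hz[2] &
    psd$freq > 0 & psd$power > 0
  f <- psd$freq[sel]
  p <- psd$power[sel]
  if (length(f) < 3) stop("fewer than 3 spectral points in the fit range")
  lp <- log10(p)
  semi <- lm(lp ~ f)
  loglog <- lm(lp ~ log10(f))
  structure(
    list(beta = unname(coef(semi)[2]),
         intercept = unname(coef(semi)[1]),
         residuals = unname(semi$residuals),
         chi = -unname(coef(loglog)[2]),
         chi_intercept = unname(coef(loglog)[1]),
         freq = f,
         fitted_semilog = unname(semi$fitted.values),
         fitted_loglog = unname(loglog$fitted.values),
         fit_range_hz = fit_range_hz),
    class = "slope_fit"
  )
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("<slope_fit> beta (semi-log) = %.4f; chi (log-log) = %.3f over %g-%g Hz\n",
              x$beta, x$chi, x$fit_range_hz[1], x$fit_range_hz[2]))
  invisible(x)
}

#' A frequency band specification
#'
#' @param centre_hz band centre (Hz).
#' @param bandwidth_hz full bandwidth (default 4 Hz).
#' @param low_hz,high_hz explicit edges; computed from centre and bandwidth
#'   when omitted.
#' @return list of class `band_spec`.
#' @export
band_spec <- function(centre_hz, bandwidth_hz = 4, low_hz = NULL,
                      high_hz = NULL) {
  if (is.null(low_hz)) low_hz <- centre_hz - bandwidth_hz / 2
  if (is.null(high_hz)) high_hz <- centre_hz + bandwidth_hz / 2
  structure(list(centre_hz = centre_hz, low_hz = low_hz, high_hz = high_hz,
                 bandwidth_hz = high_hz - low_hz),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %.2f Hz (%.2f-%.2f Hz)\n",
              x$centre_hz, x$low_hz, x$high_hz))
  invisible(x)
}

#' Select the subject-specific low-frequency band from a PSD
#'
#' The band centre is the frequency where the measured log-power lies
#' farthest above the fitted power-law background within the search range
#' (theta/alpha by default); the band is centre +/- bandwidth/2. If no point
#' lies above the fit, the range midpoint is returned with `fallback = TRUE`.
#'
#' @param psd a [welch_psd()] result.
#' @param fit a [fit_powerlaw()] result for the same spectrum.
#' @param search_range_hz search range (default 4-12 Hz).
#' @param bandwidth_hz band width (default 4 Hz).
#' @param min_peak_log10 smallest log10-power excess over the fit that counts
#'   as an oscillatory peak (default 0.05, i.e. ~12% above the background).
#' @return a [band_spec()] with an extra `fallback` flag.
#' @export
select_subject_band <- function(psd, fit, search_range_hz = c(4, 12),
                                bandwidth_hz = 4, min_peak_log10 = 0.05) {
  if (search_range_hz[1] < fit$fit_range_hz[1] ||
      search_range_hz[2] > fit$fit_range_hz[2]) {
    stop("search range must lie inside the power-law fit range")
  }
  sel <- psd$freq >= search_range_hz[1] & psd$freq <= search_range_hz[2] &
    psd$freq > 0 & psd$power > 0
  f <- psd$freq[sel]
  # distance above the log-log power-law fit, in log-power units
  pred <- fit$chi_intercept - fit$chi * log10(f)
  dist <- log10(psd$power[sel]) - pred
  if (all(dist <= min_peak_log10)) {
    warning("no oscillatory peak above the aperiodic fit; ",
            "falling back to the range midpoint")
    bs <- band_spec(mean(search_range_hz), bandwidth_hz)
    bs$fallback <- TRUE
    return(bs)
  }
  centre <- f[which.max(dist)]
  bs <- band_spec(centre, bandwidth_hz)
  if (bs$low_hz < 1) bs <- band_spec(centre, bandwidth_hz, low_hz = 1,
                                     high_hz = centre + bandwidth_hz / 2)
  bs$fallback <- FALSE
  bs
}

#' Centre frequencies of the adaptive filter bank
#'
#' Centres step geometrically by 10% of the current centre; the band at each
#' centre is `c +/- 0.3 c` (fractional bandwidth 0.3, full width `0.6 c`).
#' At 10 Hz the next centre is 11 Hz and the bandwidth 6 Hz.
#'
#' @param f_min,f_max grid limits (Hz).
#' @return numeric vector of centre frequencies.
#' @export
filterbank_centres <- function(f_min, f_max) {
  if (f_min < 1 || f_max <= f_min) stop("need 1 <= f_min < f_max")
  centres <- f_min
  while (tail(centres, 1) * 1.1 <= f_max + 1e-9) {
    centres <- c(centres, tail(centres, 1) * 1.1)
  }
  centres
}

#' Adaptive filter-bank Hilbert decomposition
#'
#' Filters the signal into the [filterbank_centres()] grid (band `c +/-
#' 0.3 c`) and Hilbert-transforms each band into instantaneous amplitude and
#' phase. Narrow low-frequency bands give well-defined phase; broad
#' high-frequency bands accommodate modulation sidebands.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param f_min,f_max grid limits; `f_max` is clipped below Nyquist.
#' @param cycles FIR length rule passed to [bandpass_fir()].
#' @return list of [analytic_signal] objects, one per centre.
#' @export
filterbank_decompose <- function(x, fs, f_min = 1, f_max = 30, cycles = 4) {
  f_max <- min(f_max, fs / 2 / 1.3 * 0.999)
  centres <- filterbank_centres(f_min, f_max)
  if (!length(centres)) stop("empty filter-bank grid")
  lapply(centres, function(cf) {
    lo <- 0.7 * cf
    hi <- 1.3 * cf
    xb <- bandpass_fir(x, lo, hi, fs = fs, cycles = cycles)
    analytic_signal(xb, fs, band = band_spec(cf, low_hz = lo, high_hz = hi))
  })
}

#' PSD of the high-gamma amplitude envelope
#'
#' Band-passes the signal around a high-gamma centre (40 Hz bandwidth by
#' default), extracts the Hilbert amplitude envelope and returns its Welch
#' PSD. A low-frequency peak in this spectrum indicates that gamma amplitude
#' fluctuates rhythmically at that frequency.
#'
#' @param x numeric signal.
#' @param fs sampling rate.
#' @param centre_hz high-gamma centre frequency.
#' @param bandwidth_hz full bandwidth (default 40 Hz).
#' @param ... passed to [welch_psd()].
#' @return a `power_spectrum` of the envelope.
#' @export
hg_envelope_psd <- function(x, fs, centre_hz, bandwidth_hz = 40, ...) {
  lo <- centre_hz - bandwidth_hz / 2
  hi <- centre_hz + bandwidth_hz / 2
  if (lo <= 30 || hi >= fs / 2) {
    stop("high-gamma band must lie inside (30, fs/2)")
  }
  env <- analytic_signal(bandpass_fir(x, lo, hi, fs = fs), fs)$amplitude
  welch_psd(env - mean(env), fs, ...)
}
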