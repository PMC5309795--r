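# Event-locked high-gamma time courses, ERPs, and theta-trough-locked
# time-frequency averages.

#' Event-locked z-scored high-gamma amplitude
#'
#' The continuous high-gamma (70-180 Hz) Hilbert amplitude is epoched around
#' clip onsets and each trial trace is converted to z-scores relative to its
#' own full time series (removing the positive skew of amplitude values).
#' The session-blank baseline (the pre-session blank screen) is then
#' subtracted: for each trial the blank-segment amplitude is expressed in
#' that trial's z-units and its mean removed. If no blank exists the
#' per-trial pre-stimulus window is used instead, with a warning.
#'
#' @param rec an [lfp_recording] with events.
#' @param channel channel label or index.
#' @param window epoch window (s, default `c(-0.5, 1.5)`).
#' @param band high-gamma band (Hz).
#' @param baseline `"session"` (blank screen at session start) or `"trial"`
#'   (pre-stimulus window per trial).
#' @return list of class `hg_timecourse`: `z` (trials x samples), `times`,
#'   `condition`, `fs`, `channel`, `baseline`.
#' @export
hg_timecourse <- function(rec, channel, window = c(-0.5, 1.5),
                          band = c(70, 180), baseline = c("session", "trial")) {
  baseline <- match.arg(baseline)
  fs <- rec$fs
  x <- channel_signal(rec, channel)
  amp <- analytic_signal(bandpass_fir(x, band[1], band[2], fs = fs), fs)$amplitude
  ev <- rec$events
  if (is.null(ev)) stop("recording carries no events table")
  rel <- seq(round(window[1] * fs), round(window[2] * fs) - 1L)
  n <- length(amp)
  keep <- vapply(seq_len(nrow(ev)), function(i) {
    c0 <- round(ev$onset_s[i] * fs) + 1L
    c0 + rel[1] >= 1L && c0 + rel[length(rel)] <= n
  }, logical(1))
  ev <- ev[keep, , drop = FALSE]
  z <- matrix(NA_real_, nrow(ev), length(rel))
  blank_n <- round(min(ev$onset_s) * fs)
  use_session <- baseline == "session" && blank_n >= round(0.25 * fs)
  if (baseline == "session" && !use_session) {
    warning("no session blank available; falling back to per-trial baseline")
  }
  # drop the filter edge transient at the very start of the session before
  # averaging the blank
  edge <- min(round(0.15 * fs), blank_n %/% 2)
  blank_amp <- if (use_session) amp[(edge + 1L):blank_n] else NULL
  times <- rel / fs
  pre <- times < 0
  for (i in seq_len(nrow(ev))) {
    c0 <- round(ev$onset_s[i] * fs) + 1L
    a <- amp[c0 + rel]
    mu <- mean(a); s <- sd(a)
    if (s == 0) {
      z[i, ] <- 0
      next
    }
    zi <- (a - mu) / s
    b <- if (use_session) mean((blank_amp - mu) / s) else mean(zi[pre])
    z[i, ] <- zi - b
  }
  structure(
    list(z = z, times = times, condition = as.character(ev$condition),
         fs = fs, channel = channel, band = band,
         baseline = if (use_session) "session" else "trial"),
    class = "hg_timecourse"
  )
}

#' @export
print.hg_timecourse <- function(x, ...) {
  cat(sprintf("<hg_timecourse> %d trials, %.2f..%.2f s, band %g-%g Hz (%s baseline)\n",
              nrow(x$z), min(x$times), max(x$times), x$band[1], x$band[2],
              x$baseline))
  invisible(x)
}

#' Condition contrast of a high-gamma time course
#'
#' Cluster-mass permutation test (aversive vs neutral) restricted to the
#' post-stimulus part of the epoch.
#'
#' @param tc an [hg_timecourse()] result.
#' @param contrast the two condition labels, difference is first - second.
#' @param post_only restrict cluster formation to t >= 0 (default TRUE).
#' @param ... passed to [cluster_permutation_test()].
#' @return the `cluster_test` plus `times` used, as attribute.
#' @export
hg_condition_contrast <- function(tc, contrast = c("aversive", "neutral"),
                                  post_only = TRUE, ...) {
  sel <- if (post_only) tc$times >= 0 else rep(TRUE, length(tc$times))
  a <- tc$z[tc$condition == contrast[1], sel, drop = FALSE]
  b <- tc$z[tc$condition == contrast[2], sel, drop = FALSE]
  res <- cluster_permutation_test(a, b, ...)
  attr(res, "times") <- tc$times[sel]
  res
}

#' Peak latency of a trial-averaged trace inside a window
#'
#' The latency of the maximum of the trial-averaged trace within the given
#' window; ties are broken by the earliest sample.
#'
#' @param trace numeric vector (trial average) or trials x samples matrix
#'   (averaged over rows).
#' @param times sample times in seconds.
#' @param window length-2 window in seconds; `NULL` window returns `NULL`.
#' @return latency in milliseconds, or `NULL` for an empty window.
#' @export
peak_latency <- function(trace, times, window) {
  if (is.null(window)) return(NULL)
  if (is.matrix(trace)) trace <- colMeans(trace)
  sel <- which(times >= window[1] & times <= window[2])
  if (!length(sel)) return(NULL)
  1000 * times[sel[which.max(trace[sel])]]
}

#' Event-related potentials with pointwise condition tests
#'
#' Low-pass filters the recording (30 Hz), epochs it, subtracts the
#' pre-stimulus baseline and returns per-condition averages with pointwise
#' two-sample t-tests.
#'
#' @param rec an [lfp_recording] with events.
#' @param channel channel label or index.
#' @param window epoch window (s).
#' @param lp_hz low-pass cut-off (Hz, default 30).
#' @param baseline baseline window (s, default `c(-0.5, 0)`).
#' @param contrast condition labels to compare.
#' @return list with `times`, per-condition means, `t`, `p`.
#' @export
erp <- function(rec, channel, window = c(-0.5, 1.5), lp_hz = 30,
                baseline = c(-0.5, 0), contrast = c("aversive", "neutral")) {
  fs <- rec$fs
  x <- lowpass_fir(channel_signal(rec, channel), lp_hz, fs = fs)
  ev <- rec$events
  rel <- seq(round(window[1] * fs), round(window[2] * fs) - 1L)
  n <- length(x)
  rows <- list(); labs <- character(0)
  for (i in seq_len(nrow(ev))) {
    c0 <- round(ev$onset_s[i] * fs) + 1L
    idx <- c0 + rel
    if (idx[1] < 1L || idx[length(idx)] > n) next
    rows[[length(rows) + 1L]] <- x[idx]
    labs <- c(labs, as.character(ev$condition[i]))
  }
  ep <- do.call(rbind, rows)
  times <- rel / fs
  bsel <- times >= baseline[1] & times < baseline[2]
  ep <- ep - rowMeans(ep[, bsel, drop = FALSE])
  out <- list(times = times, condition = labs)
  for (lab in unique(labs)) {
    out[[paste0("mean_", lab)]] <- colMeans(ep[labs == lab, , drop = FALSE])
  }
  if (all(contrast %in% labs)) {
    tt <- pointwise_t(ep[labs == contrast[1], , drop = FALSE],
                      ep[labs == contrast[2], , drop = FALSE])
    out$t <- tt$t; out$p <- tt$p; out$contrast <- contrast
  }
  out
}

#' Theta-trough-locked time-frequency average
#'
#' The signal is filtered into the subject-specific low-frequency band and
#' Hilbert phase extracted (cosine convention: 0 = peak, +/-pi = trough).
#' Troughs are the local phase minima below `-pi + 0.01` (equivalently the
#' phase wrap points). One-second epochs centred on troughs are cut from a
#' set of normalised instantaneous power series (filter-bank bands whose
#' signals are z-scored before squaring the Hilbert amplitude) and averaged.
#' An optional surrogate test compares each (time, frequency) cell to epochs
#' centred at random times.
#'
#' @param x numeric signal (>= 10 s recommended).
#' @param fs sampling rate (Hz).
#' @param band a [band_spec()] for the phase-bearing low-frequency band.
#' @param freq_range frequency range of the power map (default `c(20, 180)`).
#' @param epoch_s epoch length centred on each trough (default 1 s).
#' @param n_perm surrogate count for pointwise p-values (0 = skip).
#' @param seed RNG seed for surrogates.
#' @return list of class `trough_tf`: `times`, `freqs`, `power` (freq x
#'   time), `erp` (trough-locked average of the raw signal), `trough_idx`,
#'   optionally `p`.
#' @export
trough_locked_tf <- function(x, fs, band, freq_range = c(20, 180),
                             epoch_s = 1, n_perm = 0, seed = NULL) {
  xb <- bandpass_fir(x, band$low_hz, band$high_hz, fs = fs)
  phi <- Arg(hilbert_analytic(xb))
  n <- length(x)
  # troughs: wrap points of the increasing phase (local phase minima just
  # above -pi); the tolerance tracks the per-sample phase step so detection
  # does not depend on the sampling rate
  tol <- max(0.01, 2 * pi * band$high_hz / fs)
  wrap <- which(diff(phi) < -pi) + 1L
  wrap <- wrap[phi[wrap] < -pi + tol]
  # snap each trough to the filtered-trace minimum in a 2-sample neighbourhood
  wrap <- vapply(wrap, function(i) {
    lo <- max(1L, i - 2L); hi <- min(n, i + 2L)
    lo + which.min(xb[lo:hi]) - 1L
  }, integer(1))
  half <- round(epoch_s * fs / 2)
  wrap <- wrap[wrap > half & wrap + half <= n]
  if (length(wrap) < 5) stop("fewer than 5 troughs detected")
  rel <- seq(-half, half - 1L)
  centres <- filterbank_centres(max(1, freq_range[1]),
                                min(freq_range[2], fs / 2 / 1.3 * 0.999))
  cut_epochs <- function(series, centres_idx) {
    sapply(centres_idx, function(c0) series[c0 + rel])
  }
  power_map <- matrix(NA_real_, length(centres), length(rel))
  pmap <- if (n_perm > 0) matrix(NA_real_, length(centres), length(rel)) else NULL
  surrogate_centres <- if (n_perm > 0) {
    with_seed(seed, replicate(n_perm,
      sample((half + 1L):(n - half), length(wrap), replace = TRUE),
      simplify = FALSE))
  } else {
    NULL
  }
  for (k in seq_along(centres)) {
    cf <- centres[k]
    xf <- bandpass_fir(x, 0.7 * cf, 1.3 * cf, fs = fs)
    xf <- (xf - mean(xf)) / sd(xf)
    pw <- analytic_signal(xf, fs)$amplitude^2
    power_map[k, ] <- rowMeans(cut_epochs(pw, wrap))
    if (n_perm > 0) {
      null_means <- vapply(surrogate_centres, function(sc) {
        rowMeans(cut_epochs(pw, sc))
      }, numeric(length(rel)))
      pmap[k, ] <- vapply(seq_along(rel), function(i) {
        (1 + sum(null_means[i, ] >= power_map[k, i])) / (n_perm + 1)
      }, numeric(1))
    }
  }
  structure(
    list(times = rel / fs, freqs = centres, power = power_map,
         erp = rowMeans(sapply(wrap, function(c0) x[c0 + rel])),
         trough_idx = wrap, p = pmap, band = band),
    class = "trough_tf"
  )
}
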