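# Inter-electrode phase locking, circular-linear phase-amplitude coupling,
# permutation z-PAC, and time-lagged PAC.

#' Phase locking value over 1-second windows
#'
#' The phase difference series is segmented into non-overlapping windows and
#' each window's PLV is the modulus of its time-averaged unit phasor:
#' `|mean(exp(i (phi_i - phi_j)))|`. Values lie in `[0, 1]`; 1 means a
#' constant phase difference.
#'
#' @param phase_i,phase_j wrapped phase series of equal length (radians).
#' @param fs sampling rate (Hz).
#' @param window_s window length in seconds (default 1).
#' @return list of class `plv_result`: `window_plv`, `mean`, `n_windows`,
#'   `window_starts` (sample index of each window).
#' @export
plv <- function(phase_i, phase_j, fs, window_s = 1) {
  stopifnot(length(phase_i) == length(phase_j))
  nwin <- round(window_s * fs)
  n <- length(phase_i)
  if (n < nwin) stop("phase series shorter than one window")
  k <- n %/% nwin
  d <- exp(1i * (phase_i - phase_j))
  starts <- (seq_len(k) - 1L) * nwin + 1L
  wplv <- vapply(starts, function(s) {
    Mod(mean(d[s:(s + nwin - 1L)]))
  }, numeric(1))
  structure(list(window_plv = wplv, mean = mean(wplv), n_windows = k,
                 window_starts = starts, window_s = window_s, fs = fs),
            class = "plv_result")
}

#' @export
print.plv_result <- function(x, ...) {
  cat(sprintf("<plv_result> mean PLV %.3f over %d windows of %g s\n",
              x$mean, x$n_windows, x$window_s))
  invisible(x)
}

# window-level condition labels from sample-level labels (label at window
# start; windows spanning a boundary inherit the start label)
window_labels <- function(labels, window_starts) labels[window_starts]

#' Two-step PLV condition contrast for one electrode pair
#'
#' Step 1 (within-condition significance): the observed per-condition mean
#' PLV is compared with the 99th percentile of a null in which the pairing
#' between the two channels' windows is shuffled within the condition. Step
#' 2 (condition difference): for pairs passing step 1 in both conditions,
#' window condition labels are permuted to obtain a p-value for the PLV
#' difference (first condition minus second).
#'
#' @param phase_i,phase_j wrapped phase series.
#' @param labels per-sample condition labels (see [sample_conditions()]).
#' @param fs sampling rate.
#' @param window_s PLV window (s).
#' @param contrast two condition labels, difference = first - second.
#' @param n_perm permutations for both steps.
#' @param q within-condition percentile threshold (default 99).
#' @param seed RNG seed.
#' @return list of class `plv_contrast`: per-condition `plv`, `threshold`,
#'   `passed` (both conditions supra-threshold), `difference`, `p_difference`
#'   (NA unless passed).
#' @export
plv_pair_contrast <- function(phase_i, phase_j, labels, fs, window_s = 1,
                              contrast = c("aversive", "neutral"),
                              n_perm = 200, q = 99, seed = NULL) {
  res <- plv(phase_i, phase_j, fs, window_s)
  wl <- window_labels(labels, res$window_starts)
  nwin <- round(window_s * fs)
  seg_i <- lapply(res$window_starts, function(s) phase_i[s:(s + nwin - 1L)])
  seg_j <- lapply(res$window_starts, function(s) phase_j[s:(s + nwin - 1L)])
  plv_of <- function(ii, jj) {
    mean(vapply(seq_along(ii), function(w) {
      Mod(mean(exp(1i * (seg_i[[ii[w]]] - seg_j[[jj[w]]]))))
    }, numeric(1)))
  }
  out <- list(contrast = contrast, window_plv = res$window_plv, labels = wl)
  obs <- thr <- setNames(numeric(2), contrast)
  with_seed(seed, {
    for (cond in contrast) {
      idx <- which(wl == cond)
      if (length(idx) < 2) stop("fewer than 2 windows in condition ", cond)
      obs[cond] <- mean(res$window_plv[idx])
      null <- vapply(seq_len(n_perm), function(p) {
        plv_of(idx, sample(idx))
      }, numeric(1))
      thr[cond] <- quantile(null, q / 100, names = FALSE)
    }
    passed <- all(obs > thr)
    difference <- unname(obs[contrast[1]] - obs[contrast[2]])
    p_diff <- NA_real_
    if (passed) {
      both <- which(wl %in% contrast)
      wp <- res$window_plv
      lab <- wl[both]
      null_diff <- vapply(seq_len(n_perm), function(p) {
        pl <- sample(lab)
        mean(wp[both[pl == contrast[1]]]) - mean(wp[both[pl == contrast[2]]])
      }, numeric(1))
      p_diff <- (1 + sum(abs(null_diff) >= abs(difference))) / (n_perm + 1)
    }
  })
  out$plv <- obs
  out$threshold <- thr
  out$passed <- passed
  out$difference <- difference
  out$p_difference <- p_diff
  class(out) <- "plv_contrast"
  out
}

#' @export
print.plv_contrast <- function(x, ...) {
  cat(sprintf("<plv_contrast> %s: %.3f vs %s: %.3f (thresholds %.3f/%.3f)\n",
              x$contrast[1], x$plv[1], x$contrast[2], x$plv[2],
              x$threshold[1], x$threshold[2]))
  cat(sprintf("  passed both thresholds: %s; difference %.4f, p = %s\n",
              x$passed, x$difference, format(x$p_difference)))
  invisible(x)
}

#' PLV contrast across a set of electrode pairs
#'
#' Applies [plv_pair_contrast()] to every pair and keeps those passing the
#' within-condition thresholds in both conditions. Ties in significance are
#' broken towards lower channel indices.
#'
#' @param rec an [lfp_recording] whose events define the condition labels.
#' @param pairs data frame with columns `chan_i`, `chan_j` (labels).
#' @param band a [band_spec()]; both channels are filtered to this band.
#' @param ... passed to [plv_pair_contrast()].
#' @return list of class `plv_pair_table`: `table` (one row per pair with
#'   PLVs, thresholds, pass flag, difference, p) and `results` (full per-pair
#'   objects).
#' @export
plv_contrast <- function(rec, pairs, band, ...) {
  labels <- sample_conditions(rec)
  phases <- new.env()
  get_phase <- function(lab) {
    if (is.null(phases[[lab]])) {
      xb <- bandpass_fir(channel_signal(rec, lab), band$low_hz, band$high_hz,
                         fs = rec$fs)
      phases[[lab]] <- Arg(hilbert_analytic(xb))
    }
    phases[[lab]]
  }
  results <- vector("list", nrow(pairs))
  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    pi_ <- get_phase(pairs$chan_i[k])
    pj <- get_phase(pairs$chan_j[k])
    r <- plv_pair_contrast(pi_, pj, labels, rec$fs, ...)
    results[[k]] <- r
    rows[[k]] <- data.frame(
      chan_i = pairs$chan_i[k], chan_j = pairs$chan_j[k],
      plv_1 = unname(r$plv[1]), plv_2 = unname(r$plv[2]),
      thr_1 = unname(r$threshold[1]), thr_2 = unname(r$threshold[2]),
      passed = r$passed, difference = r$difference, p = r$p_difference
    )
  }
  structure(list(table = do.call(rbind, rows), results = results),
            class = "plv_pair_table")
}

#' z-scored PLV difference spectrum (1-30 Hz)
#'
#' Per filter-bank bin, window PLVs are computed for both channels and the
#' per-condition means differenced (first minus second condition). The
#' difference curve is z-normalised across bins and smoothed with an
#' interpolating spline of order 5 for display.
#'
#' @param x_i,x_j raw (broadband) signals for the two channels.
#' @param labels per-sample condition labels.
#' @param fs sampling rate.
#' @param f_min,f_max filter-bank grid (default 1-30 Hz).
#' @param contrast condition labels, difference = first - second.
#' @param window_s PLV window (s).
#' @param n_interp number of display points for the spline.
#' @return data frame-based list of class `plv_spectrum`: `centres`, `diff`,
#'   `z`, and `smooth` (data frame `freq`, `z`).
#' @export
plv_spectrum <- function(x_i, x_j, labels, fs, f_min = 1, f_max = 30,
                         contrast = c("aversive", "neutral"), window_s = 1,
                         n_interp = 200) {
  bank_i <- filterbank_decompose(x_i, fs, f_min, f_max)
  bank_j <- filterbank_decompose(x_j, fs, f_min, f_max)
  centres <- vapply(bank_i, function(b) b$band$centre_hz, numeric(1))
  diffs <- vapply(seq_along(bank_i), function(k) {
    r <- plv(bank_i[[k]]$phase, bank_j[[k]]$phase, fs, window_s)
    wl <- window_labels(labels, r$window_starts)
    mean(r$window_plv[wl == contrast[1]]) -
      mean(r$window_plv[wl == contrast[2]])
  }, numeric(1))
  z <- (diffs - mean(diffs)) / sd(diffs)
  fine <- seq(min(centres), max(centres), length.out = n_interp)
  smooth <- data.frame(freq = fine,
                       z = spline_interp(centres, z, fine, order = 5L))
  structure(list(centres = centres, diff = diffs, z = z, smooth = smooth,
                 contrast = contrast),
            class = "plv_spectrum")
}

#' Circular-linear correlation between phase and amplitude
#'
#' The coupling strength between a wrapped phase series and a non-negative
#' amplitude series: with `r_ca = cor(cos phi, a)`, `r_sa = cor(sin phi, a)`
#' and `r_cs = cor(sin phi, cos phi)` (both circular terms from the
#' modulating phase),
#' `rho = sqrt((r_ca^2 + r_sa^2 - 2 r_ca r_sa r_cs) / (1 - r_cs^2))`.
#'
#' @param phase wrapped phase series (radians).
#' @param amplitude amplitude series (same length, >= 0).
#' @return list of class `pac_result`: `rho`, `r_ca`, `r_sa`, `r_cs`,
#'   `z_rho`, `degenerate` (TRUE when the amplitude had zero variance).
#' @export
pac_circular_linear <- function(phase, amplitude) {
  stopifnot(length(phase) == length(amplitude))
  if (sd(amplitude) == 0) {
    return(structure(list(rho = 0, r_ca = 0, r_sa = 0, r_cs = 0, z_rho = 0,
                          degenerate = TRUE), class = "pac_result"))
  }
  cp <- cos(phase); sp <- sin(phase)
  r_ca <- safe_cor(cp, amplitude)
  r_sa <- safe_cor(sp, amplitude)
  r_cs <- safe_cor(sp, cp)
  rho2 <- (r_ca^2 + r_sa^2 - 2 * r_ca * r_sa * r_cs) / (1 - r_cs^2)
  rho <- sqrt(max(min(rho2, 1), 0))
  structure(list(rho = rho, r_ca = r_ca, r_sa = r_sa, r_cs = r_cs,
                 z_rho = fisher_z(min(rho, 1 - 1e-12)), degenerate = FALSE),
            class = "pac_result")
}

#' @export
print.pac_result <- function(x, ...) {
  cat(sprintf("<pac_result> rho = %.4f (r_ca %.3f, r_sa %.3f, r_cs %.3f)\n",
              x$rho, x$r_ca, x$r_sa, x$r_cs))
  invisible(x)
}

#' Permutation z-score of the condition difference in PAC
#'
#' PAC (Fisher-z of the circular-linear rho) is computed per condition over
#' the samples belonging to that condition's windows; the observed
#' difference `z(rho_1) - z(rho_2)` is standardised against a null obtained
#' by permuting window-level condition labels. Positive z means stronger
#' coupling in the first contrast condition.
#'
#' @param phase,amplitude series from the modulating and modulated signals.
#' @param labels per-sample condition labels.
#' @param fs sampling rate (windows of `window_s` are the exchangeable unit).
#' @param contrast condition labels, difference = first - second.
#' @param window_s exchangeable-window length (default 1 s).
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @return list of class `z_pac`: `z`, `delta_rho_z`, `rho` (per condition),
#'   `null_mean`, `null_sd`.
#' @export
z_pac <- function(phase, amplitude, labels, fs,
                  contrast = c("aversive", "neutral"), window_s = 1,
                  n_perm = 200, seed = NULL) {
  stopifnot(length(phase) == length(amplitude),
            length(labels) == length(phase))
  nwin <- round(window_s * fs)
  k <- length(phase) %/% nwin
  starts <- (seq_len(k) - 1L) * nwin + 1L
  wl <- window_labels(labels, starts)
  widx <- lapply(starts, function(s) s:(s + nwin - 1L))
  use <- which(wl %in% contrast)
  if (length(unique(wl[use])) < 2) stop("both contrast conditions required")
  delta_of <- function(assign_labels) {
    i1 <- unlist(widx[use[assign_labels == contrast[1]]])
    i2 <- unlist(widx[use[assign_labels == contrast[2]]])
    z_difference(pac_circular_linear(phase[i1], amplitude[i1])$rho,
                 pac_circular_linear(phase[i2], amplitude[i2])$rho)
  }
  obs <- delta_of(wl[use])
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(p) delta_of(sample(wl[use])),
                   numeric(1))
  })
  mu <- mean(null); s <- sd(null)
  rho1 <- pac_circular_linear(
    phase[unlist(widx[use[wl[use] == contrast[1]]])],
    amplitude[unlist(widx[use[wl[use] == contrast[1]]])])$rho
  rho2 <- pac_circular_linear(
    phase[unlist(widx[use[wl[use] == contrast[2]]])],
    amplitude[unlist(widx[use[wl[use] == contrast[2]]])])$rho
  structure(
    list(z = if (s > 0) (obs - mu) / s else 0,
         delta_rho_z = obs, rho = setNames(c(rho1, rho2), contrast),
         null_mean = mu, null_sd = s, n_perm = n_perm, contrast = contrast),
    class = "z_pac"
  )
}

#' @export
print.z_pac <- function(x, ...) {
  cat(sprintf("<z_pac> z = %.2f (delta rho_z = %.4f; rho %s = %.4f, %s = %.4f)\n",
              x$z, x$delta_rho_z, x$contrast[1], x$rho[1], x$contrast[2],
              x$rho[2]))
  invisible(x)
}

#' z-PAC comodulogram over phase and amplitude frequency grids
#'
#' Computes [z_pac()] for every (phase bin, amplitude bin) combination of
#' the adaptive filter-bank grids.
#'
#' @param x_phase,x_amp raw signals providing modulating phase and modulated
#'   amplitude.
#' @param labels per-sample condition labels.
#' @param fs sampling rate.
#' @param phase_range,amp_range frequency ranges of the two grids (defaults
#'   1-30 Hz and 30-250 Hz; the amplitude grid is clipped below Nyquist).
#' @param ... passed to [z_pac()].
#' @return list of class `comodulogram`: `phase_freqs`, `amp_freqs`, `z`
#'   (phase x amplitude matrix).
#' @export
pac_comodulogram <- function(x_phase, x_amp, labels, fs,
                             phase_range = c(1, 30), amp_range = c(30, 250),
                             ...) {
  bank_p <- filterbank_decompose(x_phase, fs, phase_range[1], phase_range[2])
  bank_a <- filterbank_decompose(x_amp, fs, amp_range[1],
                                 min(amp_range[2], fs / 2 / 1.3 * 0.999))
  pf <- vapply(bank_p, function(b) b$band$centre_hz, numeric(1))
  af <- vapply(bank_a, function(b) b$band$centre_hz, numeric(1))
  z <- matrix(NA_real_, length(pf), length(af))
  for (i in seq_along(pf)) {
    for (j in seq_along(af)) {
      z[i, j] <- z_pac(bank_p[[i]]$phase, bank_a[[j]]$amplitude, labels, fs,
                       ...)$z
    }
  }
  structure(list(phase_freqs = pf, amp_freqs = af, z = z),
            class = "comodulogram")
}

#' Time-lagged phase-amplitude coupling profile
#'
#' PAC is recomputed after shifting the amplitude series relative to the
#' phase series over a grid of lags (10 ms steps, +/-200 ms by default).
#' Sign convention: a negative peak lag means the modulating phase precedes
#' the modulated amplitude (the modulator leads by |lag|).
#'
#' @param phase,amplitude series as in [pac_circular_linear()].
#' @param fs sampling rate.
#' @param lags_ms lag grid in ms (symmetric about 0).
#' @param labels optional per-sample labels; when given, PAC per lag is
#'   computed only over samples of `condition`.
#' @param condition condition to restrict to (default `"aversive"`).
#' @return list of class `lag_pac`: `lags_ms`, `rho`, `peak_lag_ms`.
#' @export
lag_pac <- function(phase, amplitude, fs, lags_ms = seq(-200, 200, by = 10),
                    labels = NULL, condition = "aversive") {
  n <- length(phase)
  max_shift <- max(abs(round(lags_ms / 1000 * fs)))
  if (n <= 2 * max_shift) stop("signals shorter than twice the maximum lag")
  core <- (max_shift + 1L):(n - max_shift)
  if (!is.null(labels)) core <- core[labels[core] == condition]
  rho <- vapply(lags_ms, function(L) {
    s <- round(L / 1000 * fs)
    pac_circular_linear(phase[core], amplitude[core - s])$rho
  }, numeric(1))
  structure(list(lags_ms = lags_ms, rho = rho,
                 peak_lag_ms = lags_ms[which.max(rho)]),
            class = "lag_pac")
}

#' @export
print.lag_pac <- function(x, ...) {
  cat(sprintf("<lag_pac> peak at %g ms (rho %.4f)\n",
              x$peak_lag_ms, max(x$rho)))
  invisible(x)
}
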