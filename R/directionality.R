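# Directionality: phase slope index and spectral Granger causality.

# epoch-averaged complex coherency on a zero-padded FFT grid.
# x, y: trials x samples matrices; returns list(freqs, coh).
.coherency <- function(x, y, fs, delta_f) {
  stopifnot(all(dim(x) == dim(y)))
  ns <- ncol(x)
  nfft <- max(ns, round(fs / delta_f))
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ns) - 1) / (ns - 1))  # Hann taper
  taper <- function(m) {
    m <- m - rowMeans(m)
    m <- sweep(m, 2L, w, `*`)
    t(mvfft(t(cbind(m, matrix(0, nrow(m), nfft - ns)))))
  }
  X <- taper(x); Y <- taper(y)
  Sxy <- colMeans(X * Conj(Y))
  Sxx <- colMeans(Mod(X)^2)
  Syy <- colMeans(Mod(Y)^2)
  half <- floor(nfft / 2) + 1L
  coh <- Sxy[seq_len(half)] / sqrt(Sxx[seq_len(half)] * Syy[seq_len(half)])
  list(freqs = (seq_len(half) - 1L) * fs / nfft, coh = coh)
}

#' Phase slope index between two sets of epochs
#'
#' The complex coherency is estimated from epoch-averaged cross- and
#' auto-spectra (single Hann taper per epoch, zero-padded to the requested
#' frequency resolution) and the phase slope index is
#' `Psi = Im( sum_f conj(C(f)) C(f + delta_f) )` over a band of total width
#' `8 delta_f` centred on `nu` (e.g. centre 8 Hz with 1 Hz resolution spans
#' 4-12 Hz). Positive Psi means the first signal leads. Antisymmetric:
#' `psi(x, y) = -psi(y, x)`.
#'
#' @param x_epochs,y_epochs trials x samples matrices (>= 8 epochs
#'   recommended).
#' @param fs sampling rate (Hz).
#' @param nu_hz centre frequency of the estimation band.
#' @param delta_f_hz frequency resolution (band spans `nu +/- 4 delta_f`).
#' @return list of class `psi_result`: `psi`, `band_hz`, `nu_hz`,
#'   `delta_f_hz`.
#' @export
psi <- function(x_epochs, y_epochs, fs, nu_hz, delta_f_hz = 1) {
  band <- c(nu_hz - 4 * delta_f_hz, nu_hz + 4 * delta_f_hz)
  if (band[1] < 0 || band[2] > fs / 2) {
    stop("estimation band [", band[1], ", ", band[2],
         "] Hz outside the resolvable range")
  }
  ch <- .coherency(as.matrix(x_epochs), as.matrix(y_epochs), fs, delta_f_hz)
  # bins at spacing delta_f covering [nu - 4 df, nu + 4 df - df]
  fgrid <- seq(band[1], band[2] - delta_f_hz, by = delta_f_hz)
  idx <- vapply(fgrid, function(f) which.min(abs(ch$freqs - f)), integer(1))
  idx2 <- vapply(fgrid + delta_f_hz, function(f) which.min(abs(ch$freqs - f)),
                 integer(1))
  val <- Im(sum(Conj(ch$coh[idx]) * ch$coh[idx2]))
  structure(list(psi = val, band_hz = band, nu_hz = nu_hz,
                 delta_f_hz = delta_f_hz),
            class = "psi_result")
}

#' Sliding-window PSI with per-condition permutation thresholds
#'
#' [psi()] is evaluated in sliding windows across the epoch (100 ms windows
#' stepped by 25 ms by default), separately per condition. A null
#' distribution per window is built by shuffling the trial pairing of the
#' second signal; the 99.5th percentile of |Psi| gives the significance
#' threshold.
#'
#' @param x_epochs,y_epochs trials x samples matrices.
#' @param condition per-trial condition labels (or NULL for a single set).
#' @param fs sampling rate.
#' @param nu_hz,delta_f_hz band parameters passed to [psi()].
#' @param window_s,step_s sliding-window length and step (s).
#' @param n_perm trial-shuffle permutations (0 skips thresholds).
#' @param seed RNG seed.
#' @return list of class `psi_profile`: `times` (window centres, s,
#'   relative to epoch start), per-condition `psi` matrices and `threshold`.
#' @export
psi_sliding <- function(x_epochs, y_epochs, condition = NULL, fs, nu_hz,
                        delta_f_hz = 1, window_s = 0.1, step_s = 0.025,
                        n_perm = 0, seed = NULL) {
  x_epochs <- as.matrix(x_epochs); y_epochs <- as.matrix(y_epochs)
  ns <- ncol(x_epochs)
  nwin <- round(window_s * fs)
  hop <- max(1L, round(step_s * fs))
  starts <- seq(1L, ns - nwin + 1L, by = hop)
  conds <- if (is.null(condition)) list(all = seq_len(nrow(x_epochs)))
           else split(seq_len(nrow(x_epochs)), condition)
  out_psi <- lapply(conds, function(rows) {
    vapply(starts, function(s) {
      psi(x_epochs[rows, s:(s + nwin - 1L), drop = FALSE],
          y_epochs[rows, s:(s + nwin - 1L), drop = FALSE],
          fs, nu_hz, delta_f_hz)$psi
    }, numeric(1))
  })
  thresholds <- NULL
  if (n_perm > 0) {
    with_seed(seed, {
      thresholds <- lapply(conds, function(rows) {
        null_abs <- replicate(n_perm, {
          perm <- sample(rows)
          max(abs(vapply(starts, function(s) {
            psi(x_epochs[rows, s:(s + nwin - 1L), drop = FALSE],
                y_epochs[perm, s:(s + nwin - 1L), drop = FALSE],
                fs, nu_hz, delta_f_hz)$psi
          }, numeric(1))))
        })
        quantile(null_abs, 0.995, names = FALSE)
      })
    })
  }
  structure(list(times = (starts + nwin / 2) / fs, psi = out_psi,
                 threshold = thresholds, nu_hz = nu_hz,
                 delta_f_hz = delta_f_hz),
            class = "psi_profile")
}

# ---- spectral Granger causality -------------------------------------------

# Fit a bivariate VAR(m) across trial realizations by OLS.
# x, y: trials x samples. Returns coefficient array A (2 x 2 x m) and
# residual covariance Sigma (ML estimate).
fit_var <- function(x, y, m, burn = m) {
  x <- as.matrix(x); y <- as.matrix(y)
  nt <- nrow(x); ns <- ncol(x)
  burn <- max(burn, m)
  if (ns <= burn + 2) stop("epochs too short for VAR order ", m)
  rows <- (burn + 1L):ns
  Yresp <- NULL; Z <- NULL
  # build per-trial lagged design, stacked
  nrows <- nt * length(rows)
  Z <- matrix(0, nrows, 2L * m)
  Yresp <- matrix(0, nrows, 2L)
  r0 <- 0L
  for (tr in seq_len(nt)) {
    xi <- x[tr, ]; yi <- y[tr, ]
    blk <- r0 + seq_along(rows)
    Yresp[blk, 1] <- xi[rows]
    Yresp[blk, 2] <- yi[rows]
    for (k in seq_len(m)) {
      Z[blk, 2 * k - 1L] <- xi[rows - k]
      Z[blk, 2 * k] <- yi[rows - k]
    }
    r0 <- r0 + length(rows)
  }
  B <- qr.solve(crossprod(Z) + diag(1e-10, ncol(Z)), crossprod(Z, Yresp))
  resid <- Yresp - Z %*% B
  Sigma <- crossprod(resid) / nrow(resid)
  A <- array(0, dim = c(2, 2, m))
  for (k in seq_len(m)) {
    A[, , k] <- t(B[c(2 * k - 1L, 2 * k), ])
  }
  list(A = A, Sigma = Sigma, n_obs = nrow(resid), order = m)
}

var_aic <- function(fit) {
  # log det Sigma + 2 * p * n^2 / T  (n = 2 channels)
  d <- determinant(fit$Sigma, logarithm = TRUE)
  as.numeric(d$modulus) + 2 * fit$order * 4 / fit$n_obs
}

var_stable <- function(fit, margin = 1 - 1e-6) {
  m <- fit$order
  comp <- matrix(0, 2 * m, 2 * m)
  for (k in seq_len(m)) comp[1:2, (2 * k - 1):(2 * k)] <- fit$A[, , k]
  if (m > 1) comp[3:(2 * m), 1:(2 * (m - 1))] <- diag(2 * (m - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values)) < margin
}

#' Spectral Granger causality between two epoch sets
#'
#' A bivariate autoregressive model is fitted across epoch realizations by
#' least squares, with the order chosen by AIC over `order_range` (unstable
#' fits are refitted at a lower order with a warning). Geweke's
#' frequency-domain decomposition gives the Granger index per direction and
#' frequency.
#'
#' @param x_epochs,y_epochs trials x samples matrices (already low-pass
#'   filtered and down-sampled, e.g. to 250 Hz).
#' @param fs sampling rate of the epochs (Hz).
#' @param freqs frequency grid (default 1-85 Hz clipped below Nyquist).
#' @param order fixed VAR order (overrides selection).
#' @param order_range AIC search range (default 1:20).
#' @return list of class `granger_result`: `freqs`, `gc_xy` (x drives y),
#'   `gc_yx`, `order`, `aic`, `Sigma`.
#' @export
granger_spectral <- function(x_epochs, y_epochs, fs, freqs = NULL,
                             order = NULL, order_range = 1:20) {
  x_epochs <- as.matrix(x_epochs); y_epochs <- as.matrix(y_epochs)
  if (is.null(freqs)) freqs <- seq(1, min(85, 0.98 * fs / 2), by = 0.5)
  if (is.null(order)) {
    # all candidate orders are scored on the same effective sample so the
    # AIC comparison is not biased by differing sample counts
    burn <- max(order_range)
    aics <- vapply(order_range, function(m) {
      var_aic(fit_var(x_epochs, y_epochs, m, burn = burn))
    }, numeric(1))
    order <- order_range[which.min(aics)]
  } else {
    aics <- NULL
  }
  fit <- fit_var(x_epochs, y_epochs, order)
  while (!var_stable(fit) && fit$order > 1) {
    warning("unstable VAR fit at order ", fit$order, "; refitting at ",
            fit$order - 1)
    fit <- fit_var(x_epochs, y_epochs, fit$order - 1L)
  }
  Sigma <- fit$Sigma
  gc_xy <- gc_yx <- numeric(length(freqs))
  for (i in seq_along(freqs)) {
    Af <- diag(2) + 0i
    for (k in seq_len(fit$order)) {
      Af <- Af - fit$A[, , k] * exp(-2i * pi * freqs[i] * k / fs)
    }
    H <- solve(Af)
    S <- H %*% Sigma %*% Conj(t(H))
    # partial noise variances (Geweke)
    s_xx_p <- Sigma[1, 1] - Sigma[1, 2]^2 / Sigma[2, 2]
    s_yy_p <- Sigma[2, 2] - Sigma[1, 2]^2 / Sigma[1, 1]
    gc_xy[i] <- log(Re(S[2, 2]) /
                      max(Re(S[2, 2]) - s_xx_p * Mod(H[2, 1])^2, 1e-300))
    gc_yx[i] <- log(Re(S[1, 1]) /
                      max(Re(S[1, 1]) - s_yy_p * Mod(H[1, 2])^2, 1e-300))
  }
  structure(
    list(freqs = freqs, gc_xy = pmax(gc_xy, 0), gc_yx = pmax(gc_yx, 0),
         order = fit$order, aic = aics, Sigma = Sigma),
    class = "granger_result"
  )
}

#' @export
print.granger_result <- function(x, ...) {
  cat(sprintf("<granger_result> order %d; mean GC x->y %.4f, y->x %.4f\n",
              x$order, mean(x$gc_xy), mean(x$gc_yx)))
  invisible(x)
}

#' Channel-swap null confidence band for spectral Granger causality
#'
#' Per permutation, each epoch's x/y channel assignment is independently
#' swapped and the spectral Granger index recomputed (at the observed model
#' order). The per-frequency 99% band (0.5th and 99.5th percentiles) of the
#' null is returned for each direction.
#'
#' @param x_epochs,y_epochs trials x samples matrices.
#' @param fs sampling rate.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param ... passed to [granger_spectral()] (e.g. a fixed `order`).
#' @return list of class `granger_null`: `freqs`, per-direction `lower` /
#'   `upper` matrices-of-vectors, `observed` (the unpermuted result).
#' @export
granger_null_channel_swap <- function(x_epochs, y_epochs, fs, n_perm = 100,
                                      seed = NULL, ...) {
  x_epochs <- as.matrix(x_epochs); y_epochs <- as.matrix(y_epochs)
  observed <- granger_spectral(x_epochs, y_epochs, fs, ...)
  nt <- nrow(x_epochs)
  with_seed(seed, {
    null_xy <- matrix(NA_real_, n_perm, length(observed$freqs))
    null_yx <- matrix(NA_real_, n_perm, length(observed$freqs))
    for (p in seq_len(n_perm)) {
      swap <- runif(nt) < 0.5
      xp <- x_epochs; yp <- y_epochs
      xp[swap, ] <- y_epochs[swap, ]
      yp[swap, ] <- x_epochs[swap, ]
      g <- granger_spectral(xp, yp, fs, order = observed$order,
                            freqs = observed$freqs)
      null_xy[p, ] <- g$gc_xy
      null_yx[p, ] <- g$gc_yx
    }
  })
  band <- function(m) {
    list(lower = apply(m, 2, quantile, 0.005, names = FALSE),
         upper = apply(m, 2, quantile, 0.995, names = FALSE))
  }
  structure(list(freqs = observed$freqs, xy = band(null_xy),
                 yx = band(null_yx), observed = observed, n_perm = n_perm),
            class = "granger_null")
}

#' Condition contrast of spectral Granger causality
#'
#' The observed per-frequency difference (first minus second condition) per
#' direction is compared with a null built by permuting per-trial condition
#' labels. The band is two-sided with 1% tail mass per side; frequencies
#' where the observed difference exits the band are flagged.
#'
#' @param x_epochs,y_epochs trials x samples matrices (all trials).
#' @param condition per-trial condition labels.
#' @param fs sampling rate.
#' @param contrast two condition labels, difference = first - second.
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @param ... passed to [granger_spectral()].
#' @return list of class `granger_contrast`: `freqs`, per-direction
#'   `diff`, `lower`, `upper`, `flagged` (logical), plus per-condition fits.
#' @export
granger_condition_contrast <- function(x_epochs, y_epochs, condition, fs,
                                       contrast = c("aversive", "neutral"),
                                       n_perm = 100, seed = NULL, ...) {
  x_epochs <- as.matrix(x_epochs); y_epochs <- as.matrix(y_epochs)
  condition <- as.character(condition)
  sel1 <- condition == contrast[1]
  sel2 <- condition == contrast[2]
  if (!any(sel1) || !any(sel2)) stop("both contrast conditions required")
  fit1 <- granger_spectral(x_epochs[sel1, , drop = FALSE],
                           y_epochs[sel1, , drop = FALSE], fs, ...)
  fit2 <- granger_spectral(x_epochs[sel2, , drop = FALSE],
                           y_epochs[sel2, , drop = FALSE], fs,
                           freqs = fit1$freqs, order = fit1$order)
  obs_xy <- fit1$gc_xy - fit2$gc_xy
  obs_yx <- fit1$gc_yx - fit2$gc_yx
  use <- which(sel1 | sel2)
  labs <- condition[use]
  with_seed(seed, {
    null_xy <- matrix(NA_real_, n_perm, length(fit1$freqs))
    null_yx <- matrix(NA_real_, n_perm, length(fit1$freqs))
    for (p in seq_len(n_perm)) {
      pl <- sample(labs)
      i1 <- use[pl == contrast[1]]
      i2 <- use[pl == contrast[2]]
      g1 <- granger_spectral(x_epochs[i1, , drop = FALSE],
                             y_epochs[i1, , drop = FALSE], fs,
                             freqs = fit1$freqs, order = fit1$order)
      g2 <- granger_spectral(x_epochs[i2, , drop = FALSE],
                             y_epochs[i2, , drop = FALSE], fs,
                             freqs = fit1$freqs, order = fit1$order)
      null_xy[p, ] <- g1$gc_xy - g2$gc_xy
      null_yx[p, ] <- g1$gc_yx - g2$gc_yx
    }
  })
  mkband <- function(nm, obs) {
    lower <- apply(nm, 2, quantile, 0.01, names = FALSE)
    upper <- apply(nm, 2, quantile, 0.99, names = FALSE)
    list(diff = obs, lower = lower, upper = upper,
         flagged = obs > upper | obs < lower)
  }
  structure(list(freqs = fit1$freqs, xy = mkband(null_xy, obs_xy),
                 yx = mkband(null_yx, obs_yx), fit1 = fit1, fit2 = fit2,
                 contrast = contrast, n_perm = n_perm),
            class = "granger_contrast")
}
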