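# Signal conditioning: line-noise regression, white-matter re-referencing,
# saccade detection and perisaccadic high-gamma control analyses.

#' Remove line noise and its harmonics by sliding-window regression
#'
#' For each harmonic `k * base_hz`, sine and cosine regressors are fitted by
#' least squares over overlapping segments and the fitted component is
#' subtracted. Segments are combined with a Hann-weighted overlap-add so the
#' removed component can track slow amplitude/phase drift of the mains.
#'
#' @param rec an [lfp_recording] (or numeric vector, with `fs`).
#' @param base_hz fundamental line frequency (default 60 Hz).
#' @param n_harmonics number of harmonics to remove (fundamental included).
#' @param segment_s segment length in seconds (default 10).
#' @param overlap fractional overlap between segments (default 0.5).
#' @param fs sampling rate for plain-vector input.
#' @return the input with line components subtracted.
#' @export
remove_line_noise <- function(rec, base_hz = 60, n_harmonics = 3,
                              segment_s = 10, overlap = 0.5, fs = NULL) {
  if (inherits(rec, "lfp_recording")) {
    if (base_hz >= rec$fs / 2) stop("base_hz must be below Nyquist")
    rec$data <- t(apply(rec$data, 1L, remove_line_noise, base_hz = base_hz,
                        n_harmonics = n_harmonics, segment_s = segment_s,
                        overlap = overlap, fs = rec$fs))
    return(rec)
  }
  x <- as.numeric(rec)
  if (is.null(fs)) stop("fs required for plain numeric input")
  if (base_hz >= fs / 2) stop("base_hz must be below Nyquist")
  n <- length(x)
  harmonics <- base_hz * seq_len(n_harmonics)
  harmonics <- harmonics[harmonics < fs / 2]
  if (!length(harmonics)) return(x)
  nseg <- max(16L, round(segment_s * fs))
  if (nseg >= n) {
    return(x - .line_fit(x, seq_len(n) / fs, harmonics))
  }
  hop <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, n - 1L, by = hop)
  t_all <- seq_len(n) / fs
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nseg) - 1) / (nseg - 1))  # Hann
  fitted <- numeric(n)
  wsum <- numeric(n)
  for (s in starts) {
    idx <- s:min(s + nseg - 1L, n)
    wi <- w[seq_along(idx)]
    fitted[idx] <- fitted[idx] + wi * .line_fit(x[idx], t_all[idx], harmonics)
    wsum[idx] <- wsum[idx] + wi
    if (s + nseg - 1L >= n) break
  }
  ok <- wsum > 1e-6
  fitted[ok] <- fitted[ok] / wsum[ok]
  fitted[!ok] <- 0
  x - fitted
}

# least-squares sine/cosine fit at the given frequencies
.line_fit <- function(x, t, freqs) {
  X <- do.call(cbind, lapply(freqs, function(f) {
    cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  }))
  beta <- qr.solve(X, x - mean(x))
  as.numeric(X %*% beta)
}

#' Re-reference grey-matter channels to the nearest white-matter contact
#'
#' Each grey-matter channel is re-referenced to the white-matter contact on
#' the same shaft with the smallest contact-index distance. The assigned
#' reference is recorded in `channel_meta$reference`. EOG and white-matter
#' channels are left untouched.
#'
#' @param rec an [lfp_recording].
#' @return the re-referenced recording.
#' @export
rereference_white_matter <- function(rec) {
  cm <- rec$channel_meta
  cm$reference <- NA_character_
  wm <- which(cm$region == "white-matter")
  if (!length(wm)) stop("no white-matter channel available for re-referencing")
  for (ch in seq_len(nrow(cm))) {
    if (cm$region[ch] %in% c("white-matter", "EOG")) next
    cand <- wm[cm$shaft[wm] == cm$shaft[ch]]
    if (!length(cand)) {
      stop("no white-matter contact on shaft ", cm$shaft[ch],
           " for channel ", cm$label[ch])
    }
    ref <- cand[which.min(abs(cm$contact[cand] - cm$contact[ch]))]
    rec$data[ch, ] <- rec$data[ch, ] - rec$data[ref, ]
    cm$reference[ch] <- cm$label[ref]
  }
  rec$channel_meta <- cm
  rec$meta$rereferenced <- TRUE
  rec
}

#' Detect saccades from two-channel EOG by velocity thresholding
#'
#' Velocity is the first difference of the Euclidean distance between
#' successive (horizontal, vertical) gaze samples. Saccades are marked at
#' local velocity peaks above the 99th percentile of the whole-session
#' velocity series, enforcing a minimum 200 ms spacing (the larger peak wins
#' on conflict).
#'
#' @param eog an [lfp_recording] with two EOG channels, or a 2 x n matrix.
#' @param fs sampling rate for matrix input.
#' @param threshold_quantile velocity percentile for the detection threshold.
#' @param min_separation_s refractory spacing between detected events.
#' @return data frame with columns `time_s` and `velocity` (possibly empty).
#' @export
detect_saccades <- function(eog, fs = NULL, threshold_quantile = 0.99,
                            min_separation_s = 0.2) {
  if (inherits(eog, "lfp_recording")) {
    idx <- which(eog$channel_meta$region == "EOG")
    if (length(idx) < 2) idx <- seq_len(min(2L, nrow(eog$data)))
    m <- eog$data[idx[1:2], , drop = FALSE]
    fs <- eog$fs
  } else {
    m <- as.matrix(eog)
    if (is.null(fs)) stop("fs required for matrix input")
  }
  v <- sqrt(diff(m[1, ])^2 + diff(m[2, ])^2)
  if (all(v == 0)) {
    return(data.frame(time_s = numeric(0), velocity = numeric(0)))
  }
  thr <- quantile(v, threshold_quantile, names = FALSE)
  nv <- length(v)
  is_peak <- c(FALSE, v[2:(nv - 1)] > v[1:(nv - 2)] &
                 v[2:(nv - 1)] >= v[3:nv], FALSE) & v > thr
  cand <- which(is_peak)
  if (!length(cand)) {
    return(data.frame(time_s = numeric(0), velocity = numeric(0)))
  }
  # greedy: keep the largest peaks, discard neighbours closer than spacing
  ord <- cand[order(v[cand], decreasing = TRUE)]
  min_gap <- min_separation_s * fs
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) >= min_gap)) kept <- c(kept, p)
  }
  kept <- sort(kept)
  data.frame(time_s = (kept + 0.5) / fs, velocity = v[kept])
}

#' Perisaccadic high-gamma traces with pointwise condition tests
#'
#' High-gamma (70-180 Hz) amplitude is epoched around saccade events,
#' baseline-corrected, and compared between conditions with pointwise
#' two-sample Welch t-tests. The condition of a saccade is the condition of
#' the block it falls in; saccades in the blank are dropped.
#'
#' @param lfp an [lfp_recording] with an events table.
#' @param saccades data frame from [detect_saccades()].
#' @param channel channel label or index to analyse.
#' @param window epoch window around each saccade (s).
#' @param baseline baseline window (s) subtracted per epoch.
#' @param band high-gamma band (Hz).
#' @return list with `times`, per-condition mean traces, pointwise `t` and
#'   `p`, and the per-epoch condition labels; `NULL` (with a warning) if no
#'   saccades were supplied.
#' @export
perisaccadic_hg <- function(lfp, saccades, channel = 1L,
                            window = c(-0.2, 0.5), baseline = c(-0.2, 0),
                            band = c(70, 180)) {
  if (is.null(saccades) || nrow(saccades) == 0) {
    warning("no saccades supplied; returning NULL")
    return(NULL)
  }
  fs <- lfp$fs
  x <- channel_signal(lfp, channel)
  amp <- analytic_signal(bandpass_fir(x, band[1], band[2], fs = fs), fs)$amplitude
  rel <- seq(round(window[1] * fs), round(window[2] * fs) - 1L)
  cond_all <- sample_conditions(lfp)
  n <- length(amp)
  keep <- list()
  labs <- character(0)
  for (i in seq_len(nrow(saccades))) {
    c0 <- round(saccades$time_s[i] * fs) + 1L
    idx <- c0 + rel
    if (idx[1] < 1L || idx[length(idx)] > n) next
    lab <- cond_all[c0]
    if (lab == "blank") next
    keep[[length(keep) + 1L]] <- amp[idx]
    labs <- c(labs, lab)
  }
  if (!length(keep)) {
    warning("no in-block saccade epochs; returning NULL")
    return(NULL)
  }
  ep <- do.call(rbind, keep)
  times <- rel / fs
  bsel <- times >= baseline[1] & times < baseline[2]
  ep <- ep - rowMeans(ep[, bsel, drop = FALSE])
  out <- list(times = times, condition = labs)
  for (lab in unique(labs)) {
    out[[paste0("mean_", lab)]] <- colMeans(ep[labs == lab, , drop = FALSE])
  }
  two <- unique(labs)
  if (length(two) >= 2) {
    tt <- pointwise_t(ep[labs == two[1], , drop = FALSE],
                      ep[labs == two[2], , drop = FALSE])
    out$t <- tt$t
    out$p <- tt$p
    out$contrast <- two[1:2]
  }
  out
}

# vectorised pointwise Welch two-sample t-test over columns
pointwise_t <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, var); vb <- apply(b, 2, var)
  se2 <- va / na + vb / nb
  tstat <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               na + nb - 2)
  p <- 2 * pt(-abs(tstat), df)
  list(t = tstat, p = p, df = df)
}
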