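# Synthetic two-region LFP with known, recoverable coupling.
#
# Each channel is spectrally shaped 1/f^chi Gaussian noise plus a narrow-band
# low-frequency oscillation. The receiver channel additionally carries a
# gamma-band carrier whose instantaneous amplitude follows the lagged
# low-frequency phase of the driver channel with a condition-dependent
# modulation depth (phase-amplitude coupling ground truth), and its
# low-frequency oscillation mixes in a lagged copy of the driver's
# oscillation with a condition-dependent weight (phase-phase coupling ground
# truth). Clip onsets evoke a high-gamma amplitude transient with
# region-specific onset latency and condition-dependent size. An optional
# 60 Hz line component (plus harmonics) is added identically to every
# channel so that white-matter re-referencing can remove it.

#' Ground-truth coupling parameters for the simulator
#'
#' @param driver_channel,receiver_channel labels of the modulating (amygdala)
#'   and modulated (hippocampus) channels.
#' @param f_low_driver_hz,f_low_receiver_hz centre frequencies of each
#'   channel's low-frequency oscillation (Hz).
#' @param f_gamma_receiver_hz centre of the modulated gamma carrier (Hz,
#'   >= 30 and > f_low).
#' @param modulation_depth_aversive,modulation_depth_neutral phase-amplitude
#'   modulation depths in `[0, 1]` per condition (0 during the blank).
#' @param lf_coupling_aversive,lf_coupling_neutral mixing weight in `[0, 1]`
#'   of the lagged driver oscillation into the receiver's low-frequency
#'   oscillation, per condition (drives inter-regional phase locking).
#' @param conduction_lag_ms conduction delay in ms (positive: driver phase
#'   precedes receiver amplitude); |lag| <= 200 ms.
#' @param psd_exponent_chi power-law exponent of the 1/f background.
#' @param hg_onset_ms named vector of evoked high-gamma onset latencies (ms)
#'   per region group (`amygdala`, `hippocampus`).
#' @param evoked_amp_aversive,evoked_amp_neutral evoked high-gamma amplitude
#'   per condition (relative to the unit-variance background).
#' @param evoked_rise_ms,evoked_hold_ms,evoked_fall_ms evoked envelope shape:
#'   half-cosine rise, plateau, half-cosine fall (ms).
#' @param line_noise_amp amplitude of the common 60 Hz component (0 = off).
#' @param lf_bw_hz spectral width of the low-frequency oscillators (Hz).
#' @param lf_amp,gamma_amp,gamma_base oscillation amplitude, gamma scale and
#'   baseline gamma amplitude offset (relative to unit background).
#' @return list of class `coupling_ground_truth`.
#' @export
coupling_ground_truth <- function(driver_channel = "AMY1",
                                  receiver_channel = "HIP1",
                                  f_low_driver_hz = 6,
                                  f_low_receiver_hz = 6.5,
                                  f_gamma_receiver_hz = 100,
                                  modulation_depth_aversive = 0.6,
                                  modulation_depth_neutral = 0.2,
                                  lf_coupling_aversive = 0.8,
                                  lf_coupling_neutral = 0.5,
                                  conduction_lag_ms = 15,
                                  psd_exponent_chi = 2,
                                  hg_onset_ms = c(amygdala = 120,
                                                  hippocampus = 240),
                                  evoked_amp_aversive = 0.6,
                                  evoked_amp_neutral = 0.15,
                                  evoked_rise_ms = 100,
                                  evoked_hold_ms = 300,
                                  evoked_fall_ms = 300,
                                  line_noise_amp = 0.25,
                                  lf_bw_hz = 2,
                                  lf_amp = 2,
                                  gamma_amp = 0.6,
                                  gamma_base = 0.3) {
  depths <- c(modulation_depth_aversive, modulation_depth_neutral,
              lf_coupling_aversive, lf_coupling_neutral)
  if (any(depths < 0 | depths > 1)) {
    stop("modulation depths and coupling weights must lie in [0, 1]")
  }
  if (!(f_gamma_receiver_hz >= 30 && f_gamma_receiver_hz > f_low_driver_hz)) {
    stop("f_gamma must be >= 30 Hz and above the low frequency")
  }
  if (abs(conduction_lag_ms) > 200) {
    stop("conduction lag outside the +/-200 ms analysis range")
  }
  structure(
    list(driver_channel = driver_channel,
         receiver_channel = receiver_channel,
         f_low_driver_hz = f_low_driver_hz,
         f_low_receiver_hz = f_low_receiver_hz,
         f_gamma_receiver_hz = f_gamma_receiver_hz,
         modulation_depth_aversive = modulation_depth_aversive,
         modulation_depth_neutral = modulation_depth_neutral,
         lf_coupling_aversive = lf_coupling_aversive,
         lf_coupling_neutral = lf_coupling_neutral,
         conduction_lag_ms = conduction_lag_ms,
         psd_exponent_chi = psd_exponent_chi,
         hg_onset_ms = hg_onset_ms,
         evoked_amp_aversive = evoked_amp_aversive,
         evoked_amp_neutral = evoked_amp_neutral,
         evoked_rise_ms = evoked_rise_ms,
         evoked_hold_ms = evoked_hold_ms,
         evoked_fall_ms = evoked_fall_ms,
         line_noise_amp = line_noise_amp,
         lf_bw_hz = lf_bw_hz, lf_amp = lf_amp, gamma_amp = gamma_amp,
         gamma_base = gamma_base),
    class = "coupling_ground_truth"
  )
}

#' Default synthetic electrode montage
#'
#' One amygdala shaft (three grey-matter contacts in the basolateral complex
#' plus a white-matter contact) and one hippocampal shaft (four grey-matter
#' contacts spanning subfields plus a white-matter contact). Contact 1 is the
#' most medial on each shaft.
#'
#' @return channel metadata data frame.
#' @export
default_channel_meta <- function() {
  data.frame(
    label = c("AMY1", "AMY2", "AMY3", "AWM4",
              "HIP1", "HIP2", "HIP3", "HIP4", "HWM5"),
    region = c("amygdala-BLA", "amygdala-BLA", "amygdala-CeA", "white-matter",
               "hippocampus-CA1", "hippocampus-CA3", "hippocampus-DG",
               "hippocampus-subiculum", "white-matter"),
    shaft = c(rep("A", 4), rep("H", 5)),
    contact = c(1:4, 1:5),
    laterality = "L",
    stringsAsFactors = FALSE
  )
}

# 1/f^(chi) noise by frequency-domain shaping of white Gaussian noise,
# normalised to unit standard deviation
powerlaw_noise <- function(n, fs, chi) {
  x <- rnorm(n)
  if (chi == 0) return(x)
  X <- fft(x)
  f <- c(0, seq_len(n - 1)) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]  # mirror for negative frequencies
  shape <- c(0, f[-1]^(-chi / 2))      # amplitude ~ f^(-chi/2), kill DC
  y <- Re(fft(X * shape, inverse = TRUE)) / n
  y / sd(y)
}

# narrow-band Gaussian oscillation: white noise shaped with a Gaussian
# spectral bump at f0 (sd_hz wide), unit variance
narrowband_noise <- function(n, fs, f0, bw_hz = 1) {
  x <- rnorm(n)
  X <- fft(x)
  f <- c(0, seq_len(n - 1)) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]
  shape <- exp(-(f - f0)^2 / (2 * (bw_hz / 2)^2))
  y <- Re(fft(X * shape, inverse = TRUE)) / n
  y / sd(y)
}

# half-cosine rise / plateau / half-cosine fall evoked envelope, sampled at fs
evoked_envelope <- function(fs, rise_ms, hold_ms, fall_ms) {
  nr <- max(1L, round(rise_ms / 1000 * fs))
  nh <- max(0L, round(hold_ms / 1000 * fs))
  nf <- max(1L, round(fall_ms / 1000 * fs))
  c((1 - cos(pi * seq_len(nr) / nr)) / 2,
    rep(1, nh),
    (1 + cos(pi * seq_len(nf) / nf)) / 2)
}

#' Simulate a task-structured two-region LFP recording
#'
#' @param schedule events table from [make_task_schedule()].
#' @param truth a [coupling_ground_truth()] object.
#' @param fs sampling rate in Hz; must be at least 4x the gamma frequency.
#' @param seed RNG seed; identical seeds give bit-identical recordings.
#' @param channel_meta montage (default [default_channel_meta()]).
#' @return an [lfp_recording] carrying the schedule and ground truth in its
#'   metadata.
#' @export
simulate_lfp <- function(schedule, truth = coupling_ground_truth(),
                         fs = 2000, seed = 1L,
                         channel_meta = default_channel_meta()) {
  stopifnot(inherits(truth, "coupling_ground_truth"))
  if (fs < 4 * truth$f_gamma_receiver_hz) {
    stop("fs must be at least 4x the gamma frequency")
  }
  if (abs(truth$conduction_lag_ms) > 200) {
    stop("conduction lag outside the +/-200 ms analysis range")
  }
  total_s <- max(schedule$onset_s + schedule$duration_s)
  n <- round(total_s * fs)
  cond <- sample_conditions(schedule, n = n, fs = fs)
  depth <- numeric(n)
  depth[cond == "aversive"] <- truth$modulation_depth_aversive
  depth[cond == "neutral"] <- truth$modulation_depth_neutral
  lfc <- numeric(n)
  lfc[cond == "aversive"] <- truth$lf_coupling_aversive
  lfc[cond == "neutral"] <- truth$lf_coupling_neutral
  lag_n <- round(truth$conduction_lag_ms / 1000 * fs)
  t <- seq_len(n) / fs

  with_seed(seed, {
    nch <- nrow(channel_meta)
    data <- matrix(0, nrow = nch, ncol = n)
    # common line noise (shared across contacts, removable by re-referencing)
    line <- if (truth$line_noise_amp > 0) {
      truth$line_noise_amp * (sin(2 * pi * 60 * t) +
                                0.5 * sin(2 * pi * 120 * t + 0.7) +
                                0.25 * sin(2 * pi * 180 * t + 1.3))
    } else {
      numeric(n)
    }
    # driver oscillation first so its lagged phase is available to all
    drv_idx <- match(truth$driver_channel, channel_meta$label)
    rcv_idx <- match(truth$receiver_channel, channel_meta$label)
    if (is.na(drv_idx) || is.na(rcv_idx)) {
      stop("driver/receiver channels not present in the montage")
    }
    osc_driver <- narrowband_noise(n, fs, truth$f_low_driver_hz,
                                   bw_hz = truth$lf_bw_hz)
    osc_driver_lag <- shift_samples(osc_driver, lag_n)
    phi_driver_lag <- Arg(hilbert_analytic(osc_driver_lag))

    env_shape <- evoked_envelope(fs, truth$evoked_rise_ms,
                                 truth$evoked_hold_ms, truth$evoked_fall_ms)
    region_group <- ifelse(grepl("^amygdala", channel_meta$region), "amygdala",
                    ifelse(grepl("^hippocampus", channel_meta$region),
                           "hippocampus", NA))
    clip_amp <- ifelse(schedule$condition == "aversive",
                       truth$evoked_amp_aversive, truth$evoked_amp_neutral)

    for (ch in seq_len(nch)) {
      reg <- channel_meta$region[ch]
      if (reg == "white-matter") {
        data[ch, ] <- 0.5 * powerlaw_noise(n, fs, truth$psd_exponent_chi) + line
        next
      }
      bg <- powerlaw_noise(n, fs, truth$psd_exponent_chi)
      # low-frequency oscillation
      if (ch == drv_idx) {
        osc <- osc_driver
      } else {
        f0 <- if (identical(region_group[ch], "hippocampus"))
          truth$f_low_receiver_hz else truth$f_low_driver_hz
        own <- narrowband_noise(n, fs, f0, bw_hz = truth$lf_bw_hz)
        if (ch == rcv_idx) {
          osc <- sqrt(pmax(1 - lfc^2, 0)) * own + lfc * osc_driver_lag
        } else {
          osc <- own
        }
      }
      # gamma carrier
      carrier <- narrowband_noise(n, fs, truth$f_gamma_receiver_hz, bw_hz = 25)
      if (ch == rcv_idx) {
        amp <- truth$gamma_base + depth * (1 + cos(phi_driver_lag)) / 2
      } else {
        amp <- truth$gamma_base + mean(depth) / 2
      }
      sig <- bg + truth$lf_amp * osc + truth$gamma_amp * amp * carrier
      # evoked high-gamma transient after each clip onset
      onset_ms <- truth$hg_onset_ms[[region_group[ch]]]
      if (!is.null(onset_ms) && !is.na(onset_ms)) {
        ev_env <- numeric(n)
        starts <- round((schedule$onset_s + onset_ms / 1000) * fs) + 1L
        for (k in seq_along(starts)) {
          idx <- starts[k] + seq_along(env_shape) - 1L
          ok <- idx <= n
          ev_env[idx[ok]] <- ev_env[idx[ok]] + clip_amp[k] * env_shape[ok]
        }
        ev_carrier <- narrowband_noise(n, fs, truth$f_gamma_receiver_hz,
                                       bw_hz = 25)
        sig <- sig + truth$gamma_amp * ev_env * ev_carrier
      }
      data[ch, ] <- sig + line
    }
  })

  lfp_recording(data, fs, channel_meta, events = schedule,
                meta = list(seed = seed, truth = truth, generator = "simulate_lfp"))
}

#' Simulate horizontal/vertical EOG channels with saccade transients
#'
#' Two channels of slow ocular drift plus step-like saccade transients at
#' Poisson event times thinned to a 200 ms refractory period. Ground-truth
#' saccade times are returned in the recording metadata.
#'
#' @param schedule events table (sets the session duration).
#' @param saccade_rate_hz mean saccade rate before refractory thinning (>= 0).
#' @param fs sampling rate (Hz).
#' @param seed RNG seed.
#' @param refractory_s minimum inter-saccade interval (default 0.2 s).
#' @return an [lfp_recording] with channels `EOGH`, `EOGV` (region `"EOG"`)
#'   and `meta$saccade_times_s`.
#' @export
simulate_eog <- function(schedule, saccade_rate_hz = 2, fs = 500, seed = 1L,
                         refractory_s = 0.2) {
  stopifnot(saccade_rate_hz >= 0)
  total_s <- max(schedule$onset_s + schedule$duration_s)
  n <- round(total_s * fs)
  t <- seq_len(n) / fs
  with_seed(seed, {
    # Poisson process then greedy refractory thinning
    times <- numeric(0)
    if (saccade_rate_hz > 0) {
      raw <- cumsum(rexp(ceiling(2 * saccade_rate_hz * total_s) + 20,
                         rate = saccade_rate_hz))
      raw <- raw[raw < total_s - 0.05]
      last <- -Inf
      for (tt in raw) {
        if (tt - last >= refractory_s) {
          times <- c(times, tt)
          last <- tt
        }
      }
    }
    drift_h <- 20 * narrowband_noise(n, fs, 0.3, bw_hz = 0.4)
    drift_v <- 20 * narrowband_noise(n, fs, 0.3, bw_hz = 0.4)
    ramp <- (1 - cos(pi * seq_len(max(1L, round(0.02 * fs))) /
                       max(1L, round(0.02 * fs)))) / 2
    h <- drift_h
    v <- drift_v
    for (tt in times) {
      i0 <- round(tt * fs) + 1L
      step_h <- runif(1, -1, 1) * 60
      step_v <- runif(1, -1, 1) * 60
      idx <- i0 + seq_along(ramp) - 1L
      ok <- idx <= n
      h[idx[ok]] <- h[idx[ok]] + step_h * ramp[ok]
      v[idx[ok]] <- v[idx[ok]] + step_v * ramp[ok]
      if (i0 + length(ramp) <= n) {
        h[(i0 + length(ramp)):n] <- h[(i0 + length(ramp)):n] + step_h
        v[(i0 + length(ramp)):n] <- v[(i0 + length(ramp)):n] + step_v
      }
    }
    h <- h + rnorm(n, sd = 1)
    v <- v + rnorm(n, sd = 1)
  })
  meta <- data.frame(
    label = c("EOGH", "EOGV"), region = "EOG", shaft = "E",
    contact = 1:2, laterality = NA, stringsAsFactors = FALSE
  )
  lfp_recording(rbind(h, v), fs, meta, events = schedule,
                meta = list(seed = seed, saccade_times_s = times,
                            saccade_rate_hz = saccade_rate_hz,
                            generator = "simulate_eog"))
}
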