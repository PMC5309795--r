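# Orchestration: electrode-pair selection and the end-to-end analysis run.

#' Pipeline configuration
#'
#' @param out_dir directory for result tables (NULL = return only).
#' @param seed master RNG seed for all permutation machinery.
#' @param fs_analysis sampling rate of the analysis stage (Hz).
#' @param fs_granger sampling rate of the Granger stage (Hz).
#' @param granger_lp_hz low-pass cut-off before Granger down-sampling.
#' @param n_amygdala,n_hippocampus electrode-pair rule: the most medial
#'   contacts per region entering the phase-coupling analysis (3 x 4 by
#'   default).
#' @param band_search_hz search range for the subject-specific band.
#' @param psd_fit_hz power-law fit range.
#' @param n_perm permutation count for the coupling statistics.
#' @param n_perm_cluster permutation count for cluster tests.
#' @param contrast condition labels (difference = first - second).
#' @param epoch_window epoch window around clip onsets (s).
#' @param granger_epoch_s epoch length used as Granger trial realizations.
#' @param lag_grid_ms lag grid for the lag-PAC profile.
#' @param hg_band high-gamma band (Hz).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = NULL, seed = 1L,
                            fs_analysis = 2000, fs_granger = 250,
                            granger_lp_hz = 85,
                            n_amygdala = 3L, n_hippocampus = 4L,
                            band_search_hz = c(4, 12),
                            psd_fit_hz = c(2, 80),
                            n_perm = 200L, n_perm_cluster = 500L,
                            contrast = c("aversive", "neutral"),
                            epoch_window = c(-0.5, 1.5),
                            granger_epoch_s = 1.5,
                            lag_grid_ms = seq(-200, 200, 10),
                            hg_band = c(70, 180)) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Select electrode pairs by the medial-contact rule
#'
#' Takes the `n_amygdala` most medial amygdala contacts and the
#' `n_hippocampus` most medial hippocampal contacts (contact 1 = most
#' medial) and forms their Cartesian product. If a region has fewer
#' contacts, all available ones are used (with a message).
#'
#' @param channel_meta channel metadata data frame.
#' @param n_amygdala,n_hippocampus contacts per region.
#' @return data frame with columns `chan_i` (amygdala), `chan_j`
#'   (hippocampus).
#' @export
select_pairs <- function(channel_meta, n_amygdala = 3L, n_hippocampus = 4L) {
  pick <- function(prefix, k) {
    rows <- channel_meta[grepl(prefix, channel_meta$region), , drop = FALSE]
    rows <- rows[order(rows$contact), , drop = FALSE]
    if (nrow(rows) < k) {
      message("only ", nrow(rows), " ", prefix, " contacts available (rule ",
              "asked for ", k, "); using all")
      k <- nrow(rows)
    }
    head(rows$label, k)
  }
  amy <- pick("^amygdala", n_amygdala)
  hip <- pick("^hippocampus", n_hippocampus)
  expand.grid(chan_i = amy, chan_j = hip, KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)
}

#' Run the full analysis chain on a recording
#'
#' Executes line-noise removal, white-matter re-referencing, subject-specific
#' band selection, the PLV pair contrast with forwarding of the most
#' significant pair, directional z-PAC and lag-PAC, the high-gamma envelope
#' spectrum, PSI, spectral Granger causality with the condition contrast,
#' and event-locked high-gamma onset/peak statistics. Results are returned
#' as a structured list and, when `config$out_dir` is set, written as
#' TSV/JSON files together with a run manifest.
#'
#' @param rec an [lfp_recording] with events (e.g. from [simulate_lfp()] or
#'   [load_recording()]).
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_report`.
#' @export
run_pipeline <- function(rec, config = pipeline_config()) {
  stopifnot(inherits(rec, "lfp_recording"))
  cfg <- config
  manifest <- list(seed = cfg$seed, fs_in = rec$fs,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  # --- conditioning ---------------------------------------------------------
  if (rec$fs != cfg$fs_analysis) rec <- resample_recording(rec, cfg$fs_analysis)
  rec <- remove_line_noise(rec)
  rec <- rereference_white_matter(rec)
  labels <- sample_conditions(rec)
  fs <- rec$fs

  # --- spectra and band selection ------------------------------------------
  cm <- rec$channel_meta
  grey <- cm$label[!(cm$region %in% c("white-matter", "EOG"))]
  band_by_channel <- list()
  chi_by_channel <- numeric(0)
  for (lab in grey) {
    ps <- welch_psd(channel_signal(rec, lab), fs)
    fit <- fit_powerlaw(ps, cfg$psd_fit_hz)
    band_by_channel[[lab]] <- select_subject_band(ps, fit, cfg$band_search_hz)
    chi_by_channel[lab] <- fit$chi
  }

  # --- PLV pair contrast ----------------------------------------------------
  pairs <- select_pairs(cm, cfg$n_amygdala, cfg$n_hippocampus)
  # band for pair analysis: mean of the two regions' selected centres
  amy_centres <- vapply(band_by_channel[grepl("^amygdala",
    cm$region[match(names(band_by_channel), cm$label)])],
    function(b) b$centre_hz, numeric(1))
  hip_centres <- vapply(band_by_channel[grepl("^hippocampus",
    cm$region[match(names(band_by_channel), cm$label)])],
    function(b) b$centre_hz, numeric(1))
  pair_band <- band_spec(mean(c(amy_centres, hip_centres)))
  plv_res <- plv_contrast(rec, pairs, pair_band, contrast = cfg$contrast,
                          n_perm = cfg$n_perm, seed = cfg$seed)
  tab <- plv_res$table
  passed <- which(tab$passed)
  best <- if (length(passed)) passed[order(tab$p[passed],
                                           tab$chan_i[passed],
                                           tab$chan_j[passed])][1]
          else NA_integer_
  # --- directional coupling on the forwarded pair --------------------------
  directional <- NULL
  if (!is.na(best)) {
    ch_amy <- tab$chan_i[best]; ch_hip <- tab$chan_j[best]
    x_amy <- channel_signal(rec, ch_amy)
    x_hip <- channel_signal(rec, ch_hip)
    b_amy <- band_by_channel[[ch_amy]]
    b_hip <- band_by_channel[[ch_hip]]
    phase_amy <- Arg(hilbert_analytic(
      bandpass_fir(x_amy, b_amy$low_hz, b_amy$high_hz, fs = fs)))
    phase_hip <- Arg(hilbert_analytic(
      bandpass_fir(x_hip, b_hip$low_hz, b_hip$high_hz, fs = fs)))
    amp_hip <- analytic_signal(
      bandpass_fir(x_hip, cfg$hg_band[1], cfg$hg_band[2], fs = fs), fs)$amplitude
    amp_amy <- analytic_signal(
      bandpass_fir(x_amy, cfg$hg_band[1], cfg$hg_band[2], fs = fs), fs)$amplitude

    z_fwd <- z_pac(phase_amy, amp_hip, labels, fs, contrast = cfg$contrast,
                   n_perm = cfg$n_perm, seed = cfg$seed)
    z_rev <- z_pac(phase_hip, amp_amy, labels, fs, contrast = cfg$contrast,
                   n_perm = cfg$n_perm, seed = cfg$seed + 1L)
    lag_fwd <- lag_pac(phase_amy, amp_hip, fs, cfg$lag_grid_ms, labels,
                       condition = cfg$contrast[1])
    lag_rev <- lag_pac(phase_hip, amp_amy, fs, cfg$lag_grid_ms, labels,
                       condition = cfg$contrast[1])
    env_psd <- hg_envelope_psd(x_hip, fs, mean(cfg$hg_band))

    # PSI on (modulating-band signal, modulated envelope): 1 s windows of
    # the first contrast condition; the 8*delta_f estimation band is tied to
    # the subject-specific band (centre +/- bandwidth/2)
    ep <- epoch_recording(rec, window = c(0, cfg$granger_epoch_s))
    keep <- !ep$bad
    amy_band_sig <- bandpass_fir(x_amy, b_amy$low_hz, b_amy$high_hz, fs = fs)
    wstarts <- seq(1L, ncol(rec$data) - fs, by = fs)
    wstarts <- wstarts[vapply(wstarts, function(s0) {
      all(labels[s0:(s0 + fs - 1L)] == cfg$contrast[1])
    }, logical(1))]
    segw <- function(series) {
      t(vapply(wstarts, function(c0) series[c0:(c0 + fs - 1L)], numeric(fs)))
    }
    psi_fwd <- psi(segw(amy_band_sig), segw(amp_hip), fs,
                   nu_hz = b_amy$centre_hz,
                   delta_f_hz = b_amy$bandwidth_hz / 8)

    # Granger on low-pass filtered, down-sampled raw signals
    ratio <- .ratio_to_pq(cfg$fs_granger / fs)
    down <- function(x) {
      as.numeric(signal::resample(lowpass_fir(x, cfg$granger_lp_hz, fs = fs),
                                  ratio[1], ratio[2]))
    }
    xg <- down(x_amy); yg <- down(x_hip)
    nsg <- round(cfg$granger_epoch_s * cfg$fs_granger)
    segg <- function(series) {
      t(vapply(which(keep), function(i) {
        c0 <- round(rec$events$onset_s[i] * cfg$fs_granger) + 1L
        series[c0:(c0 + nsg - 1L)]
      }, numeric(nsg)))
    }
    gx <- segg(xg); gy <- segg(yg)
    gcond <- as.character(rec$events$condition[keep])
    granger <- granger_condition_contrast(gx, gy, gcond, cfg$fs_granger,
                                          contrast = cfg$contrast,
                                          n_perm = cfg$n_perm, seed = cfg$seed,
                                          order_range = 1:12)
    lowf <- granger$freqs <= 12
    direction_call <- if (mean(granger$xy$diff[lowf]) >
                            mean(granger$yx$diff[lowf]) &&
                          psi_fwd$psi > 0 && z_fwd$z > z_rev$z) {
      "amygdala->hippocampus"
    } else if (z_fwd$z <= 0 && z_rev$z <= 0 && psi_fwd$psi <= 0) {
      "none"
    } else {
      "mixed"
    }
    directional <- list(pair = c(amygdala = ch_amy, hippocampus = ch_hip),
                        z_pac_forward = z_fwd, z_pac_reverse = z_rev,
                        lag_forward = lag_fwd, lag_reverse = lag_rev,
                        envelope_psd = env_psd, psi_forward = psi_fwd,
                        granger = granger, direction_call = direction_call)
  } else {
    directional <- list(direction_call = "none",
                        note = "no pair passed both within-condition thresholds")
  }

  # --- event-locked high gamma ---------------------------------------------
  hg <- list()
  for (reg in c("amygdala", "hippocampus")) {
    lab <- cm$label[grepl(paste0("^", reg), cm$region)][1]
    tc <- hg_timecourse(rec, lab, window = cfg$epoch_window, band = cfg$hg_band)
    ct <- hg_condition_contrast(tc, contrast = cfg$contrast,
                                n_perm = cfg$n_perm_cluster, seed = cfg$seed)
    oo <- onset_offset_from_clusters(ct)
    times_post <- attr(ct, "times")
    onset_ms <- if (is.null(oo)) NA_real_ else 1000 * times_post[oo["onset"]]
    sigwin <- if (is.null(oo)) NULL else
      c(times_post[oo["onset"]], times_post[oo["offset"]])
    pk <- if (is.null(sigwin)) NA_real_ else
      peak_latency(tc$z[tc$condition == cfg$contrast[1], , drop = FALSE],
                   tc$times, sigwin)
    hg[[reg]] <- list(channel = lab, timecourse = tc, contrast = ct,
                      onset_ms = onset_ms, peak_ms = pk)
  }

  report <- structure(
    list(config = cfg, manifest = manifest,
         chi = chi_by_channel, bands = band_by_channel,
         plv = plv_res, best_pair = if (!is.na(best)) tab[best, ] else NULL,
         directional = directional, hg = hg),
    class = "pipeline_report"
  )
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("  band centres:",
      paste(sprintf("%s %.1f Hz", names(x$bands),
                    vapply(x$bands, function(b) b$centre_hz, numeric(1))),
            collapse = ", "), "\n")
  if (!is.null(x$best_pair)) {
    cat(sprintf("  best PLV pair: %s-%s (diff %.4f, p = %.3g)\n",
                x$best_pair$chan_i, x$best_pair$chan_j,
                x$best_pair$difference, x$best_pair$p))
  }
  cat("  direction call:", x$directional$direction_call, "\n")
  for (reg in names(x$hg)) {
    cat(sprintf("  %s HG onset %.0f ms, peak %.0f ms\n", reg,
                x$hg[[reg]]$onset_ms, x$hg[[reg]]$peak_ms))
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits TSV tables (PLV pairs, lag profiles, Granger curves) and a JSON
#' summary + manifest under `dir`.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$plv$table, file.path(dir, "plv_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  d <- report$directional
  if (!is.null(d$lag_forward)) {
    utils::write.table(
      data.frame(lag_ms = d$lag_forward$lags_ms,
                 rho_forward = d$lag_forward$rho,
                 rho_reverse = d$lag_reverse$rho),
      file.path(dir, "lag_pac.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(freq = d$granger$freqs,
                 diff_xy = d$granger$xy$diff, diff_yx = d$granger$yx$diff,
                 flagged_xy = d$granger$xy$flagged,
                 flagged_yx = d$granger$yx$flagged),
      file.path(dir, "granger_contrast.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  summary <- list(
    manifest = report$manifest,
    chi = as.list(report$chi),
    band_centres = lapply(report$bands, function(b) b$centre_hz),
    direction_call = d$direction_call,
    z_pac_forward = if (!is.null(d$z_pac_forward)) d$z_pac_forward$z,
    z_pac_reverse = if (!is.null(d$z_pac_reverse)) d$z_pac_reverse$z,
    peak_lag_forward_ms = if (!is.null(d$lag_forward)) d$lag_forward$peak_lag_ms,
    psi_forward = if (!is.null(d$psi_forward)) d$psi_forward$psi,
    hg = lapply(report$hg, function(h) {
      list(channel = h$channel, onset_ms = h$onset_ms, peak_ms = h$peak_ms)
    })
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
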