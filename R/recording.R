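# Containers for continuous recordings and epoched data.

#' Construct a continuous multichannel recording
#'
#' @param data channels x samples numeric matrix (microvolts); row names are
#'   channel labels.
#' @param fs sampling rate in Hz.
#' @param channel_meta data frame with one row per channel: `label`, `region`
#'   (e.g. `"amygdala-BLA"`, `"hippocampus-CA1"`, `"white-matter"`, `"EOG"`),
#'   `shaft` (electrode shaft id), `contact` (contact index along the shaft,
#'   1 = most medial) and optionally `laterality`.
#' @param events optional events table (see [make_task_schedule()]).
#' @param meta free-form list of provenance (seed, ground truth, reference
#'   assignments, ...).
#' @return an object of class `lfp_recording`.
#' @export
lfp_recording <- function(data, fs, channel_meta, events = NULL, meta = list()) {
  data <- as.matrix(data)
  stopifnot(fs > 0, nrow(channel_meta) == nrow(data))
  if (anyNA(data)) stop("recording data must not contain NAs")
  required <- c("label", "region", "shaft", "contact")
  missing_cols <- setdiff(required, names(channel_meta))
  if (length(missing_cols)) {
    stop("channel_meta lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  rownames(data) <- channel_meta$label
  structure(
    list(data = data, fs = fs, channel_meta = channel_meta,
         events = events, meta = meta),
    class = "lfp_recording"
  )
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  regs <- table(x$channel_meta$region)
  cat("  regions:", paste(sprintf("%s (%d)", names(regs), regs), collapse = ", "),
      "\n")
  if (!is.null(x$events)) {
    cat(sprintf("  events: %d clips, conditions %s\n", nrow(x$events),
                paste(unique(x$events$condition), collapse = "/")))
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an [lfp_recording].
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

#' Extract one channel as a numeric vector
#' @param rec an [lfp_recording].
#' @param channel channel label or index.
#' @export
channel_signal <- function(rec, channel) {
  if (is.character(channel)) {
    idx <- match(channel, rec$channel_meta$label)
    if (is.na(idx)) stop("unknown channel: ", channel)
  } else {
    idx <- channel
  }
  rec$data[idx, ]
}

#' Per-sample condition labels from the events table
#'
#' Samples before the first clip (the pre-session blank) are labelled
#' `"blank"`; samples inside a clip inherit the clip's condition.
#'
#' @param rec an [lfp_recording] carrying an events table, or the table itself
#'   (then `n` and `fs` are required).
#' @param n,fs number of samples and sampling rate when `rec` is a table.
#' @return character vector of length `n`.
#' @export
sample_conditions <- function(rec, n = NULL, fs = NULL) {
  if (inherits(rec, "lfp_recording")) {
    events <- rec$events; n <- ncol(rec$data); fs <- rec$fs
  } else {
    events <- rec
  }
  out <- rep("blank", n)
  for (i in seq_len(nrow(events))) {
    a <- floor(events$onset_s[i] * fs) + 1L
    b <- min(n, ceiling((events$onset_s[i] + events$duration_s[i]) * fs))
    if (a <= n) out[a:min(b, n)] <- as.character(events$condition[i])
  }
  out
}

#' Epoch a recording around event onsets
#'
#' One trial per clip, windowed relative to clip onset. Trials whose window
#' extends outside the recording, or overlaps a supplied bad-interval mask,
#' are flagged (never silently dropped).
#'
#' @param rec an [lfp_recording].
#' @param events events table; defaults to `rec$events`.
#' @param window numeric length-2, seconds relative to onset (default
#'   `c(-0.5, 1.5)`).
#' @param bad_intervals optional matrix/data frame with columns start/end (s)
#'   marking epochs to flag.
#' @return object of class `lfp_epochs`: `data` (trials x channels x samples),
#'   `times`, `fs`, `condition`, `block`, `bad` (logical flag per trial) and
#'   `channel_meta`.
#' @export
epoch_recording <- function(rec, events = NULL, window = c(-0.5, 1.5),
                            bad_intervals = NULL) {
  events <- if (is.null(events)) rec$events else events
  if (is.null(events)) stop("no events available for epoching")
  n <- ncol(rec$data)
  fs <- rec$fs
  rel <- seq(round(window[1] * fs), round(window[2] * fs) - 1L)
  n_samp <- length(rel)
  n_trial <- nrow(events)
  dat <- array(NA_real_, dim = c(n_trial, nrow(rec$data), n_samp))
  bad <- logical(n_trial)
  reason <- character(n_trial)
  for (i in seq_len(n_trial)) {
    centre <- round(events$onset_s[i] * fs) + 1L
    idx <- centre + rel
    ok <- idx >= 1L & idx <= n
    if (!all(ok)) {
      bad[i] <- TRUE
      reason[i] <- "incomplete"
      dat[i, , which(ok)] <- rec$data[, idx[ok], drop = FALSE]
    } else {
      dat[i, , ] <- rec$data[, idx, drop = FALSE]
    }
    if (!is.null(bad_intervals) && nrow(bad_intervals)) {
      t0 <- events$onset_s[i] + window[1]
      t1 <- events$onset_s[i] + window[2]
      hit <- any(bad_intervals[[1]] < t1 & bad_intervals[[2]] > t0)
      if (hit) {
        bad[i] <- TRUE
        reason[i] <- paste0(reason[i], if (nzchar(reason[i])) "+", "bad-interval")
      }
    }
  }
  structure(
    list(data = dat, times = rel / fs, fs = fs,
         condition = as.character(events$condition),
         block = events$block, bad = bad, bad_reason = reason,
         channel_meta = rec$channel_meta, window = window),
    class = "lfp_epochs"
  )
}

#' @export
print.lfp_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<lfp_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  window %.2f..%.2f s; %d flagged trial(s)\n",
              x$window[1], x$window[2], sum(x$bad)))
  invisible(x)
}

#' Trials x samples matrix for one channel of an epochs object
#' @param ep an `lfp_epochs` object.
#' @param channel label or index.
#' @param drop_bad drop flagged trials (default TRUE).
#' @export
epoch_matrix <- function(ep, channel, drop_bad = TRUE) {
  if (is.character(channel)) channel <- match(channel, ep$channel_meta$label)
  keep <- if (drop_bad) !ep$bad else rep(TRUE, dim(ep$data)[1])
  m <- ep$data[keep, channel, , drop = FALSE]
  out <- matrix(m, nrow = sum(keep), ncol = dim(ep$data)[3])
  attr(out, "condition") <- ep$condition[keep]
  attr(out, "times") <- ep$times
  out
}
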