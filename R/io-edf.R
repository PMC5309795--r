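# Interchange formats: EDF recording files, events TSV, channel-metadata
# JSON sidecar. EDF is the clinical-EEG standard (16-bit integers with
# per-channel physical scaling); the sidecar carries what EDF cannot
# (region tags, ground truth, exact sample count).

.pad <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

#' Write a recording to an EDF file with sidecar and events table
#'
#' Writes `<stem>.edf` (16-bit EDF, 1 s data records), `<stem>.events.tsv`
#' (columns `onset_s`, `duration_s`, `condition`, `block`) and
#' `<stem>.json` (channel labels, regions, shafts, contacts, sampling rate,
#' exact sample count, seed and ground truth when present).
#'
#' @param rec an [lfp_recording]; `fs` must be a whole number.
#' @param stem output path stem (no extension).
#' @return the stem, invisibly.
#' @export
write_recording <- function(rec, stem) {
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  n <- ncol(rec$data)
  nch <- nrow(rec$data)
  n_rec <- ceiling(n / fs)
  pad_n <- n_rec * fs - n
  phys_min <- apply(rec$data, 1, min)
  phys_max <- apply(rec$data, 1, max)
  span <- pmax(phys_max - phys_min, 1e-6)
  phys_min <- phys_min - 0.001 * span
  phys_max <- phys_max + 0.001 * span
  dig_min <- -32768; dig_max <- 32767

  con <- file(paste0(stem, ".edf"), "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(.pad(s, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256 * (nch + 1L)), 8)
  wr("", 44)
  wr(as.character(n_rec), 8)
  wr("1", 8)
  wr(as.character(nch), 4)
  widths <- c(16, 80, 8, 8, 8, 8, 8, 80, 8, 32)
  fields <- list(rec$channel_meta$label,
                 rep("intracranial", nch),
                 rep("uV", nch),
                 sprintf("%.8g", phys_min),
                 sprintf("%.8g", phys_max),
                 rep(as.character(dig_min), nch),
                 rep(as.character(dig_max), nch),
                 rep("", nch),
                 rep(as.character(fs), nch),
                 rep("", nch))
  for (fi in seq_along(fields)) {
    for (ch in seq_len(nch)) wr(fields[[fi]][ch], widths[fi])
  }
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  dig <- matrix(0L, nch, n + pad_n)
  for (ch in seq_len(nch)) {
    d <- round((rec$data[ch, ] - phys_min[ch]) * scale[ch] + dig_min)
    dig[ch, ] <- c(as.integer(pmin(pmax(d, dig_min), dig_max)),
                   rep(0L, pad_n))
  }
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
  }

  if (!is.null(rec$events)) {
    write_events_tsv(rec$events, paste0(stem, ".events.tsv"))
  }
  sidecar <- list(
    fs = fs, n_samples = n,
    channels = rec$channel_meta,
    seed = rec$meta$seed,
    generator = rec$meta$generator,
    truth = if (!is.null(rec$meta$truth)) unclass(rec$meta$truth)
  )
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(stem)
}

#' Write an events table as TSV
#' @param events a `task_schedule`/events data frame.
#' @param path output path.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an events TSV
#' @param path path to the TSV.
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("onset_s", "duration_s", "condition", "block")
  miss <- setdiff(required, names(ev))
  if (length(miss)) stop("events table lacks columns: ",
                         paste(miss, collapse = ", "))
  ev
}

#' Load a recording written by [write_recording()]
#'
#' Reads `<stem>.edf`, validates it against the JSON sidecar (sampling-rate
#' or channel mismatches are rejected; events with onsets outside the
#' recording are reported by row), and returns an [lfp_recording].
#'
#' @param stem path stem used at write time.
#' @return an [lfp_recording].
#' @export
load_recording <- function(stem) {
  sidecar_path <- paste0(stem, ".json")
  if (!file.exists(sidecar_path)) stop("missing sidecar: ", sidecar_path)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  con <- file(paste0(stem, ".edf"), "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), character(1))
  for (i in seq_len(nch)) rd(80)  # transducer
  for (i in seq_len(nch)) rd(8)   # unit
  phys_min <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  phys_max <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  dig_min <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  dig_max <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(nch)) rd(80)  # prefilter
  spr <- vapply(seq_len(nch), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(nch)) rd(32)
  fs <- spr[1] / rec_dur
  if (!isTRUE(all.equal(fs, side$fs))) {
    stop("sampling-rate mismatch between EDF header (", fs,
         ") and sidecar (", side$fs, ")")
  }
  cm <- as.data.frame(side$channels, stringsAsFactors = FALSE)
  if (nrow(cm) != nch) stop("channel-count mismatch between EDF and sidecar")
  no_meta <- labels[!(labels %in% cm$label)]
  if (length(no_meta)) {
    stop("channels missing from metadata: ", paste(no_meta, collapse = ", "))
  }
  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2,
                 endian = "little")
  data <- matrix(0, nch, n_rec * spr[1])
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nch)) {
      seg <- raw[(pos + 1L):(pos + spr[ch])]
      data[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <- seg
      pos <- pos + spr[ch]
    }
  }
  for (ch in seq_len(nch)) {
    scale <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
    data[ch, ] <- (data[ch, ] - dig_min[ch]) * scale + phys_min[ch]
  }
  n_true <- side$n_samples
  data <- data[, seq_len(n_true), drop = FALSE]
  # reorder to sidecar channel order
  data <- data[match(cm$label, labels), , drop = FALSE]
  events <- NULL
  ev_path <- paste0(stem, ".events.tsv")
  if (file.exists(ev_path)) {
    events <- read_events_tsv(ev_path)
    dur_s <- ncol(data) / fs
    bad_rows <- which(events$onset_s < 0 | events$onset_s > dur_s)
    if (length(bad_rows)) {
      stop("events with out-of-range onset at row(s): ",
           paste(bad_rows, collapse = ", "))
    }
  }
  lfp_recording(data, fs, cm, events = events,
                meta = list(seed = side$seed, truth = side$truth,
                            source = paste0(stem, ".edf")))
}
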