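# Synthetic task schedule: alternating blocks of neutral and aversive movie
# clips, each block tiled contiguously by clips.

#' Parameters of the synthetic block/clip schedule
#'
#' Defaults reproduce the study conditions: a roughly 7-minute session of 9
#' neutral (landscape) and 8 aversive (fearful-face) blocks of ~24 s each,
#' tiled by 70 neutral and 71 aversive clips of 2.8 +/- 1.3 s, preceded by a
#' 0.5 s blank used as the session baseline.
#'
#' @param n_neutral_blocks,n_aversive_blocks block counts (>= 1 neutral).
#' @param block_duration_s block duration in seconds.
#' @param n_neutral_clips,n_aversive_clips total clip counts per condition.
#' @param clip_duration_mean_s,clip_duration_sd_s clip-duration distribution
#'   (truncated normal, truncated at > 0).
#' @param pre_session_blank_s blank screen before the first block (seconds).
#' @param first_condition which condition starts the alternation (the study
#'   does not state it; neutral-first by default).
#' @param seed RNG seed for clip-duration draws.
#' @return a list of class `task_schedule_params`.
#' @export
task_schedule_params <- function(n_neutral_blocks = 9L,
                                 n_aversive_blocks = 8L,
                                 block_duration_s = 24,
                                 n_neutral_clips = 70L,
                                 n_aversive_clips = 71L,
                                 clip_duration_mean_s = 2.8,
                                 clip_duration_sd_s = 1.3,
                                 pre_session_blank_s = 0.5,
                                 first_condition = c("neutral", "aversive"),
                                 seed = 1L) {
  first_condition <- match.arg(first_condition)
  stopifnot(n_neutral_blocks >= 1, n_aversive_blocks >= 0,
            block_duration_s > 0, clip_duration_mean_s > 0,
            clip_duration_sd_s >= 0, pre_session_blank_s >= 0)
  structure(
    list(n_neutral_blocks = as.integer(n_neutral_blocks),
         n_aversive_blocks = as.integer(n_aversive_blocks),
         block_duration_s = block_duration_s,
         n_neutral_clips = as.integer(n_neutral_clips),
         n_aversive_clips = as.integer(n_aversive_clips),
         clip_duration_mean_s = clip_duration_mean_s,
         clip_duration_sd_s = clip_duration_sd_s,
         pre_session_blank_s = pre_session_blank_s,
         first_condition = first_condition,
         seed = seed),
    class = "task_schedule_params"
  )
}

# truncated-normal draw (> lower), by rejection with a safe floor
rtruncnorm_pos <- function(n, mean, sd, lower = 0.05) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw > lower
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Build the synthetic events table
#'
#' Blocks alternate conditions starting with `first_condition`. Clips of each
#' condition are distributed across that condition's blocks as evenly as
#' possible; within a block, durations are drawn from a truncated normal and
#' rescaled so the clips exactly tile the block (clips run continuously
#' without breaks).
#'
#' @param params a [task_schedule_params()] object.
#' @return data frame of class `task_schedule` with columns `onset_s`,
#'   `duration_s`, `condition`, `block`.
#' @export
make_task_schedule <- function(params = task_schedule_params()) {
  stopifnot(inherits(params, "task_schedule_params"))
  p <- params
  n_blocks <- p$n_neutral_blocks + p$n_aversive_blocks
  conds <- if (p$first_condition == "neutral") c("neutral", "aversive") else
    c("aversive", "neutral")
  block_cond <- rep(conds, length.out = n_blocks)
  if (sum(block_cond == "neutral") != p$n_neutral_blocks ||
      sum(block_cond == "aversive") != p$n_aversive_blocks) {
    stop("block counts are incompatible with a strict alternation starting ",
         "with ", p$first_condition)
  }
  clip_totals <- c(neutral = p$n_neutral_clips, aversive = p$n_aversive_clips)
  for (cond in names(clip_totals)) {
    nb <- sum(block_cond == cond)
    if (nb > 0 && clip_totals[[cond]] < nb) {
      stop("schedule error: fewer ", cond, " clips than ", cond, " blocks")
    }
  }
  # distribute clips over blocks as evenly as possible
  per_block <- integer(n_blocks)
  for (cond in names(clip_totals)) {
    idx <- which(block_cond == cond)
    if (!length(idx)) next
    base <- clip_totals[[cond]] %/% length(idx)
    extra <- clip_totals[[cond]] %% length(idx)
    per_block[idx] <- base + as.integer(seq_along(idx) <= extra)
  }
  with_seed(p$seed, {
    rows <- vector("list", n_blocks)
    t0 <- p$pre_session_blank_s
    for (b in seq_len(n_blocks)) {
      k <- per_block[b]
      dur <- rtruncnorm_pos(k, p$clip_duration_mean_s, p$clip_duration_sd_s)
      dur <- dur / sum(dur) * p$block_duration_s  # exact tiling
      onset <- t0 + cumsum(c(0, dur[-k]))
      rows[[b]] <- data.frame(onset_s = onset, duration_s = dur,
                              condition = block_cond[b], block = b)
      t0 <- t0 + p$block_duration_s
    }
    out <- do.call(rbind, rows)
  })
  rownames(out) <- NULL
  class(out) <- c("task_schedule", "data.frame")
  attr(out, "params") <- p
  out
}

#' @export
print.task_schedule <- function(x, ...) {
  cat(sprintf("<task_schedule> %d clips in %d blocks (%s), %.1f s total\n",
              nrow(x), length(unique(x$block)),
              paste(sprintf("%s: %d", names(table(x$condition)),
                            table(x$condition)), collapse = ", "),
              max(x$onset_s + x$duration_s)))
  invisible(x)
}
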