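# Shared fixtures: reduced-size task schedules and cached simulations so the
# suite stays fast. All fixtures are generated in code at test time.

# compact session: 4 neutral / 3 aversive blocks of 16 s (112.5 s with blank)
small_params <- function(seed = 3) {
  task_schedule_params(
    n_neutral_blocks = 4, n_aversive_blocks = 3, block_duration_s = 16,
    n_neutral_clips = 20, n_aversive_clips = 16, seed = seed
  )
}

small_schedule <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_task_schedule(small_params())
    cache
  }
})

# cached compact simulations keyed by (seed, truth-signature)
.sim_cache <- new.env(parent = emptyenv())
small_sim <- function(seed, truth = coupling_ground_truth(line_noise_amp = 0),
                      fs = 500) {
  key <- paste0(seed, "|", fs, "|",
                paste(unlist(truth[sapply(truth, is.numeric)]), collapse = ","))
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_lfp(small_schedule(), truth, fs = fs,
                                      seed = seed)
  }
  .sim_cache[[key]]
}

# brute-force single-loop oracles, written directly from the definitions
plv_brute <- function(phase_i, phase_j) {
  n <- length(phase_i)
  s <- 0 + 0i
  for (k in seq_len(n)) s <- s + exp(1i * (phase_i[k] - phase_j[k]))
  Mod(s / n)
}

rho_brute <- function(phase, amp) {
  pearson <- function(x, y) {
    n <- length(x)
    mx <- sum(x) / n; my <- sum(y) / n
    sxy <- 0; sxx <- 0; syy <- 0
    for (k in seq_len(n)) {
      sxy <- sxy + (x[k] - mx) * (y[k] - my)
      sxx <- sxx + (x[k] - mx)^2
      syy <- syy + (y[k] - my)^2
    }
    sxy / sqrt(sxx * syy)
  }
  r_ca <- pearson(cos(phase), amp)
  r_sa <- pearson(sin(phase), amp)
  r_cs <- pearson(sin(phase), cos(phase))
  sqrt((r_ca^2 + r_sa^2 - 2 * r_ca * r_sa * r_cs) / (1 - r_cs^2))
}

# band-limited phase series for coupling tests
theta_phase <- function(n, fs, f0 = 6, seed = 1) {
  withr_seed <- function(seed, expr) {
    set.seed(seed); expr
  }
  withr_seed(seed, {
    Arg(hilfun(lfpcoupling:::narrowband_noise(n, fs, f0, bw_hz = 2)))
  })
}

hilfun <- function(x) lfpcoupling:::hilbert_analytic(x)
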