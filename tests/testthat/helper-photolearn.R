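# shared fixture builders -- everything is generated in code at test time

# hand-written 3-trial table (one of each interesting outcome path)
tiny_table <- function() {
  trial_table(mouse_id = "t1", trial_index = 0:2, day = 1,
              stimulus_freq_hz = c(10000, 7071, 10000),
              stimulus_class = c("go", "no-go", "go"),
              lick_times_s = list(c(1.2, 1.5), numeric(0), 0.5))
}

# minimal session: explicit trace matrix on a 30 Hz grid spanning the cue
toy_session <- function(traces, fs = 30, t0 = -3, normalized = TRUE) {
  traces <- as.matrix(traces)
  time_s <- t0 + (seq_len(ncol(traces)) - 1) / fs
  photometry_session(traces, time_s, fs, baseline_window = c(-2.5, -2),
                     normalized = normalized)
}

# a small simulated bundle shared by several files (cached per session)
std_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_preset("standard", seed = 402)
      trials <- simulate_behavior(cfg)
      sim <- simulate_photometry(trials, cfg)
      cache <<- list(cfg = cfg, trials = trials,
                     session = normalize_trials(sim$session),
                     raw = sim$session, gt = sim$ground_truth)
    }
    cache
  }
})

# brute-force AUC oracle: direct pair counting with half ties
auc_bruteforce <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(a) * length(b))
}
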