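test_that("sim_config validates its inputs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(go_fraction = 1.3), "probability")
  expect_error(sim_config(trial_window = c(0.5, 4)), "span stimulus onset")
  expect_error(sim_config(behavior = list(
    hit = list(a = 0.8, b = 900, c = 100, floor = 0.5),
    cr = list(a = 0.6, b = 900, c = 100, floor = 0.3))), "\\[0, 1\\]")
  expect_error(sim_config(calcium_kernel = list(rise_s = 0.5, decay_s = 0.4)),
               "rise_s")
})

test_that("simulate_behavior is deterministic and respects degenerate rates", {
  cfg <- sim_config(n_trials = 300, seed = 8)
  t1 <- simulate_behavior(cfg)
  t2 <- simulate_behavior(cfg)
  expect_identical(t1, t2)

  # hit rate 1, FA rate 0: every go a hit, every no-go a CR
  perfect <- sim_config(n_trials = 200, behavior = list(
    hit = list(a = 0, b = 900, c = 100, floor = 1),
    cr = list(a = 0, b = 900, c = 100, floor = 1)), seed = 3)
  tp <- simulate_behavior(perfect)
  expect_true(all(tp$outcome[tp$stimulus_class == "go"] == "hit"))
  expect_true(all(tp$outcome[tp$stimulus_class == "no-go"] == "CR"))
})

test_that("labels and lick times are mutually consistent", {
  tab <- std_bundle()$trials
  rw <- attr(tab, "response_window")
  win_lick <- vapply(tab$lick_times_s,
                     function(l) any(l > rw[1] & l <= rw[2]), logical(1))
  expect_true(all(win_lick[tab$outcome %in% c("hit", "FA")]))
  expect_false(any(win_lick[tab$outcome %in% c("miss", "CR")]))
})

test_that("empirical rates stay within 3 binomial SE of constant targets", {
  cfg <- sim_config(n_trials = 2500, behavior = list(
    hit = list(a = 0, b = 900, c = 100, floor = 0.8),
    cr = list(a = 0, b = 900, c = 100, floor = 0.65)), seed = 12)
  tab <- simulate_behavior(cfg)
  go <- tab$stimulus_class == "go"
  hr <- mean(tab$outcome[go] == "hit")
  fr <- mean(tab$outcome[!go] == "FA")
  expect_lt(abs(hr - 0.8), 3 * sqrt(0.8 * 0.2 / sum(go)))
  expect_lt(abs(fr - 0.35), 3 * sqrt(0.35 * 0.65 / sum(!go)))
})

test_that("photometry construction honours degenerate configurations", {
  base_beh <- list(hit = list(a = 0, b = 900, c = 100, floor = 0.7),
                   cr = list(a = 0, b = 900, c = 100, floor = 0.3))
  # all amplitudes and noise zero -> flat traces at the trial baseline
  flat_cfg <- sim_config(
    n_trials = 20, behavior = base_beh,
    stim_response = list(onset_s = 0.05, duration_s = 1, amplitude = 0,
                         nogo_gain = 0.25, onset_boost = 5,
                         onset_boost_duration_s = 0.1),
    choice_response = list(onset_s = 0.2, duration_s = 2.8, amplitude = 0,
                           sign = 1, fa_gain = 1),
    noise_sd = 0, baseline_jitter_sd = 0, seed = 4)
  tr <- simulate_behavior(flat_cfg)
  ses <- simulate_photometry(tr, flat_cfg)$session
  expect_equal(max(abs(ses$traces - flat_cfg$baseline_f)), 0)

  # zero choice amplitude + zero noise: hit and miss mean traces identical
  stim_only <- sim_config(
    n_trials = 60, behavior = base_beh,
    choice_response = list(onset_s = 0.2, duration_s = 2.8, amplitude = 0,
                           sign = 1, fa_gain = 1),
    noise_sd = 0, baseline_jitter_sd = 0, seed = 5)
  tr2 <- simulate_behavior(stim_only)
  ses2 <- normalize_trials(simulate_photometry(tr2, stim_only)$session)
  hit_mean <- colMeans(ses2$traces[tr2$outcome == "hit", , drop = FALSE])
  miss_mean <- colMeans(ses2$traces[tr2$outcome == "miss", , drop = FALSE])
  expect_equal(hit_mean, miss_mean, tolerance = 1e-12)
})

test_that("negative choice sign puts expert hits below misses late", {
  cfg <- sim_preset("tuned_away", seed = 21)
  tr <- simulate_behavior(cfg)
  ses <- normalize_trials(simulate_photometry(tr, cfg)$session)
  pa <- phase_average(ses, tr, "expert")
  late <- ses$time_s > 0.6 & ses$time_s <= 1
  expect_lt(mean(pa$hit$mean[late]), mean(pa$miss$mean[late]))
})

test_that("simulated photometry and frames are seed-deterministic", {
  cfg <- sim_config(n_trials = 30, seed = 77,
                    frame = list(height = 12L, width = 12L, rate = 30,
                                 noise_sd = 2))
  tr <- simulate_behavior(cfg)
  s1 <- simulate_photometry(tr, cfg)
  s2 <- simulate_photometry(tr, cfg)
  expect_identical(s1$session$traces, s2$session$traces)
  expect_identical(s1$ground_truth, s2$ground_truth)
  f1 <- simulate_movement_frames(tr, cfg, trials = 1:3)
  f2 <- simulate_movement_frames(tr, cfg, trials = 1:3)
  expect_identical(f1$stack$frames, f2$stack$frames)
})

test_that("ground-truth movement intervals stay inside the trial window", {
  b <- std_bundle()
  for (iv in b$gt$movement_intervals) {
    if (is.null(iv)) next
    expect_true(all(iv[, 1] >= b$cfg$trial_window[1]))
    expect_true(all(iv[, 2] <= b$cfg$trial_window[2]))
    expect_true(all(iv[, 2] > iv[, 1]))
  }
})

test_that("behavioral d' crossing matches the closed-form schedule", {
  # binned d' curve fitted and inverted must land within +/- 2 bins of the
  # generative schedule's crossing, for a fast and a slow learner
  for (b in c(700, 1200)) {
    cfg <- sim_preset("standard", seed = 30 + b, b = b, n_trials = 1800)
    tr <- simulate_behavior(cfg)
    lc <- learning_curve(tr)
    ok <- is.finite(lc$dprime)
    fit <- fit_sigmoid(lc$bin_center_trial[ok], lc$dprime[ok])
    est <- learning_threshold(fit)
    expect_lt(abs(est - attr(tr, "true_learning_threshold")), 100)
  }
})

test_that("passive tuning recovers the ground-truth tuning function", {
  cfg <- sim_config(seed = 9,
                    tuning = list(best_freq_hz = 10000, bandwidth_oct = 0.8,
                                  amplitude = 0.15))
  passive <- normalize_trials(simulate_passive_tuning(cfg, n_repeats = 20))
  tr <- tuning(passive)
  # peak at 10 kHz: argmax of the tuning curve at the nearest grid frequency
  expect_equal(unname(which.max(tr$tuning_curve)),
               which.min(abs(tr$freqs_hz - 10000)))
  # FRA rows ordered by attenuation at the best frequency
  bf_col <- which.max(tr$tuning_curve)
  expect_true(all(diff(tr$fra[, bf_col]) < 0))

  # zero-gain tuning: flat response area (all cells near zero)
  flat_cfg <- sim_config(seed = 9, tuning = list(best_freq_hz = 10000,
                                                 bandwidth_oct = 0.8,
                                                 amplitude = 0))
  flat <- tuning(normalize_trials(simulate_passive_tuning(flat_cfg,
                                                          n_repeats = 5)))
  expect_lt(max(abs(flat$fra)), 0.02)
})
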