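test_that("auc equals brute-force pair counting on hand cases", {
  expect_equal(auc(c(1, 2, 3), c(0, 1, 2)), 7 / 9)
  expect_equal(auc(c(4, 4, 4), c(4, 4, 4)), 0.5)
  expect_equal(auc(c(10, 11), c(1, 2, 3)), 1.0)
  expect_equal(auc(c(1, 2, 3), c(10, 11)), 0.0)
  expect_error(auc(numeric(0), 1), "empty")
})

test_that("auc obeys its algebraic invariants on random sets", {
  set.seed(42)
  for (i in 1:50) {
    a <- sample(0:4, sample(1:8, 1), replace = TRUE)
    b <- sample(0:4, sample(1:8, 1), replace = TRUE)
    v <- auc(a, b)
    expect_equal(v, auc_bruteforce(a, b))
    expect_equal(v + auc(b, a), 1)                 # complement identity
    expect_equal(auc(exp(a), exp(b)), v)           # monotone invariance
  }
})

test_that("auc_timecourse separates classes only where they differ", {
  # identical traces in both classes -> 0.5 everywhere, never significant
  tab <- trial_table("m", 0:39, 1, 10000, rep("go", 40),
                     c(as.list(rep(1.5, 20)),
                       replicate(20, numeric(0), simplify = FALSE)))
  ses <- toy_session(matrix(rep(sin(1:210), 40), 40, byrow = TRUE))
  tc <- auc_timecourse(ses, tab, "choice", "all", n_shuffles = 50, seed = 1)
  expect_true(all(tc$auc == 0.5))
  expect_true(is.na(tc$latency_s))

  # a late step on hits only: AUC rises to 1 after the step
  set.seed(3)
  traces <- matrix(rnorm(40 * 210, sd = 0.01), 40, 210)
  step_idx <- which(ses$time_s >= 0.5)
  traces[1:20, step_idx] <- traces[1:20, step_idx] + 1
  ses2 <- toy_session(traces)
  tc2 <- auc_timecourse(ses2, tab, "choice", "all", n_shuffles = 100,
                        seed = 2)
  expect_equal(tc2$latency_s, 0.5, tolerance = 1e-6)
  expect_true(all(tc2$auc[step_idx] == 1))
  expect_true(mean(abs(tc2$auc[ses2$time_s < 0.4] - 0.5) < 0.3) > 0.95)

  # class too small -> NULL with warning
  tab1 <- trial_table("m", 0:3, 1, 10000, rep("go", 4),
                      list(1.5, 1.5, 1.5, numeric(0)))
  expect_warning(
    expect_null(auc_timecourse(toy_session(matrix(0, 4, 210)), tab1,
                               "choice", "all")),
    "too small")
})

test_that("shuffle null is seeded, centred and reproducible", {
  b <- std_bundle()
  n1 <- shuffle_null(b$session, b$trials, "choice", "expert", n = 50,
                     seed = 9)
  n2 <- shuffle_null(b$session, b$trials, "choice", "expert", n = 50,
                     seed = 9)
  expect_identical(n1, n2)
  # exchangeable labels: null mean near 0.5 at nearly all frames
  expect_gt(mean(abs(n1$mean - 0.5) < 3 * n1$sd / sqrt(50) * 3), 0.9)
  expect_true(all(n1$sd >= 1e-6))
  expect_error(shuffle_null(b$session, b$trials, "choice", "expert", n = 1),
               "at least 2")
})

test_that("significance_latency honours the eligibility rule", {
  tc <- structure(list(time_s = seq(-1, 1, by = 0.1),
                       auc = rep(0.5, 21), null_mean = rep(0.5, 21),
                       null_sd = rep(0.01, 21)),
                  class = "auc_timecourse")
  expect_true(is.na(significance_latency(tc)))
  # significant only before t = 0 -> still undefined
  tc$auc[3] <- 0.9
  expect_true(is.na(significance_latency(tc)))
  # first post-onset crossing wins
  tc$auc[15] <- 0.1
  tc$auc[18] <- 0.9
  expect_equal(significance_latency(tc), tc$time_s[15])
  expect_error(significance_latency(structure(list(null_mean = NULL),
                                              class = "auc_timecourse")),
               "no null")
})

test_that("trace_onset matches finite-difference oracles", {
  fs <- 30
  time_s <- -1 + (0:119) / fs
  # quadratic-to-linear ramp beginning at t0: curvature lives only in the
  # short quadratic segment, so the argmax must land at the kink region
  t0 <- 0.4
  seg <- 0.1
  ramp <- ifelse(time_s < t0, 0,
                 ifelse(time_s < t0 + seg, (time_s - t0)^2 * 10,
                        seg^2 * 10 + 2 * seg * 10 * (time_s - t0 - seg)))
  expect_lt(abs(trace_onset(ramp, time_s) - t0), seg + 2 / fs)
  # logistic trace: the second derivative peaks at t0 - 1.317 * tau
  tau <- 0.15
  tinf <- 0.8
  logi <- plogis((time_s - tinf) / tau)
  expect_lt(abs(trace_onset(logi, time_s) - (tinf - 1.317 * tau)), 2 / fs)
  # constant trace undefined; short trace errors
  expect_true(is.na(trace_onset(rep(2, 60), time_s[1:60])))
  expect_error(trace_onset(1:3, 1:3), "too short")
})

test_that("lick_rate_trace reflects the lick raster", {
  time_s <- -3 + (0:209) / 30
  tab <- trial_table("m", 0:9, 1, 10000, rep("go", 10),
                     replicate(10, 1.5, simplify = FALSE))
  lr <- lick_rate_trace(tab, time_s)
  peak <- which.max(lr)
  expect_lt(abs(time_s[peak] - 1.5), 1 / 30)
  expect_equal(max(lr), 1)
  expect_equal(sum(lr > 0), 1)
  # no licks -> zero trace, onset undefined
  quiet <- trial_table("m", 0:9, 1, 10000, rep("go", 10),
                       replicate(10, numeric(0), simplify = FALSE))
  lr0 <- lick_rate_trace(quiet, time_s)
  expect_true(all(lr0 == 0))
  expect_true(is.na(trace_onset(lr0, time_s)))
})

test_that("alternative pairs behave as constructed", {
  # no-go responses and FA choice zeroed: alt_choice AUC hovers near 0.5
  cfg <- sim_config(
    n_trials = 600,
    stim_response = list(onset_s = 0.05, duration_s = 1, amplitude = 0.06,
                         nogo_gain = 0, onset_boost = 5,
                         onset_boost_duration_s = 0.1),
    choice_response = list(onset_s = 0.2, duration_s = 2.8,
                           amplitude = 0.05, sign = 1, fa_gain = 0),
    seed = 31)
  tr <- simulate_behavior(cfg)
  ses <- normalize_trials(simulate_photometry(tr, cfg)$session)
  tc <- auc_timecourse(ses, tr, "alt_choice", "novice", n_shuffles = 100,
                       seed = 32)
  expect_lt(max(abs(tc$auc - 0.5)), 0.2)
})
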