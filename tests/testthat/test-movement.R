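# a tiny frame world shared by the motion-energy tests
tiny_masks <- function() {
  m1 <- matrix(FALSE, 8, 8); m1[5:8, 1:4] <- TRUE
  m2 <- matrix(FALSE, 8, 8); m2[1:4, 5:8] <- TRUE
  list(roi1 = m1, roi2 = m2)
}

test_that("motion energy is 0 for static frames and 2 for inversion", {
  masks <- tiny_masks()
  time_s <- -3 + (0:89) / 30
  quiet <- build_frame_stack(list(list(roi1 = NULL, roi2 = NULL)),
                             time_s, masks, noise_sd = 0, seed = 2)
  e <- motion_energy(quiet, "roi1")
  expect_equal(max(abs(e)), 0)

  # hand-built 2x2 ROI: frame vs its contrast inversion has r = -1
  mask <- matrix(TRUE, 2, 2)
  fr <- array(0L, dim = c(1, 2, 2, 2))
  fr[1, 1, , ] <- matrix(c(10, 200, 60, 150), 2, 2)
  fr[1, 2, , ] <- 255 - fr[1, 1, , ] * 1L
  st <- frame_stack(fr, c(0, 1 / 30), 30, list(all = mask))
  e2 <- motion_energy(st, "all")
  expect_equal(e2[1, 2], 2)
  # zero-variance frames get energy 0 by convention
  fr0 <- array(7L, dim = c(1, 3, 2, 2))
  st0 <- frame_stack(fr0, (0:2) / 30, 30, list(all = mask))
  expect_equal(max(abs(motion_energy(st0, "all"))), 0)
  expect_error(motion_energy(st0, "nope"), "unknown ROI")
})

test_that("injected movement is detected within one frame", {
  masks <- tiny_masks()
  time_s <- -3 + (0:119) / 30
  iv <- list(list(roi1 = c(0.4, 0.9), roi2 = NULL))
  st <- build_frame_stack(iv, time_s, masks, noise_sd = 1, seed = 5)
  mt <- movement_traces(st)
  moving <- which(mt$binary$roi1[1, ])
  expected <- which(time_s >= 0.4 & time_s < 0.9)
  expect_lte(abs(min(moving) - min(expected)), 1)
  expect_lte(abs(max(moving) - max(expected)), 1)
  expect_equal(sum(mt$binary$roi1[1, -c(min(moving):(max(moving) + 1))]), 0)
  # movement only in ROI 1: ROI 2 stays quiet
  expect_false(any(mt$binary$roi2[1, ]))
  # onset is 0.2 s before the first crossing
  expect_equal(mt$onset_s[1], time_s[min(moving)] - 0.2)
})

test_that("binarize thresholds at baseline mean + 3 SD with an SD floor", {
  set.seed(8)
  energy <- abs(rnorm(120, 0.02, 0.003))
  base_idx <- 1:30
  burst_idx <- 60:75
  energy[burst_idx] <- 0.5
  b <- binarize(energy, base_idx)
  expect_equal(which(b$binary), burst_idx)
  expect_equal(b$threshold,
               mean(energy[base_idx]) + 3 * sd(energy[base_idx]))
  # energy identically zero -> all quiet
  expect_false(any(binarize(rep(0, 50), 1:10)$binary))
  # zero baseline SD with a positive excursion: epsilon floor still flags it
  e0 <- c(rep(0.01, 30), rep(0.4, 5), rep(0.01, 15))
  expect_equal(which(binarize(e0, 1:30)$binary), 31:35)
  expect_error(binarize(e0, 1:2), "at least 3")
})

test_that("movement_map tracks scheduled movement probability", {
  cfg <- sim_preset("standard", seed = 55)
  tr <- simulate_behavior(cfg)
  me <- simulate_motion_energy(tr, cfg)
  mt <- energy_movement_traces(me$energy, me$time_s)
  mm <- movement_map(mt$binary$composite, tr, me$time_s)
  expect_true(all(mm$probability >= 0 & mm$probability <= 1, na.rm = TRUE))
  # movement rises with learning: expert late-window probability > novice
  n_bins <- nrow(mm$probability)
  expect_gt(mean(mm$windows[(n_bins - 9):n_bins, "stim"]),
            mean(mm$windows[1:10, "stim"]))
  # degenerate cases
  all_move <- matrix(TRUE, nrow(tr), length(me$time_s))
  expect_equal(unique(as.vector(
    movement_map(all_move, tr, me$time_s)$probability)), 1)
  none <- movement_map(!all_move, tr, me$time_s)
  expect_equal(max(none$probability, na.rm = TRUE), 0)
})

test_that("licking never precedes jaw-inclusive movement onset", {
  b <- std_bundle()
  me <- simulate_motion_energy(b$trials, b$cfg)
  mt <- energy_movement_traces(me$energy, me$time_s)
  lick_trials <- which(b$trials$outcome %in% c("hit", "FA"))
  onsets <- mt$onset_s[lick_trials]
  firsts <- b$trials$first_lick_s[lick_trials]
  ok <- !is.na(onsets)
  expect_true(all(firsts[ok] > onsets[ok]))
})

test_that("truncation preserves surviving samples bit-exactly", {
  b <- std_bundle()
  ses <- b$session
  onsets <- rep(NA_real_, nrow(ses$traces))
  onsets[3] <- 0.5
  onsets[4] <- ses$time_s[1] - 1         # before the trial start
  tr <- truncate_movement(ses, onsets)
  # untouched trial: identical to input
  expect_identical(tr$trials[[1]], ses$traces[1, ])
  # truncated trial: exact prefix, ends strictly before 0.5 s
  kept <- tr$trials[[3]]
  expect_identical(kept, ses$traces[3, seq_along(kept)])
  expect_lt(ses$time_s[length(kept)], 0.5)
  expect_gte(ses$time_s[length(kept) + 1], 0.5)
  # fully truncated trial flagged
  expect_true(tr$fully_truncated[4])
  expect_equal(tr$n_kept[4], 0L)
})

test_that("movement_free_response windows surviving samples only", {
  ses <- toy_session(matrix(seq(0, 1, length.out = 210), 3, 210,
                            byrow = TRUE))
  onsets <- c(NA, 0.5, -2.9)
  tr <- truncate_movement(ses, onsets)
  full <- window_response(ses, c(0, 1))
  mf <- movement_free_response(tr, c(0, 1))
  expect_equal(mf[1], full[1])           # untruncated = window_response
  # half-truncated ramp: mean of the surviving frames, computed by hand
  idx_all <- which(ses$time_s >= 0 & ses$time_s < 1)
  idx_kept <- idx_all[ses$time_s[idx_all] < 0.5]
  expect_equal(mf[2], mean(ses$traces[2, idx_kept]))
  expect_true(is.na(mf[3]))              # truncated before the window
  # min_samples rule
  expect_true(is.na(movement_free_response(tr, c(0, 1),
                                           min_samples = 60)[2]))
})

test_that("choice encoding survives truncation when it is not movement", {
  # movement coupling 0, real choice amplitude: truncation keeps direction
  agree <- sapply(1:10, function(s) {
    cfg <- sim_preset("standard", seed = 700 + s)
    tr <- simulate_behavior(cfg)
    ses <- normalize_trials(simulate_photometry(tr, cfg)$session)
    me <- simulate_motion_energy(tr, cfg)
    mt <- energy_movement_traces(me$energy, me$time_s)
    expert <- phase_trials(tr, "expert")
    # late window so surviving trials share comparable frame sets
    w <- c(0.6, 1) + 1e-9
    full <- window_response(ses, w)
    mf <- movement_free_response(truncate_movement(ses, mt$onset_s), w,
                                 min_samples = 6)
    h <- expert & tr$outcome == "hit"; m <- expert & tr$outcome == "miss"
    d_full <- mean(full[h]) - mean(full[m])
    d_free <- mean(mf[h], na.rm = TRUE) - mean(mf[m], na.rm = TRUE)
    sign(d_full) == sign(d_free)
  })
  expect_gte(mean(agree), 0.9)
})
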