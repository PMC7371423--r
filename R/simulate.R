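#' Simulate the behavioral record of a learning run
#'
#' Per trial, the stimulus class is drawn with \code{go_fraction}; the
#' lick/no-lick decision follows the trial-indexed hit-rate (go) or
#' false-alarm-rate (no-go) acquisition sigmoid; the first lick time is
#' drawn from the configured latency distribution truncated to the response
#' window and is followed by a lick bout; outcomes are assigned by
#' [classify_outcomes()]. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @param mouse_id identifier stored in the table.
#' @return a \code{trial_table}; attribute \code{true_learning_threshold}
#'   holds the trial at which the generative d' schedule crosses 1 (NA if it
#'   never does).
#' @export
simulate_behavior <- function(config, mouse_id = "sim1") {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_trials
  with_seed(config$seed, {
    t <- seq_len(n)
    is_go <- stats::runif(n) < config$go_fraction
    p_hit <- schedule_rate(config$behavior$hit, t)
    p_fa <- 1 - schedule_rate(config$behavior$cr, t)
    lick <- stats::runif(n) < ifelse(is_go, p_hit, p_fa)
    licks <- replicate(n, numeric(0), simplify = FALSE)
    rw <- .RESPONSE_WINDOW
    ll <- config$lick_latency
    lick_idx <- which(lick)
    if (length(lick_idx)) {
      nl <- length(lick_idx)
      # inverse-CDF truncated normal first lick inside the response window
      plo <- stats::pnorm(rw[1], ll$mean_s, ll$sd_s)
      phi <- stats::pnorm(rw[2], ll$mean_s, ll$sd_s)
      first <- stats::qnorm(plo + stats::runif(nl) * (phi - plo),
                            ll$mean_s, ll$sd_s)
      # lick bout: Poisson train after the first lick (30 draws cover
      # > 99.9% of bouts at the default rate and duration)
      n_draw <- max(10L, ceiling(4 * config$lick_rate_hz *
                                   config$lick_train_end_s))
      gaps <- matrix(stats::rexp(nl * n_draw, config$lick_rate_hz),
                     nl, n_draw)
      for (j in seq_len(nl)) {
        bout <- first[j] + c(0, cumsum(gaps[j, ]))
        licks[[lick_idx[j]]] <-
          bout[bout <= min(config$lick_train_end_s + first[j],
                           config$trial_window[2])]
      }
    }
    tab <- trial_table(
      mouse_id = mouse_id, trial_index = t - 1L,
      day = ceiling(t / 300), # ~300 trials/day over the 3-7 day schedule
      stimulus_freq_hz = ifelse(is_go, config$go_freq_hz,
                                config$nogo_freq_hz),
      stimulus_class = ifelse(is_go, "go", "no-go"),
      lick_times_s = licks)
    attr(tab, "true_learning_threshold") <- true_dprime_crossing(config)
    attr(tab, "sim_config") <- config
    tab
  })
}

# trial at which the generative (noise-free) d' schedule crosses 1
true_dprime_crossing <- function(config, criterion = 1) {
  dp <- function(t) {
    h <- schedule_rate(config$behavior$hit, t)
    f <- 1 - schedule_rate(config$behavior$cr, t)
    stats::qnorm(pmin(pmax(h, 1e-12), 1 - 1e-12)) -
      stats::qnorm(pmin(pmax(f, 1e-12), 1 - 1e-12)) - criterion
  }
  lo <- 1; hi <- config$n_trials
  if (dp(lo) >= 0) return(lo)
  if (dp(hi) < 0) return(NA_real_)
  stats::uniroot(dp, c(lo, hi), tol = 1e-3)$root
}

# unit-sum difference-of-exponentials calcium kernel sampled at fs
calcium_kernel <- function(rise_s, decay_s, fs, length_s = 5 * decay_s) {
  tau <- seq(0, length_s, by = 1 / fs)
  k <- exp(-tau / decay_s) - exp(-tau / rise_s)
  k / sum(k)
}

# causal convolution of each row of drive with kernel k (zero-padded past)
convolve_rows <- function(drive, k) {
  nf <- ncol(drive)
  k <- k[seq_len(min(length(k), nf))]
  kmat <- matrix(0, nf, nf)
  for (j in seq_along(k)) {
    idx <- seq_len(nf - j + 1)
    kmat[cbind(idx, idx + j - 1)] <- k[j]
  }
  drive %*% kmat
}

# per-trial movement intervals, deterministic given config (shared between
# the photometry and frame generators so ground truth agrees)
simulate_movement_intervals <- function(table, config) {
  n <- nrow(table)
  mv <- config$movement
  wend <- config$trial_window[2]
  with_seed(config$seed + 104729L, {  # fixed offset: independent substream
    p_burst <- schedule_rate(mv$prob, seq_len(n))
    spontaneous <- stats::runif(n) < p_burst
    starts <- pmax(0.05, stats::rnorm(n, mv$onset_mean_s, mv$onset_sd_s))
    lick_burst <- stats::runif(n) < (mv$lick_prob %||% 0.5)
    lapply(seq_len(n), function(i) {
      licks_i <- table$lick_times_s[[i]]
      body <- NULL
      if ((mv$lick_coupled && lick_burst[i] && length(licks_i)) ||
          spontaneous[i])
        body <- c(starts[i], min(starts[i] + mv$burst_duration_s, wend))
      jaw <- if (length(licks_i))
        c(max(min(licks_i) - 0.1, config$trial_window[1]),
          min(max(licks_i) + 0.1, wend))
      list(body = body, jaw = jaw)
    })
  })
}

# union of body + jaw intervals, merged, clipped to the trial window
composite_intervals <- function(iv, config) {
  segs <- rbind(if (!is.null(iv$body)) iv$body, if (!is.null(iv$jaw)) iv$jaw)
  if (is.null(segs) || nrow(segs) == 0) return(NULL)
  segs <- segs[order(segs[, 1]), , drop = FALSE]
  out <- segs[1, , drop = FALSE]
  for (r in seq_len(nrow(segs))[-1]) {
    if (segs[r, 1] <= out[nrow(out), 2])
      out[nrow(out), 2] <- max(out[nrow(out), 2], segs[r, 2])
    else out <- rbind(out, segs[r, ])
  }
  out
}

#' Simulate the trial-aligned photometry of a behavioral run
#'
#' Each trial's raw fluorescence is \code{F0 * (1 + s(t))} where the signal
#' drive s is the sum of a frequency-tuned stimulus component (go/no-go
#' gains, onset transient), a choice component on lick trials whose
#' amplitude follows the learning schedule (signed), an additive movement
#' coupling during movement intervals, and per-frame white noise; the summed
#' drive is convolved with the calcium kernel. Ground truth (true onsets,
#' movement intervals, per-trial choice amplitude) is returned alongside.
#'
#' @param table a \code{trial_table} from [simulate_behavior()].
#' @param config the same [sim_config()].
#' @return list with elements \code{session} (raw \code{photometry_session})
#'   and \code{ground_truth} (list: \code{learning_threshold_trial},
#'   \code{stim_onset_s}, \code{choice_onset_s}, \code{movement_intervals}
#'   per trial, \code{choice_amplitude} per trial).
#' @export
simulate_photometry <- function(table, config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sampling_rate
  tw <- config$trial_window
  nf <- as.integer(round((tw[2] - tw[1]) * fs))
  if (nf < 2) stop("sampling_rate x trial_window too small", call. = FALSE)
  time_s <- tw[1] + (seq_len(nf) - 1) / fs
  n <- nrow(table)
  sr <- config$stim_response
  ch <- config$choice_response
  if ((sr$onset_s + sr$duration_s) > tw[2])
    stop("sampling_rate x trial_window too small to contain the stimulus period",
         call. = FALSE)

  intervals <- simulate_movement_intervals(table, config)
  with_seed(config$seed + 15485863L, {
    drive <- matrix(stats::rnorm(n * nf, sd = config$noise_sd), n, nf)
    # stimulus component (same for every trial of a class, all of learning)
    stim_idx <- which(time_s >= sr$onset_s &
                        time_s < sr$onset_s + sr$duration_s)
    boost_idx <- which(time_s >= sr$onset_s &
                         time_s < sr$onset_s + sr$onset_boost_duration_s)
    amp_stim <- sr$amplitude * ifelse(table$stimulus_class == "go", 1,
                                      sr$nogo_gain)
    drive[, stim_idx] <- drive[, stim_idx] + amp_stim
    drive[, boost_idx] <- drive[, boost_idx] +
      amp_stim * (sr$onset_boost - 1)
    # choice component on lick trials, amplitude scheduled to learning
    sched <- stats::plogis((seq_len(n) - config$behavior$hit$b) /
                             config$behavior$hit$c)
    lick_gain <- ifelse(table$outcome == "hit", 1,
                        ifelse(table$outcome == "FA", ch$fa_gain, 0))
    choice_amp <- ch$sign * ch$amplitude * sched * lick_gain
    choice_idx <- which(time_s >= ch$onset_s &
                          time_s < ch$onset_s + ch$duration_s)
    drive[, choice_idx] <- drive[, choice_idx] + choice_amp
    # movement coupling
    if (config$movement$coupling != 0) {
      for (i in seq_len(n)) {
        comp <- composite_intervals(intervals[[i]], config)
        if (is.null(comp)) next
        for (r in seq_len(nrow(comp))) {
          idx <- which(time_s >= comp[r, 1] & time_s < comp[r, 2])
          drive[i, idx] <- drive[i, idx] + config$movement$coupling
        }
      }
    }
    k <- calcium_kernel(config$calcium_kernel$rise_s,
                        config$calcium_kernel$decay_s, fs)
    signal <- convolve_rows(drive, k)
    f0 <- config$baseline_f *
      (1 + stats::rnorm(n, sd = config$baseline_jitter_sd))
    f0 <- pmax(f0, 0.05 * config$baseline_f)
    traces <- f0 * (1 + signal)
    session <- photometry_session(traces, time_s, fs,
                                  config$baseline_window,
                                  mouse_id = table$mouse_id[1],
                                  normalized = FALSE)
    gt <- list(
      learning_threshold_trial = attr(table, "true_learning_threshold") %||%
        true_dprime_crossing(config),
      stim_onset_s = sr$onset_s,
      choice_onset_s = ch$onset_s,
      movement_intervals = lapply(intervals, composite_intervals, config),
      movement_intervals_by_roi = intervals,
      choice_amplitude = choice_amp)
    list(session = session, ground_truth = gt)
  })
}

# default ROI geometry: three rectangles on the camera image
default_roi_masks <- function(height, width) {
  mk <- function(r1, r2, c1, c2) {
    m <- matrix(FALSE, height, width)
    m[r1:r2, c1:c2] <- TRUE
    m
  }
  h3 <- max(2L, height %/% 3); w2 <- max(2L, width %/% 2)
  list(forelimbs = mk(height - h3 + 1L, height, 1L, w2),
       neck = mk(h3 + 1L, min(2L * h3, height), 1L, w2),
       jaw = mk(1L, h3, w2 + 1L, width))
}

#' Build a body-camera frame stack with prescribed movement intervals
#'
#' Low-level generator used by [simulate_movement_frames()] and by tests:
#' a static textured background plus, during each ROI's movement intervals,
#' a frame-to-frame translation of the texture inside that ROI. Per-frame
#' sensor noise is added on top.
#'
#' @param intervals_by_roi list (one element per trial) of named lists of
#'   (start_s, end_s) rows per ROI name, or NULL for a quiet trial.
#' @param time_s frame times.
#' @param roi_masks named logical masks.
#' @param frame_rate Hz.
#' @param noise_sd per-pixel Gaussian sensor noise (8-bit units).
#' @param seed RNG seed.
#' @return a \code{frame_stack}.
#' @export
build_frame_stack <- function(intervals_by_roi, time_s, roi_masks,
                              frame_rate = 30, noise_sd = 2, seed = 1L) {
  n <- length(intervals_by_roi)
  nf <- length(time_s)
  h <- nrow(roi_masks[[1]]); w <- ncol(roi_masks[[1]])
  with_seed(seed, {
    background <- matrix(sample(40:215, h * w, replace = TRUE), h, w)
    frames <- array(0L, dim = c(n, nf, h, w))
    for (i in seq_len(n)) {
      base_i <- background
      shift_count <- stats::setNames(integer(length(roi_masks)),
                                     names(roi_masks))
      for (f in seq_len(nf)) {
        img <- base_i
        for (nm in names(roi_masks)) {
          segs <- intervals_by_roi[[i]][[nm]]
          if (is.null(segs)) next
          segs <- matrix(segs, ncol = 2)
          moving <- any(time_s[f] >= segs[, 1] & time_s[f] < segs[, 2])
          if (moving) shift_count[nm] <- shift_count[nm] + 1L
          if (shift_count[nm] > 0L) {
            # translate the texture inside the ROI's bounding box
            rows <- range(which(rowSums(roi_masks[[nm]]) > 0))
            cols <- range(which(colSums(roi_masks[[nm]]) > 0))
            patch <- background[rows[1]:rows[2], cols[1]:cols[2]]
            s <- shift_count[nm] %% ncol(patch)
            if (s > 0)
              patch <- patch[, c((s + 1):ncol(patch), 1:s), drop = FALSE]
            img[rows[1]:rows[2], cols[1]:cols[2]] <- patch
          }
        }
        if (noise_sd > 0)
          img <- img + round(stats::rnorm(h * w, sd = noise_sd))
        frames[i, f, , ] <- pmin(pmax(img, 0L), 255L)
      }
    }
    frame_stack(frames, time_s, frame_rate, roi_masks)
  })
}

#' Simulate body-camera frames for a behavioral run
#'
#' Uses the same seeded movement intervals as [simulate_photometry()] (body
#' bursts drive the forelimb and neck ROIs, lick bouts drive the jaw ROI) so
#' that photometric ground truth and video agree trial by trial.
#'
#' @param table a \code{trial_table} from [simulate_behavior()].
#' @param config the same [sim_config()].
#' @param trials optional integer subset of trials (1-based) to render;
#'   frames are memory-hungry, default first 20 trials.
#' @return list with \code{stack} (a \code{frame_stack}),
#'   \code{intervals} (ground-truth composite intervals per rendered trial)
#'   and \code{trials} (the rendered subset).
#' @export
simulate_movement_frames <- function(table, config,
                                     trials = seq_len(min(20L,
                                                          nrow(table)))) {
  stopifnot(inherits(config, "sim_config"))
  fr <- config$frame
  masks <- default_roi_masks(fr$height, fr$width)
  nf <- as.integer(round(diff(config$trial_window) * fr$rate))
  time_s <- config$trial_window[1] + (seq_len(nf) - 1) / fr$rate
  iv <- simulate_movement_intervals(table, config)[trials]
  by_roi <- lapply(iv, function(x)
    list(forelimbs = x$body, neck = x$body, jaw = x$jaw))
  stack <- build_frame_stack(by_roi, time_s, masks, frame_rate = fr$rate,
                             noise_sd = fr$noise_sd,
                             seed = config$seed + 32452843L)
  list(stack = stack,
       intervals = lapply(iv, composite_intervals, config),
       trials = trials)
}

#' Simulate precomputed motion-energy traces for a behavioral run
#'
#' The cheap counterpart of [simulate_movement_frames()]: per-trial motion
#' energy at the camera frame rate with a low positive baseline (rectified
#' sensor noise) and high-energy bursts during the same seeded ground-truth
#' movement intervals as [simulate_photometry()].
#'
#' @param table a \code{trial_table} from [simulate_behavior()].
#' @param config the same [sim_config()].
#' @param burst_energy energy level during movement (baseline is ~0.02).
#' @return list: \code{energy} (trials x frames), \code{time_s},
#'   \code{intervals} (ground-truth composite intervals per trial).
#' @export
simulate_motion_energy <- function(table, config, burst_energy = 0.8) {
  stopifnot(inherits(config, "sim_config"))
  fr <- config$frame
  nf <- as.integer(round(diff(config$trial_window) * fr$rate))
  time_s <- config$trial_window[1] + (seq_len(nf) - 1) / fr$rate
  iv <- simulate_movement_intervals(table, config)
  comp <- lapply(iv, composite_intervals, config)
  n <- nrow(table)
  with_seed(config$seed + 49979687L, {
    energy <- matrix(0.02 + abs(stats::rnorm(n * nf, sd = 0.004)), n, nf)
    for (i in seq_len(n)) {
      if (is.null(comp[[i]])) next
      for (r in seq_len(nrow(comp[[i]]))) {
        idx <- which(time_s >= comp[[i]][r, 1] & time_s < comp[[i]][r, 2])
        energy[i, idx] <- burst_energy +
          abs(stats::rnorm(length(idx), sd = 0.05))
      }
    }
    energy[, 1] <- 0  # no predecessor frame
    list(energy = energy, time_s = time_s, intervals = comp)
  })
}

#' Simulate a passive frequency-tuning session
#'
#' Short tone presentations over a frequency x attenuation grid whose evoked
#' amplitude follows a log-Gaussian tuning function scaled down with
#' attenuation, through the same kernel-and-noise pipeline as the task
#' simulator.
#'
#' @param config a [sim_config()] (fields \code{tuning}, noise and kernel
#'   are used).
#' @param freqs_hz tone frequencies (default 8 log-spaced, 4--40 kHz).
#' @param attens_db attenuations relative to the reference level (dB).
#' @param n_repeats presentations per (frequency, attenuation) cell.
#' @param seed RNG seed (defaults to the config seed).
#' @return a labelled raw \code{photometry_session} (labels: \code{freq_hz},
#'   \code{atten_db}); baseline window (-0.4, 0) s, trial window (-0.4,
#'   0.6] s.
#' @export
simulate_passive_tuning <- function(config,
                                    freqs_hz = round(2^seq(log2(4000),
                                                           log2(40000),
                                                           length.out = 8)),
                                    attens_db = c(10, 20, 30, 40),
                                    n_repeats = 10,
                                    seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sampling_rate
  tw <- c(-0.4, 0.6)
  nf <- as.integer(round(diff(tw) * fs))
  time_s <- tw[1] + (seq_len(nf) - 1) / fs
  grid <- expand.grid(freq_hz = freqs_hz, atten_db = attens_db)
  labels <- grid[rep(seq_len(nrow(grid)), each = n_repeats), , drop = FALSE]
  rownames(labels) <- NULL
  n <- nrow(labels)
  tun <- config$tuning
  with_seed(seed + 900001L, {
    labels <- labels[sample.int(n), , drop = FALSE]  # interleaved order
    rownames(labels) <- NULL
    gain <- tun$amplitude *
      exp(-(log2(labels$freq_hz / tun$best_freq_hz))^2 /
            (2 * tun$bandwidth_oct^2)) *
      (50 - labels$atten_db) / 40
    drive <- matrix(stats::rnorm(n * nf, sd = config$noise_sd), n, nf)
    stim_idx <- which(time_s >= 0 & time_s < 0.1)   # 0.1 s tones
    drive[, stim_idx] <- drive[, stim_idx] + gain * 3  # brief, punchy onset
    k <- calcium_kernel(config$calcium_kernel$rise_s,
                        config$calcium_kernel$decay_s, fs)
    signal <- convolve_rows(drive, k)
    traces <- config$baseline_f * (1 + signal)
    photometry_session(traces, time_s, fs, baseline_window = c(-0.4, 0),
                       mouse_id = "passive", normalized = FALSE,
                       labels = labels)
  })
}
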