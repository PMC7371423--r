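#' Rank-based ROC area between two sample sets
#'
#' Equals the fraction of cross-pairs (a, b) with a > b, counting ties as
#' 1/2 (the Mann-Whitney identity): the accuracy of an ideal observer
#' discriminating the two distributions. 0.5 means no discrimination.
#'
#' @param samples_a,samples_b nonempty numeric vectors (class A first:
#'   values of A above B push the AUC toward 1).
#' @return value in [0, 1].
#' @export
#' @examples
#' auc(c(1, 2, 3), c(0, 1, 2))  # 7/9
auc <- function(samples_a, samples_b) {
  n_a <- length(samples_a); n_b <- length(samples_b)
  if (n_a == 0 || n_b == 0) stop("empty sample set", call. = FALSE)
  r <- rank(c(samples_a, samples_b), ties.method = "average")
  (sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2) / (n_a * n_b)
}

.AUC_PAIRS <- list(stim = c("hit", "FA"), choice = c("hit", "miss"),
                   alt_stim = c("CR", "miss"), alt_choice = c("FA", "CR"))

pair_classes <- function(pair) {
  if (!pair %in% names(.AUC_PAIRS))
    stop("unknown AUC pair '", pair, "' (use stim, choice, alt_stim, ",
         "alt_choice)", call. = FALSE)
  .AUC_PAIRS[[pair]]
}

# column-wise ranks of a trials x frames matrix
rank_columns <- function(m) apply(m, 2, rank, ties.method = "average")

auc_from_ranks <- function(ranks, idx_a, n_b) {
  n_a <- length(idx_a)
  (colSums(ranks[idx_a, , drop = FALSE]) - n_a * (n_a + 1) / 2) /
    (n_a * n_b)
}

#' Time-resolved AUC between two trial types
#'
#' Per time frame, the ROC area between the per-trial dF/F values of the
#' two classes of the pair, over the trials of one learning phase. Pairs:
#' \code{stim} = hit vs FA (different stimulus, same choice), \code{choice}
#' = hit vs miss (same stimulus, different choice), \code{alt_stim} = CR vs
#' miss, \code{alt_choice} = FA vs CR. With \code{n_shuffles > 0} a
#' trial-shuffled null band, per-frame significance (|AUC - null mean| >
#' 3 null SD) and the discrimination latency (earliest significant frame at
#' t >= 0) are attached.
#'
#' @param session a normalized \code{photometry_session}.
#' @param table the matching \code{trial_table}.
#' @param pair one of stim, choice, alt_stim, alt_choice.
#' @param phase "novice", "expert" or "all" (first / last 500 trials).
#' @param n_shuffles shuffle iterations for the null band (default 100;
#'   0 skips the null).
#' @param seed RNG seed for the shuffles.
#' @param shuffle "pair" (default: permute the two class labels among the
#'   pooled trials of the pair) or "gonogo" (permute go/no-go identity
#'   among the pooled trials, the literal stimulus shuffle).
#' @param n_phase trials per phase.
#' @return list of class \code{auc_timecourse}: \code{time_s}, \code{auc},
#'   \code{null_mean}, \code{null_sd}, \code{significant},
#'   \code{latency_s}, \code{pair}, \code{phase}, \code{n_a}, \code{n_b};
#'   NULL (with a warning) when a class has < 2 trials in the phase.
#' @export
auc_timecourse <- function(session, table, pair = "choice",
                           phase = c("all", "novice", "expert"),
                           n_shuffles = 100, seed = 1L, shuffle = "pair",
                           n_phase = 500) {
  phase <- match.arg(phase)
  check_aligned(session, table)
  cls <- pair_classes(pair)
  in_phase <- phase_trials(table, phase, n_phase)
  idx_a <- which(in_phase & table$outcome == cls[1])
  idx_b <- which(in_phase & table$outcome == cls[2])
  if (length(idx_a) < 2 || length(idx_b) < 2) {
    warning(sprintf("pair %s in %s phase: class too small (%d vs %d)",
                    pair, phase, length(idx_a), length(idx_b)),
            call. = FALSE)
    return(NULL)
  }
  pooled <- session$traces[c(idx_a, idx_b), , drop = FALSE]
  n_a <- length(idx_a); n_b <- length(idx_b)
  ranks <- rank_columns(pooled)
  observed <- auc_from_ranks(ranks, seq_len(n_a), n_b)
  tc <- list(time_s = session$time_s, auc = observed,
             null_mean = NULL, null_sd = NULL, significant = NULL,
             latency_s = NA_real_, pair = pair, phase = phase,
             n_a = n_a, n_b = n_b, n_shuffles = n_shuffles)
  class(tc) <- "auc_timecourse"
  if (n_shuffles > 0) {
    null <- shuffle_null_from_ranks(ranks, n_a, n_b, n_shuffles, seed,
                                    shuffle = shuffle,
                                    gonogo = if (shuffle == "gonogo")
                                      table$stimulus_class[c(idx_a, idx_b)])
    tc$null_mean <- null$mean
    tc$null_sd <- null$sd
    tc$significant <- abs(observed - null$mean) > 3 * null$sd
    tc$latency_s <- significance_latency(tc)
  }
  tc
}

# the shuffle engine: labels are permuted once per iteration and applied to
# every frame (trial shuffling, not per-frame shuffling)
shuffle_null_from_ranks <- function(ranks, n_a, n_b, n_shuffles, seed,
                                    shuffle = "pair", gonogo = NULL) {
  if (n_shuffles < 2) stop("need at least 2 shuffle iterations",
                           call. = FALSE)
  n <- n_a + n_b
  with_seed(seed, {
    sel <- matrix(0, n_shuffles, n)  # indicator of the permuted class A
    for (s in seq_len(n_shuffles)) {
      idx <- if (identical(shuffle, "gonogo") && !is.null(gonogo)) {
        # permute go/no-go identity among the pooled trials and call the
        # trials landing on class A's stimulus the new class A
        perm <- sample(gonogo)
        head(which(perm == gonogo[1]), n_a)
      } else sample.int(n, n_a)
      sel[s, idx] <- 1
    }
    draws <- (sel %*% ranks - n_a * (n_a + 1) / 2) / (n_a * n_b)
    mu <- colMeans(draws)
    sdv <- sqrt(colSums(sweep(draws, 2, mu)^2) / (n_shuffles - 1))
    list(mean = mu, sd = pmax(sdv, 1e-6))
  })
}

#' Trial-shuffled null band for a time-resolved AUC
#'
#' For each of \code{n} iterations the class labels of the compared pair are
#' permuted among their pooled trials (one permutation per iteration,
#' applied to every frame) and the AUC timecourse recomputed; returns the
#' per-frame mean and SD over iterations (SD floored at 1e-6).
#'
#' @inheritParams auc_timecourse
#' @param n shuffle iterations (>= 2; default 100).
#' @return list with per-frame \code{mean} and \code{sd}.
#' @export
shuffle_null <- function(session, table, pair = "choice",
                         phase = c("all", "novice", "expert"), n = 100,
                         seed = 1L, shuffle = "pair", n_phase = 500) {
  phase <- match.arg(phase)
  cls <- pair_classes(pair)
  in_phase <- phase_trials(table, phase, n_phase)
  idx_a <- which(in_phase & table$outcome == cls[1])
  idx_b <- which(in_phase & table$outcome == cls[2])
  if (length(idx_a) < 2 || length(idx_b) < 2)
    stop("class too small for a shuffle null", call. = FALSE)
  ranks <- rank_columns(session$traces[c(idx_a, idx_b), , drop = FALSE])
  shuffle_null_from_ranks(ranks, length(idx_a), length(idx_b), n, seed,
                          shuffle = shuffle,
                          gonogo = if (shuffle == "gonogo")
                            table$stimulus_class[c(idx_a, idx_b)])
}

#' Discrimination latency of an AUC timecourse
#'
#' The earliest post-stimulus-onset frame (t >= 0) at which the observed
#' AUC leaves the mean +/- 3 SD band of the trial-shuffled null; NA when no
#' frame does.
#'
#' @param tc an \code{auc_timecourse} with a null band.
#' @return latency in seconds, or NA.
#' @export
significance_latency <- function(tc) {
  if (is.null(tc$null_mean)) stop("timecourse has no null band",
                                  call. = FALSE)
  sig <- abs(tc$auc - tc$null_mean) > 3 * pmax(tc$null_sd, 1e-6)
  eligible <- which(sig & tc$time_s >= 0)
  if (!length(eligible)) NA_real_ else tc$time_s[eligible[1]]
}

#' Onset of a slow trace: peak of the second derivative
#'
#' The trace is smoothed with a centered moving average (default 7 frames,
#' ~230 ms at 30 Hz: second differencing amplifies high-frequency noise, so
#' the pre-smoothing must be wider than the frame spacing), then the
#' discrete second difference is taken; the onset is the time of its
#' maximum. Edge frames, where the smoother has no full window, are
#' excluded from the search. Constant (or too-short) traces give NA.
#'
#' @param trace numeric vector (length >= 5).
#' @param time_s matching time axis.
#' @param smooth_frames moving-average width (odd; 1 disables smoothing).
#' @return onset time in seconds, or NA.
#' @export
trace_onset <- function(trace, time_s, smooth_frames = 7) {
  n <- length(trace)
  if (n < 5) stop("trace too short (need >= 5 frames)", call. = FALSE)
  if (n != length(time_s))
    stop("trace and time_s lengths differ", call. = FALSE)
  if (!any(is.finite(trace)) || max(trace, na.rm = TRUE) -
      min(trace, na.rm = TRUE) < 1e-12) return(NA_real_)
  k <- min(smooth_frames, if (n %% 2) n else n - 1)
  sm <- as.numeric(stats::filter(trace, rep(1 / k, k), sides = 2))
  d2 <- diff(diff(sm))                    # d2[i] ~ curvature at i + 1
  d2[!is.finite(d2)] <- -Inf              # smoother edges are ineligible
  if (max(d2) <= 0) return(NA_real_)
  time_s[which.max(d2) + 1L]
}

#' Lick-rate trace over the trial, and its onset
#'
#' Per-frame lick probability across the go trials of a phase: the fraction
#' of trials with at least one lick in each frame's bin. Feed the result to
#' [trace_onset()] for the lick onset (the same smoothing is applied
#' there).
#'
#' @param table a \code{trial_table}.
#' @param time_s frame-center time axis to bin onto.
#' @param phase "novice", "expert" or "all".
#' @param n_phase trials per phase.
#' @return numeric vector over \code{time_s} (all zero when there are no
#'   licks).
#' @export
lick_rate_trace <- function(table, time_s,
                            phase = c("all", "novice", "expert"),
                            n_phase = 500) {
  phase <- match.arg(phase)
  idx <- which(phase_trials(table, phase, n_phase) &
                 table$stimulus_class == "go")
  out <- numeric(length(time_s))
  if (!length(idx)) return(out)
  dt <- if (length(time_s) > 1) time_s[2] - time_s[1] else 1
  edges <- c(time_s - dt / 2, time_s[length(time_s)] + dt / 2)
  for (i in idx) {
    l <- table$lick_times_s[[i]]
    if (!length(l)) next
    h <- findInterval(l, edges)
    h <- unique(h[h >= 1 & h <= length(time_s)])
    out[h] <- out[h] + 1
  }
  out / length(idx)
}
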