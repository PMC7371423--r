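#' Motion energy of a frame stack within an ROI
#'
#' Per trial and frame, one minus the Pearson correlation of the ROI pixels
#' between consecutive frames. The first frame of each trial gets energy 0,
#' as does any transition involving a zero-variance (blank) frame: no pixel
#' information is not movement.
#'
#' @param stack a \code{frame_stack}.
#' @param roi ROI name (must exist in \code{stack$roi_masks}).
#' @return numeric matrix trials x frames of motion energy.
#' @export
motion_energy <- function(stack, roi) {
  if (!roi %in% names(stack$roi_masks))
    stop("unknown ROI '", roi, "'", call. = FALSE)
  mask <- stack$roi_masks[[roi]]
  d <- dim(stack$frames)
  if (nrow(mask) != d[3] || ncol(mask) != d[4])
    stop("ROI outside the image", call. = FALSE)
  sel <- which(mask)
  energy <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    prev <- stack$frames[i, 1, , ][sel]
    for (f in seq_len(d[2])[-1]) {
      cur <- stack$frames[i, f, , ][sel]
      if (stats::sd(prev) == 0 || stats::sd(cur) == 0) {
        energy[i, f] <- 0
      } else {
        energy[i, f] <- 1 - stats::cor(prev, cur)
      }
      prev <- cur
    }
  }
  energy
}

#' Binarize motion energy into moving / quiet
#'
#' The threshold is mean + 3 SD of the baseline (pre-cue) energy samples
#' (SD floored at 1e-9 so a zero-variance baseline still yields a usable
#' threshold); frames with energy above it are "moving".
#'
#' @param energy numeric vector (one trial's motion energy).
#' @param baseline_idx indices of the pre-cue baseline frames (>= 3).
#' @return list: \code{binary} (logical, TRUE = moving), \code{threshold}.
#' @export
binarize <- function(energy, baseline_idx) {
  if (length(baseline_idx) < 3)
    stop("need at least 3 baseline frames", call. = FALSE)
  base <- energy[baseline_idx]
  threshold <- mean(base) + 3 * max(stats::sd(base), 1e-9)
  list(binary = energy > threshold, threshold = threshold)
}

#' Per-trial movement traces from a frame stack
#'
#' Runs [motion_energy()] and [binarize()] for each requested ROI and
#' combines them into the strict composite "any ROI moving" vector. The
#' movement onset of a trial is 0.2 s before the first threshold crossing.
#'
#' @param stack a \code{frame_stack}.
#' @param rois ROI names (default: all masks in the stack).
#' @param cue_time_s baseline frames are those before this time (default
#'   -2 s, the visual cue).
#' @return list of class \code{movement_traces}: \code{time_s},
#'   \code{energy} (list of matrices per ROI), \code{binary} (list per ROI
#'   plus \code{composite}), \code{threshold} (matrix trials x ROIs),
#'   \code{onset_s} (per trial, NA when never moving).
#' @export
movement_traces <- function(stack, rois = names(stack$roi_masks),
                            cue_time_s = .VISUAL_CUE_S) {
  baseline_idx <- which(stack$time_s < cue_time_s)
  n <- dim(stack$frames)[1]
  energy <- lapply(stats::setNames(rois, rois),
                   function(r) motion_energy(stack, r))
  binary <- list()
  threshold <- matrix(NA_real_, n, length(rois),
                      dimnames = list(NULL, rois))
  for (r in rois) {
    bmat <- matrix(FALSE, n, dim(stack$frames)[2])
    for (i in seq_len(n)) {
      b <- binarize(energy[[r]][i, ], baseline_idx)
      bmat[i, ] <- b$binary
      threshold[i, r] <- b$threshold
    }
    binary[[r]] <- bmat
  }
  composite <- Reduce(`|`, binary)
  onset_s <- movement_onset(composite, stack$time_s)
  structure(list(time_s = stack$time_s, energy = energy,
                 binary = c(binary, list(composite = composite)),
                 threshold = threshold, onset_s = onset_s),
            class = "movement_traces")
}

#' Movement traces from precomputed motion-energy matrices
#'
#' The same binarization and onset logic as [movement_traces()] for
#' pipelines that start from precomputed motion energy rather than raw
#' frames.
#'
#' @param energy numeric matrix trials x frames.
#' @param time_s frame times.
#' @param cue_time_s baseline frames are those before this time.
#' @return list of class \code{movement_traces} with a single "energy"
#'   channel as the composite.
#' @export
energy_movement_traces <- function(energy, time_s,
                                   cue_time_s = .VISUAL_CUE_S) {
  baseline_idx <- which(time_s < cue_time_s)
  n <- nrow(energy)
  bmat <- matrix(FALSE, n, ncol(energy))
  threshold <- numeric(n)
  for (i in seq_len(n)) {
    b <- binarize(energy[i, ], baseline_idx)
    bmat[i, ] <- b$binary
    threshold[i] <- b$threshold
  }
  structure(list(time_s = time_s, energy = list(energy = energy),
                 binary = list(energy = bmat, composite = bmat),
                 threshold = matrix(threshold, ncol = 1,
                                    dimnames = list(NULL, "energy")),
                 onset_s = movement_onset(bmat, time_s)),
            class = "movement_traces")
}

#' Movement onset per trial: 0.2 s before the first threshold crossing
#'
#' @param binary logical matrix trials x frames (TRUE = moving) or vector.
#' @param time_s frame times.
#' @return numeric vector of onsets (NA for trials that never move).
#' @export
movement_onset <- function(binary, time_s) {
  if (is.vector(binary)) binary <- matrix(binary, nrow = 1)
  apply(binary, 1, function(b) {
    k <- which(b)
    if (!length(k)) NA_real_ else time_s[k[1]] - 0.2
  })
}

#' Movement-probability map across learning
#'
#' Per 50-trial bin and frame, the fraction of (filtered) trials moving,
#' plus scalar movement probabilities over the standard windows:
#' pre-stimulus (-1, 0], stimulus (0, 1] and late (0.6, 1] s.
#'
#' @param binary logical matrix trials x frames (typically the composite
#'   vector of [movement_traces()]).
#' @param table the matching \code{trial_table}.
#' @param time_s frame times.
#' @param bin_size trials per bin.
#' @param trial_filter trials entering the map (default go).
#' @return list of class \code{movement_map}: \code{probability} (bins x
#'   frames), \code{bin_center_trial}, \code{time_s}, \code{windows}
#'   (per-bin probabilities in the three windows).
#' @export
movement_map <- function(binary, table, time_s, bin_size = 50,
                         trial_filter = "go") {
  if (nrow(binary) != nrow(table))
    stop("binary matrix and table disagree on trials", call. = FALSE)
  sel <- outcome_filter(table, trial_filter)
  n_bins <- nrow(table) %/% bin_size
  bin <- ceiling((table$trial_index + 1) / bin_size)
  prob <- matrix(NA_real_, n_bins, ncol(binary))
  wins <- list(pre = c(-1, 0), stim = c(0, 1), late = c(0.6, 1))
  wprob <- matrix(NA_real_, n_bins, 3, dimnames = list(NULL, names(wins)))
  for (b in seq_len(n_bins)) {
    idx <- which(sel & bin == b)
    if (!length(idx)) next
    prob[b, ] <- colMeans(binary[idx, , drop = FALSE])
    for (w in seq_along(wins)) {
      fr <- which(time_s > wins[[w]][1] & time_s <= wins[[w]][2])
      # a trial counts as moving in a window if any frame there moves
      wprob[b, w] <- mean(apply(binary[idx, fr, drop = FALSE], 1, any))
    }
  }
  structure(list(probability = prob,
                 bin_center_trial = (seq_len(n_bins) - 1) * bin_size +
                   (bin_size + 1) / 2,
                 time_s = time_s, windows = wprob),
            class = "movement_map")
}

#' Truncate photometry trials at movement onset
#'
#' Per trial, samples at t >= onset are removed (onset = first threshold
#' crossing - 0.2 s, mapped to the nearest photometry frame at or before it
#' when clocks differ); trials without movement are kept whole; surviving
#' samples are bit-identical to the input. Trials whose onset precedes the
#' trial start come out empty and are flagged.
#'
#' @param session a \code{photometry_session}.
#' @param onset_s per-trial movement onsets (NA = no movement), e.g. from
#'   [movement_traces()].
#' @return list of class \code{truncated_session}: \code{trials} (list of
#'   surviving sample vectors), \code{time_s}, \code{onset_s},
#'   \code{n_kept}, \code{fully_truncated} (logical).
#' @export
truncate_movement <- function(session, onset_s) {
  n <- nrow(session$traces)
  if (length(onset_s) != n)
    stop("onset_s must have one value per trial", call. = FALSE)
  time_s <- session$time_s
  trials <- vector("list", n)
  n_kept <- integer(n)
  for (i in seq_len(n)) {
    if (is.na(onset_s[i])) {
      keep <- seq_along(time_s)
    } else {
      # conservative: cut at the last photometry frame strictly before onset
      keep <- which(time_s < onset_s[i] - 1e-9)
    }
    trials[[i]] <- session$traces[i, keep]
    n_kept[i] <- length(keep)
  }
  structure(list(trials = trials, time_s = time_s, onset_s = onset_s,
                 n_kept = n_kept, fully_truncated = n_kept == 0L),
            class = "truncated_session")
}

#' Windowed response of movement-free (truncated) trials
#'
#' Mean over the surviving frames inside the window; missing (NA) when
#' fewer than \code{min_samples} frames survive there ("n.a." trials).
#' Fully truncated trials are excluded rather than imputed.
#'
#' @param truncated a \code{truncated_session}.
#' @param window_s half-open window in seconds.
#' @param min_samples minimum surviving frames in the window (default 1).
#' @return numeric vector per trial (NA = not available).
#' @export
movement_free_response <- function(truncated, window_s, min_samples = 1) {
  vapply(seq_along(truncated$trials), function(i) {
    kept_times <- truncated$time_s[seq_len(truncated$n_kept[i])]
    idx <- which(in_window(kept_times, window_s))
    if (length(idx) < min_samples) NA_real_
    else mean(truncated$trials[[i]][idx])
  }, numeric(1))
}
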