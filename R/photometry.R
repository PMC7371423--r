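#' Normalize each trial to its pre-cue baseline (dF/F)
#'
#' Per trial, F0 is the mean raw fluorescence over the baseline window
#' (which ends at the visual cue); the normalized trace is \code{F/F0 - 1}
#' (dF/F: a no-change trace maps to 0) or the plain ratio \code{F/F0} when
#' \code{convention = "ratio"}. Refuses to normalize twice.
#'
#' @param session a raw \code{photometry_session}.
#' @param convention "dff" (default, F/F0 - 1) or "ratio" (F/F0).
#' @return the normalized \code{photometry_session}.
#' @export
normalize_trials <- function(session, convention = c("dff", "ratio")) {
  convention <- match.arg(convention)
  if (isTRUE(session$normalized))
    stop("session is already normalized", call. = FALSE)
  idx <- which(in_window(session$time_s, session$baseline_window))
  if (!length(idx)) stop("baseline window contains no frames", call. = FALSE)
  f0 <- rowMeans(session$traces[, idx, drop = FALSE])
  bad <- which(f0 <= 0)
  if (length(bad))
    stop("non-positive baseline F0 in trial(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  traces <- session$traces / f0
  if (convention == "dff") traces <- traces - 1
  out <- session
  out$traces <- traces
  out$normalized <- TRUE
  out
}

# trial selectors -----------------------------------------------------------

outcome_filter <- function(table, filter) {
  switch(filter,
         "go" = table$stimulus_class == "go",
         "no-go" = table$stimulus_class == "no-go",
         "hit" = table$outcome == "hit",
         "miss" = table$outcome == "miss",
         "CR" = table$outcome == "CR",
         "FA" = table$outcome == "FA",
         "all" = rep(TRUE, nrow(table)),
         stop("unknown trial filter '", filter, "'", call. = FALSE))
}

#' Select the trials of a learning phase
#'
#' Novice and expert are the first and last 500 trials of the run; when the
#' run is shorter than 2 * n_phase the phases still partition it (with a
#' warning below n_phase trials).
#'
#' @param table a \code{trial_table}.
#' @param phase "novice", "expert" or "all".
#' @param n_phase trials per phase (default 500).
#' @return logical vector over trials.
#' @export
phase_trials <- function(table, phase = c("all", "novice", "expert"),
                         n_phase = 500) {
  phase <- match.arg(phase)
  n <- nrow(table)
  if (phase == "all") return(rep(TRUE, n))
  if (n < n_phase)
    warning("run has only ", n, " trials; using all for the ", phase,
            " phase", call. = FALSE)
  k <- min(n_phase, n)
  if (phase == "novice") seq_len(n) <= k else seq_len(n) > n - k
}

#' Two-dimensional learning map: mean trace per 50-trial bin
#'
#' Rows are consecutive non-overlapping trial bins (the same binning as the
#' learning curve), columns trial time; each cell is the mean dF/F over the
#' bin's trials passing the filter. Bins with no qualifying trial give NA
#' rows.
#'
#' @param session a normalized \code{photometry_session}.
#' @param table the matching \code{trial_table}.
#' @param trial_filter one of go, no-go, hit, miss, CR, FA, all.
#' @param bin_size trials per bin (default 50).
#' @return list of class \code{learning_map}: \code{values} (bins x frames),
#'   \code{bin_center_trial}, \code{time_s}, \code{trial_filter}, \code{n}
#'   (qualifying trials per bin).
#' @export
learning_map <- function(session, table, trial_filter = "go",
                         bin_size = 50) {
  check_aligned(session, table)
  sel <- outcome_filter(table, trial_filter)
  n <- nrow(table)
  n_bins <- n %/% bin_size
  if (n_bins < 1) stop("fewer trials than one bin", call. = FALSE)
  bin <- ceiling((table$trial_index + 1) / bin_size)
  values <- matrix(NA_real_, n_bins, ncol(session$traces))
  counts <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    idx <- which(sel & bin == b)
    counts[b] <- length(idx)
    if (length(idx))
      values[b, ] <- colMeans(session$traces[idx, , drop = FALSE])
  }
  structure(list(values = values,
                 bin_center_trial = (seq_len(n_bins) - 1) * bin_size +
                   (bin_size + 1) / 2,
                 time_s = session$time_s, trial_filter = trial_filter,
                 n = counts),
            class = "learning_map")
}

#' Outcome-wise mean traces for a learning phase
#'
#' @param session a normalized \code{photometry_session}.
#' @param table the matching \code{trial_table}.
#' @param phase "novice", "expert" or "all".
#' @param outcomes which outcome groups to average.
#' @param n_phase trials per phase.
#' @return list per outcome: \code{mean} and \code{sem} traces (over
#'   trials) and \code{n}; plus \code{time_s}.
#' @export
phase_average <- function(session, table,
                          phase = c("all", "novice", "expert"),
                          outcomes = c("hit", "miss", "CR", "FA"),
                          n_phase = 500) {
  phase <- match.arg(phase)
  check_aligned(session, table)
  in_phase <- phase_trials(table, phase, n_phase)
  out <- lapply(stats::setNames(outcomes, outcomes), function(oc) {
    idx <- which(in_phase & outcome_filter(table, oc))
    if (!length(idx))
      return(list(mean = rep(NA_real_, ncol(session$traces)),
                  sem = rep(NA_real_, ncol(session$traces)), n = 0L))
    m <- session$traces[idx, , drop = FALSE]
    list(mean = colMeans(m),
         sem = apply(m, 2, stats::sd) / sqrt(nrow(m)),
         n = length(idx))
  })
  out$time_s <- session$time_s
  out
}

#' Windowed scalar response per trial
#'
#' Mean of each trial's trace over the frames whose time lies in
#' \code{[window_s[1], window_s[2])}.
#'
#' @param session a \code{photometry_session}.
#' @param window_s half-open window in seconds.
#' @return numeric vector, one value per trial.
#' @export
window_response <- function(session, window_s) {
  idx <- which(in_window(session$time_s, window_s))
  if (!length(idx)) stop("window contains no frames", call. = FALSE)
  rowMeans(session$traces[, idx, drop = FALSE])
}

#' Choice trace: hit mean minus miss mean, per frame
#'
#' @inheritParams phase_average
#' @return numeric vector over \code{session$time_s}; all-NA with a warning
#'   when either class is empty in the phase.
#' @export
choice_trace <- function(session, table,
                         phase = c("all", "novice", "expert"),
                         n_phase = 500) {
  phase <- match.arg(phase)
  pa <- phase_average(session, table, phase, outcomes = c("hit", "miss"),
                      n_phase = n_phase)
  if (pa$hit$n == 0 || pa$miss$n == 0) {
    warning("empty hit or miss class in ", phase, " phase; choice trace ",
            "undefined", call. = FALSE)
    return(rep(NA_real_, length(session$time_s)))
  }
  pa$hit$mean - pa$miss$mean
}

#' Frequency response area and tuning curve from a passive session
#'
#' Evoked response = mean dF/F over (0, 0.1] s after tone onset, averaged
#' per (frequency, attenuation) cell; the tuning curve is drawn at the
#' lowest attenuation (loudest level presented) and the best frequency is
#' its argmax.
#'
#' @param passive a normalized, labelled \code{photometry_session} (labels
#'   \code{freq_hz}, \code{atten_db}).
#' @return list of class \code{tuning_result}: \code{freqs_hz},
#'   \code{attens_db}, \code{fra} (attenuations x frequencies),
#'   \code{tuning_curve}, \code{best_frequency}.
#' @export
tuning <- function(passive) {
  if (is.null(passive$labels) ||
      !all(c("freq_hz", "atten_db") %in% names(passive$labels)))
    stop("passive session must carry freq_hz / atten_db labels",
         call. = FALSE)
  evoked <- window_response(passive, c(0, 0.1) + 1e-9)
  freqs <- sort(unique(passive$labels$freq_hz))
  attens <- sort(unique(passive$labels$atten_db))
  fra <- matrix(NA_real_, length(attens), length(freqs),
                dimnames = list(paste0(attens, "dB"), paste0(freqs, "Hz")))
  for (a in seq_along(attens)) for (f in seq_along(freqs)) {
    idx <- which(passive$labels$atten_db == attens[a] &
                   passive$labels$freq_hz == freqs[f])
    if (length(idx)) fra[a, f] <- mean(evoked[idx])
  }
  curve <- fra[1, ]
  structure(list(freqs_hz = freqs, attens_db = attens, fra = fra,
                 tuning_curve = curve,
                 best_frequency = freqs[which.max(curve)]),
            class = "tuning_result")
}

check_aligned <- function(session, table) {
  if (nrow(session$traces) != nrow(table))
    stop("session and trial table disagree on the number of trials (",
         nrow(session$traces), " vs ", nrow(table), ")", call. = FALSE)
  invisible(TRUE)
}
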