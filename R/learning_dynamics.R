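#' Neural response curve across learning and its trial threshold
#'
#' Per 50-trial bin (the learning-curve binning), the mean windowed dF/F
#' over go trials (hits and misses grouped together); the curve is fitted
#' with the sigmoid (with a baseline offset, since fluorescence response
#' curves sit on a sensory floor), the fit is normalized to [0, 1] over the
#' observed trial range, and the trial threshold is the trial at which the
#' normalized fit crosses 0.5. For monotone fits (increasing or decreasing:
#' the normalization uses the magnitude of change) the crossing always
#' exists; flat fits give an undefined threshold.
#'
#' @param session a normalized \code{photometry_session}.
#' @param table the matching \code{trial_table}.
#' @param window_s response window in seconds, default (0.6, 1] (late
#'   times; use per-subject overrides such as (0.2, 0.5) where warranted).
#' @param bin_size trials per bin (default 50).
#' @param trial_filter which trials enter the curve (default go).
#' @return list of class \code{response_curve}: \code{bin_center_trial},
#'   \code{response}, \code{window_s}, \code{fit} (\code{sigmoid_fit}),
#'   \code{normalized_fit}, \code{trial_threshold}.
#' @export
response_curve <- function(session, table, window_s = c(0.6, 1),
                           bin_size = 50, trial_filter = "go") {
  check_aligned(session, table)
  resp <- window_response(session, window_s + c(0, 1e-9))
  sel <- outcome_filter(table, trial_filter)
  n_bins <- nrow(table) %/% bin_size
  if (n_bins < 4) stop("need at least 4 full bins", call. = FALSE)
  bin <- ceiling((table$trial_index + 1) / bin_size)
  centers <- (seq_len(n_bins) - 1) * bin_size + (bin_size + 1) / 2
  curve <- vapply(seq_len(n_bins), function(b) {
    idx <- which(sel & bin == b)
    if (length(idx)) mean(resp[idx]) else NA_real_
  }, numeric(1))
  ok <- is.finite(curve)
  fit <- fit_sigmoid(centers[ok], curve[ok], offset = TRUE)
  fitted_vals <- sigmoid_curve(centers, fit$a, fit$b, fit$c, fit$d)
  s1 <- fitted_vals[1]; s2 <- fitted_vals[n_bins]
  flat <- !isTRUE(fit$converged) || abs(fit$a) < 1e-8 ||
    abs(s2 - s1) < 1e-12
  if (flat) {
    norm <- rep(NA_real_, n_bins)
    threshold <- NA_real_
  } else {
    # normalized magnitude of change: 0 at the start of the observed range,
    # 1 at its end, monotone for monotone fits
    norm <- (fitted_vals - s1) / (s2 - s1)
    p1 <- stats::plogis((centers[1] - fit$b) / fit$c)
    p2 <- stats::plogis((centers[n_bins] - fit$b) / fit$c)
    pm <- (p1 + p2) / 2                    # logistic value at norm = 0.5
    threshold <- fit$b + fit$c * log(pm / (1 - pm))
  }
  structure(list(bin_center_trial = centers, response = curve,
                 window_s = window_s, fit = fit, normalized_fit = norm,
                 trial_threshold = threshold),
            class = "response_curve")
}

#' Per-timepoint correlation between the neural response curve and the
#' behavioral learning curve
#'
#' For each frame, the per-bin mean dF/F at that frame (go trials, same
#' 50-trial bins) is Pearson-correlated with the per-bin d' of the fixed
#' learning curve; bins with missing values in either curve are
#' pairwise-deleted. No smoothing is applied.
#'
#' @param session a normalized \code{photometry_session}.
#' @param table the matching \code{trial_table}.
#' @param learning a \code{learning_curve} with the same binning.
#' @param method "pearson" (default) or "spearman".
#' @param trial_filter which trials enter the neural curve (default go).
#' @return list of class \code{correlation_timecourse}: \code{time_s},
#'   \code{r} (NA where fewer than 3 aligned bins or zero variance).
#' @export
correlation_timecourse <- function(session, table, learning,
                                   method = c("pearson", "spearman"),
                                   trial_filter = "go") {
  method <- match.arg(method)
  check_aligned(session, table)
  bin_size <- attr(learning, "bin_size")
  map <- learning_map(session, table, trial_filter, bin_size)
  if (nrow(map$values) != nrow(learning))
    stop("learning curve and session disagree on binning", call. = FALSE)
  dp <- learning$dprime
  r <- apply(map$values, 2, function(v) {
    ok <- is.finite(v) & is.finite(dp)
    if (sum(ok) < 3) return(NA_real_)
    if (stats::sd(v[ok]) == 0 || stats::sd(dp[ok]) == 0) return(NA_real_)
    stats::cor(v[ok], dp[ok], method = method)
  })
  structure(list(time_s = session$time_s, r = r),
            class = "correlation_timecourse")
}

#' Concordance of neural and behavioral thresholds across mice
#'
#' Pearson correlation between the per-mouse neural trial thresholds and
#' behavioral learning thresholds, over mice where both are defined.
#'
#' @param response_thresholds,learning_thresholds numeric vectors over
#'   mice (NA = undefined).
#' @return Pearson r.
#' @export
threshold_concordance <- function(response_thresholds,
                                  learning_thresholds) {
  if (length(response_thresholds) != length(learning_thresholds))
    stop("threshold vectors differ in length", call. = FALSE)
  ok <- is.finite(response_thresholds) & is.finite(learning_thresholds)
  if (sum(ok) < 3)
    stop("need at least 3 mice with both thresholds defined", call. = FALSE)
  stats::cor(response_thresholds[ok], learning_thresholds[ok])
}

#' Gaussian smoothing for display curves
#'
#' Convolution with a normalized Gaussian kernel (default 2*sigma = 9 bins,
#' i.e. sigma = 4.5) with reflected boundaries. Used only on plotting /
#' report paths: statistics in this package never pass through it.
#'
#' @param curve numeric vector.
#' @param two_sigma kernel width parameter, 2 * sigma in bins.
#' @return smoothed vector of the same length.
#' @export
gaussian_smooth <- function(curve, two_sigma = 9) {
  sigma <- two_sigma / 2
  half <- ceiling(3 * sigma)
  if (length(curve) < 2) return(curve)
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  n <- length(curve)
  # reflected boundaries (indices clamp for curves shorter than the kernel)
  left <- curve[pmin(pmax(half:1, 1), n)]
  right <- curve[pmax(pmin(n - seq_len(half) + 1, n), 1)]
  padded <- c(left, curve, right)
  out <- stats::filter(padded, k, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}
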