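#' Classify trial outcomes from stimulus class and lick evidence
#'
#' A trial counts as a "lick" trial when at least one lick falls inside the
#' response window (default (1, 4] s, i.e. the 3 s after stimulus offset).
#' Licking before the response window (during the stimulus) is allowed and
#' does not determine the outcome. go + lick = hit, go + no lick = miss,
#' no-go + lick = false alarm (FA), no-go + no lick = correct rejection (CR).
#'
#' @param table a \code{trial_table} (the \code{outcome} column is ignored).
#' @param response_window override of the table's lick-counting window.
#' @return character vector of outcomes ("hit", "miss", "FA", "CR").
#' @export
classify_outcomes <- function(table, response_window = NULL) {
  rw <- response_window %||% attr(table, "response_window") %||%
    .RESPONSE_WINDOW
  if (!all(table$stimulus_class %in% c("go", "no-go")))
    stop("unknown stimulus_class", call. = FALSE)
  licked <- vapply(table$lick_times_s,
                   function(l) any(l > rw[1] & l <= rw[2]), logical(1))
  ifelse(table$stimulus_class == "go",
         ifelse(licked, "hit", "miss"),
         ifelse(licked, "FA", "CR"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal-detection sensitivity d'
#'
#' \code{d' = Z(hit rate) - Z(FA rate)} with Z the standard-normal quantile
#' function. Rates at 0 or 1 are clipped to \code{[1/(2n), 1 - 1/(2n)]}
#' (log-linear correction) so d' stays finite.
#'
#' @param hit_rate,fa_rate rates in [0, 1].
#' @param n_go,n_nogo trial counts behind each rate (>= 1).
#' @return d' (numeric scalar; vectorised over its arguments).
#' @export
#' @examples
#' dprime(0.69146, 0.30854, 100, 100)  # ~ 1
dprime <- function(hit_rate, fa_rate, n_go, n_nogo) {
  if (any(hit_rate < 0 | hit_rate > 1) || any(fa_rate < 0 | fa_rate > 1))
    stop("rates must lie in [0, 1]", call. = FALSE)
  if (any(n_go < 1) || any(n_nogo < 1))
    stop("counts must be >= 1", call. = FALSE)
  h <- pmin(pmax(hit_rate, 1 / (2 * n_go)), 1 - 1 / (2 * n_go))
  f <- pmin(pmax(fa_rate, 1 / (2 * n_nogo)), 1 - 1 / (2 * n_nogo))
  stats::qnorm(h) - stats::qnorm(f)
}

#' Binned learning curve
#'
#' Trials are binned in consecutive non-overlapping bins of \code{bin_size}
#' (default 50) along the cumulative trial axis; the last partial bin is
#' dropped. Per bin, d' is computed from the bin-local hit and FA rates;
#' the hit-rate and CR-rate curves are returned alongside. A bin with zero
#' go or zero no-go trials yields NA d'.
#'
#' @param table a \code{trial_table}.
#' @param bin_size trials per bin.
#' @return data.frame of class \code{learning_curve} with columns
#'   \code{bin_center_trial} (1-based trial number of the bin center),
#'   \code{dprime}, \code{hit_rate}, \code{cr_rate}, \code{n_go},
#'   \code{n_nogo}; attribute \code{bin_size}.
#' @export
learning_curve <- function(table, bin_size = 50) {
  n <- nrow(table)
  n_bins <- n %/% bin_size
  if (n_bins < 1)
    return(structure(data.frame(bin_center_trial = numeric(0),
                                dprime = numeric(0), hit_rate = numeric(0),
                                cr_rate = numeric(0), n_go = integer(0),
                                n_nogo = integer(0)),
                     bin_size = bin_size,
                     class = c("learning_curve", "data.frame")))
  trial_no <- table$trial_index + 1L          # 1-based cumulative ordinal
  bin <- ceiling(trial_no / bin_size)
  keep <- bin <= n_bins
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    idx <- which(keep & bin == b)
    go <- table$outcome[idx] %in% c("hit", "miss")
    n_go <- sum(go); n_nogo <- sum(!go)
    hits <- sum(table$outcome[idx] == "hit")
    crs <- sum(table$outcome[idx] == "CR")
    hr <- if (n_go > 0) hits / n_go else NA_real_
    cr <- if (n_nogo > 0) crs / n_nogo else NA_real_
    dp <- if (n_go > 0 && n_nogo > 0) dprime(hr, 1 - cr, n_go, n_nogo)
          else NA_real_
    data.frame(bin_center_trial = (b - 1) * bin_size + (bin_size + 1) / 2,
               dprime = dp, hit_rate = hr, cr_rate = cr,
               n_go = n_go, n_nogo = n_nogo)
  }))
  structure(out, bin_size = bin_size,
            class = c("learning_curve", "data.frame"))
}

#' Fit the three-parameter sigmoid S(t) = d + a / (1 + exp(-(t-b)/c))
#'
#' Deterministic bounded least squares: initialisation a0 = max(y) (or the
#' signed range when a baseline offset is fitted), b0 = midpoint of x,
#' c0 = span(x)/10; bounds a in [0, 2 max(y)] (symmetric around 0 with
#' \code{offset = TRUE} so decreasing curves can be fitted), c in
#' (0, span(x)], b in [min(x) - span, max(x) + span]. Behavioral d' curves
#' are fitted without the offset (the paper's pure Eq.-1 form); fluorescence
#' response curves that sit on a non-zero floor use \code{offset = TRUE}.
#'
#' @param x trial numbers (>= 4 finite points).
#' @param y response values; non-finite entries are rejected.
#' @param offset fit an additive baseline term d? (default FALSE, d = 0).
#' @return list of class \code{sigmoid_fit}: \code{a}, \code{b}, \code{c},
#'   \code{d}, \code{rss}, \code{converged}.
#' @export
fit_sigmoid <- function(x, y, offset = FALSE) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  keep <- is.finite(x)
  x <- x[keep]; y <- y[keep]
  if (any(!is.finite(y)))
    stop("non-finite y entries; drop missing bins before fitting",
         call. = FALSE)
  if (length(x) < 4) stop("need at least 4 points to fit", call. = FALSE)
  span <- diff(range(x))
  if (span <= 0) stop("x has zero span", call. = FALSE)
  amax <- 2 * max(abs(y))
  if (amax == 0)  # y identically zero: the degenerate flat fit
    return(structure(list(a = 0, b = mean(range(x)), c = span / 10, d = 0,
                          rss = 0, converged = TRUE),
                     class = "sigmoid_fit"))
  rss_fun <- function(p)
    sum((y - sigmoid_curve(x, p[1], p[2], p[3],
                           if (offset) p[4] else 0))^2)
  ry <- diff(range(y))
  init <- if (offset) c(a = unname(y[which.max(x)] - y[which.min(x)]),
                        b = mean(range(x)), c = span / 10, d = min(y))
          else c(a = max(y), b = mean(range(x)), c = span / 10, d = 0)
  lower <- c(if (offset) -amax else 0, min(x) - span, span * 1e-4,
             min(y) - max(ry, 1e-12))
  upper <- c(amax, max(x) + span, span, max(y) + max(ry, 1e-12))
  npar <- if (offset) 4L else 3L
  # parameters live on very different scales (dF/F amplitudes vs trial
  # numbers); parscale keeps the numerical gradient informative for all
  pscale <- c(max(amax, 1e-6), span, span / 10, max(ry, 1e-6))
  opt <- stats::optim(init[seq_len(npar)], rss_fun, method = "L-BFGS-B",
                      lower = lower[seq_len(npar)],
                      upper = upper[seq_len(npar)],
                      control = list(maxit = 1000, factr = 1e7,
                                     parscale = pscale[seq_len(npar)]))
  structure(list(a = unname(opt$par[1]), b = unname(opt$par[2]),
                 c = unname(opt$par[3]),
                 d = if (offset) unname(opt$par[4]) else 0,
                 rss = opt$value, converged = opt$convergence == 0),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_fit> a = %.4g, b = %.4g, c = %.4g, d = %.4g, rss = %.4g (%s)\n",
    x$a, x$b, x$c, x$d, x$rss,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Learning threshold: first trial at which the fitted curve reaches a
#' performance criterion
#'
#' Closed-form inversion of the sigmoid: the smallest t with S(t) >=
#' criterion is \code{b - c * log(a / (criterion - d) - 1)} (offset d
#' subtracted first). Undefined (NA) when the fitted amplitude never reaches
#' the criterion.
#'
#' @param fit a \code{sigmoid_fit} (must have converged).
#' @param criterion performance level, default d' = 1.
#' @return trial number, or NA when undefined.
#' @export
#' @examples
#' f <- structure(list(a = 4, b = 1000, c = 100, d = 0, converged = TRUE),
#'                class = "sigmoid_fit")
#' learning_threshold(f)  # 1000 - 100*log(3)
learning_threshold <- function(fit, criterion = 1.0) {
  if (!isTRUE(fit$converged)) return(NA_real_)
  eff <- criterion - fit$d
  if (fit$a <= eff || eff <= 0) return(NA_real_)
  fit$b - fit$c * log(fit$a / eff - 1)
}
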