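#' Two-tailed Wilcoxon-Mann-Whitney rank-sum test
#'
#' Compares the medians of two independent samples. The p-value comes from
#' exact enumeration of the permutation distribution of the rank sum when
#' that is feasible (small samples, ties handled exactly), from the exact
#' tie-free Mann-Whitney distribution when the smaller sample has <= 8
#' observations and there are no ties, and otherwise from the normal
#' approximation with mid-ranks, tie-corrected variance and continuity
#' correction.
#'
#' @param a,b nonempty numeric samples.
#' @return list of class \code{test_result}: \code{statistic} (the
#'   Mann-Whitney U of sample a), \code{p}, \code{two_tailed} (TRUE),
#'   \code{n_a}, \code{n_b}, \code{direction} (sign of median(a) -
#'   median(b)), \code{method}.
#' @export
#' @examples
#' rank_sum(c(1, 2, 3), c(4, 5, 6))$p  # 0.1 exactly
rank_sum <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n_a <- length(a); n_b <- length(b)
  if (n_a == 0 || n_b == 0) stop("empty sample", call. = FALSE)
  pooled <- c(a, b)
  r <- rank(pooled, ties.method = "average")
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  n <- n_a + n_b
  if (choose(n, n_a) <= 2e5) {
    # exact conditional enumeration of all label assignments (ties exact)
    combos <- utils::combn(n, n_a)
    us <- colSums(matrix(r[combos], nrow = n_a)) - n_a * (n_a + 1) / 2
    mu <- n_a * n_b / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact enumeration"
  } else if (!ties && min(n_a, n_b) <= 8) {
    p <- min(1, 2 * min(stats::pwilcox(u, n_a, n_b),
                        1 - stats::pwilcox(u - 1, n_a, n_b)))
    method <- "exact Mann-Whitney"
  } else {
    mu <- n_a * n_b / 2
    tie_tab <- table(pooled)
    sigma2 <- n_a * n_b / 12 *
      (n + 1 - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  structure(list(statistic = u, p = p, two_tailed = TRUE, n_a = n_a,
                 n_b = n_b,
                 direction = sign(stats::median(a) - stats::median(b)),
                 method = paste("rank sum,", method)),
            class = "test_result")
}

#' Two-tailed Wilcoxon signed-rank test
#'
#' Compares a paired difference (or a single sample) to zero. Zero
#' differences are dropped. Exact enumeration over all 2^n sign patterns
#' for n <= 14 (ties among |differences| handled exactly), normal
#' approximation with tie-corrected variance and continuity correction
#' otherwise.
#'
#' @param x numeric sample.
#' @param y optional paired sample (same length); the test is on x - y.
#' @return a \code{test_result} (statistic = sum of positive ranks W+;
#'   all-zero differences give p = 1).
#' @export
#' @examples
#' signed_rank(rep(1, 6))$p  # 2/2^6 = 0.03125
signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) stop("paired lengths differ", call. = FALSE)
    x - y
  }
  d <- d[is.finite(d) & d != 0]
  n <- length(d)
  if (n == 0)
    return(structure(list(statistic = 0, p = 1, two_tailed = TRUE,
                          n_a = 0L, n_b = 0L, direction = 0,
                          method = "signed rank, degenerate"),
                     class = "test_result"))
  r <- rank(abs(d), ties.method = "average")
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= 14) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- as.vector(signs %*% r)
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    tie_tab <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  structure(list(statistic = w, p = p, two_tailed = TRUE, n_a = n,
                 n_b = n, direction = sign(stats::median(d)),
                 method = paste("signed rank,", method)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, p = %.4g (n = %d, %d), %s\n",
              x$method, x$statistic, x$p, x$n_a, x$n_b,
              if (x$direction > 0) "a > b" else if (x$direction < 0)
                "a < b" else "no direction"))
  invisible(x)
}

#' Per-mouse choice test: hit vs miss windowed responses
#'
#' Rank-sum test between the hit and miss windowed responses of a learning
#' phase, performed only when both classes reach the minimum trial count
#' (40 in the first cohort, 24 in the second); otherwise "not available".
#'
#' @param session a normalized \code{photometry_session}.
#' @param table the matching \code{trial_table}.
#' @param phase "novice", "expert" or "all".
#' @param min_trials minimum trials per class (default 40).
#' @param window_s response window (default (0, 1]: stimulus presentation).
#' @param n_phase trials per phase.
#' @return a \code{test_result}, or NULL (with attribute-free message) when
#'   a class is below \code{min_trials}.
#' @export
per_mouse_choice_test <- function(session, table,
                                  phase = c("all", "novice", "expert"),
                                  min_trials = 40, window_s = c(0, 1),
                                  n_phase = 500) {
  phase <- match.arg(phase)
  check_aligned(session, table)
  resp <- window_response(session, window_s + c(0, 1e-9))
  in_phase <- phase_trials(table, phase, n_phase)
  hits <- resp[in_phase & table$outcome == "hit"]
  misses <- resp[in_phase & table$outcome == "miss"]
  if (length(hits) < min_trials || length(misses) < min_trials)
    return(NULL)
  rank_sum(hits, misses)
}

#' Bonferroni correction for multiple groups
#'
#' @param p vector of p-values.
#' @return adjusted p-values (never smaller than the input).
#' @export
adjust_p <- function(p) pmin(1, p * length(p))
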