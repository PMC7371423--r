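test_that("outcomes follow the response-window lick rule", {
  tab <- tiny_table()
  # go + window lick, no-go + no lick, go + stimulus-period lick only
  expect_identical(tab$outcome, c("hit", "CR", "miss"))
  # no-go with a window lick is a false alarm
  fa <- trial_table("m", 0L, 1L, 7071, "no-go", list(2.0))
  expect_identical(fa$outcome, "FA")
  expect_error(
    classify_outcomes(data.frame(stimulus_class = "maybe")),
    "unknown stimulus_class")
})

test_that("dprime matches the inverse-normal oracle and clips extremes", {
  # Phi(0.5) = 0.691462...; qnorm is the independent oracle here
  expect_equal(dprime(0.69146, 0.30854, 100, 100), 1.0, tolerance = 1e-3)
  for (p in c(0.2, 0.5, 0.77)) expect_equal(dprime(p, p, 50, 50), 0)
  # extreme rates are clipped to 1/(2n): finite, equal to the oracle value
  expect_equal(dprime(1, 0, 50, 50), qnorm(0.99) - qnorm(0.01))
  expect_error(dprime(1.2, 0.5, 10, 10), "rates")
  expect_error(dprime(0.5, 0.5, 0, 10), "counts")
})

test_that("dprime is monotone in both rates on the interior grid", {
  rates <- seq(0.05, 0.95, length.out = 20)
  g <- outer(rates, rates, function(h, f) dprime(h, f, 100, 100))
  expect_true(all(diff(g) > 0))          # increasing in hit rate (rows)
  expect_true(all(diff(t(g)) < 0))       # decreasing in FA rate (cols)
})

test_that("learning_curve bins correctly and flags degenerate bins", {
  # 100 trials, all correct: both bins at the clipped maximum
  licks <- ifelse(rep(c(TRUE, FALSE), 50), list(1.5), list(numeric(0)))
  tab <- trial_table("m", 0:99, 1, 10000,
                     rep(c("go", "no-go"), 50), licks)
  lc <- learning_curve(tab, bin_size = 50)
  expect_equal(nrow(lc), 2L)
  expect_equal(lc$dprime, rep(qnorm(1 - 1 / 50) - qnorm(1 / 50), 2))
  expect_equal(lc$hit_rate, c(1, 1))
  expect_equal(lc$cr_rate, c(1, 1))

  # 49 trials: no full bin
  short <- trial_table("m", 0:48, 1, 10000, rep("go", 49),
                       replicate(49, numeric(0), simplify = FALSE))
  expect_equal(nrow(learning_curve(short)), 0L)

  # a bin without no-go trials yields NA dprime
  tab2 <- trial_table("m", 0:99, 1, 10000,
                      rep(c("go", "no-go"), each = 50),
                      replicate(100, numeric(0), simplify = FALSE))
  expect_true(is.na(learning_curve(tab2)$dprime[1]))
  expect_equal(learning_curve(tab2)$hit_rate[1], 0)
})

test_that("fit_sigmoid recovers exact and noisy parameters", {
  x <- seq(25, 2000, by = 50)
  y <- sigmoid_curve(x, a = 3, b = 1000, c = 100)
  f <- fit_sigmoid(x, y)
  expect_true(f$converged)
  expect_equal(c(f$a, f$b, f$c), c(3, 1000, 100), tolerance = 1e-4)

  # degenerate flat data
  f0 <- fit_sigmoid(x, rep(0, length(x)))
  expect_equal(f0$a, 0)
  expect_true(is.na(learning_threshold(f0)))

  # scale equivariance: y * k recovers (a * k, b, c)
  fk <- fit_sigmoid(x, y * 2.5)
  expect_equal(c(fk$a, fk$b, fk$c), c(7.5, 1000, 100), tolerance = 1e-3)

  expect_error(fit_sigmoid(x[1:3], y[1:3]), "at least 4")
  expect_error(fit_sigmoid(x, replace(y, 3, NA)), "non-finite")
})

test_that("fit_sigmoid is deterministic and handles offsets", {
  x <- seq(25, 1800, by = 50)
  set.seed(5)
  y <- 0.06 + sigmoid_curve(x, 0.05, 900, 120) + rnorm(length(x), sd = 0.005)
  f1 <- fit_sigmoid(x, y, offset = TRUE)
  f2 <- fit_sigmoid(x, y, offset = TRUE)
  expect_identical(f1, f2)
  expect_equal(f1$b, 900, tolerance = 0.1)  # relative to the 1800 span
  expect_equal(f1$d, 0.06, tolerance = 0.1)
})

test_that("learning_threshold inverts the sigmoid in closed form", {
  mk <- function(a, b, c) structure(list(a = a, b = b, c = c, d = 0,
                                         converged = TRUE),
                                    class = "sigmoid_fit")
  expect_equal(learning_threshold(mk(2, 1000, 100)), 1000)
  expect_equal(learning_threshold(mk(4, 1000, 100)),
               1000 - 100 * log(3), tolerance = 1e-6)
  expect_true(is.na(learning_threshold(mk(0.9, 1000, 100))))
})

test_that("threshold ordering across mice is criterion-invariant", {
  # amplitudes all exceed 1.2: orderings agree over criteria in [0.8, 1.2]
  fits <- list(
    structure(list(a = 2.6, b = 700, c = 90, d = 0, converged = TRUE),
              class = "sigmoid_fit"),
    structure(list(a = 1.9, b = 950, c = 140, d = 0, converged = TRUE),
              class = "sigmoid_fit"),
    structure(list(a = 3.1, b = 1200, c = 70, d = 0, converged = TRUE),
              class = "sigmoid_fit"))
  orders <- sapply(seq(0.8, 1.2, by = 0.1), function(cr)
    order(sapply(fits, learning_threshold, criterion = cr)))
  expect_true(all(apply(orders, 1, function(r) length(unique(r)) == 1)))
})
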