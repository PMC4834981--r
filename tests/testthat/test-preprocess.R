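test_that("filter_params validates window length and tolerance", {
  expect_error(filter_params(l = 40), "odd")
  expect_error(filter_params(l = 1), "odd|>= 3")
  expect_error(filter_params(a = 0), "0 < a")
  expect_error(filter_params(a = 1.2), "0 < a")
  p <- filter_params()
  expect_identical(p$l, 41L)
  expect_equal(p$a, 0.2)
})

test_that("constant series passes untouched; lone spike is excluded", {
  x <- rep(0.8, 100)
  f <- filter_rr(rr_series(x))
  expect_identical(f$filter_report$n_excluded, 0L)
  expect_equal(f$values, x)

  # spike at 1.6 s: window mean excluding center is 0.8, 1.6 > 1.2 * 0.8
  x[51] <- 1.6
  f <- filter_rr(rr_series(x))
  expect_identical(f$filter_report$excluded_indices, 51L)
  expect_equal(f$values, x[-51])

  # 0.9 s stays: 0.9 <= 1.2 * 0.8
  x[51] <- 0.9
  f <- filter_rr(rr_series(x))
  expect_identical(f$filter_report$n_excluded, 0L)
})

test_that("filter matches the per-index brute-force criterion on noisy data", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- 0.8 + rnorm(300, sd = 0.05)
    x[sample(300, 6)] <- x[sample(300, 6)] * sample(c(0.4, 1.7), 6, replace = TRUE)
    x <- pmax(x, 0.1)
    f <- filter_rr(rr_series(x), filter_params(l = 41, a = 0.2))
    expect_identical(f$filter_report$excluded_indices,
                     brute_filter_excluded(x, 41L, 0.2))
  }
})

test_that("output length + n_excluded = input length; scale invariance", {
  s <- synth_rr_like(2000, seed = 9, ectopy_rate = 0.02)
  f <- filter_rr(s$series)
  expect_identical(length(f$values) + f$filter_report$n_excluded, 2000L)

  f2 <- filter_rr(rr_series(s$series$values * 3.7))
  expect_identical(f2$filter_report$excluded_indices,
                   f$filter_report$excluded_indices)

  # filtering an already-clean series is the identity
  f3 <- filter_rr(f)
  expect_identical(f3$filter_report$n_excluded, 0L)
})

test_that("edge policies and short-series fallback behave as documented", {
  x <- rep(0.8, 60); x[2] <- 2; x[59] <- 2
  fk <- filter_rr(rr_series(x), edges = "keep")
  expect_identical(fk$filter_report$excluded_indices, integer(0))
  ft <- filter_rr(rr_series(x), edges = "truncated")
  expect_identical(ft$filter_report$excluded_indices, c(2L, 59L))

  # shorter than l: truncated evaluation still works, keep errors
  y <- c(rep(0.8, 30), 2, rep(0.8, 5))
  expect_error(filter_rr(rr_series(y), edges = "keep"), "full window")
  expect_error(filter_rr(rr_series(c(0.8, 0.8))), ">= 3")
})

test_that("iterated filtering removes points unmasked by earlier passes", {
  # with a short window a large artifact masks nearby beats on the first
  # pass; iterated passes must match the brute-force repeat-until-stable
  # oracle and strictly extend the single-pass exclusion set here
  brute_iterate <- function(x, l, a) {
    idx <- seq_along(x); out <- integer(0)
    repeat {
      d <- brute_filter_excluded(x, l, a)
      if (length(d) == 0L || length(x) < 3L) break
      out <- c(out, idx[d]); x <- x[-d]; idx <- idx[-d]
    }
    sort(out)
  }
  x <- rep(0.8, 100)
  x[50] <- 1.63; x[51] <- 1.15
  f1 <- filter_rr(rr_series(x), filter_params(l = 5, a = 0.2))
  f2 <- filter_rr(rr_series(x), filter_params(l = 5, a = 0.2), iterate = TRUE)
  expect_identical(f1$filter_report$excluded_indices,
                   brute_filter_excluded(x, 5L, 0.2))
  expect_identical(f2$filter_report$excluded_indices, brute_iterate(x, 5L, 0.2))
  expect_gt(f2$filter_report$n_excluded, f1$filter_report$n_excluded)
  expect_identical(filter_rr(f2, filter_params(l = 5, a = 0.2))$filter_report$n_excluded, 0L)
})
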