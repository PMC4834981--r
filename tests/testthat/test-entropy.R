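test_that("tolerance resolution follows the declared conventions", {
  ref <- c(0.72, 0.8, 0.88)                      # SD = 0.08
  p <- resolve_r(ref, entropy_params(r_value = 0.5, r_mode = "percent_of_sd"))
  expect_equal(p$resolved_r, 0.0004)
  p2 <- resolve_r(NULL, entropy_params(r_value = 2e-4, r_mode = "fixed_absolute"))
  expect_equal(p2$resolved_r, 2e-4)
  p3 <- resolve_r(ref * 10, entropy_params(r_value = 10,
                                           r_mode = "percent_of_reference_series"))
  expect_equal(p3$resolved_r, 0.08)
  expect_error(resolve_r(rep(1, 50), entropy_params(r_value = 0.5)),
               "resolves to zero")
})

test_that("constant and periodic signals have zero sample entropy", {
  e <- sample_entropy(rep(0.7, 50), m = 2, r = 0.01)
  expect_equal(e$value, 0)
  expect_equal(e$matches_m1, e$matches_m)

  e2 <- sample_entropy(rep(c(0.5, 1), 25), m = 2, r = 0.3)
  expect_equal(e2$value, 0)
})

test_that("optimized kernel equals the O(N^2) brute-force oracle exactly", {
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(30:120, 1)
    m <- sample(1:3, 1)
    x <- rnorm(n)
    r <- runif(1, 0.05, 0.8)
    est <- sample_entropy(x, m, r)
    oracle <- brute_sampen_counts(x, m, r)
    expect_identical(est$matches_m, as.numeric(oracle$B))
    expect_identical(est$matches_m1, as.numeric(oracle$A))
    expect_equal(est$value, oracle$value)
  }
})

test_that("undefined entropy is flagged, not raised", {
  # widely spaced values, tiny tolerance: no matches at all
  e <- sample_entropy(c(1, 10, 100, 1000, 1e4, 1e5), m = 2, r = 1e-6)
  expect_false(e$defined)
  expect_true(is.na(e$value))
  q <- quadratic_sample_entropy(c(1, 10, 100, 1000, 1e4, 1e5), m = 2, r = 1e-6)
  expect_true(is.na(q$value))
})

test_that("sample entropy is non-increasing in r and affine-invariant", {
  set.seed(17)
  x <- rnorm(400)
  vals <- vapply(c(0.1, 0.2, 0.4, 0.8, 1.6),
                 function(r) sample_entropy(x, 2, r)$value, numeric(1))
  expect_true(all(diff(vals) <= 0))

  e <- sample_entropy(x, 2, 0.25)
  shift <- sample_entropy(x + 5.3, 2, 0.25)
  expect_identical(shift$matches_m, e$matches_m)
  expect_identical(shift$matches_m1, e$matches_m1)
  scaled <- sample_entropy(x * 2.5, 2, 0.25 * 2.5)
  expect_equal(scaled$value, e$value)
})

test_that("i.i.d. Gaussian sample entropy approaches the closed form", {
  sigma <- 1; r <- 0.2
  closed <- -log(2 * pnorm(r / (sigma * sqrt(2))) - 1)
  vals <- vapply(1:4, function(s)
    sample_entropy(synth_white(3e4, sd = sigma, seed = 100 + s), 2, r)$value,
    numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - closed), 4 * se + 0.01)
})

test_that("quadratic sample entropy is SampEn + ln(2r)", {
  expect_equal(quadratic_sample_entropy(rep(0.8, 40), 2, r = 0.5)$value, 0)
  set.seed(23)
  x <- rnorm(300)
  s <- sample_entropy(x, 2, 0.1)$value
  expect_equal(quadratic_sample_entropy(x, 2, 0.1)$value, s + log(0.2))
})

test_that("entropy preconditions are enforced", {
  expect_error(sample_entropy(rnorm(3), m = 2, r = 0.2), "too short")
  expect_error(sample_entropy(c(1, 2, NA, 4, 5), m = 2, r = 0.2), "finite")
  expect_error(sample_entropy(rnorm(50), m = 2, r = 0), "positive")
  expect_error(sample_entropy(rnorm(50), m = 0, r = 0.2), "positive integer")
})
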