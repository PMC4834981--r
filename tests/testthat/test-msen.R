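test_that("variance curve of a constant series is identically zero", {
  curve <- mse_curve(rr_series(rep(0.8, 2000)), moment = "variance",
                     scales = 10:20,
                     params = entropy_params(r_mode = "fixed_absolute",
                                             r_value = 1e-4))
  df <- as.data.frame(curve)
  expect_true(all(df$defined))
  expect_true(all(df$entropy == 0))
})

test_that("orchestration equals a step-by-step coarse-grain + entropy pipeline", {
  x <- synth_white(2e4, seed = 41)
  params <- entropy_params(m = 2, r_value = 0.5, r_mode = "percent_of_sd")
  curve <- mse_curve(x, moment = "variance", scales = c(10:15, 40L, 100L)[1:7],
                     params = params)
  r <- resolve_r(x, params)$resolved_r
  for (tau in curve$scales) {
    cg <- coarse_grain(x, tau, "variance")
    manual <- sample_entropy(cg$values, m = 2, r = r)
    got <- curve$entries[[as.character(tau)]]
    expect_identical(got$value, manual$value)
    expect_identical(got$matches_m, manual$matches_m)
    expect_identical(got$r, r)
  }
})

test_that("curve preconditions: moment minima, feasibility, strictly increasing scales", {
  expect_error(mse_curve(rnorm(100), moment = "variance", scales = 1:5),
               "scales >= 2")
  expect_error(mse_curve(rnorm(100), moment = "variance", scales = c(10, 10, 11)),
               "strictly increasing")
  err <- tryCatch(mse_curve(rnorm(300), moment = "variance", scales = 10:100),
                  error = conditionMessage)
  expect_match(err, "maximum feasible scale is 75")
  expect_warning(mse_curve(rnorm(900), moment = "variance", scales = 10:11,
                           params = entropy_params(r_value = 0.5)),
                 "fewer than 100")
})

test_that("the resolved tolerance is shared across scales unless r_per_scale", {
  x <- synth_volatility_rr(4000, driver = "iid", seed = 6)
  curve <- suppressWarnings(mse_curve(x, moment = "variance", scales = 10:15))
  rs <- vapply(curve$entries, `[[`, numeric(1), "r")
  expect_true(all(rs == curve$params$resolved_r))
  expect_equal(curve$params$resolved_r, 0.005 * sd(x$values))

  pv <- suppressWarnings(mse_curve(x, moment = "variance", scales = 10:15,
                                   r_per_scale = TRUE))
  rs2 <- vapply(pv$entries, `[[`, numeric(1), "r")
  expect_true(length(unique(rs2)) > 1L)
})

test_that("complexity index sums inclusive ranges and is additive", {
  x <- synth_volatility_rr(6000, driver = "one_over_f", seed = 2)
  curve <- suppressWarnings(mse_curve(x, moment = "variance", scales = 10:60))
  df <- as.data.frame(curve)
  expect_true(all(df$defined))

  full <- complexity_index(curve, 10, 60)
  expect_equal(full$value, sum(df$entropy))
  expect_identical(full$n_defined, 51L)

  a <- complexity_index(curve, 10, 30)$value
  b <- complexity_index(curve, 31, 60)$value
  expect_equal(a + b, full$value)
})

test_that("index policies: strict errors on undefined/missing, skip reports them", {
  x <- synth_white(900, seed = 3)
  curve <- suppressWarnings(
    mse_curve(x, moment = "variance", scales = 10:20,
              params = entropy_params(r_mode = "fixed_absolute",
                                      r_value = 1e-9)))
  # tiny absolute tolerance: no matches anywhere
  expect_error(complexity_index(curve, policy = "strict"), "undefined")
  ci <- complexity_index(curve, policy = "skip_undefined")
  expect_identical(ci$n_defined + length(ci$undefined_scales), 11L)

  good <- suppressWarnings(mse_curve(x, moment = "variance", scales = 10:20,
                                     params = entropy_params(r_value = 0.5)))
  expect_error(complexity_index(good, 10, 57), "57")
})

test_that("mse_curve is invariant under adding a constant to the series", {
  x <- synth_white(5000, sd = 0.05, seed = 12) + 0.8
  c1 <- as.data.frame(mse_curve(x, moment = "variance", scales = 10:14,
                                params = entropy_params(r_value = 0.5)))
  c2 <- as.data.frame(mse_curve(x + 2.5, moment = "variance", scales = 10:14,
                                params = entropy_params(r_value = 0.5)))
  expect_equal(c1$entropy, c2$entropy)
  m1 <- as.data.frame(mse_curve(x, moment = "mean", scales = 1:5,
                                params = entropy_params(r_value = 15)))
  m2 <- as.data.frame(mse_curve(x + 2.5, moment = "mean", scales = 1:5,
                                params = entropy_params(r_value = 15)))
  expect_equal(m1$entropy, m2$entropy)
})
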