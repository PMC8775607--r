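test_that("constructors reject malformed specifications, naming the field", {
  expect_error(dist_triangular(5, 3, 9), "min <= mode <= max")
  expect_error(dist_mixture(c(0.5, 0.6),
                            list(dist_deterministic(1), dist_deterministic(2))),
               "weights")
  expect_error(dist_mixture(c(-0.5, 1.5),
                            list(dist_deterministic(1), dist_deterministic(2))),
               "positive")
  expect_error(dist_empirical(c(5, 4), c(0.5, 1)), "increasing")
  expect_error(dist_empirical(c(1, 2), c(0.2, 0.9)), "rise to exactly 1")
  expect_error(dist_exponential(-3), "positive")
})

test_that("sampling is reproducible per (seed, stream) and streams are independent", {
  spec <- dist_triangular(1, 5, 9)
  a <- sample_dist(spec, 50, rand_stream(11, "setup"))
  b <- sample_dist(spec, 50, rand_stream(11, "setup"))
  expect_identical(a, b)
  c <- sample_dist(spec, 50, rand_stream(11, "service"))
  expect_false(any(a == c))
  d <- sample_dist(spec, 50, rand_stream(12, "setup"))
  expect_false(any(a == d))
  # a stream advances across calls and matches one big draw
  s1 <- rand_stream(3, "x")
  two <- c(sample_dist(spec, 25, s1), sample_dist(spec, 25, s1))
  expect_identical(two, sample_dist(spec, 50, rand_stream(3, "x")))
})

test_that("draws respect the lower support bound for every kind", {
  specs <- list(
    dist_triangular(1, 5, 9),
    dist_beta_scaled(3, 7, 1.9, 1.16),
    dist_weibull_scaled(10, 3.46, 1.23),
    dist_exponential(6),
    dist_deterministic(20),
    dist_empirical(c(5, 10, 30), c(0, 0.6, 1)),
    prostate_service_spec()
  )
  for (i in seq_along(specs)) {
    lo <- dist_quantile(specs[[i]], 0)
    x <- sample_dist(specs[[i]], 2000, rand_stream(i, "support"))
    expect_true(all(is.finite(x)))
    expect_gte(min(x), lo - 1e-9)
  }
})

test_that("deterministic and triangular sampling match their closed forms", {
  expect_identical(sample_dist(dist_deterministic(20), 5, rand_stream(1, "d")),
                   rep(20, 5))
  x <- sample_dist(dist_triangular(1, 5, 9), 1e5, rand_stream(2, "tri"))
  expect_equal(mean(x), 5, tolerance = 0.05 / 5)
  expect_true(all(x >= 1 & x <= 9))
})

test_that("analytic means agree with Monte-Carlo means for every kind", {
  specs <- list(
    tri = dist_triangular(1, 5, 9),
    beta = dist_beta_scaled(3, 7, 1.9, 1.16),
    weib = dist_weibull_scaled(10, 3.46, 1.23),
    expo = dist_exponential(24),
    emp = dist_empirical(c(5, 10, 15, 20, 30), c(0, 0.25, 0.55, 0.8, 1)),
    mix = prostate_service_spec()
  )
  n <- 1e5
  for (nm in names(specs)) {
    x <- sample_dist(specs[[nm]], n, rand_stream(7, paste0("mc_", nm)))
    se <- sd(x) / sqrt(n)
    expect_lt(abs(mean(x) - dist_mean(specs[[nm]])), 3 * se)
  }
})

test_that("the fitted prostate mixture keeps its support and component weights", {
  spec <- prostate_service_spec()
  x <- sample_dist(spec, 1e5, rand_stream(5, "prostate"))
  expect_gte(min(x), 3)
  # the first component (weight 0.485) is exactly the mass on [3, 10]
  frac <- mean(x >= 3 & x <= 10)
  expect_lt(abs(frac - 0.485), 3 * sqrt(0.485 * 0.515 / 1e5))
  # third component starts at 20: at least its weight lies above 20
  expect_gte(mean(x > 20), 0.091 - 3 * sqrt(0.091 * 0.909 / 1e5))
})

test_that("mixture component frequencies follow the weights", {
  spec <- dist_mixture(c(0.3, 0.7),
                       list(dist_deterministic(1), dist_deterministic(2)))
  x <- sample_dist(spec, 1e5, rand_stream(9, "mixfreq"))
  expect_lt(abs(mean(x == 1) - 0.3), 3 * sqrt(0.3 * 0.7 / 1e5))
})

test_that("the exact CDF integrates the quantile function correctly", {
  specs <- list(dist_triangular(1, 5, 9), prostate_service_spec(),
                dist_empirical(c(5, 10, 30), c(0, 0.6, 1)))
  for (spec in specs) {
    p <- c(0.1, 0.25, 0.5, 0.9)
    q <- dist_quantile(spec, p)
    expect_equal(dist_cdf(spec, q), p, tolerance = 1e-6)
  }
})

test_that("ks_check accepts the true law at roughly the nominal rate", {
  spec <- dist_triangular(1, 5, 9)
  passes <- vapply(1:200, function(s) {
    x <- sample_dist(spec, 1000, rand_stream(s, "ksnull"))
    ks_check(x, spec, alpha = 0.05)$pass
  }, TRUE)
  expect_gt(mean(passes), 0.88)
  expect_lte(mean(passes), 1)
})

test_that("ks_check rejects a disjoint law and aligns on exact quantiles", {
  x <- sample_dist(dist_deterministic(20), 1000, rand_stream(1, "ksalt"))
  expect_false(ks_check(x, dist_triangular(1, 5, 9))$pass)

  spec <- dist_triangular(1, 5, 9)
  n <- 200
  q <- dist_quantile(spec, seq_len(n) / (n + 1))
  expect_lte(ks_check(q, spec)$statistic, 2 / n + 1e-9)

  expect_error(ks_check(numeric(0), spec), "empty")
  expect_error(ks_check(1:5, spec), "at least 20")
})

test_that("draw_stream leaves the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(sample_dist(dist_exponential(5), 10, rand_stream(4, "side")))
  expect_identical(before, .Random.seed)
})
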