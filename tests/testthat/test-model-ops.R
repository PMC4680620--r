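test_that("the access operation adds exactly the specified noise", {
  v <- seq(0, 1, length.out = 11L)
  expect_identical(accessSignal(v, eta0 = 0), v)
  expect_identical(accessSignal(v, 2, seed = 1), accessSignal(v, 2, seed = 1))
  expect_error(accessSignal(v, -1), "non-negative")
  out <- accessSignal(rep(0.5, 100000L), eta0 = 2, seed = 2)
  expect_lt(abs(sd(out) - 2), 3 * sdStderr(2, 100000L))
})

test_that("linear amplification scales values, means and SDs", {
  expect_identical(amplifyLinear(c(0.2, 5), 1), c(0.2, 5))
  expect_equal(amplifyLinear(0.2, 3), 0.6)
  set.seed(3)
  v <- rnorm(1000, 2, 0.5)
  expect_equal(mean(amplifyLinear(v, 7)), 7 * mean(v))
  expect_equal(sd(amplifyLinear(v, 7)), 7 * sd(v))
  expect_error(amplifyLinear(v, 0), "positive")
})

test_that("the zigzag map folds the dynamic range as a triangle wave", {
  v <- seq(0, 1, by = 0.01)
  expect_equal(amplifyZigzag(v, 1, 1), v)                 # identity fold
  expect_equal(amplifyZigzag(c(1/3, 1/2, 2/3), 3, 1), c(1, 0.5, 0))
  out <- amplifyZigzag(v, 3, 1)
  expect_true(all(out >= 0 & out <= 1))
  # |slope| is gain away from the fold points
  x <- seq(0.01, 0.32, by = 0.001)
  slope <- diff(amplifyZigzag(x, 3, 1)) / diff(x)
  expect_equal(unname(slope), rep(3, length(slope)), tolerance = 1e-8)
  x2 <- seq(0.35, 0.65, by = 0.001)
  expect_equal(mean(abs(diff(amplifyZigzag(x2, 3, 1)) / diff(x2))), 3,
               tolerance = 1e-8)
  # out-of-range inputs are clamped
  expect_equal(amplifyZigzag(c(-0.5, 1.7), 2, 1), c(0, 0))
  expect_error(amplifyZigzag(v, 2.5, 1), "integer")
})

test_that("averaging contracts fluctuations by sqrt(nEff)", {
  mkSample <- function() rnorm(100000L, 5, 1)
  set.seed(4)
  one <- averageRealizations(mkSample, 1)
  expect_lt(abs(sd(one) - 1), 3 * sdStderr(1, 1e5))
  four <- averageRealizations(mkSample, 4)
  expect_lt(abs(sd(four) - 0.5), 3 * sdStderr(0.5, 1e5))
  expect_lt(abs(mean(four) - 5), 4 * 0.5 / sqrt(1e5))
  # real-valued nEff rescales the fluctuation about the supplied mean
  frac <- averageRealizations(mkSample, 2.5, meanValues = 5)
  expect_lt(abs(sd(frac) - 1 / sqrt(2.5)), 3 * sdStderr(1 / sqrt(2.5), 1e5))
  expect_error(averageRealizations(mkSample, 0.5), ">= 1")
  expect_error(averageRealizations(mkSample, 2.5), "meanValues")
})

test_that("simulated strategies match their closed-form noise", {
  gr <- GradientSpec(cMax = 1, sigma0 = 1, nCells = 100000L)
  # direct: sigma0 / sqrt(nEff)
  d <- simulateStrategy(StrategyParams(gr, ReadoutSpec(nEff = 4),
                                       "direct"), seed = 5)
  expect_lt(abs(sd(d@values - d@spec$mean) - 0.5), 3 * sdStderr(0.5, 1e5))
  # two-tier: gain * sqrt((sigma0^2 + eta0^2) / nEff) = 2 here
  t2 <- simulateStrategy(
    StrategyParams(gr, ReadoutSpec(eta0 = 1, gain = 2, nEff = 2),
                   "two_tier"), seed = 6)
  expect_lt(abs(sd(t2@values - t2@spec$mean) - 2), 3 * sdStderr(2, 1e5))
  # eta0 = 0, gain = 1 collapses onto the direct strategy
  t0 <- simulateStrategy(
    StrategyParams(gr, ReadoutSpec(eta0 = 0, gain = 1, nEff = 4),
                   "two_tier"), seed = 7)
  expect_equal(t0@spec$mean, d@spec$mean)
  expect_equal(t0@spec$sd, d@spec$sd)
  expect_lt(abs(sd(t0@values - t0@spec$mean) - 0.5), 3 * sdStderr(0.5, 1e5))
})

test_that("the noise-ratio identity holds across a parameter grid", {
  grid <- expand.grid(sigma0 = c(0.5, 1), eta0 = c(0.5, 1.5),
                      nEff = c(2, 4), gain = c(2, 3))
  for (i in seq_len(nrow(grid))) {
    p <- grid[i, ]
    gr <- GradientSpec(cMax = 1, sigma0 = p$sigma0, nCells = 20000L)
    sim <- simulateStrategy(
      StrategyParams(gr, ReadoutSpec(eta0 = p$eta0, gain = p$gain,
                                     nEff = p$nEff), "two_tier"))
    ratio2 <- var(sim@values - sim@spec$mean) / p$sigma0^2
    theory <- (p$gain^2 / p$nEff) * (1 + p$eta0^2 / p$sigma0^2)
    # relative SE of a variance estimate is sqrt(2/n)
    expect_lt(abs(ratio2 / theory - 1), 3 * sqrt(2 / 20000))
  }
})

test_that("zigzag and linear amplification add identical per-cell noise", {
  # away from fold points the zigzag map is locally linear with |slope| gain
  gr <- GradientSpec(cMax = 1, sigma0 = 0.005, nCells = 50000L)
  rd <- ReadoutSpec(eta0 = 0.005, gain = 3, shape = "zigzag", nEff = 1)
  set.seed(8)
  zz <- simulateStrategy(StrategyParams(gr, rd, "two_tier"))
  folds <- (0:3) / 3
  nearFold <- vapply(zz@positions, function(x)
    min(abs(x - folds)) < 3 * sqrt(2) * 0.005, logical(1))
  eps <- (zz@values - zz@spec$mean)[!nearFold]
  theory <- 3 * sqrt(0.005^2 + 0.005^2)
  expect_lt(abs(sd(eps) - theory), 3 * sdStderr(theory, sum(!nearFold)))
})
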