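test_that("noiseless gradients lie exactly on the mean line", {
  r <- sampleGradient(GradientSpec(L = 1, cMax = 6, sigma0 = 0, nCells = 3L))
  expect_equal(r@positions, c(0, 0.5, 1))
  expect_equal(r@values, c(0, 3, 6))
})

test_that("gradient sampling is reproducible under a fixed seed", {
  spec <- GradientSpec(sigma0 = 0.3, nCells = 50L)
  r1 <- sampleGradient(spec, seed = 42)
  r2 <- sampleGradient(spec, seed = 42)
  expect_identical(r1@values, r2@values)
})

test_that("gradient noise has the specified magnitude and is independent", {
  spec <- GradientSpec(cMax = 5, sigma0 = 1, nCells = 100000L)
  r <- sampleGradient(spec, seed = 1)
  eps <- r@values - gradientMean(spec)
  expect_lt(abs(sd(eps) - 1), 3 * sdStderr(1, spec@nCells))
  # fluctuations of adjacent cells are uncorrelated
  rho <- cor(eps[-1], eps[-length(eps)])
  expect_lt(abs(rho), 3 / sqrt(spec@nCells))
})

test_that("the ensemble mean converges to the linear profile", {
  spec <- GradientSpec(cMax = 2, sigma0 = 0.5, nCells = 20L)
  set.seed(7)
  draws <- vapply(seq_len(2000L), function(i) sampleGradient(spec)@values,
                  numeric(spec@nCells))
  avg <- rowMeans(draws)
  # 4 SE bound on the worst of the 20 per-cell averages
  expect_lt(max(abs(avg - gradientMean(spec))),
            4 * spec@sigma0 / sqrt(ncol(draws)))
})

test_that("invalid gradient parameters are rejected", {
  expect_error(GradientSpec(L = -1), "positive")
  expect_error(GradientSpec(cMax = 0), "positive")
  expect_error(GradientSpec(sigma0 = -0.1), "non-negative")
  expect_error(GradientSpec(nCells = 1L), ">= 2")
})
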