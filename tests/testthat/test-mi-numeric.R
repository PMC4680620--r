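# The Monte-Carlo estimator is validated against an independent quadrature
# oracle (helper-oracle.R) and against the closed forms in their small-noise
# regime.

test_that("miNumeric matches exact quadrature for a linear channel", {
  for (phi in c(20, 200)) {
    exact <- oracleLinearChannelMI(1, 1 / phi)
    mi <- miNumeric(profileSet(linearProfile(cMax = 1, sigma = 1 / phi)),
                    nMC = 8000L, seed = phi)
    expect_lt(abs(valueNats(mi) - exact), 3 * mcStderr(mi))
  }
})

test_that("miNumeric agrees with the small-noise closed form at high phi", {
  mi <- miNumeric(profileSet(linearProfile(cMax = 1, sigma = 1 / 300)),
                  nMC = 12000L, seed = 1)
  expect_lt(abs(valueNats(mi) - valueNats(infoPhi(300))),
            3 * mcStderr(mi) + 1.81 / 300)
})

test_that("two noisy copies equal one channel with sd/sqrt(2)", {
  # Gaussian sufficiency: duplicated means with independent noise sigma are
  # informationally identical to a single channel with sigma / sqrt(2)
  sig <- 1 / 80
  pair <- profileSet(linearProfile(sigma = sig, gene = "a"),
                     linearProfile(sigma = sig, gene = "b"))
  single <- profileSet(linearProfile(sigma = sig / sqrt(2)))
  m2 <- miNumeric(pair, nMC = 8000L, seed = 2)
  m1 <- miNumeric(single, nMC = 8000L, seed = 3)
  expect_lt(abs(valueNats(m2) - valueNats(m1)),
            3 * sqrt(mcStderr(m1)^2 + mcStderr(m2)^2))
})

test_that("a processed tier cannot beat nEff copies of its input", {
  # two-tier output with nEff = 2 vs the joint information of two
  # independent input copies
  sigma0 <- 0.02; eta0 <- 0.02; gain <- 4; nEff <- 2
  xi <- gain * sqrt((sigma0^2 + eta0^2) / nEff)
  tier <- miNumeric(profileSet(linearProfile(cMax = gain, sigma = xi)),
                    nMC = 8000L, seed = 4)
  copies <- miNumeric(profileSet(linearProfile(sigma = sigma0, gene = "a"),
                                 linearProfile(sigma = sigma0, gene = "b")),
                      nMC = 8000L, seed = 5)
  expect_lt(valueNats(tier),
            valueNats(copies) +
              3 * sqrt(mcStderr(tier)^2 + mcStderr(copies)^2))
})

test_that("degenerate noiseless channels are rejected with guidance", {
  ps <- profileSet(ExpressionProfile("flatnoise", function(x) x,
                                     function(x) rep(0, length(x))))
  expect_error(miNumeric(ps, nMC = 100L), "eta0 > 0")
  # but adding readout noise regularizes them
  expect_s4_class(miNumeric(ps, eta0 = 0.05, nMC = 500L, seed = 1),
                  "InfoResult")
})

test_that("miNumeric is deterministic under a fixed seed", {
  ps <- profileSet(linearProfile(sigma = 0.05))
  a <- miNumeric(ps, nMC = 1000L, seed = 9)
  b <- miNumeric(ps, nMC = 1000L, seed = 9)
  expect_identical(valueNats(a), valueNats(b))
  expect_gt(mcStderr(a), 0)
})
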