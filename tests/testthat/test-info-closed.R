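test_that("infoPhi has its closed-form anchor points and units", {
  expect_equal(valueNats(infoPhi(sqrt(2 * pi * exp(1)))), 0)
  expect_equal(valueNats(infoPhi(exp(1) * sqrt(2 * pi * exp(1)))), 1)
  r <- infoPhi(100)
  expect_equal(valueBits(r), valueNats(r) / log(2))
  expect_identical(infoMethod(r), "closed_form")
  expect_identical(mcStderr(r), 0)
  expect_error(infoPhi(0), "positive")
  expect_error(infoPhi(-3), "positive")
})

test_that("raw information responds to averaging as a log law", {
  expect_equal(valueNats(rawInfoDirect(1, 0.05, nEff = 1)),
               valueNats(infoPhi(20)))
  # doubling nEff adds half a log-2
  expect_equal(valueNats(rawInfoDirect(1, 0.05, nEff = 8)) -
                 valueNats(rawInfoDirect(1, 0.05, nEff = 4)),
               0.5 * log(2))
})

test_that("the amplification factor cancels out of two-tier raw info", {
  vals <- vapply(c(1, 2, 4, 8), function(l)
    valueNats(rawInfoTwoTier(1, 0.05, 0.02, nEff = 4, gain = l)),
    numeric(1))
  expect_identical(max(vals) - min(vals), 0)
  # and the extra tier always costs raw information when eta0 > 0
  expect_lt(vals[1], valueNats(rawInfoDirect(1, 0.05, nEff = 4)))
  expect_equal(valueNats(rawInfoTwoTier(1, 0.05, 0, nEff = 4)),
               valueNats(rawInfoDirect(1, 0.05, nEff = 4)))
})

test_that("accessible information has the right limits", {
  # no readout noise: accessible = raw
  expect_equal(valueNats(accInfoDirect(1, 0.05, 0, nEff = 4)),
               valueNats(rawInfoDirect(1, 0.05, nEff = 4)))
  # infinite averaging leaves only the readout noise
  expect_equal(valueNats(accInfoDirect(1, 0.05, 0.02, nEff = 1e12)),
               valueNats(infoPhi(1 / 0.02)), tolerance = 1e-6)
  # infinite gain recovers the two-tier raw information
  expect_equal(valueNats(accInfoTwoTier(1, 0.05, 0.02, nEff = 4, gain = 1e7)),
               valueNats(rawInfoTwoTier(1, 0.05, 0.02, nEff = 4)),
               tolerance = 1e-9)
  # with no averaging and no amplification the second tier only hurts
  expect_lt(valueNats(accInfoTwoTier(1, 0.05, 0.02, nEff = 1, gain = 1)),
            valueNats(accInfoDirect(1, 0.05, 0.02, nEff = 1)))
  # monotone in gain when eta0 > 0
  g <- c(1, 1.5, 2, 4, 8, 32)
  v <- vapply(g, function(l)
    valueNats(accInfoTwoTier(1, 0.05, 0.02, nEff = 4, gain = l)), numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("the benefit condition matches the closed-form comparison", {
  expect_false(benefitCondition(1, nEff = 1, gain = 8)$beneficial)
  expect_false(benefitCondition(1, nEff = 64, gain = 1)$beneficial)
  bc <- benefitCondition(1, nEff = 4, gain = 2)
  expect_equal(bc$margin, 0.5)
  expect_true(bc$beneficial)
  expect_gt(valueNats(accInfoTwoTier(1, 0.3, 1, nEff = 4, gain = 2)),
            valueNats(accInfoDirect(1, 0.3, 1, nEff = 4)))

  # sign identity across a broad grid, including zero-margin points
  grid <- expand.grid(sigma0 = c(0.02, 0.1, 0.5), eta0 = c(0, 0.05, 0.3, 1),
                      nEff = c(1, 2, 4, 16), gain = c(1, 2, 3, 8))
  for (i in seq_len(nrow(grid))) {
    p <- grid[i, ]
    margin <- benefitCondition(p$eta0, p$nEff, p$gain)$margin
    delta <- valueNats(accInfoTwoTier(1, p$sigma0, p$eta0, p$nEff, p$gain)) -
      valueNats(accInfoDirect(1, p$sigma0, p$eta0, p$nEff))
    expect_equal(sign(margin), sign(round(delta, 12)))
  }
})

test_that("a zigzag fold costs exactly log(gain) nats", {
  base <- infoPhi(100)
  expect_equal(valueNats(zigzagInfo(base, 1)), valueNats(base))
  expect_equal(valueNats(zigzagInfo(base, 3)), valueNats(base) - log(3))
  # applies identically to accessible quantities
  acc <- accInfoTwoTier(1, 0.05, 0.02, nEff = 4, gain = 3)
  expect_equal(valueNats(zigzagInfo(acc, 3)), valueNats(acc) - log(3))
  expect_error(zigzagInfo(base, 2.5), "integer")
})
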