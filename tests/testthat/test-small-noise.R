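test_that("infoSmallNoise reproduces the linear-channel closed form exactly", {
  ps <- profileSet(linearProfile(cMax = 2, sigma = 0.04, L = 1))
  expect_equal(valueNats(infoSmallNoise(ps)), valueNats(infoPhi(50)),
               tolerance = 1e-9)
  # Fisher additivity: two identical channels act like sqrt(2) higher phi
  two <- profileSet(linearProfile(sigma = 0.02, gene = "a"),
                    linearProfile(sigma = 0.02, gene = "b"))
  expect_equal(valueNats(infoSmallNoise(two)),
               valueNats(infoPhi(50 * sqrt(2))), tolerance = 1e-9)
})

test_that("readout noise enters through the total channel variance", {
  ps <- profileSet(linearProfile(sigma = 0.03))
  eta <- 0.04
  expect_equal(valueNats(infoSmallNoise(ps, eta0 = eta)),
               valueNats(infoPhi(1 / sqrt(0.03^2 + eta^2))),
               tolerance = 1e-9)
  # fractional mode: eta scales with the local mean
  base <- linearProfile(sigma = 0.03)
  manual <- ExpressionProfile("manual", base@meanFun, function(x)
    sqrt(0.03^2 + (0.1 * x)^2), domain = c(0, 1))
  expect_equal(
    valueNats(infoSmallNoise(ps, eta0 = 0.1, noiseMode = "fractional")),
    valueNats(infoSmallNoise(profileSet(manual))), tolerance = 1e-9)
})

test_that("the accessibility bound holds: readout noise only destroys", {
  sets <- list(
    profileSet(linearProfile(sigma = 0.02)),
    profileSet(geneProfile(defaultEmbryoGenes()$hb), domain = c(0.3, 0.55)),
    roiRestrict(profileSet(lapply(defaultEmbryoGenes(), geneProfile)),
                c(0.37, 0.47)))
  for (ps in sets) {
    raw <- valueNats(infoSmallNoise(ps, eta0 = 0))
    prev <- raw
    for (eta in c(0.005, 0.02, 0.1, 0.5)) {
      cur <- valueNats(infoSmallNoise(ps, eta0 = eta))
      expect_lt(cur, raw)
      expect_lt(cur, prev)
      prev <- cur
    }
    expect_equal(valueNats(infoSmallNoise(ps, eta0 = 0)), raw)
  }
})

test_that("small-noise and numeric estimates agree on the synthetic triplet", {
  # deep small-noise regime (positional error << ROI length)
  genes <- defaultEmbryoGenes()
  genes$hb$sd <- 0.01; genes$kr$sd <- 0.01; genes$eve$sd <- 0.02
  ps <- roiRestrict(profileSet(lapply(genes, geneProfile)), c(0.37, 0.47))
  sn <- valueNats(infoSmallNoise(ps))
  mi <- miNumeric(ps, nMC = 12000L, seed = 6)
  expect_lt(abs(sn - valueNats(mi)), 0.05)
})

test_that("information is invariant under a common rescaling", {
  ps1 <- profileSet(linearProfile(cMax = 1, sigma = 0.02))
  ps2 <- profileSet(linearProfile(cMax = 37, sigma = 37 * 0.02))
  expect_equal(valueNats(infoSmallNoise(ps1, eta0 = 0.01)),
               valueNats(infoSmallNoise(ps2, eta0 = 0.37)),
               tolerance = 1e-9)
  m1 <- miNumeric(ps1, eta0 = 0.01, nMC = 2000L, seed = 7)
  m2 <- miNumeric(ps2, eta0 = 0.37, nMC = 2000L, seed = 7)
  expect_equal(valueNats(m1), valueNats(m2), tolerance = 1e-9)
})

test_that("vanishing Fisher information is an error", {
  flat <- ExpressionProfile("flat", function(x) rep(1, length(x)),
                            function(x) rep(0.1, length(x)))
  expect_error(infoSmallNoise(profileSet(flat)), "Fisher")
})
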