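test_that("noiseless embryos have identical DV columns", {
  genes <- defaultEmbryoGenes()
  for (g in names(genes)) genes[[g]]$sd <- 0
  tab <- generateEmbryo(EmbryoSpec(genes = genes, nAP = 30L, nDV = 4L),
                        seed = 1)
  expr <- SummarizedExperiment::assay(tab, "expression")
  for (x in unique(apPosition(tab))) {
    cols <- which(apPosition(tab) == x)
    expect_true(all(expr[, cols] == expr[, cols[1]]))
  }
})

test_that("the striped channel is steeper than the gap channels in the ROI", {
  genes <- defaultEmbryoGenes()
  xr <- seq(0.37, 0.47, length.out = 400)
  eveSlope <- max(abs(geneMeanDerivFunction(genes$eve)(xr)))
  for (g in c("hb", "kr"))
    expect_gt(eveSlope, max(abs(geneMeanDerivFunction(genes[[g]])(xr))))
  # the analytic derivative agrees with a finite-difference check
  h <- 1e-6
  fd <- (geneMeanFunction(genes$eve)(xr + h) -
         geneMeanFunction(genes$eve)(xr - h)) / (2 * h)
  expect_equal(geneMeanDerivFunction(genes$eve)(xr), fd, tolerance = 1e-6)
})

test_that("embryo specs violating the slope premise are rejected", {
  genes <- defaultEmbryoGenes()
  genes$eve <- stripeGene("eve", centers = c(0.2, 0.8), widths = 0.3)
  expect_error(EmbryoSpec(genes = genes), "steeper")
})

test_that("neighbor differences have the expected RMS", {
  genes <- list(flat = sigmoidGene("flat", midpoint = 0.5, width = 0.1,
                                   sd = 0.1))
  tab <- generateEmbryo(EmbryoSpec(genes = genes, nAP = 10000L, nDV = 2L),
                        seed = 2)
  expr <- SummarizedExperiment::assay(tab, "expression")["flat", ]
  d <- expr[dvIndex(tab) == 1L] - expr[dvIndex(tab) == 2L]
  rms <- sqrt(mean(d^2))
  expect_lt(abs(rms - 0.1 * sqrt(2)), 3 * 0.1 * sqrt(2) / sqrt(2 * 10000))
})

test_that("embryo generation is deterministic and position-structured", {
  spec <- tinyEmbryoSpec()
  t1 <- generateEmbryo(spec, seed = 5)
  t2 <- generateEmbryo(spec, seed = 5)
  expect_identical(SummarizedExperiment::assay(t1),
                   SummarizedExperiment::assay(t2))
  expect_equal(dim(t1), c(3L, spec@nAP * spec@nDV))
  expect_equal(sort(unique(apPosition(t1))),
               (seq_len(spec@nAP) - 0.5) / spec@nAP)
  expect_equal(sort(unique(dvIndex(t1))), seq_len(spec@nDV))
})

test_that("a position-dependent noise model is honored", {
  genes <- list(g = sigmoidGene("g", midpoint = 0.5, width = 0.1,
                                sd = function(x) 0.02 + 0.2 * x))
  tab <- generateEmbryo(EmbryoSpec(genes = genes, nAP = 2000L, nDV = 4L),
                        seed = 3)
  expr <- SummarizedExperiment::assay(tab, "expression")["g", ]
  x <- apPosition(tab)
  mu <- geneMeanFunction(genes$g)(x)
  lowSd <- sd((expr - mu)[x < 0.25])
  highSd <- sd((expr - mu)[x > 0.75])
  expect_lt(abs(lowSd - mean(0.02 + 0.2 * x[x < 0.25])) / lowSd, 0.1)
  expect_gt(highSd, 2 * lowSd)
})
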