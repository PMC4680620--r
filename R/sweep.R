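## Direct vs two-tier parameter sweeps.

#' Sweep the direct / two-tier comparison over a parameter grid
#'
#' Evaluates, at every combination of the supplied parameter values, the four
#' closed-form information quantities (raw and accessible, direct and
#' two-tier), the benefit margin \eqn{\eta_0^2(1 - 1/N_{eff} - 1/\lambda^2)}
#' and the accessible-information difference in bits. With
#' \code{oracle = TRUE} each grid point is additionally verified against the
#' package's independent machinery: the two-tier strategy is simulated, its
#' empirical fluctuation SD recorded, and the accessible information of the
#' matched linear channel re-estimated with [miNumeric()]; the discrepancy
#' and its Monte-Carlo standard error are returned per point. (Simulation is
#' orders of magnitude slower than the closed forms, hence opt-in.)
#'
#' @param sigma0,eta0,nEff,gain numeric vectors of parameter values; the grid
#'   is their full cross product.
#' @param cMax dynamic range (single value).
#' @param oracle run the simulation + numeric MI cross-check per grid point.
#' @param seed optional integer seed (used only when \code{oracle = TRUE}).
#' @param nCells cells per simulated realization (oracle runs).
#' @param nGrid,nMC [miNumeric()] settings for the oracle runs.
#' @return a \code{data.frame}, one row per grid point, with columns
#'   \code{sigma0, eta0, nEff, gain, rawDirect, rawTwoTier, accDirect,
#'   accTwoTier} (nats), \code{margin}, \code{beneficial},
#'   \code{deltaAccBits}, and for oracle runs \code{simSd, simSdTheory,
#'   accTwoTierNumeric, oracleStderr, oracleDiscrepancy}.
#' @export
sweepStrategies <- function(sigma0, eta0, nEff, gain, cMax = 1,
                            oracle = FALSE, seed = NULL, nCells = 10000L,
                            nGrid = 2048L, nMC = 8000L) {
  grid <- expand.grid(sigma0 = sigma0, eta0 = eta0, nEff = nEff, gain = gain,
                      KEEP.OUT.ATTRS = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(grid)
  res <- grid
  res$rawDirect <- res$rawTwoTier <- res$accDirect <- res$accTwoTier <-
    res$margin <- res$deltaAccBits <- NA_real_
  res$beneficial <- NA
  if (oracle)
    res$simSd <- res$simSdTheory <- res$accTwoTierNumeric <-
      res$oracleStderr <- res$oracleDiscrepancy <- NA_real_

  for (i in seq_len(n)) {
    p <- grid[i, ]
    res$rawDirect[i] <- valueNats(rawInfoDirect(cMax, p$sigma0, p$nEff))
    res$rawTwoTier[i] <- valueNats(rawInfoTwoTier(cMax, p$sigma0, p$eta0,
                                                  p$nEff, p$gain))
    res$accDirect[i] <- valueNats(accInfoDirect(cMax, p$sigma0, p$eta0,
                                                p$nEff))
    res$accTwoTier[i] <- valueNats(accInfoTwoTier(cMax, p$sigma0, p$eta0,
                                                  p$nEff, p$gain))
    bc <- benefitCondition(p$eta0, p$nEff, p$gain)
    res$margin[i] <- bc$margin
    res$beneficial[i] <- bc$beneficial
    res$deltaAccBits[i] <- (res$accTwoTier[i] - res$accDirect[i]) / log(2)

    if (oracle) {
      params <- StrategyParams(
        GradientSpec(L = 1, cMax = cMax, sigma0 = p$sigma0, nCells = nCells),
        ReadoutSpec(eta0 = p$eta0, gain = p$gain, shape = "linear",
                    nEff = p$nEff),
        strategy = "two_tier")
      sim <- simulateStrategy(params)
      res$simSd[i] <- stats::sd(sim@values - sim@spec$mean)
      res$simSdTheory[i] <- sim@spec$sd
      ## matched channel: the amplified mean with the simulated fluctuation
      ## SD, read through one more noisy access of magnitude eta0
      ch <- linearProfile(cMax = p$gain * cMax, sigma = res$simSd[i])
      mi <- miNumeric(profileSet(ch), eta0 = p$eta0, nGrid = nGrid, nMC = nMC)
      res$accTwoTierNumeric[i] <- valueNats(mi)
      res$oracleStderr[i] <- mcStderr(mi)
      res$oracleDiscrepancy[i] <- res$accTwoTierNumeric[i] - res$accTwoTier[i]
    }
  }
  res
}
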