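## The three toolkit operators -- access, amplify, average -- and the
## composed direct / two-tier strategy simulators.

#' Access: read a signal through a noisy channel
#'
#' One "access" operation returns a noisy estimate of the true concentration:
#' each value is corrupted by independent Gaussian noise of SD \code{eta0},
#' the intrinsic input noise of a single regulatory readout.
#'
#' @param values numeric, true concentrations.
#' @param eta0 input-noise SD (>= 0).
#' @param seed optional integer seed.
#' @return numeric, the noisy estimates.
#' @examples
#' accessSignal(c(1, 2, 3), eta0 = 0)       # noiseless access is the identity
#' @export
accessSignal <- function(values, eta0, seed = NULL) {
  if (!is.numeric(eta0) || length(eta0) != 1L || !is.finite(eta0) || eta0 < 0)
    stop("'eta0' must be a single non-negative number")
  if (!is.null(seed)) set.seed(seed)
  values + rnorm(length(values), 0, eta0)
}

#' Amplify: linear gain
#'
#' Pure linear amplification with coefficient \code{gain}: elementwise
#' multiplication. Both the mean profile and the fluctuations scale by the
#' same factor, which is why linear amplification leaves information content
#' untouched.
#'
#' @param values numeric concentrations.
#' @param gain amplification coefficient (> 0).
#' @return numeric, \code{gain * values}.
#' @export
amplifyLinear <- function(values, gain) {
  if (!is.numeric(gain) || length(gain) != 1L || !is.finite(gain) || gain <= 0)
    stop("'gain' must be a single positive number")
  gain * values
}

#' Amplify: zigzag (dynamic-range-preserving) map
#'
#' The segmentation-like input-output function: a triangle wave that folds
#' the input range \code{[0, cMax]} onto itself \code{gain} times. With
#' \eqn{t = \lambda\,\mathrm{clamp}(v, 0, c_{max})/c_{max}} and
#' \eqn{k = \lfloor t \rfloor}, the output is \eqn{(t-k)c_{max}} for even
#' \eqn{k} and \eqn{(1-(t-k))c_{max}} for odd \eqn{k}. The local slope
#' magnitude is \code{gain} everywhere except at the fold points, so the map
#' amplifies local differences while the output range stays \code{[0, cMax]}.
#' Inputs outside \code{[0, cMax]} are clamped first, reflecting the limited
#' global dynamic range of real morphogen concentrations.
#'
#' @param values numeric concentrations.
#' @param gain integer fold count \eqn{\lambda \ge 1}.
#' @param cMax dynamic range (> 0).
#' @return numeric, the folded concentrations in \code{[0, cMax]}.
#' @examples
#' amplifyZigzag(c(1/3, 1/2, 2/3), gain = 3, cMax = 1)  # 1, 0.5, 0
#' @export
amplifyZigzag <- function(values, gain, cMax) {
  if (!is.numeric(gain) || length(gain) != 1L ||
      abs(gain - round(gain)) > 1e-8 || gain < 1)
    stop("the zigzag map requires an integer 'gain' >= 1")
  if (!is.numeric(cMax) || length(cMax) != 1L || cMax <= 0)
    stop("'cMax' must be a single positive number")
  gain <- round(gain)
  t <- gain * pmin(pmax(values, 0), cMax) / cMax
  k <- floor(t)
  frac <- t - k
  ## at v = cMax, t = gain exactly: fold back into the last segment
  top <- k == gain
  k[top] <- gain - 1
  frac[top] <- 1
  ifelse(k %% 2 == 0, frac * cMax, (1 - frac) * cMax)
}

#' Average: reduce fluctuations by repeated measurement
#'
#' The averaging operator contracts fluctuations by \eqn{1/\sqrt{N_{eff}}}
#' while leaving the mean shape intact. For integer \code{nEff} it is
#' implemented literally as the mean of \code{nEff} independent realizations
#' drawn from \code{sampleFun}; for non-integer \code{nEff} a single
#' realization's fluctuation about \code{meanValues} is rescaled by
#' \eqn{1/\sqrt{N_{eff}}} (so \code{meanValues} is required in that case).
#'
#' @param sampleFun a zero-argument function returning one numeric
#'   realization (all calls must be independent draws of the same profile).
#' @param nEff effective number of independent measurements (>= 1).
#' @param meanValues numeric mean profile, required for non-integer
#'   \code{nEff}.
#' @param seed optional integer seed.
#' @return numeric, the averaged realization.
#' @export
averageRealizations <- function(sampleFun, nEff, meanValues = NULL,
                                seed = NULL) {
  if (!is.numeric(nEff) || length(nEff) != 1L || !is.finite(nEff) || nEff < 1)
    stop("'nEff' must be a single number >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (abs(nEff - round(nEff)) < 1e-8) {
    n <- round(nEff)
    acc <- sampleFun()
    if (n > 1L) for (i in seq_len(n - 1L)) acc <- acc + sampleFun()
    acc / n
  } else {
    if (is.null(meanValues))
      stop("non-integer 'nEff' needs 'meanValues' to rescale fluctuations")
    r <- sampleFun()
    meanValues + (r - meanValues) / sqrt(nEff)
  }
}

#' Simulate a full patterning strategy
#'
#' Composes the toolkit operators into the two strategies. Direct:
#' the averaged input itself,
#' \eqn{\hat c^{(0)} = G_{N_{eff}}[\hat c]}, with mean \eqn{(x/L)c_{max}} and
#' fluctuation SD \eqn{\sigma_0/\sqrt{N_{eff}}}. Two-tier: the averaged
#' amplified readout,
#' \eqn{\hat c^{(\lambda)} = G_{N_{eff}}[F_\lambda(\hat c + \hat\eta)]}, with
#' mean \eqn{(x/L)\lambda c_{max}} (or the zigzag-folded mean for the zigzag
#' shape) and fluctuation SD
#' \eqn{\xi_\lambda = \lambda\sqrt{(\sigma_0^2+\eta_0^2)/N_{eff}}}.
#'
#' @param params a [StrategyParams-class].
#' @param seed optional integer seed (one stream for the whole call).
#' @return a [ProfileRealization-class]; its \code{spec} records the strategy,
#'   the theoretical mean and the theoretical fluctuation SD.
#' @export
simulateStrategy <- function(params, seed = NULL) {
  stopifnot(is(params, "StrategyParams"))
  validObject(params)
  if (!is.null(seed)) set.seed(seed)
  gr <- params@gradient
  rd <- params@readout
  x <- seq(0, gr@L, length.out = gr@nCells)
  baseMean <- (x / gr@L) * gr@cMax

  if (params@strategy == "direct") {
    sampleFun <- function() sampleGradient(gr)@values
    meanProf <- baseMean
    theorySd <- gr@sigma0 / sqrt(rd@nEff)
  } else {
    amp <- function(v) {
      if (rd@shape == "zigzag") amplifyZigzag(v, rd@gain, gr@cMax)
      else amplifyLinear(v, rd@gain)
    }
    sampleFun <- function() amp(accessSignal(sampleGradient(gr)@values,
                                             rd@eta0))
    meanProf <- amp(baseMean)
    theorySd <- rd@gain * sqrt((gr@sigma0^2 + rd@eta0^2) / rd@nEff)
  }
  values <- averageRealizations(sampleFun, rd@nEff, meanValues = meanProf)
  ProfileRealization(x, values,
                     spec = list(strategy = params@strategy, mean = meanProf,
                                 sd = theorySd, gain = rd@gain,
                                 shape = rd@shape, nEff = rd@nEff,
                                 eta0 = rd@eta0, sigma0 = gr@sigma0,
                                 cMax = gr@cMax, L = gr@L))
}
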