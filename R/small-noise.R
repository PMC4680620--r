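## Small-noise positional information via local positional error.

#' Small-noise positional information of a profile set
#'
#' In the small-noise regime, a cell at position \eqn{x} observing all
#' channels can locate itself with a local positional error
#' \deqn{\sigma_x(x)^{-2} = \sum_i \frac{(d\bar g_i/dx)^2}
#'   {\sigma_i(x)^2 + \eta_0^2},}
#' the Fisher information about position summed over independent channels.
#' The positional information for a uniform prior on the domain is then
#' \deqn{I = \ln(L_d) - \left\langle \ln\!\big(\sqrt{2\pi e}\,\sigma_x(x)\big)
#'   \right\rangle_x,}
#' with \eqn{L_d} the domain length and the average taken over the uniform
#' position prior. For a single linear channel with constant noise this
#' reproduces [infoPhi()] exactly.
#'
#' Mean slopes are obtained by central finite differences of the channel mean
#' functions, which is exact for linear profiles and accurate for the smooth
#' sigmoid/stripe/spline profiles used throughout.
#'
#' @param profiles a [ProfileSet-class].
#' @param eta0 extra readout noise SD (>= 0).
#' @param nGrid number of quadrature nodes for the position average.
#' @param noiseMode \code{"absolute"} adds \code{eta0} to every channel;
#'   \code{"fractional"} adds \code{eta0 * mean_i(x)}.
#' @return an [InfoResult-class] with method \code{"small_noise"}.
#' @examples
#' ps <- profileSet(linearProfile(cMax = 1, sigma = 0.01))
#' valueNats(infoSmallNoise(ps)) - valueNats(infoPhi(100))  # 0
#' @export
infoSmallNoise <- function(profiles, eta0 = 0, nGrid = 512L,
                           noiseMode = c("absolute", "fractional")) {
  stopifnot(is(profiles, "ProfileSet"))
  noiseMode <- match.arg(noiseMode)
  if (!is.numeric(eta0) || length(eta0) != 1L || eta0 < 0)
    stop("'eta0' must be a single non-negative number")
  lo <- profiles@domain[1]; hi <- profiles@domain[2]
  Ld <- hi - lo
  nGrid <- as.integer(nGrid)
  xg <- lo + (seq_len(nGrid) - 0.5) * (Ld / nGrid)
  h <- Ld * 1e-5

  fisher <- numeric(nGrid)
  for (ch in profiles@channels) {
    slope <- (ch@meanFun(xg + h) - ch@meanFun(xg - h)) / (2 * h)
    m <- ch@meanFun(xg)
    v <- .totalSd(ch@sdFun(xg), m, eta0, noiseMode)^2
    if (any(v <= 0 & slope != 0))
      stop("channel '", ch@gene, "' has zero total noise where its slope ",
           "is non-zero; information diverges. Supply eta0 > 0 or a ",
           "positive noise profile")
    fisher <- fisher + ifelse(slope == 0 & v <= 0, 0, slope^2 / v)
  }
  if (any(fisher <= 0))
    stop("total Fisher information vanishes on part of the domain; the ",
         "small-noise positional information is undefined there")
  sigmaX <- 1 / sqrt(fisher)
  value <- log(Ld) - mean(log(sqrt(2 * pi * exp(1)) * sigmaX))
  InfoResult(value, "small_noise",
             params = list(eta0 = eta0, nGrid = nGrid, noiseMode = noiseMode,
                           channels = channelNames(profiles)))
}
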