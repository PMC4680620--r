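#' Sample one realization of the noisy linear gradient
#'
#' Draws one stochastic realization of the input morphogen: cells sit at
#' \code{nCells} equispaced positions spanning \code{[0, L]} and each observes
#' \eqn{(x_i/L)\,c_{max} + \epsilon_i} with \eqn{\epsilon_i} independent
#' Gaussian noise of SD \code{sigma0}.
#'
#' @param spec a [GradientSpec-class].
#' @param seed optional integer; when supplied the R RNG is seeded so the
#'   realization is reproducible. When \code{NULL} the current RNG stream is
#'   used (this is how composed simulators keep a single stream).
#' @return a [ProfileRealization-class].
#' @examples
#' r <- sampleGradient(GradientSpec(sigma0 = 0), seed = 1)
#' all.equal(r@values, r@positions)  # zero noise: values on the mean line
#' @export
sampleGradient <- function(spec, seed = NULL) {
  stopifnot(is(spec, "GradientSpec"))
  validObject(spec)
  if (!is.null(seed)) set.seed(seed)
  x <- seq(0, spec@L, length.out = spec@nCells)
  values <- (x / spec@L) * spec@cMax + rnorm(spec@nCells, 0, spec@sigma0)
  ProfileRealization(x, values,
                     spec = list(L = spec@L, cMax = spec@cMax,
                                 sigma0 = spec@sigma0, nCells = spec@nCells))
}

#' Mean profile of a gradient
#'
#' The noiseless mean \eqn{(x/L)c_{max}} evaluated at the cell positions of
#' \code{spec}.
#'
#' @inheritParams sampleGradient
#' @return numeric vector of per-cell means.
#' @export
gradientMean <- function(spec) {
  stopifnot(is(spec, "GradientSpec"))
  x <- seq(0, spec@L, length.out = spec@nCells)
  (x / spec@L) * spec@cMax
}
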