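## Closed-form information quantities for the linear gradient and the
## direct / two-tier strategies. Internal unit is nats throughout; use
## valueBits() for bits.

#' Small-noise positional information of a linear profile
#'
#' For a linear profile with dynamic range to noise ratio
#' \eqn{\phi = c_{max}/\sigma}, the positional information in the small-noise,
#' many-cells regime is \eqn{I(\phi) = \ln(\phi / \sqrt{2\pi e})} nats, an
#' increasing function of \eqn{\phi}. All strategy-level closed forms reduce
#' to \code{infoPhi} of an effective \eqn{\phi}.
#'
#' @param phi dimensionless signal-to-noise ratio (> 0).
#' @return an [InfoResult-class] with method \code{"closed_form"}.
#' @examples
#' valueNats(infoPhi(sqrt(2 * pi * exp(1))))  # 0 nats
#' valueBits(infoPhi(100))
#' @export
infoPhi <- function(phi) {
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) || phi <= 0)
    stop("'phi' must be a single positive number")
  InfoResult(log(phi) - 0.5 * log(2 * pi * exp(1)), "closed_form",
             params = list(phi = phi))
}

#' Raw information of the direct strategy
#'
#' Averaging the input over \code{nEff} effective measurements reduces its
#' noise to \eqn{\sigma_0/\sqrt{N_{eff}}}, so the controlling signal carries
#' \eqn{I(c_{max}\sqrt{N_{eff}}/\sigma_0)} nats of raw information.
#'
#' @param cMax dynamic range (> 0).
#' @param sigma0 input noise SD (> 0).
#' @param nEff effective number of measurements (>= 1).
#' @return an [InfoResult-class].
#' @export
rawInfoDirect <- function(cMax, sigma0, nEff = 1) {
  .checkInfoArgs(cMax = cMax, sigma0 = sigma0, nEff = nEff)
  r <- infoPhi(cMax * sqrt(nEff) / sigma0)
  r@params <- list(cMax = cMax, sigma0 = sigma0, nEff = nEff)
  r
}

#' Raw information of the two-tier strategy
#'
#' The amplified profile has noise
#' \eqn{\xi_\lambda = \lambda\sqrt{(\sigma_0^2+\eta_0^2)/N_{eff}}} and
#' dynamic range \eqn{\lambda c_{max}}; the gain cancels and the raw
#' information is \eqn{I(c_{max}\sqrt{N_{eff}}/\sqrt{\sigma_0^2+\eta_0^2})},
#' strictly below the direct strategy's whenever \eqn{\eta_0 > 0}. The
#' \code{gain} argument is accepted (and recorded) precisely to expose this
#' cancellation.
#'
#' @inheritParams rawInfoDirect
#' @param eta0 input noise SD of the intermediate readout (>= 0).
#' @param gain amplification factor; does not affect the value.
#' @return an [InfoResult-class].
#' @export
rawInfoTwoTier <- function(cMax, sigma0, eta0, nEff = 1, gain = 1) {
  .checkInfoArgs(cMax = cMax, sigma0 = sigma0, eta0 = eta0, nEff = nEff,
                 gain = gain)
  r <- infoPhi(cMax * sqrt(nEff) / sqrt(sigma0^2 + eta0^2))
  r@params <- list(cMax = cMax, sigma0 = sigma0, eta0 = eta0, nEff = nEff,
                   gain = gain)
  r
}

#' Accessible information of the direct strategy
#'
#' What the downstream readout can actually extract: the averaged input seen
#' through one more noisy access operation,
#' \eqn{I(c_{max}/\sqrt{\sigma_0^2/N_{eff} + \eta_0^2})}.
#'
#' @inheritParams rawInfoTwoTier
#' @return an [InfoResult-class].
#' @export
accInfoDirect <- function(cMax, sigma0, eta0, nEff = 1) {
  .checkInfoArgs(cMax = cMax, sigma0 = sigma0, eta0 = eta0, nEff = nEff)
  r <- infoPhi(cMax / sqrt(sigma0^2 / nEff + eta0^2))
  r@params <- list(cMax = cMax, sigma0 = sigma0, eta0 = eta0, nEff = nEff)
  r
}

#' Accessible information of the two-tier strategy
#'
#' The readout noise enters twice (two access operations), but amplification
#' dilutes the second one:
#' \eqn{I\!\left(c_{max}\big/\sqrt{(\sigma_0^2+\eta_0^2)/N_{eff} +
#' \eta_0^2/\lambda^2}\right)}, strictly increasing in \eqn{\lambda} whenever
#' \eqn{\eta_0 > 0} and approaching the two-tier raw information as
#' \eqn{\lambda \to \infty}.
#'
#' @inheritParams rawInfoTwoTier
#' @return an [InfoResult-class].
#' @export
accInfoTwoTier <- function(cMax, sigma0, eta0, nEff = 1, gain = 1) {
  .checkInfoArgs(cMax = cMax, sigma0 = sigma0, eta0 = eta0, nEff = nEff,
                 gain = gain)
  r <- infoPhi(cMax / sqrt((sigma0^2 + eta0^2) / nEff + eta0^2 / gain^2))
  r@params <- list(cMax = cMax, sigma0 = sigma0, eta0 = eta0, nEff = nEff,
                   gain = gain)
  r
}

#' When does the extra noisy tier pay off?
#'
#' The two-tier strategy provides more accessible information than the direct
#' one exactly when
#' \eqn{\eta_0^2 (1 - 1/N_{eff} - 1/\lambda^2) > 0}: never with
#' \code{nEff = 1} (no averaging) or \code{gain = 1} (no amplification).
#' The sign of the returned margin equals the sign of
#' \code{accInfoTwoTier - accInfoDirect} for all valid parameters.
#'
#' @param eta0 readout noise SD (>= 0).
#' @param nEff effective number of measurements (>= 1).
#' @param gain amplification factor (>= 1).
#' @return list with elements \code{beneficial} (logical) and \code{margin}
#'   (in squared concentration units).
#' @examples
#' benefitCondition(eta0 = 1, nEff = 4, gain = 2)  # margin 0.5, beneficial
#' @export
benefitCondition <- function(eta0, nEff, gain) {
  .checkInfoArgs(eta0 = eta0, nEff = nEff, gain = gain)
  margin <- eta0^2 * (1 - 1 / nEff - 1 / gain^2)
  list(beneficial = margin > 0, margin = margin)
}

#' Information after a zigzag fold
#'
#' Folding a profile onto itself \code{gain} times reuses the same output
#' values at \code{gain} distinct locations, reducing both raw and accessible
#' information by exactly \eqn{\ln\lambda} nats (in the small-noise regime).
#'
#' @param base an [InfoResult-class] for the unfolded (linear) profile.
#' @param gain integer fold count (>= 1).
#' @return an [InfoResult-class] with the same method and standard error.
#' @export
zigzagInfo <- function(base, gain) {
  stopifnot(is(base, "InfoResult"))
  if (!is.numeric(gain) || length(gain) != 1L ||
      abs(gain - round(gain)) > 1e-8 || gain < 1)
    stop("'gain' must be an integer >= 1")
  InfoResult(base@value - log(round(gain)), base@method, base@mcStderr,
             c(base@params, list(zigzagGain = round(gain))))
}

## shared domain checks for the closed forms
.checkInfoArgs <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm))
    lo <- switch(nm, cMax = , sigma0 = 0, eta0 = 0, nEff = 1, gain = 1)
    strict <- nm == "cMax"
    if ((strict && v <= lo) || (!strict && v < lo))
      stop(sprintf("'%s' must be %s %g", nm, if (strict) ">" else ">=", lo))
  }
  invisible(TRUE)
}
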