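## Analytic profile builders and domain restriction.

#' Analytic linear profile
#'
#' Mean \eqn{(x/L)c_{max}} with constant noise SD \code{sigma} on
#' \code{[0, L]}.
#'
#' @param cMax dynamic range.
#' @param sigma constant noise SD.
#' @param L domain length.
#' @param gene channel name.
#' @return an [ExpressionProfile-class].
#' @export
linearProfile <- function(cMax = 1, sigma = 0.05, L = 1, gene = "linear") {
  force(cMax); force(sigma); force(L)
  ExpressionProfile(gene,
                    meanFun = function(x) (x / L) * cMax,
                    sdFun = function(x) rep(sigma, length(x)),
                    domain = c(0, L))
}

#' Analytic zigzag profile
#'
#' The linear profile folded onto itself \code{gain} times by the triangle
#' map [amplifyZigzag()], with constant noise SD \code{sigma}.
#'
#' @inheritParams linearProfile
#' @param gain integer fold count.
#' @return an [ExpressionProfile-class].
#' @export
zigzagProfile <- function(cMax = 1, sigma = 0.05, gain = 3, L = 1,
                          gene = "zigzag") {
  force(cMax); force(sigma); force(L); force(gain)
  ExpressionProfile(gene,
                    meanFun = function(x) amplifyZigzag((x / L) * cMax, gain,
                                                        cMax),
                    sdFun = function(x) rep(sigma, length(x)),
                    domain = c(0, L))
}

#' Profile of a synthetic gene description
#'
#' Turns a gene description (from [sigmoidGene()] / [stripeGene()]) into an
#' [ExpressionProfile-class] with its exact analytic mean and noise SD —
#' useful as ground truth when checking what the fitting pipeline recovers.
#'
#' @param gene a gene description list.
#' @param domain profile domain.
#' @return an [ExpressionProfile-class].
#' @export
geneProfile <- function(gene, domain = c(0, 1)) {
  ExpressionProfile(gene$name, meanFun = geneMeanFunction(gene),
                    sdFun = geneSdFunction(gene), domain = domain)
}

#' Restrict a profile set to a region of interest
#'
#' Truncates the analysis domain and re-uniformizes the position prior on the
#' ROI (all information estimators condition the position prior on the set's
#' domain). Restricting is idempotent and errors if the ROI is not contained
#' in the current domain.
#'
#' @param profiles a [ProfileSet-class].
#' @param roi numeric(2), the new domain.
#' @return a [ProfileSet-class] on \code{roi}.
#' @export
roiRestrict <- function(profiles, roi = c(0.37, 0.47)) {
  stopifnot(is(profiles, "ProfileSet"))
  if (length(roi) != 2L || roi[1] >= roi[2])
    stop("'roi' must be an increasing interval of length 2")
  if (roi[1] < profiles@domain[1] - 1e-12 ||
      roi[2] > profiles@domain[2] + 1e-12)
    stop(sprintf("ROI [%g, %g] lies outside the profile domain [%g, %g]",
                 roi[1], roi[2], profiles@domain[1], profiles@domain[2]))
  channels <- lapply(profiles@channels, function(ch) {
    ch@domain <- as.numeric(roi)
    ch
  })
  profileSet(channels, domain = as.numeric(roi))
}
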