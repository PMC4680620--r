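#' @describeIn GradientSpec-class compact display.
#' @param object the object to display.
setMethod("show", "GradientSpec", function(object) {
  cat(sprintf(
    "GradientSpec: linear gradient on [0, %g], cMax = %g, sigma0 = %g, %d cells\n",
    object@L, object@cMax, object@sigma0, object@nCells))
})

#' @describeIn ReadoutSpec-class compact display.
setMethod("show", "ReadoutSpec", function(object) {
  cat(sprintf(
    "ReadoutSpec: eta0 = %g, %s gain = %g, nEff = %g\n",
    object@eta0, object@shape, object@gain, object@nEff))
})

#' @describeIn StrategyParams-class compact display.
setMethod("show", "StrategyParams", function(object) {
  cat(sprintf("StrategyParams (%s strategy)\n", object@strategy))
  show(object@gradient)
  show(object@readout)
})

#' @describeIn ProfileRealization-class compact display.
setMethod("show", "ProfileRealization", function(object) {
  cat(sprintf("ProfileRealization: %d cells on [%g, %g]\n",
              length(object@positions),
              min(object@positions), max(object@positions)))
})

#' @describeIn InfoResult-class compact display.
setMethod("show", "InfoResult", function(object) {
  se <- if (object@mcStderr > 0)
    sprintf(" +/- %.4f", object@mcStderr) else ""
  cat(sprintf("InfoResult [%s]: %.4f nats%s (%.4f bits)\n", object@method,
              object@value, se, object@value / log(2)))
})

#' @describeIn ExpressionProfile-class compact display.
setMethod("show", "ExpressionProfile", function(object) {
  cat(sprintf("ExpressionProfile '%s' on [%g, %g] (scale %.4g)\n",
              object@gene, object@domain[1], object@domain[2], object@scale))
})

#' @describeIn ProfileSet-class compact display.
setMethod("show", "ProfileSet", function(object) {
  cat(sprintf("ProfileSet: %d channel(s) [%s] on [%g, %g]\n",
              length(object@channels),
              paste(names(object@channels), collapse = ", "),
              object@domain[1], object@domain[2]))
})

#' @describeIn EmbryoSpec-class compact display.
setMethod("show", "EmbryoSpec", function(object) {
  cat(sprintf(
    "EmbryoSpec: %d x %d nuclei (AP x DV), ROI [%g, %g], genes: %s\n",
    object@nAP, object@nDV, object@roi[1], object@roi[2],
    paste(names(object@genes), collapse = ", ")))
})

#' @describeIn NoiseProfileEstimate-class compact display.
setMethod("show", "NoiseProfileEstimate", function(object) {
  ok <- is.finite(object@sd)
  cat(sprintf(
    "NoiseProfileEstimate '%s': %d/%d usable bins, median SD %.4g (%d embryo%s)\n",
    object@gene, sum(ok), length(object@sd),
    stats::median(object@sd[ok]), object@nReplicates,
    if (object@nReplicates > 1L) "s" else ""))
})

#' @describeIn CrossingResult-class compact display.
setMethod("show", "CrossingResult", function(object) {
  if (is.na(object@crossing))
    cat("CrossingResult: no crossing on the grid\n")
  else
    cat(sprintf("CrossingResult: triplet meets the noiseless-pair bound at eta0* = %.4g\n",
                object@crossing))
})
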