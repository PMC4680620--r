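## Synthetic embryo generation: parametric stand-ins for gap-gene and
## pair-rule expression geometry along the AP axis, with additive Gaussian
## per-nucleus noise of stated (possibly position-dependent) magnitude.

#' Describe a gap-gene-like logistic boundary
#'
#' Mean shape \eqn{A / (1 + e^{\pm(x - x_0)/w}}) — a sigmoid boundary that
#' decreases (Hb-like) or increases (Kr-like) across its midpoint. The maximal
#' absolute slope is \eqn{A/(4w)} at the midpoint.
#'
#' @param name gene name.
#' @param midpoint boundary position \eqn{x_0} (normalized AP units).
#' @param width logistic width \eqn{w} (> 0).
#' @param direction \code{"decreasing"} or \code{"increasing"}.
#' @param amplitude maximal mean level \eqn{A}.
#' @param sd noise SD: a constant or a function of position.
#' @return a gene description list for [EmbryoSpec()].
#' @export
sigmoidGene <- function(name, midpoint, width,
                        direction = c("decreasing", "increasing"),
                        amplitude = 1, sd = 0.05) {
  direction <- match.arg(direction)
  stopifnot(width > 0, amplitude > 0)
  list(name = name, type = "sigmoid", midpoint = midpoint, width = width,
       direction = direction, amplitude = amplitude, sd = sd)
}

#' Describe a pair-rule-like striped profile
#'
#' Mean shape is a sum of Gaussian stripes
#' \eqn{\sum_k A_k \exp(-(x - c_k)^2 / 2 w_k^2)}; a trough arises between
#' adjacent stripe centers. Stripes are deliberately steeper than the
#' sigmoid boundaries they are paired with in the default embryo.
#'
#' @param name gene name.
#' @param centers stripe center positions.
#' @param widths stripe Gaussian SDs (> 0), recycled to match centers.
#' @param amplitudes stripe amplitudes, recycled to match centers.
#' @param sd noise SD: a constant or a function of position.
#' @return a gene description list for [EmbryoSpec()].
#' @export
stripeGene <- function(name, centers, widths, amplitudes = 1, sd = 0.1) {
  stopifnot(length(centers) >= 1, all(widths > 0), all(amplitudes > 0))
  widths <- rep_len(widths, length(centers))
  amplitudes <- rep_len(amplitudes, length(centers))
  list(name = name, type = "stripes", centers = centers, widths = widths,
       amplitudes = amplitudes, sd = sd)
}

#' Default synthetic gene set
#'
#' Three channels emulating the geometry the pipeline analyses: a decreasing
#' sigmoid (\code{hb}-like) and an increasing sigmoid (\code{kr}-like) forming
#' opposing boundaries at AP position 0.42 (inside the 0.37-0.47 region of
#' interest), and a steeper striped channel (\code{eve}-like) whose two
#' stripes flank the ROI so that its trough falls between them. The striped
#' channel carries twice the noise of the sigmoid channels while being more
#' than three times steeper inside the ROI.
#'
#' @return named list of gene descriptions.
#' @export
defaultEmbryoGenes <- function() {
  list(
    hb = sigmoidGene("hb", midpoint = 0.42, width = 0.035,
                     direction = "decreasing", sd = 0.05),
    kr = sigmoidGene("kr", midpoint = 0.42, width = 0.035,
                     direction = "increasing", sd = 0.05),
    eve = stripeGene("eve", centers = c(0.35, 0.49),
                     widths = c(0.024, 0.028), amplitudes = c(1, 0.95),
                     sd = 0.1))
}

#' Evaluate a gene description's mean, slope and noise SD
#'
#' @param gene a gene description from [sigmoidGene()] or [stripeGene()].
#' @return a function of normalized AP position.
#' @export
geneMeanFunction <- function(gene) {
  if (gene$type == "sigmoid") {
    s <- if (gene$direction == "decreasing") 1 else -1
    function(x) gene$amplitude / (1 + exp(s * (x - gene$midpoint) / gene$width))
  } else {
    function(x) {
      out <- numeric(length(x))
      for (k in seq_along(gene$centers))
        out <- out + gene$amplitudes[k] *
          exp(-(x - gene$centers[k])^2 / (2 * gene$widths[k]^2))
      out
    }
  }
}

#' @rdname geneMeanFunction
#' @export
geneMeanDerivFunction <- function(gene) {
  if (gene$type == "sigmoid") {
    s <- if (gene$direction == "decreasing") 1 else -1
    function(x) {
      p <- 1 / (1 + exp(s * (x - gene$midpoint) / gene$width))
      -s * gene$amplitude * p * (1 - p) / gene$width
    }
  } else {
    function(x) {
      out <- numeric(length(x))
      for (k in seq_along(gene$centers))
        out <- out - gene$amplitudes[k] *
          (x - gene$centers[k]) / gene$widths[k]^2 *
          exp(-(x - gene$centers[k])^2 / (2 * gene$widths[k]^2))
      out
    }
  }
}

#' @rdname geneMeanFunction
#' @export
geneSdFunction <- function(gene) {
  if (is.function(gene$sd)) return(gene$sd)
  s <- as.numeric(gene$sd)
  function(x) rep(s, length(x))
}

#' Generate a synthetic embryo
#'
#' Lays out \code{nAP x nDV} nuclei on a rectangular grid (AP rows at the
#' midpoints of \code{nAP} equal subdivisions of \code{[0, 1]}) and draws, for
#' every gene, \code{expression = mean(x_ap) + N(0, sd(x_ap)^2)} independently
#' across nuclei and genes. All dorsal-ventral columns of a row share the same
#' AP position, which is what makes adjacent-column differences a pure noise
#' measurement.
#'
#' @param spec an [EmbryoSpec-class].
#' @param seed optional integer seed (single RNG stream per call).
#' @return a [NucleusTable-class].
#' @examples
#' tab <- generateEmbryo(EmbryoSpec(nAP = 20L, nDV = 3L), seed = 1)
#' dim(tab)
#' @export
generateEmbryo <- function(spec, seed = NULL) {
  stopifnot(is(spec, "EmbryoSpec"))
  validObject(spec)
  if (!is.null(seed)) set.seed(seed)
  xAP <- (seq_len(spec@nAP) - 0.5) / spec@nAP
  grid <- expand.grid(dv = seq_len(spec@nDV), x = xAP)
  n <- nrow(grid)
  genes <- names(spec@genes)
  expr <- matrix(NA_real_, nrow = length(genes), ncol = n,
                 dimnames = list(genes, NULL))
  for (g in genes) {
    mu <- geneMeanFunction(spec@genes[[g]])(grid$x)
    sdv <- geneSdFunction(spec@genes[[g]])(grid$x)
    expr[g, ] <- mu + rnorm(n, 0, sdv)
  }
  NucleusTable(expr, xAP = grid$x, dvIndex = grid$dv)
}
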