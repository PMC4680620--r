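#' @import methods
#' @importFrom stats rnorm runif dnorm sd smooth.spline predict setNames
#' @importFrom utils read.delim packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
NULL

## ---------------------------------------------------------------------------
## Model parameter classes
## ---------------------------------------------------------------------------

#' Parameters of the noisy linear input gradient
#'
#' A one-dimensional field of \code{nCells} cells at positions
#' \eqn{0 \le x_i \le L} is exposed to a morphogen whose mean concentration
#' rises linearly from 0 to \code{cMax} along the axis, with additive Gaussian
#' noise of constant standard deviation \code{sigma0}, uncorrelated between
#' cells.
#'
#' @slot L axis length (arbitrary length units, > 0).
#' @slot cMax maximal mean concentration (concentration units, > 0).
#' @slot sigma0 input noise SD, same units as \code{cMax} (>= 0).
#' @slot nCells number of cells (integer >= 2).
#' @export
setClass("GradientSpec",
  slots = c(L = "numeric", cMax = "numeric", sigma0 = "numeric",
            nCells = "integer"))

setValidity("GradientSpec", function(object) {
  msg <- character()
  if (length(object@L) != 1L || !is.finite(object@L) || object@L <= 0)
    msg <- c(msg, "'L' must be a single positive number")
  if (length(object@cMax) != 1L || !is.finite(object@cMax) || object@cMax <= 0)
    msg <- c(msg, "'cMax' must be a single positive number")
  if (length(object@sigma0) != 1L || !is.finite(object@sigma0) ||
      object@sigma0 < 0)
    msg <- c(msg, "'sigma0' must be a single non-negative number")
  if (length(object@nCells) != 1L || is.na(object@nCells) ||
      object@nCells < 2L)
    msg <- c(msg, "'nCells' must be an integer >= 2")
  if (length(msg)) msg else TRUE
})

#' @param L,cMax,sigma0,nCells see slot descriptions.
#' @return \code{GradientSpec()} returns a validated \code{GradientSpec}.
#' @examples
#' GradientSpec(L = 1, cMax = 1, sigma0 = 0.05, nCells = 100)
#' @rdname GradientSpec-class
#' @export
GradientSpec <- function(L = 1, cMax = 1, sigma0 = 0.1, nCells = 100L) {
  new("GradientSpec", L = as.numeric(L), cMax = as.numeric(cMax),
      sigma0 = as.numeric(sigma0), nCells = as.integer(nCells))
}

#' One tier of gradient interpretation
#'
#' Describes a single readout tier: the intrinsic input noise \code{eta0} that
#' one "access" operation adds, the amplification \code{gain} and shape of the
#' deterministic input-output function (pure linear amplification, or a
#' dynamic-range-preserving zigzag/triangle-wave map), and the effective number
#' \code{nEff} of independent measurements that temporal/spatial averaging
#' provides (averaging divides the fluctuation variance by \code{nEff}).
#'
#' @slot eta0 input-noise SD of one access operation (concentration units,
#'   >= 0).
#' @slot gain amplification factor (>= 1; must be a whole number when
#'   \code{shape} is \code{"zigzag"}).
#' @slot shape \code{"linear"} or \code{"zigzag"}.
#' @slot nEff effective number of independent measurements (>= 1; real values
#'   are allowed, \code{nEff = 1} means no averaging).
#' @export
setClass("ReadoutSpec",
  slots = c(eta0 = "numeric", gain = "numeric", shape = "character",
            nEff = "numeric"))

setValidity("ReadoutSpec", function(object) {
  msg <- character()
  if (length(object@eta0) != 1L || !is.finite(object@eta0) || object@eta0 < 0)
    msg <- c(msg, "'eta0' must be a single non-negative number")
  if (length(object@gain) != 1L || !is.finite(object@gain) || object@gain < 1)
    msg <- c(msg, "'gain' must be a single number >= 1")
  if (!object@shape %in% c("linear", "zigzag"))
    msg <- c(msg, "'shape' must be \"linear\" or \"zigzag\"")
  if (identical(object@shape, "zigzag") &&
      abs(object@gain - round(object@gain)) > 1e-8)
    msg <- c(msg, "the zigzag readout requires an integer 'gain'")
  if (length(object@nEff) != 1L || !is.finite(object@nEff) || object@nEff < 1)
    msg <- c(msg, "'nEff' must be a single number >= 1")
  if (length(msg)) msg else TRUE
})

#' @param eta0,gain,shape,nEff see slot descriptions.
#' @return \code{ReadoutSpec()} returns a validated \code{ReadoutSpec}.
#' @examples
#' ReadoutSpec(eta0 = 0.1, gain = 3, shape = "zigzag", nEff = 4)
#' @rdname ReadoutSpec-class
#' @export
ReadoutSpec <- function(eta0 = 0, gain = 1, shape = c("linear", "zigzag"),
                        nEff = 1) {
  shape <- match.arg(shape)
  new("ReadoutSpec", eta0 = as.numeric(eta0), gain = as.numeric(gain),
      shape = shape, nEff = as.numeric(nEff))
}

#' A complete patterning strategy
#'
#' Combines an input gradient with a readout tier. Under the direct strategy
#' the target genes read the averaged input itself and the amplification
#' parameters (\code{gain}, \code{shape}) are ignored; under the two-tier
#' strategy an intermediate profile is produced by a noisy amplifying readout
#' of the input and then averaged.
#'
#' @slot gradient a [GradientSpec-class].
#' @slot readout a [ReadoutSpec-class].
#' @slot strategy \code{"direct"} or \code{"two_tier"}.
#' @export
setClass("StrategyParams",
  slots = c(gradient = "GradientSpec", readout = "ReadoutSpec",
            strategy = "character"))

setValidity("StrategyParams", function(object) {
  if (!object@strategy %in% c("direct", "two_tier"))
    return("'strategy' must be \"direct\" or \"two_tier\"")
  TRUE
})

#' @param gradient,readout,strategy see slot descriptions.
#' @return \code{StrategyParams()} returns a validated \code{StrategyParams}.
#' @rdname StrategyParams-class
#' @export
StrategyParams <- function(gradient, readout,
                           strategy = c("direct", "two_tier")) {
  new("StrategyParams", gradient = gradient, readout = readout,
      strategy = match.arg(strategy))
}

## ---------------------------------------------------------------------------
## Realizations and profiles
## ---------------------------------------------------------------------------

#' One sampled concentration profile
#'
#' A single stochastic realization of a morphogen profile: per-cell positions
#' (strictly increasing, within \code{[0, L]}) and the sampled concentration
#' at each cell. The \code{spec} slot records the generating parameters.
#'
#' @slot positions numeric, per-cell position.
#' @slot values numeric, per-cell concentration, same length.
#' @slot spec list, provenance of the realization.
#' @export
setClass("ProfileRealization",
  slots = c(positions = "numeric", values = "numeric", spec = "list"))

setValidity("ProfileRealization", function(object) {
  msg <- character()
  if (length(object@positions) != length(object@values))
    msg <- c(msg, "'positions' and 'values' must have the same length")
  if (length(object@positions) && any(diff(object@positions) <= 0))
    msg <- c(msg, "'positions' must be strictly increasing")
  if (length(msg)) msg else TRUE
})

ProfileRealization <- function(positions, values, spec = list()) {
  new("ProfileRealization", positions = as.numeric(positions),
      values = as.numeric(values), spec = spec)
}

#' A channel's mean and noise profile
#'
#' An idealized Gaussian-noise expression profile: the mean level and the
#' noise SD of one gene, both as functions of normalized axis position over a
#' common domain. Profiles are what the information estimators consume; they
#' can be built analytically (e.g. [linearProfile()]) or fitted from data with
#' [fitIdealizedProfile()].
#'
#' @slot gene channel name.
#' @slot meanFun function of position returning the mean level.
#' @slot sdFun function of position returning the noise SD (>= 0).
#' @slot domain numeric(2), the interval on which both functions are valid.
#' @slot scale numeric, the factor the raw profile was divided by during
#'   normalization (1 for analytic profiles).
#' @export
setClass("ExpressionProfile",
  slots = c(gene = "character", meanFun = "function", sdFun = "function",
            domain = "numeric", scale = "numeric"))

setValidity("ExpressionProfile", function(object) {
  msg <- character()
  if (length(object@domain) != 2L || object@domain[1] >= object@domain[2])
    msg <- c(msg, "'domain' must be an increasing interval of length 2")
  if (length(msg)) msg else TRUE
})

#' @param gene,meanFun,sdFun,domain,scale see slot descriptions.
#' @return \code{ExpressionProfile()} returns a validated
#'   \code{ExpressionProfile}.
#' @rdname ExpressionProfile-class
#' @export
ExpressionProfile <- function(gene, meanFun, sdFun, domain = c(0, 1),
                              scale = 1) {
  if (is.numeric(sdFun)) {
    s <- as.numeric(sdFun)[1]
    sdFun <- function(x) rep(s, length(x))
  }
  new("ExpressionProfile", gene = as.character(gene), meanFun = meanFun,
      sdFun = sdFun, domain = as.numeric(domain), scale = as.numeric(scale))
}

#' A set of channels over a common domain
#'
#' Several [ExpressionProfile-class] channels over a common position domain,
#' with the position prior taken uniform on that domain. This is the input of
#' all information estimators ([infoSmallNoise()], [miNumeric()]).
#'
#' @slot channels list of [ExpressionProfile-class] objects.
#' @slot domain numeric(2), common analysis domain.
#' @export
setClass("ProfileSet",
  slots = c(channels = "list", domain = "numeric"))

setValidity("ProfileSet", function(object) {
  msg <- character()
  if (!length(object@channels))
    msg <- c(msg, "a ProfileSet needs at least one channel")
  if (!all(vapply(object@channels, is, logical(1), "ExpressionProfile")))
    msg <- c(msg, "all channels must be ExpressionProfile objects")
  if (length(object@domain) != 2L || object@domain[1] >= object@domain[2])
    msg <- c(msg, "'domain' must be an increasing interval of length 2")
  if (length(msg)) msg else TRUE
})

#' @param ... \code{ExpressionProfile} objects (or a single list of them).
#' @param domain analysis domain; defaults to the first channel's domain.
#' @return \code{profileSet()} returns a validated \code{ProfileSet}.
#' @rdname ProfileSet-class
#' @export
profileSet <- function(..., domain = NULL) {
  channels <- list(...)
  if (length(channels) == 1L && is.list(channels[[1]]) &&
      !is(channels[[1]], "ExpressionProfile"))
    channels <- channels[[1]]
  if (is.null(domain)) domain <- channels[[1]]@domain
  names(channels) <- vapply(channels, function(ch) ch@gene, character(1))
  new("ProfileSet", channels = channels, domain = as.numeric(domain))
}

## ---------------------------------------------------------------------------
## Synthetic embryo
## ---------------------------------------------------------------------------

#' Parameters of a synthetic embryo
#'
#' Describes the mean shapes and noise models of a small set of genes on a
#' rectangular grid of nuclei (\code{nAP} rows along the anterior-posterior
#' axis times \code{nDV} columns along the dorsal-ventral direction), plus the
#' region of interest in which the gap-like genes form opposing boundaries.
#' Gene entries are lists built by [sigmoidGene()] (gap-gene-like logistic
#' boundary) or [stripeGene()] (pair-rule-like Gaussian stripes whose trough
#' falls between the stripe centers).
#'
#' The geometric premise of the pipeline's headline comparison is enforced at
#' validation time: within the ROI, the maximum absolute slope of every
#' stripe-type (pair-rule-like) gene must exceed that of every sigmoid-type
#' (gap-like) gene.
#'
#' @slot genes named list of gene descriptions.
#' @slot nAP integer, number of nucleus rows along the AP axis.
#' @slot nDV integer, number of nucleus columns along the DV direction.
#' @slot roi numeric(2) inside \code{[0, 1]}.
#' @export
setClass("EmbryoSpec",
  slots = c(genes = "list", nAP = "integer", nDV = "integer",
            roi = "numeric"))

setValidity("EmbryoSpec", function(object) {
  msg <- character()
  if (object@nAP < 2L) msg <- c(msg, "'nAP' must be >= 2")
  if (object@nDV < 1L) msg <- c(msg, "'nDV' must be >= 1")
  if (length(object@roi) != 2L || object@roi[1] >= object@roi[2] ||
      object@roi[1] < 0 || object@roi[2] > 1)
    msg <- c(msg, "'roi' must be an increasing interval inside [0, 1]")
  if (!length(object@genes) || is.null(names(object@genes)) ||
      anyDuplicated(names(object@genes)))
    msg <- c(msg, "'genes' must be a non-empty uniquely named list")
  xs <- seq(0, 1, length.out = 512L)
  for (g in object@genes) {
    mu <- geneMeanFunction(g)(xs)
    if (any(mu < -1e-9))
      msg <- c(msg, sprintf("gene '%s' has a negative mean profile", g$name))
    if (any(geneSdFunction(g)(xs) < 0))
      msg <- c(msg, sprintf("gene '%s' has a negative noise SD", g$name))
  }
  types <- vapply(object@genes, `[[`, character(1), "type")
  if (any(types == "stripes") && any(types == "sigmoid")) {
    xr <- seq(object@roi[1], object@roi[2], length.out = 512L)
    slope <- function(g) max(abs(geneMeanDerivFunction(g)(xr)))
    sMax <- vapply(object@genes[types == "sigmoid"], slope, numeric(1))
    for (g in object@genes[types == "stripes"]) {
      if (!all(slope(g) > sMax))
        msg <- c(msg, sprintf(
          "within the ROI, stripe gene '%s' must be steeper than every sigmoid gene",
          g$name))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @param genes,nAP,nDV,roi see slot descriptions.
#' @return \code{EmbryoSpec()} returns a validated \code{EmbryoSpec}.
#' @examples
#' spec <- EmbryoSpec()           # default Hb/Kr/Eve-like geometry
#' names(spec@genes)
#' @rdname EmbryoSpec-class
#' @export
EmbryoSpec <- function(genes = defaultEmbryoGenes(), nAP = 100L, nDV = 12L,
                       roi = c(0.37, 0.47)) {
  if (is.null(names(genes)))
    names(genes) <- vapply(genes, `[[`, character(1), "name")
  new("EmbryoSpec", genes = genes, nAP = as.integer(nAP),
      nDV = as.integer(nDV), roi = as.numeric(roi))
}

#' Synthetic embryo expression table
#'
#' A \linkS4class{SummarizedExperiment} holding one expression value per gene
#' (rows) and nucleus (columns), with per-nucleus metadata in
#' \code{colData}: \code{nucleus_id}, \code{x_ap} (normalized AP position in
#' \code{[0, 1]}) and \code{dv_index} (integer column index along the
#' dorsal-ventral direction). Nuclei sharing \code{x_ap} with adjacent
#' \code{dv_index} are immediate dorsal/ventral neighbors, which is what the
#' neighbor-difference noise estimator relies on.
#'
#' @export
setClass("NucleusTable", contains = "SummarizedExperiment")

setValidity("NucleusTable", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  need <- c("nucleus_id", "x_ap", "dv_index")
  missing <- setdiff(need, colnames(cd))
  if (length(missing))
    return(sprintf("colData lacks column(s): %s",
                   paste(missing, collapse = ", ")))
  if (any(cd$x_ap < 0 | cd$x_ap > 1))
    msg <- c(msg, "'x_ap' must lie in [0, 1]")
  if (any(cd$dv_index != round(cd$dv_index)) || any(cd$dv_index < 1))
    msg <- c(msg, "'dv_index' must be positive integers")
  if (anyDuplicated(paste(cd$x_ap, cd$dv_index)))
    msg <- c(msg, "duplicate (x_ap, dv_index) pairs")
  if (!"expression" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'expression' is required")
  if (length(msg)) msg else TRUE
})

#' @param expression numeric matrix, genes in rows, nuclei in columns;
#'   rownames are gene names.
#' @param xAP numeric, normalized AP position per nucleus.
#' @param dvIndex integer, DV column index per nucleus.
#' @param nucleusId character, optional nucleus identifiers.
#' @return \code{NucleusTable()} returns a validated \code{NucleusTable}.
#' @rdname NucleusTable-class
#' @export
NucleusTable <- function(expression, xAP, dvIndex, nucleusId = NULL) {
  expression <- as.matrix(expression)
  if (is.null(rownames(expression)))
    stop("'expression' must have gene names as rownames")
  if (is.null(nucleusId))
    nucleusId <- sprintf("n%05d", seq_len(ncol(expression)))
  colnames(expression) <- nucleusId
  cd <- S4Vectors::DataFrame(nucleus_id = as.character(nucleusId),
                             x_ap = as.numeric(xAP),
                             dv_index = as.integer(dvIndex),
                             row.names = nucleusId)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expression = expression), colData = cd)
  new("NucleusTable", se)
}

## ---------------------------------------------------------------------------
## Results
## ---------------------------------------------------------------------------

#' An information value
#'
#' The value of an information quantity in nats, together with the method that
#' produced it (\code{"closed_form"}, \code{"small_noise"} or
#' \code{"numeric"}) and, for Monte-Carlo estimates, the standard error.
#' Use [valueNats()] / [valueBits()] to extract the value.
#'
#' @slot value information in nats.
#' @slot method one of \code{"closed_form"}, \code{"small_noise"},
#'   \code{"numeric"}.
#' @slot mcStderr Monte-Carlo standard error in nats (0 for closed forms).
#' @slot params list, parameters the value was computed from.
#' @export
setClass("InfoResult",
  slots = c(value = "numeric", method = "character", mcStderr = "numeric",
            params = "list"))

setValidity("InfoResult", function(object) {
  msg <- character()
  if (!object@method %in% c("closed_form", "small_noise", "numeric"))
    msg <- c(msg, "unknown 'method'")
  if (length(object@mcStderr) != 1L || object@mcStderr < 0)
    msg <- c(msg, "'mcStderr' must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

InfoResult <- function(value, method, mcStderr = 0, params = list()) {
  new("InfoResult", value = as.numeric(value), method = method,
      mcStderr = as.numeric(mcStderr), params = params)
}

#' Binned neighbor-difference noise estimate
#'
#' Per-AP-bin root-mean-square difference between the expression of a nucleus
#' and its immediate dorsal/ventral neighbor, for one gene. Under independent
#' per-nucleus noise the per-nucleus SD is \code{rms / sqrt(2)}. Bins with
#' fewer than two neighbor pairs are flagged missing (\code{NA}). When the
#' estimate combines several embryo replicates, \code{replicateSD} holds the
#' across-embryo standard deviation of the per-bin SD.
#'
#' @slot gene gene name.
#' @slot breaks bin boundaries along the AP axis.
#' @slot mid bin midpoints.
#' @slot rms per-bin RMS neighbor difference.
#' @slot sd per-bin per-nucleus SD estimate (\code{rms/sqrt(2)}).
#' @slot nPairs per-bin number of neighbor pairs.
#' @slot replicateSD across-replicate SD of the per-bin SD (NA for a single
#'   table).
#' @slot nReplicates number of embryos combined.
#' @export
setClass("NoiseProfileEstimate",
  slots = c(gene = "character", breaks = "numeric", mid = "numeric",
            rms = "numeric", sd = "numeric", nPairs = "integer",
            replicateSD = "numeric", nReplicates = "integer"))

#' Crossing of the triplet curve and the noiseless-pair bound
#'
#' Holds the two accessible-information curves evaluated on a common readout
#' noise grid — the best-case bound from the hypothetically noiseless input
#' pair, and the accessible information of the full triplet with its measured
#' noise — together with the smallest readout noise at which the triplet curve
#' meets or exceeds the bound (NA if no crossing occurs on the grid). The
#' bound diverges as the readout noise approaches zero; grid entries where it
#' is infinite are reported as \code{Inf} and flagged, never interpolated
#' through.
#'
#' @slot eta0 readout-noise grid.
#' @slot boundBits noiseless-pair bound, bits (possibly \code{Inf}).
#' @slot tripletBits triplet accessible information, bits.
#' @slot crossing smallest crossing eta0, or \code{NA_real_}.
#' @slot bracket grid interval bracketing the crossing (NA if none or if the
#'   crossing sits on the first grid point).
#' @export
setClass("CrossingResult",
  slots = c(eta0 = "numeric", boundBits = "numeric", tripletBits = "numeric",
            crossing = "numeric", bracket = "numeric"))
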