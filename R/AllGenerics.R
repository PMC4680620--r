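#' @rdname InfoResult-class
#' @param object,x an object.
#' @export
setGeneric("valueNats", function(x) standardGeneric("valueNats"))

#' @rdname InfoResult-class
#' @export
setGeneric("valueBits", function(x) standardGeneric("valueBits"))

#' @rdname InfoResult-class
#' @export
setGeneric("mcStderr", function(x) standardGeneric("mcStderr"))

#' @rdname InfoResult-class
#' @export
setGeneric("infoMethod", function(x) standardGeneric("infoMethod"))

#' @rdname NucleusTable-class
#' @export
setGeneric("apPosition", function(x) standardGeneric("apPosition"))

#' @rdname NucleusTable-class
#' @export
setGeneric("dvIndex", function(x) standardGeneric("dvIndex"))

#' @rdname NucleusTable-class
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname ProfileSet-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname CrossingResult-class
#' @export
setGeneric("crossingPoint", function(x) standardGeneric("crossingPoint"))

#' @describeIn InfoResult-class information in nats.
setMethod("valueNats", "InfoResult", function(x) x@value)

#' @describeIn InfoResult-class information in bits (\code{value / ln 2}).
setMethod("valueBits", "InfoResult", function(x) x@value / log(2))

#' @describeIn InfoResult-class Monte-Carlo standard error in nats.
setMethod("mcStderr", "InfoResult", function(x) x@mcStderr)

#' @describeIn InfoResult-class how the value was obtained.
setMethod("infoMethod", "InfoResult", function(x) x@method)

#' @describeIn NucleusTable-class normalized AP position per nucleus.
setMethod("apPosition", "NucleusTable",
  function(x) SummarizedExperiment::colData(x)$x_ap)

#' @describeIn NucleusTable-class DV column index per nucleus.
setMethod("dvIndex", "NucleusTable",
  function(x) SummarizedExperiment::colData(x)$dv_index)

#' @describeIn NucleusTable-class gene names (assay rownames).
setMethod("geneNames", "NucleusTable", function(x) rownames(x))

#' @describeIn ProfileSet-class names of the channels in the set.
setMethod("channelNames", "ProfileSet", function(x) names(x@channels))

#' @describeIn CrossingResult-class the crossing readout noise
#'   (\code{NA_real_} when the curves do not cross on the grid).
setMethod("crossingPoint", "CrossingResult", function(x) x@crossing)
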