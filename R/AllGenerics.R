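#' Accessors for plsperm classes
#'
#' Small accessor generics used throughout the package:
#' \describe{
#'   \item{\code{xBlock}, \code{yBlock}}{the two data matrices of a
#'     [TwoBlockDataset-class].}
#'   \item{\code{nObs}}{number of matched observations.}
#'   \item{\code{featureNamesX}, \code{featureNamesY}}{column labels of
#'     the two blocks.}
#'   \item{\code{leftVectors}, \code{rightVectors}}{U and V of a
#'     [PLSDecomposition-class].}
#'   \item{\code{singularValues}, \code{covarianceExplained},
#'     \code{numLV}}{strength summaries of a decomposition.}
#'   \item{\code{nullValues}, \code{pValues}, \code{observedValues},
#'     \code{rotationMethod}}{components of a
#'     [NullDistributions-class].}
#'   \item{\code{canonicalCorrelation}}{the embedded first-pair
#'     canonical correlation of a [JointCorrelationModel-class].}
#'   \item{\code{jointMatrix}}{the assembled (p+q) x (p+q) population
#'     correlation matrix of a model.}
#'   \item{\code{stabilityX}, \code{stabilityY}}{per-split absolute
#'     correlations of a [StabilityResult-class].}
#'   \item{\code{bootstrapRatios}, \code{behaviourLoadings},
#'     \code{loadingCI}}{components of a [BootstrapResult-class].}
#' }
#'
#' @param object an object of the matching class.
#' @return The corresponding slot value (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("xBlock", function(object) standardGeneric("xBlock"))
#' @rdname accessors
#' @export
setGeneric("yBlock", function(object) standardGeneric("yBlock"))
#' @rdname accessors
#' @export
setGeneric("nObs", function(object) standardGeneric("nObs"))
#' @rdname accessors
#' @export
setGeneric("featureNamesX", function(object) standardGeneric("featureNamesX"))
#' @rdname accessors
#' @export
setGeneric("featureNamesY", function(object) standardGeneric("featureNamesY"))
#' @rdname accessors
#' @export
setGeneric("leftVectors", function(object) standardGeneric("leftVectors"))
#' @rdname accessors
#' @export
setGeneric("rightVectors", function(object) standardGeneric("rightVectors"))
#' @rdname accessors
#' @export
setGeneric("singularValues", function(object) standardGeneric("singularValues"))
#' @rdname accessors
#' @export
setGeneric("covarianceExplained",
           function(object) standardGeneric("covarianceExplained"))
#' @rdname accessors
#' @export
setGeneric("numLV", function(object) standardGeneric("numLV"))
#' @rdname accessors
#' @export
setGeneric("nullValues", function(object) standardGeneric("nullValues"))
#' @rdname accessors
#' @export
setGeneric("pValues", function(object) standardGeneric("pValues"))
#' @rdname accessors
#' @export
setGeneric("observedValues", function(object) standardGeneric("observedValues"))
#' @rdname accessors
#' @export
setGeneric("rotationMethod", function(object) standardGeneric("rotationMethod"))
#' @rdname accessors
#' @export
setGeneric("canonicalCorrelation",
           function(object) standardGeneric("canonicalCorrelation"))
#' @rdname accessors
#' @export
setGeneric("jointMatrix", function(object) standardGeneric("jointMatrix"))
#' @rdname accessors
#' @export
setGeneric("stabilityX", function(object) standardGeneric("stabilityX"))
#' @rdname accessors
#' @export
setGeneric("stabilityY", function(object) standardGeneric("stabilityY"))
#' @rdname accessors
#' @export
setGeneric("bootstrapRatios", function(object) standardGeneric("bootstrapRatios"))
#' @rdname accessors
#' @export
setGeneric("behaviourLoadings",
           function(object) standardGeneric("behaviourLoadings"))
#' @rdname accessors
#' @export
setGeneric("loadingCI", function(object) standardGeneric("loadingCI"))
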