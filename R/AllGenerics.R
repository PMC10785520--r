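#' @import methods
#' @importFrom stats cor predict rnbinom rpois runif rnorm var sd quantile
#' @importFrom utils head read.table write.table packageVersion
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Matrix Matrix
NULL

#' @export
setGeneric("anchorOne", function(x) standardGeneric("anchorOne"))

#' @export
setGeneric("anchorTwo", function(x) standardGeneric("anchorTwo"))

#' @export
setGeneric("strength", function(x) standardGeneric("strength"))

#' @export
setGeneric("strength<-", function(x, value) standardGeneric("strength<-"))

#' @export
setGeneric("reads", function(x) standardGeneric("reads"))

#' @export
setGeneric("chromTotals", function(x) standardGeneric("chromTotals"))

#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @export
setGeneric("contactMatrix", function(x) standardGeneric("contactMatrix"))

#' @export
setGeneric("schemaColumns", function(x) standardGeneric("schemaColumns"))

#' @export
setGeneric("schemaMode", function(x) standardGeneric("schemaMode"))

#' @export
setGeneric("modelVariant", function(x) standardGeneric("modelVariant"))

#' @export
setGeneric("modelSchema", function(x) standardGeneric("modelSchema"))

#' @export
setGeneric("predictStrength", function(object, x, ...)
    standardGeneric("predictStrength"))
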