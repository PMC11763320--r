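#' @rdname AmpliconPanel-class
#' @export
setGeneric("cpgSites", function(x) standardGeneric("cpgSites"))

#' @rdname AmpliconPanel-class
#' @export
setGeneric("ampliconSeqs", function(x) standardGeneric("ampliconSeqs"))

#' @rdname AmpliconPanel-class
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname SiteCountMatrix-class
#' @export
setGeneric("retainedSites", function(x) standardGeneric("retainedSites"))

#' @rdname SiteCountMatrix-class
#' @export
setGeneric("normFactors", function(x) standardGeneric("normFactors"))

#' @rdname SiteCountMatrix-class
#' @export
setGeneric("conversionRate", function(x) standardGeneric("conversionRate"))

#' @rdname geneMethylation
#' @export
setGeneric("geneMethylation",
           function(x, type = c("pooled", "mean"), percent = TRUE)
               standardGeneric("geneMethylation"))

#' @rdname StandardCurve-class
#' @export
setGeneric("curveSlope", function(x) standardGeneric("curveSlope"))

#' @rdname StandardCurve-class
#' @export
setGeneric("curveIntercept", function(x) standardGeneric("curveIntercept"))

#' @rdname StandardCurve-class
#' @export
setGeneric("curveEfficiency", function(x) standardGeneric("curveEfficiency"))

#' @rdname StandardCurve-class
#' @export
setGeneric("curveR2", function(x) standardGeneric("curveR2"))
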