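NULL

#' @export
setGeneric("meth", function(object) standardGeneric("meth"))

#' @export
setGeneric("unmeth", function(object) standardGeneric("unmeth"))

#' @export
setGeneric("betaValues", function(object, ...) standardGeneric("betaValues"))

#' @export
setGeneric("chromosomeGroup", function(object) standardGeneric("chromosomeGroup"))

#' @export
setGeneric("designType", function(object) standardGeneric("designType"))

#' @export
setGeneric("sampleSex", function(object) standardGeneric("sampleSex"))

#' @export
setGeneric("chipRow", function(object) standardGeneric("chipRow"))

#' @export
setGeneric("methodId", function(object) standardGeneric("methodId"))

#' @export
setGeneric("interpolatedProbes", function(object) standardGeneric("interpolatedProbes"))

#' @export
setGeneric("normParameters", function(object) standardGeneric("normParameters"))
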