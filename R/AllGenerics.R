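#' @export
setGeneric("clones", function(x, ...) standardGeneric("clones"))

#' @export
setGeneric("cloneRecords", function(x, ...) standardGeneric("cloneRecords"))

#' @export
setGeneric("cloneParams", function(x) standardGeneric("cloneParams"))

#' @export
setGeneric("nClones", function(x) standardGeneric("nClones"))

#' @export
setGeneric("vSegments", function(x) standardGeneric("vSegments"))

#' @export
setGeneric("jSegments", function(x) standardGeneric("jSegments"))

#' @export
setGeneric("jaccard", function(x) standardGeneric("jaccard"))

#' @export
setGeneric("cosine", function(x) standardGeneric("cosine"))

#' @export
setGeneric("vennRegions", function(x) standardGeneric("vennRegions"))

#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))
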