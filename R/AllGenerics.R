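#' @rdname RegulatoryNetwork-class
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname RegulatoryNetwork-class
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))

#' @rdname RegulatoryNetwork-class
#' @export
setGeneric("numNodes", function(object) standardGeneric("numNodes"))

#' @rdname RegulatoryNetwork-class
#' @export
setGeneric("numEdges", function(object) standardGeneric("numEdges"))

#' @rdname RegulatoryNetwork-class
#' @export
setGeneric("aggregationRule", function(object) standardGeneric("aggregationRule"))

#' @rdname RegulatoryNetwork-class
#' @export
setGeneric("nodeAnnotations", function(object) standardGeneric("nodeAnnotations"))

#' @rdname addInteraction
#' @export
setGeneric("addInteraction",
  function(object, source, target, weight, promoter = NA_character_)
    standardGeneric("addInteraction"))

#' @rdname addInteraction
#' @export
setGeneric("addInteractions",
  function(object, records) standardGeneric("addInteractions"))

#' @rdname degrees
#' @export
setGeneric("degrees", function(object) standardGeneric("degrees"))

#' @rdname tfSubnetwork
#' @export
setGeneric("tfSubnetwork", function(object) standardGeneric("tfSubnetwork"))

#' @rdname targetSubnetwork
#' @export
setGeneric("targetSubnetwork",
  function(object, sources) standardGeneric("targetSubnetwork"))

#' @rdname EdgeProvider-class
#' @export
setGeneric("regulatorsOf", function(provider, gene) standardGeneric("regulatorsOf"))

#' @rdname EdgeProvider-class
#' @export
setGeneric("targetsOf", function(provider, gene) standardGeneric("targetsOf"))

#' @rdname EdgeProvider-class
#' @export
setGeneric("providerCalls", function(provider) standardGeneric("providerCalls"))
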