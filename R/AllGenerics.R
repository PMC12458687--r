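#' @export
setGeneric("atoms", function(x, ...) standardGeneric("atoms"))

#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @export
setGeneric("polymerResidues", function(x) standardGeneric("polymerResidues"))

#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @export
setGeneric("modelKind", function(x) standardGeneric("modelKind"))

#' @export
setGeneric("spheres", function(x) standardGeneric("spheres"))

#' @export
setGeneric("nPockets", function(x) standardGeneric("nPockets"))

#' @export
setGeneric("pocketIds", function(x) standardGeneric("pocketIds"))

#' @export
setGeneric("contactAtoms", function(x, pocket) standardGeneric("contactAtoms"))

#' @export
setGeneric("contactResidues", function(x, pocket) standardGeneric("contactResidues"))

#' @export
setGeneric("descriptorRows", function(x) standardGeneric("descriptorRows"))

#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @export
setGeneric("compId", function(x) standardGeneric("compId"))

#' @export
setGeneric("centerOfMass", function(x) standardGeneric("centerOfMass"))

#' @export
setGeneric("featureOrder", function(x) standardGeneric("featureOrder"))

#' @export
setGeneric("scoreThreshold", function(x) standardGeneric("scoreThreshold"))
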