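#' @rdname additiveMatrix
#' @export
setGeneric("additiveMatrix", function(ped, ...) standardGeneric("additiveMatrix"))

#' @rdname inbreeding
#' @export
setGeneric("inbreeding", function(ped) standardGeneric("inbreeding"))

#' @rdname founders
#' @export
setGeneric("founders", function(ped) standardGeneric("founders"))

#' @rdname nIndividuals
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname ids
#' @export
setGeneric("ids", function(x) standardGeneric("ids"))

#' @rdname culturalRelatednessMatrix
#' @export
setGeneric("culturalRelatednessMatrix",
           function(cped, ...) standardGeneric("culturalRelatednessMatrix"))

#' @rdname cultureIdentityMatrix
#' @export
setGeneric("cultureIdentityMatrix",
           function(cped) standardGeneric("cultureIdentityMatrix"))

#' @rdname cultures
#' @export
setGeneric("cultures", function(x) standardGeneric("cultures"))

#' @rdname heritabilities
#' @export
setGeneric("heritabilities", function(fit) standardGeneric("heritabilities"))
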