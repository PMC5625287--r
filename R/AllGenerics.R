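#' @title Accessor generics
#' @description Small accessor generics shared by the package's containers.
#' @param object a package object
#' @param value replacement value
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("speciesLabels", function(object) standardGeneric("speciesLabels"))

#' @rdname accessors
#' @export
setGeneric("speciesList", function(object) standardGeneric("speciesList"))

#' @rdname accessors
#' @export
setGeneric("reactionList", function(object) standardGeneric("reactionList"))

#' @rdname accessors
#' @export
setGeneric("reactionLabels", function(object) standardGeneric("reactionLabels"))

#' @rdname accessors
#' @export
setGeneric("nSpecies", function(object) standardGeneric("nSpecies"))

#' @rdname accessors
#' @export
setGeneric("nReactions", function(object) standardGeneric("nReactions"))

#' @rdname accessors
#' @export
setGeneric("stoichMatrix", function(object) standardGeneric("stoichMatrix"))

#' @rdname accessors
#' @export
setGeneric("rates", function(object) standardGeneric("rates"))

#' @rdname accessors
#' @export
setGeneric("rates<-", function(object, value) standardGeneric("rates<-"))

#' @rdname accessors
#' @export
setGeneric("deltaT", function(object) standardGeneric("deltaT"))

#' @rdname accessors
#' @export
setGeneric("countsMatrix", function(object) standardGeneric("countsMatrix"))

#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))
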