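#' Accessor generics
#'
#' Small accessor generics shared by the package's S4 result classes.
#'
#' @param object an \code{atheroBMA} S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cohortCases", function(object) standardGeneric("cohortCases"))

#' @rdname accessors
#' @export
setGeneric("cohortPlasma", function(object) standardGeneric("cohortPlasma"))

#' @rdname accessors
#' @export
setGeneric("cohortProteins", function(object) standardGeneric("cohortProteins"))

#' @rdname accessors
#' @export
setGeneric("cohortHistology", function(object) standardGeneric("cohortHistology"))

#' @rdname accessors
#' @export
setGeneric("outcomeMatrix", function(object) standardGeneric("outcomeMatrix"))

#' @rdname accessors
#' @export
setGeneric("predictorMatrix", function(object) standardGeneric("predictorMatrix"))

#' @rdname accessors
#' @export
setGeneric("variableCatalog", function(object) standardGeneric("variableCatalog"))

#' @rdname accessors
#' @export
setGeneric("inclusionProb", function(object) standardGeneric("inclusionProb"))

#' @rdname accessors
#' @export
setGeneric("avgCoefficient", function(object) standardGeneric("avgCoefficient"))

#' @rdname accessors
#' @export
setGeneric("retainedVariables", function(object) standardGeneric("retainedVariables"))

#' @rdname accessors
#' @export
setGeneric("modelTable", function(object) standardGeneric("modelTable"))

#' @rdname accessors
#' @export
setGeneric("selectedFlags", function(object) standardGeneric("selectedFlags"))

#' @rdname accessors
#' @export
setGeneric("selectionCoefficients", function(object) standardGeneric("selectionCoefficients"))

#' @rdname accessors
#' @export
setGeneric("ledgerTable", function(object) standardGeneric("ledgerTable"))
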