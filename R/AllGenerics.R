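#' @name favshift-generics
#' @title Accessor generics for favshift classes
#' @description Small accessor generics shared by the S4 containers:
#'   grid geometry, layer access and presence/background bookkeeping.
#' @param x a favshift S4 object
#' @param object a favshift S4 object
#' @param ... passed on to methods
NULL

#' @rdname favshift-generics
#' @export
setGeneric("gridDef", function(x) standardGeneric("gridDef"))

#' @rdname favshift-generics
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' @rdname favshift-generics
#' @export
setGeneric("layerValues", function(x, layer) standardGeneric("layerValues"))

#' @rdname favshift-generics
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname favshift-generics
#' @export
setGeneric("nPresence", function(x) standardGeneric("nPresence"))

#' @rdname favshift-generics
#' @export
setGeneric("nBackground", function(x) standardGeneric("nBackground"))

#' @rdname favshift-generics
#' @export
setGeneric("prevalence", function(x) standardGeneric("prevalence"))

#' Predict presence probability from a fitted model
#'
#' Applies the inverse-logit of the fitted linear predictor to new data:
#' either an [EnvStack-class] of named layers (returning a per-cell matrix)
#' or a data frame / [ModelFrame-class] with one column per model variable
#' (returning a vector).
#'
#' @param model a [FavorabilityModel-class]
#' @param newdata an [EnvStack-class], [ModelFrame-class] or data.frame
#'   providing every model variable
#' @param ... passed on to methods
#' @return probabilities in (0, 1); matrix for stacks, vector otherwise
#' @export
setGeneric("predictProbability",
           function(model, newdata, ...) standardGeneric("predictProbability"))
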