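#' @rdname DecisionTable-accessors
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))

#' @rdname DecisionTable-accessors
#' @export
setGeneric("objectIds", function(x) standardGeneric("objectIds"))

#' @rdname DecisionTable-accessors
#' @export
setGeneric("decisions", function(x) standardGeneric("decisions"))

#' @rdname DecisionTable-accessors
#' @export
setGeneric("conditionValues", function(x) standardGeneric("conditionValues"))

#' @rdname DecisionTable-accessors
#' @export
setGeneric("attributeInfo", function(x) standardGeneric("attributeInfo"))

#' @rdname DecisionTable-accessors
#' @export
setGeneric("tableMetadata", function(x) standardGeneric("tableMetadata"))

#' @rdname rules-accessors
#' @export
setGeneric("rules", function(x) standardGeneric("rules"))

#' Classify objects with a rule ensemble
#'
#' @param object a [RuleEnsemble-class] (or a [RuleSet-class] wrapped into a
#'   single-bag ensemble).
#' @param newdata a data.frame of condition-attribute values, or a
#'   [DecisionTable-class].
#' @param ... further arguments passed to methods.
#' @return integer vector of predicted class labels.
#' @export
setGeneric("classify", function(object, newdata, ...) standardGeneric("classify"))
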