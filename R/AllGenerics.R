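#' @rdname generator
#' @export
setGeneric("generator", function(x) standardGeneric("generator"))

#' @rdname transient
#' @export
setGeneric("transient", function(x, t, ...) standardGeneric("transient"))

#' @rdname embed-ctmc
#' @export
setGeneric("embed", function(x) standardGeneric("embed"))

#' @rdname rateMatrix
#' @export
setGeneric("rateMatrix", function(model) standardGeneric("rateMatrix"))

#' @rdname transitionProbability
#' @export
setGeneric("transitionProbability",
           function(model, i, j, d) standardGeneric("transitionProbability"))

#' @rdname prune
#' @export
setGeneric("prune", function(tree, model, ...) standardGeneric("prune"))

#' @rdname checkFormula
#' @export
setGeneric("checkFormula",
           function(x, formula, ...) standardGeneric("checkFormula"))

#' @rdname accessors
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' @rdname accessors
#' @export
setGeneric("rates", function(x) standardGeneric("rates"))

#' @rdname accessors
#' @export
setGeneric("labeling", function(x) standardGeneric("labeling"))

#' @rdname accessors
#' @export
setGeneric("initialStates", function(x) standardGeneric("initialStates"))

#' @rdname accessors
#' @export
setGeneric("exitRates", function(x) standardGeneric("exitRates"))

#' @rdname accessors
#' @export
setGeneric("jumpProbs", function(x) standardGeneric("jumpProbs"))

#' @rdname tree-accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname tree-accessors
#' @export
setGeneric("leafIds", function(x) standardGeneric("leafIds"))

#' @rdname tree-accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname tree-accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname tree-accessors
#' @export
setGeneric("branchLengths", function(x) standardGeneric("branchLengths"))

#' @rdname likelihood-accessors
#' @export
setGeneric("siteLikelihoods", function(x) standardGeneric("siteLikelihoods"))

#' @rdname likelihood-accessors
#' @export
setGeneric("totalLikelihood", function(x) standardGeneric("totalLikelihood"))

#' @rdname likelihood-accessors
#' @export
setGeneric("logLikelihood", function(x) standardGeneric("logLikelihood"))

#' @rdname likelihood-accessors
#' @export
setGeneric("partialLikelihoods",
           function(x, node) standardGeneric("partialLikelihoods"))

#' @rdname satresult-accessors
#' @export
setGeneric("satStates", function(x) standardGeneric("satStates"))

#' @rdname satresult-accessors
#' @export
setGeneric("stateProbs", function(x) standardGeneric("stateProbs"))
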