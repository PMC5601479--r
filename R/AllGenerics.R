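#' @rdname featureMatrix
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname featureMatrix
#' @export
setGeneric("survTimes", function(x) standardGeneric("survTimes"))

#' @rdname featureMatrix
#' @export
setGeneric("survEvents", function(x) standardGeneric("survEvents"))

#' @rdname featureMatrix
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @rdname featureMatrix
#' @export
setGeneric("featureKinds", function(x) standardGeneric("featureKinds"))

#' @rdname predictRisk
#' @export
setGeneric("predictRisk", function(object, ds, ...) standardGeneric("predictRisk"))

#' @rdname featureRiskScores
#' @export
setGeneric("riskScores", function(x) standardGeneric("riskScores"))

#' @rdname optimizeHyperparameters
#' @export
setGeneric("bestConfig", function(x) standardGeneric("bestConfig"))

#' @rdname optimizeHyperparameters
#' @export
setGeneric("evaluations", function(x) standardGeneric("evaluations"))
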