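#' @rdname LungModel-class
#' @param x,object a package object
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))

#' @rdname LungModel-class
#' @export
setGeneric("lowerLobeTAR", function(x) standardGeneric("lowerLobeTAR"))

#' @rdname LungModel-class
#' @export
setGeneric("denominatorConvention",
           function(x) standardGeneric("denominatorConvention"))

#' @rdname PlanSelection-class
#' @export
setGeneric("isFeasible", function(x) standardGeneric("isFeasible"))

#' @rdname PlanSelection-class
#' @export
setGeneric("chosenOption", function(x) standardGeneric("chosenOption"))

#' @rdname PlanSelection-class
#' @export
setGeneric("planAudit", function(x) standardGeneric("planAudit"))

#' @rdname PlanSelection-class
#' @export
setGeneric("diseaseRank", function(x) standardGeneric("diseaseRank"))

#' @rdname EligibilityDecision-class
#' @export
setGeneric("isEligible", function(x) standardGeneric("isEligible"))

#' @rdname EligibilityDecision-class
#' @export
setGeneric("criteriaTable", function(x) standardGeneric("criteriaTable"))

#' @rdname EligibilityDecision-class
#' @export
setGeneric("failedCriteria", function(x) standardGeneric("failedCriteria"))
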