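#' @import methods
NULL

#' Frame schedule accessors
#'
#' Start, end and midpoint times (minutes post injection) of the frames of a
#' \linkS4class{TimeActivityCurve}.
#'
#' @param x A \linkS4class{TimeActivityCurve}.
#' @return Numeric vector of times in minutes.
#' @export
#' @rdname frame-accessors
setGeneric("frameStart", function(x) standardGeneric("frameStart"))

#' @export
#' @rdname frame-accessors
setGeneric("frameEnd", function(x) standardGeneric("frameEnd"))

#' @export
#' @rdname frame-accessors
setGeneric("frameMid", function(x) standardGeneric("frameMid"))

#' @export
#' @rdname frame-accessors
setGeneric("frameLength", function(x) standardGeneric("frameLength"))

#' Activity matrix of a time-activity curve
#'
#' @param x A \linkS4class{TimeActivityCurve}.
#' @return Numeric matrix, frames in rows, regions in columns, kBq/mL.
#' @export
setGeneric("activity", function(x) standardGeneric("activity"))

#' Region names of a multi-region object
#'
#' @param x A \linkS4class{TimeActivityCurve}.
#' @return Character vector.
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))

#' Common time grid of an input-function set
#'
#' @param x An \linkS4class{InputFunctionSet}.
#' @return Numeric vector, minutes.
#' @export
setGeneric("timeGrid", function(x) standardGeneric("timeGrid"))

#' Blood curve accessors
#'
#' Whole-blood, parent (6-FDOPA) plasma, metabolite (3-OMFD) plasma and
#' parent-fraction curves of an \linkS4class{InputFunctionSet}, on its common
#' time grid.
#'
#' @param x An \linkS4class{InputFunctionSet}.
#' @return Numeric vector (kBq/mL, or dimensionless for the parent fraction).
#' @export
#' @rdname blood-accessors
setGeneric("wholeBlood", function(x) standardGeneric("wholeBlood"))

#' @export
#' @rdname blood-accessors
setGeneric("plasmaParent", function(x) standardGeneric("plasmaParent"))

#' @export
#' @rdname blood-accessors
setGeneric("plasmaMetabolite", function(x) standardGeneric("plasmaMetabolite"))

#' @export
#' @rdname blood-accessors
setGeneric("parentFraction", function(x) standardGeneric("parentFraction"))

#' Noise-free net-influx constant implied by kinetic parameters
#'
#' For the irreversible two-tissue compartment model the net influx constant
#' is \eqn{K_i = K_1 k_3 / (k_2 + k_3)} (1/min).
#'
#' @param x A \linkS4class{KineticParams} object.
#' @return Numeric, 1/min.
#' @export
setGeneric("trueKi", function(x) standardGeneric("trueKi"))

#' Design matrix of a GLM design or fit
#'
#' @param x A \linkS4class{GlmDesign} or \linkS4class{GlmFit}.
#' @return Numeric matrix, frames in rows.
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))

#' Reconstructed per-regressor signal components of a GLM fit
#'
#' @param x A \linkS4class{GlmFit}.
#' @return Matrix (frames x regressors): each column is the design column
#'   multiplied by its coefficient, in kBq/mL.
#' @export
setGeneric("fittedComponents", function(x) standardGeneric("fittedComponents"))
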