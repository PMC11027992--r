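#' @import methods
NULL

#' Accessor generics
#'
#' Small accessor generics for the core data containers: the signal matrix,
#' sampling rate, channel labels and channel-to-region map of an
#' \linkS4class{EEGRecording}, and the identifier, marker value and group
#' label of a \linkS4class{SubjectRecord}.
#'
#' @param x an object.
#' @return The corresponding slot value.
#' @name accessors
#' @aliases eegData samplingRate channelNames regionMap subjectId abetaRatio
#'   groupLabel
NULL

#' @rdname accessors
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("regionMap", function(x) standardGeneric("regionMap"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("abetaRatio", function(x) standardGeneric("abetaRatio"))

#' @rdname accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' Feature-set accessor generics
#'
#' @param x an \linkS4class{AbetaFeatureSet}.
#' @return \code{featureMatrix} returns the subjects x features numeric
#'   matrix; \code{targetRatio} the per-subject marker value;
#'   \code{featureModalities} the modality prefix of every feature.
#' @name featureset-accessors
#' @aliases featureMatrix targetRatio featureModalities
NULL

#' @rdname featureset-accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname featureset-accessors
#' @export
setGeneric("targetRatio", function(x) standardGeneric("targetRatio"))

#' @rdname featureset-accessors
#' @export
setGeneric("featureModalities", function(x) standardGeneric("featureModalities"))
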