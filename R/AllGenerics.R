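#' @rdname DDPInstance-accessors
#' @export
setGeneric("fragmentsA", function(x) standardGeneric("fragmentsA"))

#' @rdname DDPInstance-accessors
#' @export
setGeneric("fragmentsB", function(x) standardGeneric("fragmentsB"))

#' @rdname DDPInstance-accessors
#' @export
setGeneric("fragmentsC", function(x) standardGeneric("fragmentsC"))

#' @rdname DDPInstance-accessors
#' @export
setGeneric("instanceName", function(x) standardGeneric("instanceName"))

#' @rdname DDPInstance-accessors
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))

#' @rdname validateInstance
#' @export
setGeneric("validateInstance", function(x) standardGeneric("validateInstance"))

#' @rdname padToCanonical
#' @export
setGeneric("padToCanonical", function(x) standardGeneric("padToCanonical"))

#' @rdname evolveDDP
#' @export
setGeneric("evolveDDP",
  function(instance, config = GAConfig(), ...) standardGeneric("evolveDDP"))

#' @rdname runTrials
#' @export
setGeneric("runTrials",
  function(instance, config = GAConfig(), nTrials = 20L, ...)
    standardGeneric("runTrials"))
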