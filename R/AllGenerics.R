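#' @rdname filterInstances
#' @export
setGeneric("filterInstances", function(ps, ...) standardGeneric("filterInstances"))

#' @rdname selectHighestConcentration
#' @export
setGeneric("selectHighestConcentration",
           function(ps, ...) standardGeneric("selectHighestConcentration"))

#' @rdname meanCenterBatch
#' @export
setGeneric("meanCenterBatch", function(ps, ...) standardGeneric("meanCenterBatch"))

#' @rdname controlCenterBatch
#' @export
setGeneric("controlCenterBatch",
           function(ps, ...) standardGeneric("controlCenterBatch"))

#' @rdname mergeReplicates
#' @export
setGeneric("mergeReplicates", function(ps, ...) standardGeneric("mergeReplicates"))

#' @rdname assignPresence
#' @export
setGeneric("assignPresence", function(ps, ...) standardGeneric("assignPresence"))

#' Accessors for compendium objects
#'
#' `drugIds()` returns the drug of every treatment instance (or profile);
#' `batchIds()`, `cellLines()` and `isControl()` return the corresponding
#' metadata columns; `exprValues()` and `callValues()` return the expression
#' and detection-call assays; `amplitudeValues()` the profile matrix.
#'
#' @param x a [PerturbationSet-class] or [AmplitudeProfiles-class].
#' @return vector or matrix, see details.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))
#' @rdname accessors
#' @export
setGeneric("batchIds", function(x) standardGeneric("batchIds"))
#' @rdname accessors
#' @export
setGeneric("cellLines", function(x) standardGeneric("cellLines"))
#' @rdname accessors
#' @export
setGeneric("isControl", function(x) standardGeneric("isControl"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("callValues", function(x) standardGeneric("callValues"))
#' @rdname accessors
#' @export
setGeneric("amplitudeValues", function(x) standardGeneric("amplitudeValues"))

#' @rdname accessors
setMethod("drugIds", "PerturbationSet",
          function(x) as.character(colData(x)$drug_id))
#' @rdname accessors
setMethod("batchIds", "PerturbationSet",
          function(x) as.character(colData(x)$batch_id))
#' @rdname accessors
setMethod("cellLines", "PerturbationSet",
          function(x) unique(as.character(colData(x)$cell_line)))
#' @rdname accessors
setMethod("isControl", "PerturbationSet",
          function(x) as.logical(colData(x)$is_control))
#' @rdname accessors
setMethod("exprValues", "PerturbationSet", function(x) assay(x, "exprs"))
#' @rdname accessors
setMethod("callValues", "PerturbationSet", function(x) {
  if (!("calls" %in% assayNames(x)))
    stop("this PerturbationSet carries no detection calls")
  assay(x, "calls")
})
#' @rdname accessors
setMethod("drugIds", "AmplitudeProfiles",
          function(x) as.character(colData(x)$drug_id))
#' @rdname accessors
setMethod("cellLines", "AmplitudeProfiles",
          function(x) unique(as.character(colData(x)$cell_line)))
#' @rdname accessors
setMethod("amplitudeValues", "AmplitudeProfiles",
          function(x) assay(x, "amplitude"))
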