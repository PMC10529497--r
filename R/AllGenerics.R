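# Accessor generics. Slot access from user code is discouraged; these are
# the supported surface.

#' @rdname accessors
#' @param x a boneTexture object.
#' @export
setGeneric("cohortData", function(x) standardGeneric("cohortData"))

#' @rdname accessors
#' @export
setGeneric("cohortImages", function(x) standardGeneric("cohortImages"))

#' @rdname accessors
#' @export
setGeneric("targetNames", function(x) standardGeneric("targetNames"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("glcmMatrix", function(x) standardGeneric("glcmMatrix"))

#' @rdname accessors
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))

#' @rdname accessors
#' @export
setGeneric("modelBias", function(x) standardGeneric("modelBias"))

#' @rdname accessors
#' @export
setGeneric("selectionCounts", function(x) standardGeneric("selectionCounts"))

#' @rdname accessors
#' @export
setGeneric("selectionTop", function(x) standardGeneric("selectionTop"))

#' @rdname accessors
#' @export
setGeneric("selectionCorrelations",
           function(x) standardGeneric("selectionCorrelations"))

#' Accessors for boneTexture objects
#'
#' \code{cohortData} returns the per-row metadata of a [BoneCohort-class]
#' (or the \code{colData} of a [TextureExperiment-class]);
#' \code{cohortImages} the list of HU matrices; \code{targetNames} the
#' reference-target column names; \code{featureMatrix} the samples x
#' features matrix of a [TextureExperiment-class]; \code{glcmMatrix} the
#' normalised co-occurrence matrix of a [GLCM-class]; \code{modelWeights}
#' / \code{modelBias} the coefficients of a [BMDModel-class];
#' \code{selectionCounts}, \code{selectionTop} and
#' \code{selectionCorrelations} the components of a
#' [SelectionResult-class].
#'
#' @param x a boneTexture object.
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setMethod("cohortData", "BoneCohort", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("cohortData", "TextureExperiment", function(x) colData(x))

#' @rdname accessors
#' @export
setMethod("cohortImages", "BoneCohort", function(x) x@images)

#' @rdname accessors
#' @export
setMethod("targetNames", "BoneCohort", function(x) {
    spec <- x@meta$spec
    if (!is.null(spec)) return(spec@targetModel$target)
    setdiff(colnames(x@data),
            c("caseId", "region", "boneFraction", "missingFeature",
              "imagePath", "row0", "col0", "height", "width"))
})

#' @rdname accessors
#' @export
setMethod("targetNames", "TextureExperiment", function(x) {
    tn <- metadata(x)$targetNames
    if (is.null(tn)) character(0) else tn
})

#' @rdname accessors
#' @export
setMethod("featureMatrix", "TextureExperiment", function(x) {
    t(assay(x, "features"))
})

#' @rdname accessors
#' @export
setMethod("glcmMatrix", "GLCM", function(x) x@p)

#' @rdname accessors
#' @export
setMethod("modelWeights", "BMDModel", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("modelBias", "BMDModel", function(x) x@bias)

#' @rdname accessors
#' @export
setMethod("selectionCounts", "SelectionResult", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("selectionTop", "SelectionResult", function(x) x@top)

#' @rdname accessors
#' @export
setMethod("selectionCorrelations", "SelectionResult",
          function(x) x@correlations)
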