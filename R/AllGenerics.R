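#' @rdname SlidePreview-class
#' @param object,x a \linkS4class{SlidePreview} or other package object.
#' @export
setGeneric("previewImage", function(x) standardGeneric("previewImage"))

#' @rdname SlidePreview-class
#' @export
setGeneric("tissueMask", function(x) standardGeneric("tissueMask"))

#' @rdname SlidePreview-class
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname ArtifactOverlay-class
#' @export
setGeneric("overlayPatch", function(x) standardGeneric("overlayPatch"))

#' @rdname ArtifactOverlay-class
#' @export
setGeneric("overlayMask", function(x) standardGeneric("overlayMask"))

#' @rdname ArtifactOverlay-class
#' @export
setGeneric("overlayCategory", function(x) standardGeneric("overlayCategory"))

#' @rdname ArtifactOverlay-class
#' @export
setGeneric("overlayId", function(x) standardGeneric("overlayId"))

#' @rdname ArtifactBank-class
#' @export
setGeneric("overlays", function(x, category = NULL) standardGeneric("overlays"))

#' @rdname ArtifactBank-class
#' @export
setGeneric("categoriesPresent",
           function(x) standardGeneric("categoriesPresent"))

#' @rdname ConfusionCounts-class
#' @export
setGeneric("sensitivity", function(x, ...) standardGeneric("sensitivity"))

#' @rdname ConfusionCounts-class
#' @export
setGeneric("precision", function(x, ...) standardGeneric("precision"))

#' @rdname ConfusionCounts-class
#' @export
setGeneric("f1Score", function(x, ...) standardGeneric("f1Score"))

#' @rdname ConfusionCounts-class
#' @export
setGeneric("iou", function(x, ...) standardGeneric("iou"))
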