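#' @describeIn SlidePreview-class the RGB pixel array (M x N x 3, 0--255).
#' @export
setMethod("previewImage", "SlidePreview", function(x) x@image)

#' @describeIn SlidePreview-class the binary tissue mask or NULL.
#' @export
setMethod("tissueMask", "SlidePreview", function(x) x@mask)

#' @describeIn SlidePreview-class the sample identifier.
#' @export
setMethod("sampleId", "SlidePreview", function(x) x@id)

#' @describeIn ArtifactOverlay-class the canonical white-background patch.
#' @export
setMethod("overlayPatch", "ArtifactOverlay", function(x) x@patch)

#' @describeIn ArtifactOverlay-class the binary foreground mask.
#' @export
setMethod("overlayMask", "ArtifactOverlay", function(x) x@mask)

#' @describeIn ArtifactOverlay-class the artifact category.
#' @export
setMethod("overlayCategory", "ArtifactOverlay", function(x) x@category)

#' @describeIn ArtifactOverlay-class the overlay identifier.
#' @export
setMethod("overlayId", "ArtifactOverlay", function(x) x@overlayId)

#' @describeIn ArtifactBank-class overlays, optionally restricted to one
#'   category.
#' @param category optional category filter.
#' @export
setMethod("overlays", "ArtifactBank", function(x, category = NULL) {
    if (is.null(category)) return(x@overlays)
    stopifnot(category %in% artifactCategories())
    Filter(function(o) o@category %in% category, x@overlays)
})

#' @describeIn ArtifactBank-class the set of categories with at least one
#'   overlay.
#' @export
setMethod("categoriesPresent", "ArtifactBank", function(x)
    sort(unique(vapply(x@overlays, function(o) o@category, character(1)))))

#' @describeIn ArtifactBank-class number of overlays in the bank.
#' @export
setMethod("length", "ArtifactBank", function(x) length(x@overlays))

setMethod("show", "SlidePreview", function(object) {
    d <- dim(object@image)
    cat(sprintf("SlidePreview '%s': %d x %d RGB, tissue mask: %s\n",
                object@id, d[1], d[2],
                if (is.null(object@mask)) "absent" else
                    sprintf("%.1f%% foreground",
                            100 * mean(object@mask > 0))))
})

setMethod("show", "ArtifactOverlay", function(object) {
    d <- dim(object@patch)
    cat(sprintf("ArtifactOverlay '%s' (%s): %d x %d, mask area %d px\n",
                object@overlayId, object@category, d[1], d[2],
                sum(object@mask > 0L)))
})

setMethod("show", "ArtifactBank", function(object) {
    cats <- vapply(object@overlays, function(o) o@category, character(1))
    cat(sprintf("ArtifactBank with %d overlay(s)\n", length(cats)))
    if (length(cats))
        for (cc in sort(unique(cats)))
            cat(sprintf("  %-10s %d\n", cc, sum(cats == cc)))
})

setMethod("show", "ConfusionCounts", function(object) {
    cat(sprintf("ConfusionCounts: TP=%g FP=%g TN=%g FN=%g\n",
                object@tp, object@fp, object@tn, object@fn))
})

setMethod("show", "TransformParams", function(object) {
    cat(sprintf(paste0("TransformParams: scale=%.3f angle=%d mirror=%s ",
                       "hue=%s scratches=%d (f=%.3f) perlin=%.3f ",
                       "intensity=%.3f\n"),
                object@scaleFactor, object@rotationAngle, object@mirrorAxis,
                ifelse(is.na(object@hueValue), "off", object@hueValue),
                object@scratchCount, object@scratchFactor,
                object@perlinWeight, object@intensityFactor))
})

setMethod("show", "Placement", function(object) {
    cat(sprintf("Placement: x0=%d y0=%d cropX=%d cropY=%d\n",
                object@x0, object@y0, object@cropX, object@cropY))
})
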