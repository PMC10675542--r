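#' @import methods
NULL

#' Artifact categories
#'
#' The four artifact classes handled by the overlay augmentation method:
#' felt-pen markings drawn on the glass, air bubbles trapped in the covering
#' glue, speckles of dirt, and slide brand marks.
#'
#' @return Character vector of the category names.
#' @export
artifactCategories <- function() c("felt_pen", "bubble", "dirt", "brand_mark")

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

.validPixels <- function(px, what) {
    if (!is.array(px) || length(dim(px)) != 3L || dim(px)[3] != 3L)
        return(sprintf("%s must be a height x width x 3 array", what))
    if (dim(px)[1] < 1L || dim(px)[2] < 1L)
        return(sprintf("%s must be at least 1x1", what))
    if (anyNA(px) || min(px) < 0 || max(px) > 255)
        return(sprintf("%s intensities must lie in [0, 255]", what))
    NULL
}

.validMask <- function(m, what) {
    if (!is.matrix(m))
        return(sprintf("%s must be a matrix", what))
    if (!all(m %in% c(0L, 255L)))
        return(sprintf("%s values must be exactly 0 or 255", what))
    NULL
}

#' SlidePreview: an RGB slide preview image with its binary tissue mask
#'
#' The canonical in-memory sample: an 8-bit RGB preview image of a glass
#' slide stored as an integer array of dimension \code{height x width x 3}
#' (intensities 0--255, 0-based \code{(x = column, y = row)} coordinate
#' convention with top-left origin), plus an optional binary tissue mask of
#' the same height/width with foreground (tissue) = 255 and background = 0.
#'
#' @slot image integer array, \code{M x N x 3}, values in 0--255.
#' @slot mask integer matrix \code{M x N} with values in \{0, 255\}, or
#'   \code{NULL} for unannotated previews.
#' @slot id character scalar identifier.
#' @export
setClass("SlidePreview",
    representation(image = "array", mask = "matrixOrNULL", id = "character"),
    validity = function(object) {
        msg <- .validPixels(object@image, "image")
        if (!is.null(msg)) return(msg)
        if (!is.null(object@mask)) {
            msg <- .validMask(object@mask, "mask")
            if (!is.null(msg)) return(msg)
            if (!identical(dim(object@mask), dim(object@image)[1:2]))
                return(sprintf(
                    "mask dimensions (%d x %d) differ from image (%d x %d)",
                    nrow(object@mask), ncol(object@mask),
                    dim(object@image)[1], dim(object@image)[2]))
        }
        if (length(object@id) != 1L) return("id must be a single string")
        TRUE
    })

#' ArtifactOverlay: one artifact patch in canonical white-background form
#'
#' A cropped RGB artifact patch with its binary foreground mask and category.
#' The patch is stored in canonical white-background form: every pixel outside
#' the mask is 255 on all channels, so the subtractive blend
#' \code{max(0, I_in + I_over - 255)} is an identity there. This is the
#' pre-negation equivalent of masking the negative overlay to zero at the
#' background.
#'
#' @slot patch integer array \code{h x w x 3}, 0--255, white outside mask.
#' @slot mask integer matrix \code{h x w}, values in \{0, 255\}, at least one
#'   foreground pixel.
#' @slot category one of \code{artifactCategories()}.
#' @slot sourceId identifier of the labeled source image the artifact was
#'   extracted from.
#' @slot overlayId unique identifier of this overlay within a bank.
#' @export
setClass("ArtifactOverlay",
    representation(patch = "array", mask = "matrix", category = "character",
                   sourceId = "character", overlayId = "character"),
    validity = function(object) {
        msg <- .validPixels(object@patch, "patch")
        if (!is.null(msg)) return(msg)
        msg <- .validMask(object@mask, "mask")
        if (!is.null(msg)) return(msg)
        if (!identical(dim(object@mask), dim(object@patch)[1:2]))
            return("mask and patch dimensions differ")
        if (!any(object@mask > 0L))
            return("mask must contain at least one foreground pixel")
        if (!(object@category %in% artifactCategories()))
            return(sprintf("unknown category '%s'", object@category))
        bg <- object@mask == 0L
        if (any(bg)) {
            px <- object@patch
            if (!all(px[cbind(which(bg, arr.ind = TRUE)[, 1],
                              which(bg, arr.ind = TRUE)[, 2], 1L)] == 255L) ||
                !all(apply(px, 3, function(ch) all(ch[bg] == 255L))))
                return("pixels outside the mask must be 255 on all channels")
        }
        TRUE
    })

#' ArtifactBank: a reusable collection of artifact overlays
#'
#' @slot overlays list of \linkS4class{ArtifactOverlay} objects. An empty
#'   bank is legal.
#' @export
setClass("ArtifactBank",
    representation(overlays = "list"),
    validity = function(object) {
        ok <- vapply(object@overlays, function(o) is(o, "ArtifactOverlay"),
                     logical(1))
        if (!all(ok)) return("all elements must be ArtifactOverlay objects")
        ids <- vapply(object@overlays, function(o) o@overlayId, character(1))
        if (anyDuplicated(ids)) return("overlay ids must be unique")
        TRUE
    })

#' TransformParams: a fully determined overlay transform chain
#'
#' One draw of the seven transform parameters. Given a \code{TransformParams}
#' object the transform chain is deterministic: the two transforms with
#' internal randomness (scratch line geometry, Perlin gradient field) carry
#' their own integer seeds.
#'
#' Identity values are: scale 1, rotation 0, mirror \code{"none"}, hue
#' \code{NA} (disabled), scratch count 0, perlin weight 0, intensity factor 1.
#'
#' @slot scaleFactor numeric > 0 (published range \[0.75, 1.25\]).
#' @slot rotationAngle integer degrees in \[0, 359\].
#' @slot mirrorAxis one of "none", "horizontal", "vertical", "both".
#' @slot hueValue integer in \[0, 180\] (OpenCV half-degree units) or NA.
#' @slot scratchCount integer >= 0.
#' @slot scratchFactor numeric in \[0, 0.2\].
#' @slot scratchSeed integer seed for the line geometry.
#' @slot perlinWeight numeric in \[0, 1\].
#' @slot perlinOctaves numeric lattice frequency of the noise field.
#' @slot perlinThreshold numeric in \[0, 1\] or NA for none.
#' @slot perlinNormalize logical, min-max rescale the field to \[0, 1\].
#' @slot perlinSeed integer seed for the gradient field.
#' @slot intensityFactor numeric in (0, 1\] (published sampler:
#'   \code{sqrt(U(0.3, 0.7))}).
#' @export
setClass("TransformParams",
    representation(scaleFactor = "numeric", rotationAngle = "integer",
                   mirrorAxis = "character", hueValue = "integer",
                   scratchCount = "integer", scratchFactor = "numeric",
                   scratchSeed = "integer", perlinWeight = "numeric",
                   perlinOctaves = "numeric", perlinThreshold = "numeric",
                   perlinNormalize = "logical", perlinSeed = "integer",
                   intensityFactor = "numeric"),
    validity = function(object) {
        if (object@scaleFactor <= 0) return("scaleFactor must be > 0")
        if (object@rotationAngle < 0L || object@rotationAngle > 359L)
            return("rotationAngle must be in [0, 359]")
        if (!(object@mirrorAxis %in%
              c("none", "horizontal", "vertical", "both")))
            return("invalid mirrorAxis")
        if (!is.na(object@hueValue) &&
            (object@hueValue < 0L || object@hueValue > 180L))
            return("hueValue must be in [0, 180]")
        if (object@scratchCount < 0L) return("scratchCount must be >= 0")
        if (object@scratchFactor < 0 || object@scratchFactor > 0.2)
            return("scratchFactor must be in [0, 0.2]")
        if (object@perlinWeight < 0 || object@perlinWeight > 1)
            return("perlinWeight must be in [0, 1]")
        if (object@intensityFactor <= 0 || object@intensityFactor > 1)
            return("intensityFactor must be in (0, 1]")
        TRUE
    })

#' Placement: where an overlay lands on a preview
#'
#' Offsets are 0-based. For an axis where the overlay fits inside the preview
#' the offset ranges over \code{0 .. preview_dim - overlay_dim} and the crop
#' start is 0; where the overlay exceeds the preview the offset is 0 and the
#' crop start ranges over \code{0 .. overlay_dim - preview_dim}. The two axes
#' are independent.
#'
#' @slot x0,y0 integer column/row offsets into the preview.
#' @slot cropX,cropY integer column/row crop starts into the overlay.
#' @export
setClass("Placement",
    representation(x0 = "integer", y0 = "integer",
                   cropX = "integer", cropY = "integer"),
    validity = function(object) {
        v <- c(object@x0, object@y0, object@cropX, object@cropY)
        if (anyNA(v) || any(v < 0L)) return("offsets must be >= 0")
        TRUE
    })

#' ConfusionCounts: pixel-level confusion counts between two binary masks
#'
#' @slot tp,fp,tn,fn non-negative pixel counts (stored as doubles so large
#'   images do not overflow).
#' @export
setClass("ConfusionCounts",
    representation(tp = "numeric", fp = "numeric",
                   tn = "numeric", fn = "numeric"),
    validity = function(object) {
        v <- c(object@tp, object@fp, object@tn, object@fn)
        if (anyNA(v) || any(v < 0)) return("counts must be non-negative")
        TRUE
    })

#' AugmentationConfig: ranges, toggles and sampling policy for augmentation
#'
#' Defaults reproduce the published parameter ranges: scale factor in
#' \[0.75, 1.25\], integer rotation angle in \[0, 359\], mirror axis from
#' \{horizontal, vertical, both\}, hue in \[0, 180\], scratch multiplication
#' factor in \[0, 0.2\], Perlin fade weight in \[0, 1\], intensity factor
#' \code{sqrt(u)} with u uniform in \[0.3, 0.7\]. Content transforms (hue,
#' scratch, perlin, intensity) apply only to categories listed in
#' \code{contentCategories} (felt pen by default).
#'
#' @slot enabled named logical over the seven transforms.
#' @slot scaleRange,scratchFactorRange,perlinWeightRange,intensityURange
#'   numeric length-2 sampling ranges.
#' @slot rotationRange,hueRange,scratchCountRange,overlayCountRange integer
#'   length-2 inclusive sampling ranges.
#' @slot contentCategories categories eligible for content transforms.
#' @slot categoryWeights named non-negative sampling weights per category.
#' @slot exclusions named list: sample-type -> categories never applied to it.
#' @slot perlinOctaves,perlinThreshold,perlinNormalize Perlin field settings.
#' @slot seed master seed used by pipeline runs.
#' @export
setClass("AugmentationConfig",
    representation(enabled = "logical", scaleRange = "numeric",
                   rotationRange = "integer", hueRange = "integer",
                   scratchCountRange = "integer",
                   scratchFactorRange = "numeric",
                   perlinWeightRange = "numeric", intensityURange = "numeric",
                   perlinOctaves = "numeric", perlinThreshold = "numeric",
                   perlinNormalize = "logical",
                   overlayCountRange = "integer",
                   contentCategories = "character",
                   categoryWeights = "numeric", exclusions = "list",
                   seed = "integer"),
    validity = function(object) {
        need <- c("scale", "rotate", "mirror", "hue", "scratch", "perlin",
                  "intensity")
        if (!identical(sort(names(object@enabled)), sort(need)))
            return("enabled must name exactly the seven transforms")
        inRange <- function(r, lo, hi)
            length(r) == 2L && r[1] <= r[2] && r[1] >= lo && r[2] <= hi
        if (!inRange(object@scaleRange, 1e-6, Inf))
            return("invalid scaleRange")
        if (!inRange(object@rotationRange, 0L, 359L))
            return("rotationRange must lie within [0, 359]")
        if (!inRange(object@hueRange, 0L, 180L))
            return("hueRange must lie within [0, 180]")
        if (!inRange(object@scratchFactorRange, 0, 0.2))
            return("scratchFactorRange must lie within [0, 0.2]")
        if (!inRange(object@perlinWeightRange, 0, 1))
            return("perlinWeightRange must lie within [0, 1]")
        if (!inRange(object@intensityURange, 0, 1))
            return("intensityURange must lie within (0, 1]")
        if (!inRange(object@overlayCountRange, 0L, Inf))
            return("invalid overlayCountRange")
        if (!all(object@contentCategories %in% artifactCategories()))
            return("unknown category in contentCategories")
        if (!all(names(object@categoryWeights) %in% artifactCategories()))
            return("unknown category in categoryWeights")
        if (any(object@categoryWeights < 0))
            return("categoryWeights must be non-negative")
        bad <- unlist(object@exclusions)
        if (length(bad) && !all(bad %in% artifactCategories()))
            return("exclusions reference unknown categories")
        TRUE
    })
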