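# The seven overlay transformations. Geometric ops (scale, rotate, mirror)
# act on patch + mask together; content ops (hue, scratch, perlin, intensity)
# act in strength space S = 255 - patch inside the mask and never touch a
# pixel outside it. All ops return canonical white-background overlays.

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
rot180 <- function(m) m[nrow(m):1, ncol(m):1, drop = FALSE]
rot270cw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

applyChannels <- function(px, f) {
    out <- lapply(1:3, function(ch) f(px[, , ch, drop = TRUE]))
    array(unlist(out), c(dim(out[[1]]), 3L))
}

# Rebuild a canonical overlay from transformed pieces; if a geometric op
# wiped out the mask entirely, keep a single pixel at the patch centre so the
# overlay invariants still hold (only reachable far outside the published
# scale range).
rebuildOverlay <- function(o, patch, mask) {
    mask <- binarizeMask(mask)
    if (!any(mask > 0L))
        mask[ceiling(nrow(mask) / 2), ceiling(ncol(mask) / 2)] <- 255L
    patch <- round(pmin(pmax(patch, 0), 255))
    storage.mode(patch) <- "integer"
    new("ArtifactOverlay", patch = whitenBackground(patch, mask),
        mask = mask, category = o@category, sourceId = o@sourceId,
        overlayId = o@overlayId)
}

#' Scale an overlay by a uniform factor
#'
#' Uniform linear dilation: new dimensions are
#' \code{floor(dim * factor + 0.5)} (at least 1). The patch is interpolated
#' bilinearly, the mask nearest-neighbour and re-binarized. The published
#' sampling range for the factor is \[0.75, 1.25\].
#'
#' @param o an \linkS4class{ArtifactOverlay}.
#' @param factor positive scale factor.
#' @return The scaled overlay.
#' @export
scaleOverlay <- function(o, factor) {
    if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
        stop("scale factor must be a single positive number")
    if (factor == 1) return(o)
    d <- dim(o@patch)
    nh <- max(1L, as.integer(floor(d[1] * factor + 0.5)))
    nw <- max(1L, as.integer(floor(d[2] * factor + 0.5)))
    patch <- fromEBImageRGB(EBImage::resize(asEBImageRGB(o@patch),
                                            w = nw, h = nh,
                                            filter = "bilinear"))
    mask <- fromEBImageGray(EBImage::resize(asEBImageGray(o@mask),
                                            w = nw, h = nh, filter = "none"))
    rebuildOverlay(o, patch, mask)
}

#' Rotate an overlay by an integer angle
#'
#' Clockwise rotation about the patch centre by a whole number of degrees in
#' \[0, 359\]. The canvas is expanded to the rotated bounding box (no
#' cropping). Multiples of 90 degrees are exact index permutations; other
#' angles interpolate the patch bilinearly and the mask nearest-neighbour.
#' Newly exposed canvas lies outside the rotated mask and is therefore white
#' in the canonical patch.
#'
#' @param o an \linkS4class{ArtifactOverlay}.
#' @param angle integer degrees in \[0, 359\].
#' @return The rotated overlay.
#' @export
rotateOverlay <- function(o, angle) {
    if (!is.numeric(angle) || length(angle) != 1L || angle != round(angle) ||
        angle < 0 || angle > 359)
        stop("rotation angle must be an integer in [0, 359]")
    angle <- as.integer(angle)
    if (angle == 0L) return(o)
    if (angle %% 90L == 0L) {
        f <- switch(as.character(angle), "90" = rot90cw, "180" = rot180,
                    "270" = rot270cw)
        return(rebuildOverlay(o, applyChannels(o@patch, f), f(o@mask)))
    }
    patch <- fromEBImageRGB(EBImage::rotate(asEBImageRGB(o@patch), angle,
                                            filter = "bilinear",
                                            bg.col = "white"))
    mask <- fromEBImageGray(EBImage::rotate(asEBImageGray(o@mask), angle,
                                            filter = "none", bg.col = 0))
    if (!identical(dim(mask), dim(patch)[1:2])) # guard against 1px mismatch
        mask <- mask[seq_len(dim(patch)[1]), seq_len(dim(patch)[2]),
                     drop = FALSE]
    rebuildOverlay(o, patch, mask)
}

#' Mirror an overlay
#'
#' Flips patch and mask identically. \code{"horizontal"} reverses columns
#' (left-right), \code{"vertical"} reverses rows (up-down), \code{"both"}
#' does both (equal to a 180-degree rotation), \code{"none"} is the identity.
#'
#' @param o an \linkS4class{ArtifactOverlay}.
#' @param axis one of "horizontal", "vertical", "both", "none".
#' @return The mirrored overlay.
#' @export
mirrorOverlay <- function(o, axis) {
    axis <- match.arg(axis, c("horizontal", "vertical", "both", "none"))
    if (axis == "none") return(o)
    f <- switch(axis,
        horizontal = function(m) m[, ncol(m):1, drop = FALSE],
        vertical = function(m) m[nrow(m):1, , drop = FALSE],
        both = rot180)
    rebuildOverlay(o, applyChannels(o@patch, f), f(o@mask))
}

#' Replace the hue of the masked artifact pixels
#'
#' Converts masked pixels to HSV, replaces the hue channel by the given
#' value and converts back, preserving saturation and value up to 8-bit
#' rounding. Hue uses the half-degree convention: integers in \[0, 180\]
#' with 180 treated modulo 180. Gray pixels (saturation 0) are unchanged.
#' Pixels outside the mask are untouched.
#'
#' @param o an \linkS4class{ArtifactOverlay} (intended for felt-pen marks).
#' @param hue integer in \[0, 180\], half-degree units.
#' @return The re-colored overlay.
#' @export
hueSet <- function(o, hue) {
    if (!is.numeric(hue) || length(hue) != 1L || hue != round(hue) ||
        hue < 0 || hue > 180)
        stop("hue must be an integer in [0, 180]")
    idx <- o@mask > 0L
    if (!any(idx)) return(o)
    r <- o@patch[, , 1][idx]; g <- o@patch[, , 2][idx]
    b <- o@patch[, , 3][idx]
    hsvm <- grDevices::rgb2hsv(r, g, b, maxColorValue = 255)
    hsvm[1, ] <- ((hue %% 180) * 2) / 360
    rgb <- grDevices::col2rgb(grDevices::hsv(hsvm[1, ], hsvm[2, ],
                                             hsvm[3, ]))
    patch <- o@patch
    for (ch in 1:3) {
        pl <- patch[, , ch]
        pl[idx] <- as.integer(rgb[ch, ])
        patch[, , ch] <- pl
    }
    rebuildOverlay(o, patch, o@mask)
}

# Integer Bresenham line between (r0,c0) and (r1,c1); returns cbind(row,col).
bresenham <- function(r0, c0, r1, c1) {
    dr <- abs(r1 - r0); dc <- abs(c1 - c0)
    sr <- sign(r1 - r0); sc <- sign(c1 - c0)
    if (sr == 0) sr <- 1L
    if (sc == 0) sc <- 1L
    err <- dc - dr
    r <- r0; c <- c0
    pts <- matrix(0L, dr + dc + 1L, 2L)
    k <- 0L
    repeat {
        k <- k + 1L
        pts[k, ] <- c(r, c)
        if (r == r1 && c == c1) break
        e2 <- 2L * err
        if (e2 > -dr) { err <- err - dr; c <- c + sc }
        if (e2 < dc) { err <- err + dc; r <- r + sr }
    }
    pts[seq_len(k), , drop = FALSE]
}

# Random point on one of the four image borders (1=top,2=bottom,3=left,4=right)
edgePoint <- function(edge, h, w) {
    switch(edge,
        c(1L, sampleInt(1L, w)),
        c(h, sampleInt(1L, w)),
        c(sampleInt(1L, h), 1L),
        c(sampleInt(1L, h), w))
}

#' Add scratch lines to a felt-pen overlay
#'
#' Draws \code{count} one-pixel-thick straight lines between two random
#' points on distinct, randomly chosen image edges. Line pixels carry a
#' multiplication factor in \[0, 0.2\]; the factor map is blurred with a
#' 3x3 mean kernel and the artifact strength (255 - intensity) is multiplied
#' by the blurred factor on the pixels where the lines intersect the
#' artifact mask. All other pixels are bit-identical to the input, so a
#' scratch can only lighten the marking (ink scraped off lets light
#' through).
#'
#' @param o an \linkS4class{ArtifactOverlay} (intended for felt-pen marks).
#' @param count number of lines (>= 0).
#' @param factor multiplication factor in \[0, 0.2\] shared by all lines, or
#'   \code{NULL} to draw an independent factor per line from \[0, 0.2\].
#' @param seed integer seed for the line geometry (and per-line factors when
#'   \code{factor} is NULL); \code{NULL} uses the current RNG stream.
#' @return The scratched overlay.
#' @export
addScratches <- function(o, count, factor = NULL, seed = NULL) {
    if (!is.numeric(count) || length(count) != 1L || count < 0 ||
        count != round(count))
        stop("scratch count must be a non-negative integer")
    if (!is.null(factor) && (factor < 0 || factor > 0.2))
        stop("scratch factor must lie in [0, 0.2]")
    if (count == 0L) return(o)
    h <- nrow(o@mask); w <- ncol(o@mask)
    weight <- matrix(0, h, w)
    onLine <- matrix(FALSE, h, w)
    withSeed(seed, {
        for (i in seq_len(count)) {
            edges <- sample(4L, 2L)     # two distinct edges
            p0 <- edgePoint(edges[1], h, w)
            p1 <- edgePoint(edges[2], h, w)
            f <- if (is.null(factor)) stats::runif(1, 0, 0.2) else factor
            pts <- bresenham(p0[1], p0[2], p1[1], p1[2])
            weight[pts] <- f
            onLine[pts] <- TRUE
        }
    })
    blurred <- blur3x3(weight)
    hit <- onLine & (o@mask > 0L)
    if (!any(hit)) return(o)
    s <- strengthField(o)
    for (ch in 1:3) {
        pl <- s[, , ch]
        pl[hit] <- pl[hit] * blurred[hit]
        s[, , ch] <- pl
    }
    rebuildOverlay(o, patchFromStrength(s, o@mask), o@mask)
}

# 3x3 mean filter with zero padding at the borders.
blur3x3 <- function(m) {
    h <- nrow(m); w <- ncol(m)
    p <- matrix(0, h + 2L, w + 2L)
    p[2:(h + 1), 2:(w + 1)] <- m
    out <- matrix(0, h, w)
    for (dr in 0:2) for (dc in 0:2)
        out <- out + p[(1 + dr):(h + dr), (1 + dc):(w + dc)]
    out / 9
}

#' Fade overlay regions with Perlin noise
#'
#' Samples a Perlin field over the patch grid (see \code{\link{perlinField}})
#' and multiplies the artifact strength by \code{1 - weight * noise} inside
#' the mask: smooth random regions of the marking fade towards the white
#' background. Pixels outside the mask are untouched; the result is
#' deterministic given the seed.
#'
#' @param o an \linkS4class{ArtifactOverlay} (intended for felt-pen marks).
#' @param weight fade weight in \[0, 1\]; 0 is the identity.
#' @param octaves lattice frequency of the noise field (default 4).
#' @param threshold optional cutoff in \[0, 1\] zeroing low noise values.
#' @param normalize min-max rescale the field to \[0, 1\] (default TRUE).
#' @param seed integer seed for the gradient field.
#' @return The faded overlay.
#' @export
perlinFade <- function(o, weight, octaves = 4, threshold = NA_real_,
                       normalize = TRUE, seed = NULL) {
    if (!is.numeric(weight) || length(weight) != 1L || weight < 0 ||
        weight > 1)
        stop("perlin weight must lie in [0, 1]")
    if (weight == 0) return(o)
    noise <- perlinField(nrow(o@mask), ncol(o@mask), frequency = octaves,
                         seed = seed, normalize = normalize,
                         threshold = threshold)
    fg <- o@mask > 0L
    s <- strengthField(o)
    for (ch in 1:3) {
        pl <- s[, , ch]
        pl[fg] <- pl[fg] * (1 - weight * noise[fg])
        s[, , ch] <- pl
    }
    rebuildOverlay(o, patchFromStrength(s, o@mask), o@mask)
}

#' Scale the intensity (strength) of an overlay
#'
#' Multiplies the artifact strength by a factor in (0, 1\]:
#' \code{patch' = 255 - round(factor * (255 - patch))} inside the mask,
#' untouched outside. The published sampler draws
#' \code{factor = sqrt(u)} with \code{u} uniform in \[0.3, 0.7\], i.e.
#' factor in about \[0.548, 0.837\].
#'
#' @param o an \linkS4class{ArtifactOverlay} (intended for felt-pen marks).
#' @param factor strength multiplier in (0, 1\].
#' @return The attenuated overlay.
#' @export
intensityScale <- function(o, factor) {
    if (!is.numeric(factor) || length(factor) != 1L || factor <= 0 ||
        factor > 1)
        stop("intensity factor must lie in (0, 1]")
    if (factor == 1) return(o)
    s <- strengthField(o) * factor
    rebuildOverlay(o, patchFromStrength(s, o@mask), o@mask)
}

#' Construct identity transform parameters
#'
#' @return A \linkS4class{TransformParams} whose chain is the identity.
#' @export
identityParams <- function()
    new("TransformParams", scaleFactor = 1, rotationAngle = 0L,
        mirrorAxis = "none", hueValue = NA_integer_, scratchCount = 0L,
        scratchFactor = 0, scratchSeed = 0L, perlinWeight = 0,
        perlinOctaves = 4, perlinThreshold = NA_real_,
        perlinNormalize = TRUE, perlinSeed = 0L, intensityFactor = 1)

#' Draw one set of transform parameters from a configuration
#'
#' Each enabled transform gets a uniform draw from its configured range;
#' disabled transforms receive identity values. Content transforms (hue,
#' scratch, perlin, intensity) are forced to identity for categories outside
#' \code{config@contentCategories} (felt pen only, by default). The draw
#' consumes the current RNG stream; sub-seeds for the scratch and Perlin
#' randomness are drawn here, so the returned object fully determines the
#' chain.
#'
#' @param config an \linkS4class{AugmentationConfig}.
#' @param category the category of the overlay the parameters are for.
#' @return A \linkS4class{TransformParams}.
#' @export
sampleParams <- function(config, category) {
    stopifnot(is(config, "AugmentationConfig"),
              category %in% artifactCategories())
    en <- config@enabled
    content <- category %in% config@contentCategories
    p <- identityParams()
    if (en[["scale"]])
        p@scaleFactor <- stats::runif(1, config@scaleRange[1],
                                      config@scaleRange[2])
    if (en[["rotate"]])
        p@rotationAngle <- sampleInt(config@rotationRange[1],
                                     config@rotationRange[2])
    if (en[["mirror"]])
        p@mirrorAxis <- sample(c("none", "horizontal", "vertical", "both"),
                               1L)
    if (en[["hue"]] && content)
        p@hueValue <- sampleInt(config@hueRange[1], config@hueRange[2])
    if (en[["scratch"]] && content) {
        p@scratchCount <- sampleInt(config@scratchCountRange[1],
                                    config@scratchCountRange[2])
        p@scratchFactor <- stats::runif(1, config@scratchFactorRange[1],
                                        config@scratchFactorRange[2])
        p@scratchSeed <- drawSeed()
    }
    if (en[["perlin"]] && content) {
        p@perlinWeight <- stats::runif(1, config@perlinWeightRange[1],
                                       config@perlinWeightRange[2])
        p@perlinOctaves <- config@perlinOctaves
        p@perlinThreshold <- config@perlinThreshold
        p@perlinNormalize <- config@perlinNormalize
        p@perlinSeed <- drawSeed()
    }
    if (en[["intensity"]] && content)
        p@intensityFactor <- sqrt(stats::runif(1, config@intensityURange[1],
                                               config@intensityURange[2]))
    validObject(p)
    p
}

#' Apply a full transform chain to an overlay
#'
#' Applies, in fixed order, scale, rotate, mirror, hue, scratch, perlin,
#' intensity. Identity-valued steps are skipped bit-exactly. The order is
#' fixed (geometric then content) so that a \linkS4class{TransformParams}
#' object reproduces the same overlay every time.
#'
#' @param o an \linkS4class{ArtifactOverlay}.
#' @param p a \linkS4class{TransformParams}.
#' @return The transformed overlay.
#' @export
applyChain <- function(o, p) {
    stopifnot(is(o, "ArtifactOverlay"), is(p, "TransformParams"))
    validObject(p)
    o <- scaleOverlay(o, p@scaleFactor)
    o <- rotateOverlay(o, p@rotationAngle)
    o <- mirrorOverlay(o, p@mirrorAxis)
    if (!is.na(p@hueValue)) o <- hueSet(o, p@hueValue)
    if (p@scratchCount > 0L)
        o <- addScratches(o, p@scratchCount, p@scratchFactor, p@scratchSeed)
    if (p@perlinWeight > 0)
        o <- perlinFade(o, p@perlinWeight, octaves = p@perlinOctaves,
                        threshold = p@perlinThreshold,
                        normalize = p@perlinNormalize, seed = p@perlinSeed)
    o <- intensityScale(o, p@intensityFactor)
    o
}
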