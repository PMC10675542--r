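# Masked subtractive compositing: the negative of the artifact overlay is
# subtracted from the preview, I_out = max(0, I_in + I_over - 255), applied
# channel-wise over the placed overlay window. Because overlays are stored
# in canonical white-background form (255 outside the mask), the blend is an
# identity off the artifact and needs no conditional.

#' Blend a single pixel pair subtractively
#'
#' \code{max(0, i_in + i_over - 255)}: a white overlay pixel leaves the
#' input unchanged; darker overlay pixels subtract their strength, clamped
#' at 0. Vectorized over its arguments.
#'
#' @param iIn,iOver intensities in \[0, 255\].
#' @return Blended intensity in \[0, 255\].
#' @export
blendPixel <- function(iIn, iOver) {
    stopifnot(all(iIn >= 0 & iIn <= 255), all(iOver >= 0 & iOver <= 255))
    pmax(0L, as.integer(iIn) + as.integer(iOver) - 255L)
}

#' Sample a random placement for an overlay on a preview
#'
#' Each axis is handled independently: where the overlay fits, the offset is
#' uniform over \code{0 .. preview - overlay}; where it exceeds the preview,
#' the offset is 0 and a uniform crop start over
#' \code{0 .. overlay - preview} selects the visible window. Every size
#' combination therefore has a valid placement.
#'
#' @param previewDims c(height, width) of the preview.
#' @param overlayDims c(height, width) of the overlay.
#' @return A \linkS4class{Placement}.
#' @export
samplePlacement <- function(previewDims, overlayDims) {
    stopifnot(all(previewDims >= 1L), all(overlayDims >= 1L))
    M <- previewDims[1]; N <- previewDims[2]
    oh <- overlayDims[1]; ow <- overlayDims[2]
    if (ow <= N) { x0 <- sampleInt(0L, N - ow); cx <- 0L }
    else { x0 <- 0L; cx <- sampleInt(0L, ow - N) }
    if (oh <= M) { y0 <- sampleInt(0L, M - oh); cy <- 0L }
    else { y0 <- 0L; cy <- sampleInt(0L, oh - M) }
    placement(x0 = x0, y0 = y0, cropX = cx, cropY = cy)
}

validatePlacement <- function(pl, previewDims, overlayDims) {
    M <- previewDims[1]; N <- previewDims[2]
    oh <- overlayDims[1]; ow <- overlayDims[2]
    ok <- if (ow <= N) pl@cropX == 0L && pl@x0 >= 0L && pl@x0 <= N - ow
          else pl@x0 == 0L && pl@cropX >= 0L && pl@cropX <= ow - N
    ok <- ok && if (oh <= M) pl@cropY == 0L && pl@y0 >= 0L && pl@y0 <= M - oh
                else pl@y0 == 0L && pl@cropY >= 0L && pl@cropY <= oh - M
    if (!ok)
        stop(sprintf(
            "invalid placement (x0=%d y0=%d cropX=%d cropY=%d) for overlay %d x %d on preview %d x %d",
            pl@x0, pl@y0, pl@cropX, pl@cropY, oh, ow, M, N))
    invisible(TRUE)
}

#' Composite one overlay onto a preview
#'
#' Applies the subtractive blend channel-wise over the placed (and possibly
#' cropped) overlay window. The tissue mask passes through unchanged:
#' artifacts are background for the segmentation label, the detector is
#' trained to find tissue despite them. Also returns the artifact footprint,
#' i.e. the overlay mask positioned in preview coordinates.
#'
#' @param preview a \linkS4class{SlidePreview}.
#' @param overlay an \linkS4class{ArtifactOverlay}.
#' @param pl a \linkS4class{Placement} valid for this size pair.
#' @return List with elements \code{sample} (the augmented
#'   \linkS4class{SlidePreview}) and \code{footprint} (binary matrix of
#'   preview dimensions).
#' @export
composeOverlay <- function(preview, overlay, pl) {
    stopifnot(is(preview, "SlidePreview"), is(overlay, "ArtifactOverlay"),
              is(pl, "Placement"))
    d <- dim(preview@image)
    od <- dim(overlay@mask)
    validatePlacement(pl, d[1:2], od)
    hEff <- min(od[1], d[1]); wEff <- min(od[2], d[2])
    srcR <- pl@cropY + seq_len(hEff); srcC <- pl@cropX + seq_len(wEff)
    dstR <- pl@y0 + seq_len(hEff); dstC <- pl@x0 + seq_len(wEff)
    img <- preview@image
    win <- img[dstR, dstC, , drop = FALSE]
    ovr <- overlay@patch[srcR, srcC, , drop = FALSE]
    blended <- pmax(win + ovr - 255L, 0L)
    storage.mode(blended) <- "integer"
    img[dstR, dstC, ] <- blended
    foot <- matrix(0L, d[1], d[2])
    foot[dstR, dstC] <- overlay@mask[srcR, srcC, drop = FALSE]
    list(sample = new("SlidePreview", image = img, mask = preview@mask,
                      id = preview@id),
         footprint = foot)
}

#' Augment one preview with randomly drawn overlays
#'
#' Draws the overlay count from the configured range, then for each overlay:
#' picks a category by the configured weights among categories present in
#' the bank (minus exclusions for this sample type), picks an overlay of
#' that category uniformly, draws transform parameters with
#' \code{\link{sampleParams}}, applies the chain, samples a placement and
#' composites sequentially (later overlays blend over earlier results). The
#' tissue mask is unchanged. Returns full provenance so any augmentation can
#' be replayed bit-exactly.
#'
#' @param preview a \linkS4class{SlidePreview}.
#' @param bank an \linkS4class{ArtifactBank}.
#' @param config an \linkS4class{AugmentationConfig}.
#' @param seed integer seed making the draw reproducible; \code{NULL} uses
#'   the current RNG stream.
#' @param sampleType optional sample-type label checked against
#'   \code{config@exclusions}.
#' @return List with \code{sample} (augmented preview), \code{footprint}
#'   (union of artifact footprints) and \code{records} (list of provenance
#'   records; see \code{\link{replayRecord}}).
#' @export
augmentSample <- function(preview, bank, config, seed = NULL,
                          sampleType = NULL) {
    stopifnot(is(preview, "SlidePreview"), is(bank, "ArtifactBank"),
              is(config, "AugmentationConfig"))
    allowed <- names(config@categoryWeights)[config@categoryWeights > 0]
    if (!is.null(sampleType) && sampleType %in% names(config@exclusions))
        allowed <- setdiff(allowed, config@exclusions[[sampleType]])
    allowed <- intersect(allowed, categoriesPresent(bank))
    withSeed(seed, {
        k <- sampleInt(config@overlayCountRange[1],
                       config@overlayCountRange[2])
        if (k > 0L && !length(allowed))
            stop("augmentation requested but no overlay category is ",
                 "available in the bank after filtering")
        out <- preview
        foot <- matrix(0L, dim(preview@image)[1], dim(preview@image)[2])
        records <- vector("list", k)
        for (i in seq_len(k)) {
            w <- config@categoryWeights[allowed]
            cat_i <- sample(allowed, 1L, prob = w / sum(w))
            pool <- overlays(bank, cat_i)
            ov <- pool[[sampleInt(1L, length(pool))]]
            p <- sampleParams(config, cat_i)
            tr <- applyChain(ov, p)
            pl <- samplePlacement(dim(out@image)[1:2], dim(tr@mask))
            cps <- composeOverlay(out, tr, pl)
            out <- cps$sample
            foot <- pmax(foot, cps$footprint)
            records[[i]] <- list(overlay_id = ov@overlayId,
                                 category = cat_i, params = p,
                                 placement = pl)
        }
        list(sample = out, footprint = foot, records = records)
    })
}

#' Replay one augmentation record
#'
#' Re-applies the stored transform parameters and placement to the stored
#' bank overlay, reproducing the corresponding \code{\link{augmentSample}}
#' step bit-exactly.
#'
#' @param preview the input \linkS4class{SlidePreview} (for a multi-overlay
#'   record list, feed each step's output into the next).
#' @param bank the same \linkS4class{ArtifactBank} used originally.
#' @param record one element of \code{augmentSample()$records}.
#' @return As \code{\link{composeOverlay}}.
#' @export
replayRecord <- function(preview, bank, record) {
    ids <- vapply(bank@overlays, overlayId, character(1))
    pos <- match(record$overlay_id, ids)
    if (is.na(pos)) stop("overlay '", record$overlay_id, "' not in bank")
    tr <- applyChain(bank@overlays[[pos]], record$params)
    composeOverlay(preview, tr, record$placement)
}

# JSON-serializable form of one provenance record.
recordToList <- function(rec) {
    p <- rec$params
    list(overlay_id = rec$overlay_id, category = rec$category,
         params = list(scale_factor = p@scaleFactor,
                       rotation_angle = p@rotationAngle,
                       mirror_axis = p@mirrorAxis,
                       hue_value = if (is.na(p@hueValue)) NULL else p@hueValue,
                       scratch_count = p@scratchCount,
                       scratch_factor = p@scratchFactor,
                       scratch_seed = p@scratchSeed,
                       perlin_weight = p@perlinWeight,
                       perlin_octaves = p@perlinOctaves,
                       perlin_threshold = if (is.na(p@perlinThreshold)) NULL
                                          else p@perlinThreshold,
                       perlin_normalize = p@perlinNormalize,
                       perlin_seed = p@perlinSeed,
                       intensity_factor = p@intensityFactor),
         placement = list(x0 = rec$placement@x0, y0 = rec$placement@y0,
                          crop_x = rec$placement@cropX,
                          crop_y = rec$placement@cropY))
}
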