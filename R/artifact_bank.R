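# Extraction of labeled artifact instances into a reusable bank.

# 8-connected component labels. EBImage::bwlabel is 4-connected, so labels
# that touch across any of the four diagonal shifts are merged (union-find).
label8 <- function(mask) {
    lab <- EBImage::imageData(EBImage::bwlabel(asEBImageGray(mask)))
    lab <- t(lab)                         # back to [row, col]
    n <- max(lab)
    if (n <= 1L) return(lab)
    parent <- seq_len(n)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    h <- nrow(lab); w <- ncol(lab)
    shifts <- list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))
    for (s in shifts) {
        r0 <- max(1L, 1L + s[1]):min(h, h + s[1])
        c0 <- max(1L, 1L + s[2]):min(w, w + s[2])
        a <- lab[r0, c0, drop = FALSE]
        b <- lab[r0 - s[1], c0 - s[2], drop = FALSE]
        hit <- a > 0 & b > 0 & a != b
        if (any(hit)) {
            prs <- unique(cbind(a[hit], b[hit]))
            for (k in seq_len(nrow(prs))) {
                ra <- find(prs[k, 1]); rb <- find(prs[k, 2])
                if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
            }
        }
    }
    root <- vapply(seq_len(n), find, numeric(1))
    relabel <- match(root, sort(unique(root)))
    out <- lab
    out[lab > 0] <- relabel[lab[lab > 0]]
    out
}

#' Extract artifact instances from a labeled source image
#'
#' Finds the 8-connected foreground components of the artifact mask with
#' area at least \code{minArea}, and crops each to its bounding box plus a
#' 2-pixel margin (clipped at the image border; the margin keeps later 3x3
#' blurs away from the crop edge). Non-component pixels inside the crop are
#' whitened to 255 so each overlay is in canonical white-background form.
#' Overlays are ordered by component top-left corner, row-major. With
#' \code{splitComponents = FALSE} the whole mask is extracted as a single
#' overlay instead.
#'
#' @param source a \linkS4class{SlidePreview} whose mask marks the artifact
#'   (white ROI on black background).
#' @param category artifact category assigned to the extracted overlays.
#' @param minArea minimum component area in pixels (default 9, drops
#'   labeling specks).
#' @param splitComponents split per 8-connected component (default) or keep
#'   the whole mask as one overlay.
#' @return List of \linkS4class{ArtifactOverlay} (possibly empty).
#' @export
extractArtifacts <- function(source, category, minArea = 9L,
                             splitComponents = TRUE) {
    stopifnot(is(source, "SlidePreview"), minArea >= 1L)
    if (is.null(source@mask)) stop("source sample has no artifact mask")
    stopifnot(category %in% artifactCategories())
    mask <- source@mask
    if (!any(mask > 0L)) return(list())
    lab <- if (splitComponents) label8(mask)
           else matrix(as.numeric(mask > 0L), nrow(mask), ncol(mask))
    ids <- setdiff(sort(unique(as.vector(lab))), 0)
    comps <- list()
    for (k in ids) {
        idx <- which(lab == k, arr.ind = TRUE)
        if (nrow(idx) < minArea) next
        comps[[length(comps) + 1L]] <- idx
    }
    if (!length(comps)) return(list())
    # row-major order of the component bounding-box top-left corners
    tl <- t(vapply(comps, function(idx) c(min(idx[, 1]), min(idx[, 2])),
                   numeric(2)))
    ord <- order(tl[, 1], tl[, 2])
    comps <- comps[ord]
    h <- nrow(mask); w <- ncol(mask)
    out <- vector("list", length(comps))
    for (i in seq_along(comps)) {
        idx <- comps[[i]]
        r0 <- max(1L, min(idx[, 1]) - 2L); r1 <- min(h, max(idx[, 1]) + 2L)
        c0 <- max(1L, min(idx[, 2]) - 2L); c1 <- min(w, max(idx[, 2]) + 2L)
        cm <- matrix(0L, r1 - r0 + 1L, c1 - c0 + 1L)
        cm[cbind(idx[, 1] - r0 + 1L, idx[, 2] - c0 + 1L)] <- 255L
        patch <- source@image[r0:r1, c0:c1, , drop = FALSE]
        out[[i]] <- artifactOverlay(patch, cm, category,
            sourceId = source@id,
            overlayId = sprintf("%s-%s-%03d", source@id, category, i))
    }
    out
}

#' Save an artifact bank to a directory
#'
#' Layout: \code{<category>/<id>.png} + \code{<category>/<id>.mask.png} and
#' a \code{manifest.json} listing id, category, source_id, width and height
#' per overlay.
#'
#' @param bank an \linkS4class{ArtifactBank}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
saveBank <- function(bank, dir) {
    stopifnot(is(bank, "ArtifactBank"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    entries <- lapply(bank@overlays, function(o) {
        sub <- file.path(dir, o@category)
        dir.create(sub, showWarnings = FALSE)
        png::writePNG(o@patch / 255, file.path(sub,
                                               paste0(o@overlayId, ".png")))
        png::writePNG(o@mask / 255,
                      file.path(sub, paste0(o@overlayId, ".mask.png")))
        list(id = o@overlayId, category = o@category,
             source_id = o@sourceId, width = ncol(o@mask),
             height = nrow(o@mask))
    })
    manifest <- file.path(dir, "manifest.json")
    jsonlite::write_json(entries, manifest, auto_unbox = TRUE, pretty = TRUE)
    invisible(manifest)
}

#' Load an artifact bank from a directory
#'
#' @param dir a directory written by \code{\link{saveBank}}.
#' @return An \linkS4class{ArtifactBank} with overlays in manifest order.
#' @export
loadBank <- function(dir) {
    manifest <- file.path(dir, "manifest.json")
    if (!file.exists(manifest)) stop("no manifest.json in ", dir)
    entries <- jsonlite::read_json(manifest)
    overlays <- lapply(seq_along(entries), function(i) {
        e <- entries[[i]]
        need <- c("id", "category", "source_id")
        if (!all(need %in% names(e)))
            stop(sprintf("corrupt manifest entry %d in '%s': fields %s required",
                         i, manifest, paste(need, collapse = ", ")))
        pf <- file.path(dir, e$category, paste0(e$id, ".png"))
        mf <- file.path(dir, e$category, paste0(e$id, ".mask.png"))
        for (f in c(pf, mf)) if (!file.exists(f))
            stop("bank file missing: ", f)
        artifactOverlay(pageToRGB(png::readPNG(pf)),
                        pageToMask(png::readPNG(mf)),
                        e$category, sourceId = e$source_id, overlayId = e$id)
    })
    artifactBank(overlays)
}
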