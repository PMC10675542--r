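# Internal pixel model: integer array [rows M, cols N, 3] in 0..255 for RGB,
# integer matrix [M, N] in {0, 255} for masks. 0-based (x = col, y = row)
# offsets at the interfaces that take placements.

#' Construct a SlidePreview
#'
#' @param image numeric/integer \code{M x N x 3} array with values in 0--255
#'   (a grayscale matrix is promoted to three identical channels).
#' @param mask optional binary mask; any value > 127 becomes 255, else 0.
#' @param id sample identifier.
#' @return A \linkS4class{SlidePreview}.
#' @export
slidePreview <- function(image, mask = NULL, id = "sample") {
    if (is.matrix(image))
        image <- array(rep(image, 3L), c(dim(image), 3L))
    storage.mode(image) <- "integer"
    if (!is.null(mask)) mask <- binarizeMask(mask)
    new("SlidePreview", image = image, mask = mask, id = as.character(id))
}

#' Construct an ArtifactOverlay (canonicalizing the background to white)
#'
#' @param patch numeric/integer \code{h x w x 3} array, 0--255.
#' @param mask binary foreground mask (binarized at 127).
#' @param category one of \code{artifactCategories()}.
#' @param sourceId,overlayId identifiers.
#' @return An \linkS4class{ArtifactOverlay} with all pixels outside the mask
#'   set to 255.
#' @export
artifactOverlay <- function(patch, mask, category,
                            sourceId = "unknown", overlayId = sourceId) {
    storage.mode(patch) <- "integer"
    mask <- binarizeMask(mask)
    patch <- whitenBackground(patch, mask)
    new("ArtifactOverlay", patch = patch, mask = mask,
        category = category, sourceId = as.character(sourceId),
        overlayId = as.character(overlayId))
}

#' Construct an ArtifactBank
#'
#' @param overlays list of \linkS4class{ArtifactOverlay}.
#' @return An \linkS4class{ArtifactBank}.
#' @export
artifactBank <- function(overlays = list())
    new("ArtifactBank", overlays = overlays)

#' Construct a Placement
#'
#' @param x0,y0 0-based column/row offsets into the preview.
#' @param cropX,cropY 0-based crop starts into the overlay.
#' @return A \linkS4class{Placement}.
#' @export
placement <- function(x0 = 0L, y0 = 0L, cropX = 0L, cropY = 0L)
    new("Placement", x0 = as.integer(x0), y0 = as.integer(y0),
        cropX = as.integer(cropX), cropY = as.integer(cropY))

#' Binarize a mask at the midpoint threshold
#'
#' Any value strictly greater than 127 maps to 255, everything else to 0.
#' Accepts 0--1 scaled masks (anything with max <= 1 is first rescaled by
#' 255) and logical masks. Idempotent.
#'
#' @param m numeric/integer/logical matrix.
#' @return Integer matrix with values in \{0, 255\}.
#' @export
binarizeMask <- function(m) {
    if (is.logical(m)) m <- m * 255L
    if (length(m) && max(m) <= 1 && min(m) >= 0 && !all(m %in% c(0L, 255L)))
        m <- m * 255
    out <- ifelse(m > 127, 255L, 0L)
    storage.mode(out) <- "integer"
    matrix(out, nrow = nrow(m), ncol = ncol(m))
}

# Set all channels to 255 wherever mask is background.
whitenBackground <- function(patch, mask) {
    bg <- mask == 0L
    for (ch in 1:3) {
        pl <- patch[, , ch]
        pl[bg] <- 255L
        patch[, , ch] <- pl
    }
    storage.mode(patch) <- "integer"
    patch
}

# Strength (negative) space: S = 255 - patch inside the mask, 0 outside.
strengthField <- function(overlay) {
    s <- 255L - overlay@patch
    s <- sweep3(s, overlay@mask == 0L, 0L)
    s
}

# Rebuild a canonical patch from a strength field (rounded, clamped).
patchFromStrength <- function(s, mask) {
    p <- 255 - s
    p <- round(pmin(pmax(p, 0), 255))
    storage.mode(p) <- "integer"
    whitenBackground(p, mask)
}

# Assign `value` on all channels at TRUE positions of a logical matrix.
sweep3 <- function(arr, where, value) {
    for (ch in 1:3) {
        pl <- arr[, , ch]
        pl[where] <- value
        arr[, , ch] <- pl
    }
    arr
}

# --- EBImage bridges (EBImage stores [x = col, y = row]) ------------------

asEBImageRGB <- function(px)
    EBImage::Image(aperm(px, c(2L, 1L, 3L)) / 255, colormode = "Color")

fromEBImageRGB <- function(img) {
    a <- aperm(EBImage::imageData(img), c(2L, 1L, 3L)) * 255
    a <- round(pmin(pmax(a, 0), 255))
    storage.mode(a) <- "integer"
    a
}

asEBImageGray <- function(m) EBImage::Image(t(m) / 255)

fromEBImageGray <- function(img) binarizeMask(t(EBImage::imageData(img)) * 255)

# --- seeding ---------------------------------------------------------------

#' Derive a child seed from a master seed and a string label
#'
#' Hierarchical seeding for reproducible pipelines: the master seed is
#' combined with an identifier (e.g. sample id plus copy index) through a
#' djb2-style polynomial hash modulo 2^31 - 1, so every sample gets its own
#' independent, order-insensitive random stream.
#'
#' @param seed master integer seed.
#' @param label character label of the child stream.
#' @return An integer seed in \code{[0, 2^31 - 2]}.
#' @export
deriveSeed <- function(seed, label) {
    mod <- 2147483647
    h <- as.numeric(seed) %% mod
    for (b in utf8ToInt(as.character(label)))
        h <- (h * 33 + b) %% mod
    as.integer(h)
}

# Evaluate expr with the RNG temporarily seeded (restores prior state).
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = .GlobalEnv)
    on.exit({
        if (had) assign(".Random.seed", old, envir = .GlobalEnv)
        else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
            rm(".Random.seed", envir = .GlobalEnv)
    })
    set.seed(seed)
    expr
}

# Uniform integer in [lo, hi] inclusive.
sampleInt <- function(lo, hi, n = 1L)
    as.integer(lo) + (sample.int(as.integer(hi) - as.integer(lo) + 1L, n,
                                 replace = TRUE) - 1L)

# Draw a fresh sub-seed from the current stream.
drawSeed <- function() sample.int(2147483646L, 1L)
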