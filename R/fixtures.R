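# Synthetic slide previews, tissue masks and artifact overlays with the
# structure the augmentation method assumes: a bright glass background, a
# darker label area on the left, and one or more irregular stained tissue
# blobs darker than the background. These fixtures stand in for proprietary
# scanner preview archives; no biological realism is claimed.

#' Specify a synthetic preview fixture
#'
#' @param dims c(height, width) in pixels; default 512 x 1024, the landscape
#'   working resolution of the preparation pipeline (25 x 75 mm slides are
#'   wider than tall). Minimum 32 x 32.
#' @param nBlobsRange inclusive range of tissue blobs per slide.
#' @param blobRadiusFrac range of blob semi-axes as a fraction of the
#'   shorter image side.
#' @param stainColors list of RGB triplets sampled as tissue base color;
#'   defaults emulate eosin-pink and hematoxylin-purple staining.
#' @param backgroundRange near-white background brightness range.
#' @param labelFraction fraction of the width taken by the darker label area
#'   at the left edge (0 disables it).
#' @param seed integer seed.
#' @return A list of class \code{FixtureSpec}.
#' @export
fixtureSpec <- function(dims = c(512L, 1024L), nBlobsRange = c(1L, 3L),
                        blobRadiusFrac = c(0.12, 0.28),
                        stainColors = list(c(214, 131, 166),
                                           c(150, 112, 180),
                                           c(186, 104, 132)),
                        backgroundRange = c(235, 252),
                        labelFraction = 0.18, seed = 1L) {
    stopifnot(length(dims) == 2L, all(dims >= 32L),
              all(backgroundRange >= 0 & backgroundRange <= 255),
              labelFraction >= 0, labelFraction < 1)
    if (max(blobRadiusFrac) > 0.5)
        stop("blob radius fraction above 0.5 would exceed the image")
    structure(list(dims = as.integer(dims),
                   nBlobsRange = as.integer(nBlobsRange),
                   blobRadiusFrac = blobRadiusFrac,
                   stainColors = stainColors,
                   backgroundRange = backgroundRange,
                   labelFraction = labelFraction,
                   seed = as.integer(seed)),
              class = "FixtureSpec")
}

#' Generate a clean synthetic slide preview with its tissue mask
#'
#' Builds a near-white slide field with smooth Perlin intensity texture, a
#' darker rectangular label area at the left edge, and 1 or more irregular
#' tissue blobs (Perlin-perturbed ellipses) with interior color jitter. The
#' tissue mask is the exact union of the painted blob supports; the label
#' area is excluded from both blobs and mask. Deterministic given the spec
#' seed.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param id sample identifier.
#' @return A \linkS4class{SlidePreview}.
#' @export
generateCleanPreview <- function(spec, id = sprintf("fixture-%06d",
                                                    spec$seed)) {
    stopifnot(inherits(spec, "FixtureSpec"))
    M <- spec$dims[1]; N <- spec$dims[2]
    withSeed(spec$seed, {
        b0 <- stats::runif(1, spec$backgroundRange[1],
                           spec$backgroundRange[2])
        tex <- perlinField(M, N, frequency = 6, seed = drawSeed())
        base <- pmin(255, pmax(0, b0 + (tex - 0.5) * 8))
        img <- array(rep(base, 3L), c(M, N, 3L))
        labelW <- as.integer(floor(spec$labelFraction * N))
        if (labelW > 0L) {
            lg <- stats::runif(1, 95, 140)
            ltex <- perlinField(M, labelW, frequency = 3, seed = drawSeed())
            img[, seq_len(labelW), ] <- rep(lg + (ltex - 0.5) * 10, 3L)
        }
        mask <- matrix(0L, M, N)
        nb <- sampleInt(spec$nBlobsRange[1], spec$nBlobsRange[2])
        short <- min(M, N)
        rowIdx <- matrix(seq_len(M), M, N)
        colIdx <- matrix(seq_len(N), M, N, byrow = TRUE)
        for (b in seq_len(nb)) {
            ry <- stats::runif(1, spec$blobRadiusFrac[1],
                               spec$blobRadiusFrac[2]) * short
            rx <- stats::runif(1, spec$blobRadiusFrac[1],
                               spec$blobRadiusFrac[2]) * short
            cy <- stats::runif(1, ry + 2, M - ry - 2)
            cx <- stats::runif(1, labelW + rx + 2, N - rx - 2)
            wob <- perlinField(M, N, frequency = 5, seed = drawSeed())
            d <- sqrt(((rowIdx - cy) / ry)^2 + ((colIdx - cx) / rx)^2)
            support <- d <= 1 + 0.55 * (wob - 0.5)
            if (labelW > 0L) support[, seq_len(labelW)] <- FALSE
            if (!any(support)) next
            col <- unlist(spec$stainColors[sampleInt(
                1L, length(spec$stainColors))])
            jit <- perlinField(M, N, frequency = 8, seed = drawSeed())
            for (ch in 1:3) {
                pl <- img[, , ch]
                pl[support] <- pmin(255, pmax(0,
                    col[ch] + (jit[support] - 0.5) * 40))
                img[, , ch] <- pl
            }
            mask[support] <- 255L
        }
        slidePreview(round(img), mask, id = id)
    })
}

# paint a filled disk onto logical matrix `m`
paintDisk <- function(m, cy, cx, r) {
    h <- nrow(m); w <- ncol(m)
    rows <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
    cols <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
    for (rr in rows) {
        dy2 <- (rr - cy)^2
        cc <- cols[(cols - cx)^2 + dy2 <= r^2]
        m[rr, cc] <- TRUE
    }
    m
}

#' Generate a synthetic artifact overlay
#'
#' Emulates the four artifact classes at fixture scale: \code{felt_pen} is
#' one or more thick curved strokes of a saturated ink color at moderate
#' strength; \code{bubble} is a bright, nearly transparent interior with a
#' darker thin ring; \code{dirt} is a scatter of small dark speckles;
#' \code{brand_mark} is a block of dark glyph-like rectangles. All are
#' returned in canonical white-background form.
#'
#' @param category one of \code{artifactCategories()}.
#' @param dims c(height, width), at least 8 x 8.
#' @param seed integer seed.
#' @return An \linkS4class{ArtifactOverlay}.
#' @export
generateSyntheticArtifact <- function(category, dims = c(64L, 64L),
                                      seed = 1L) {
    if (!(category %in% artifactCategories()))
        stop("unknown artifact category: ", category)
    stopifnot(length(dims) == 2L, all(dims >= 8L))
    h <- dims[1]; w <- dims[2]
    withSeed(seed, {
        patch <- array(255, c(h, w, 3L))
        sup <- matrix(FALSE, h, w)
        if (category == "felt_pen") {
            nStroke <- sampleInt(1L, 2L)
            hue <- stats::runif(1)
            ink <- grDevices::col2rgb(grDevices::hsv(hue,
                s = stats::runif(1, 0.6, 0.95),
                v = stats::runif(1, 0.45, 0.75)))[, 1]
            thick <- max(2, round(0.07 * min(h, w)))
            for (s in seq_len(nStroke)) {
                p0 <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
                p2 <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
                p1 <- (p0 + p2) / 2 + stats::runif(2, -0.4, 0.4) * c(h, w)
                for (t in seq(0, 1, length.out = 4L * max(h, w))) {
                    q <- (1 - t)^2 * p0 + 2 * t * (1 - t) * p1 + t^2 * p2
                    if (q[1] >= 1 && q[1] <= h && q[2] >= 1 && q[2] <= w)
                        sup <- paintDisk(sup, q[1], q[2], thick)
                }
            }
            # translucent ink: moderate strength, keeps some of the white
            for (ch in 1:3) {
                pl <- patch[, , ch]
                pl[sup] <- round(0.35 * 255 + 0.65 * ink[ch])
                patch[, , ch] <- pl
            }
        } else if (category == "bubble") {
            r <- stats::runif(1, 0.3, 0.45) * min(h, w)
            cy <- h / 2 + stats::runif(1, -2, 2)
            cx <- w / 2 + stats::runif(1, -2, 2)
            sup <- paintDisk(sup, cy, cx, r)
            inner <- paintDisk(matrix(FALSE, h, w), cy, cx,
                               r - max(2, 0.06 * r))
            ring <- sup & !inner
            for (ch in 1:3) {
                pl <- patch[, , ch]
                pl[inner] <- round(stats::runif(1, 238, 250))
                pl[ring] <- round(stats::runif(1, 130, 170))
                patch[, , ch] <- pl
            }
        } else if (category == "dirt") {
            n <- sampleInt(6L, 18L)
            shade <- round(stats::runif(n, 50, 120))
            for (i in seq_len(n)) {
                d <- paintDisk(matrix(FALSE, h, w),
                               stats::runif(1, 2, h - 1),
                               stats::runif(1, 2, w - 1),
                               stats::runif(1, 1, max(2, 0.04 * min(h, w))))
                sup <- sup | d
                tint <- shade[i] + c(10, 0, -8)   # brownish speckles
                for (ch in 1:3) {
                    pl <- patch[, , ch]
                    pl[d] <- min(255, max(0, tint[ch]))
                    patch[, , ch] <- pl
                }
            }
        } else { # brand_mark
            nGlyph <- sampleInt(2L, 4L)
            gw <- max(2L, as.integer(w / (2L * nGlyph + 1L)))
            gh <- max(3L, as.integer(0.4 * h))
            top <- as.integer((h - gh) / 2) + 1L
            dark <- round(stats::runif(1, 25, 80))
            for (g in seq_len(nGlyph)) {
                left <- as.integer(g * 2L * gw - gw) + 1L
                right <- min(w, left + gw - 1L)
                sup[top:min(h, top + gh - 1L), left:right] <- TRUE
            }
            patch <- sweep3(patch, sup, dark)
        }
        if (!any(sup)) sup[round(h / 2), round(w / 2)] <- TRUE
        artifactOverlay(round(patch), sup, category,
                        sourceId = sprintf("synthetic-%s-%d", category, seed),
                        overlayId = sprintf("synthetic-%s-%d", category,
                                            seed))
    })
}

#' Generate a fixture dataset on disk
#'
#' Writes \code{n} clean synthetic previews as multilayer TIFs plus a
#' fixture artifact bank, with a manifest recording the per-sample seeds.
#' Fully deterministic under the master seed.
#'
#' @param n number of preview samples (>= 1).
#' @param dir output directory; previews go to \code{dir/previews}, the bank
#'   to \code{dir/bank}.
#' @param spec a \code{\link{fixtureSpec}} (its seed is overridden
#'   per sample from the master seed).
#' @param seed master seed.
#' @param bankPerCategory overlays generated per artifact category.
#' @param bankDims dimensions of generated artifact overlays.
#' @return List with \code{paths} (the TIF files), \code{bankDir} and
#'   \code{manifest}.
#' @export
generateFixtureDataset <- function(n, dir, spec = fixtureSpec(),
                                   seed = 1L, bankPerCategory = 2L,
                                   bankDims = c(64L, 64L)) {
    stopifnot(n >= 1L)
    pdir <- file.path(dir, "previews")
    dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(n)
    seeds <- integer(n)
    for (i in seq_len(n)) {
        id <- sprintf("fixture-%03d", i)
        seeds[i] <- deriveSeed(seed, id)
        s <- spec
        s$seed <- seeds[i]
        sm <- generateCleanPreview(s, id = id)
        paths[i] <- file.path(pdir, paste0(id, ".tif"))
        writeMultilayerTif(sm, paths[i])
    }
    ovl <- list()
    for (cc in artifactCategories())
        for (j in seq_len(bankPerCategory))
            ovl[[length(ovl) + 1L]] <- generateSyntheticArtifact(
                cc, dims = bankDims,
                seed = deriveSeed(seed, paste0("bank-", cc, "-", j)))
    bankDir <- file.path(dir, "bank")
    saveBank(artifactBank(ovl), bankDir)
    manifest <- file.path(dir, "fixtures.json")
    jsonlite::write_json(list(master_seed = seed,
                              samples = data.frame(id = basename(paths),
                                                   seed = seeds)),
                         manifest, auto_unbox = TRUE, pretty = TRUE)
    list(paths = paths, bankDir = bankDir, manifest = manifest)
}
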