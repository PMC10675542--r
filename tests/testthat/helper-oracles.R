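# Shared fixtures and independent oracles. The oracles are deliberately
# naive (explicit loops, BFS) so they share no code with the implementation
# they check.

randomPreview <- function(h, w, seed, withMask = TRUE) {
    set.seed(seed)
    img <- array(sample.int(256L, h * w * 3L, replace = TRUE) - 1L,
                 c(h, w, 3L))
    mask <- if (withMask)
        matrix(sample(c(0L, 255L), h * w, replace = TRUE), h, w)
    else NULL
    slidePreview(img, mask, id = sprintf("rand-%d", seed))
}

randomOverlay <- function(h, w, seed, category = "dirt", density = 0.4) {
    set.seed(seed)
    mask <- matrix(sample(c(0L, 255L), h * w, replace = TRUE,
                          prob = c(1 - density, density)), h, w)
    if (!any(mask > 0L)) mask[1, 1] <- 255L
    patch <- array(sample.int(256L, h * w * 3L, replace = TRUE) - 1L,
                   c(h, w, 3L))
    artifactOverlay(patch, mask, category,
                    sourceId = sprintf("rnd-%d", seed),
                    overlayId = sprintf("rnd-%d", seed))
}

# Eq-style subtractive blend, written as an explicit per-pixel triple loop.
bruteCompose <- function(img, patch, x0, y0, cropX, cropY) {
    M <- dim(img)[1]; N <- dim(img)[2]
    oh <- dim(patch)[1]; ow <- dim(patch)[2]
    hEff <- min(oh, M); wEff <- min(ow, N)
    out <- img
    for (c in 1:3)
        for (yy in seq_len(hEff))
            for (xx in seq_len(wEff)) {
                iIn <- img[y0 + yy, x0 + xx, c]
                iOv <- patch[cropY + yy, cropX + xx, c]
                out[y0 + yy, x0 + xx, c] <- max(0L, iIn + iOv - 255L)
            }
    out
}

# 8-connected components by BFS flood fill; returns a label matrix.
bruteLabel8 <- function(mask) {
    h <- nrow(mask); w <- ncol(mask)
    lab <- matrix(0L, h, w)
    nxt <- 0L
    for (r in seq_len(h)) for (c in seq_len(w)) {
        if (mask[r, c] > 0L && lab[r, c] == 0L) {
            nxt <- nxt + 1L
            queue <- list(c(r, c))
            lab[r, c] <- nxt
            while (length(queue)) {
                p <- queue[[1]]; queue <- queue[-1]
                for (dr in -1:1) for (dc in -1:1) {
                    rr <- p[1] + dr; cc <- p[2] + dc
                    if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
                        mask[rr, cc] > 0L && lab[rr, cc] == 0L) {
                        lab[rr, cc] <- nxt
                        queue[[length(queue) + 1L]] <- c(rr, cc)
                    }
                }
            }
        }
    }
    lab
}

# Per-pixel confusion tally with an explicit double loop.
bruteConfusion <- function(pred, truth) {
    tp <- fp <- tn <- fn <- 0L
    for (r in seq_len(nrow(pred))) for (c in seq_len(ncol(pred))) {
        p <- pred[r, c] > 127
        t <- truth[r, c] > 127
        if (p && t) tp <- tp + 1L
        else if (p && !t) fp <- fp + 1L
        else if (!p && t) fn <- fn + 1L
        else tn <- tn + 1L
    }
    c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Exact clockwise 90-degree rotation by index permutation.
bruteRot90cw <- function(m) {
    h <- nrow(m); w <- ncol(m)
    out <- matrix(m[1, 1], w, h)
    for (r in seq_len(h)) for (c in seq_len(w))
        out[c, h - r + 1L] <- m[r, c]
    out
}

smallBank <- function(seed = 100L) {
    artifactBank(list(
        generateSyntheticArtifact("felt_pen", c(40L, 40L), seed),
        generateSyntheticArtifact("bubble", c(32L, 32L), seed + 1L),
        generateSyntheticArtifact("dirt", c(32L, 32L), seed + 2L),
        generateSyntheticArtifact("brand_mark", c(24L, 48L), seed + 3L)))
}

maskedStrength <- function(o) {
    s <- 255L - overlayPatch(o)
    fg <- overlayMask(o) > 0L
    for (ch in 1:3) {
        pl <- s[, , ch]
        pl[!fg] <- 0L
        s[, , ch] <- pl
    }
    s
}
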