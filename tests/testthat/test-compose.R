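test_that("the subtractive blend follows max(0, in + over - 255)", {
    expect_identical(blendPixel(200L, 255L), 200L)   # white overlay: identity
    expect_identical(blendPixel(100L, 100L), 0L)     # clamp active
    expect_identical(blendPixel(240L, 200L), 185L)
    expect_identical(blendPixel(0L, 0L), 0L)
    expect_identical(blendPixel(255L, 255L), 255L)
    expect_error(blendPixel(300L, 0L))
})

test_that("compose matches the per-pixel triple-loop oracle", {
    for (seed in c(61, 62, 63)) {
        pv <- randomPreview(40, 48, seed)
        ov <- randomOverlay(12, 15, seed + 10)
        set.seed(seed + 20)
        pl <- samplePlacement(c(40L, 48L), c(12L, 15L))
        res <- composeOverlay(pv, ov, pl)
        expected <- bruteCompose(previewImage(pv), overlayPatch(ov),
                                 pl@x0, pl@y0, pl@cropX, pl@cropY)
        expect_identical(previewImage(res$sample), expected)
    }
})

test_that("compose never brightens and never leaks outside the footprint", {
    pv <- randomPreview(30, 30, 71)
    ov <- randomOverlay(10, 10, 72)
    pl <- placement(x0 = 5L, y0 = 8L)
    res <- composeOverlay(pv, ov, pl)
    out <- previewImage(res$sample)
    inp <- previewImage(pv)
    expect_true(all(out <= inp))
    off <- res$footprint == 0L
    for (ch in 1:3)
        expect_identical(out[, , ch][off], inp[, , ch][off])
    # inside the footprint the output is also bounded by the placed overlay
    fp <- which(res$footprint > 0L, arr.ind = TRUE)
    for (ch in 1:3)
        expect_true(all(out[cbind(fp, ch)] <=
                        overlayPatch(ov)[cbind(fp[, 1] - 8L, fp[, 2] - 5L,
                                               rep(ch, nrow(fp)))]))
    # tissue mask passes through unchanged
    expect_identical(tissueMask(res$sample), tissueMask(pv))
})

test_that("an all-white overlay is the identity", {
    pv <- randomPreview(20, 20, 73)
    patch <- array(255L, c(6, 6, 3))
    o <- new("ArtifactOverlay", patch = patch, mask = matrix(255L, 6, 6),
             category = "bubble", sourceId = "white", overlayId = "white")
    res <- composeOverlay(pv, o, placement(x0 = 3L, y0 = 3L))
    expect_identical(previewImage(res$sample), previewImage(pv))
})

test_that("placements satisfy the size-case constraints", {
    set.seed(81)
    # overlay 10x10 in a 100-wide, 50-tall preview
    for (i in 1:200) {
        pl <- samplePlacement(c(50L, 100L), c(10L, 10L))
        expect_true(pl@x0 >= 0L && pl@x0 <= 90L)
        expect_true(pl@y0 >= 0L && pl@y0 <= 40L)
        expect_identical(c(pl@cropX, pl@cropY), c(0L, 0L))
    }
    # overlay wider than the preview: cropped horizontally
    for (i in 1:200) {
        pl <- samplePlacement(c(50L, 100L), c(10L, 120L))
        expect_identical(pl@x0, 0L)
        expect_true(pl@cropX >= 0L && pl@cropX <= 20L)
    }
    # exactly preview-sized: unique placement
    pl <- samplePlacement(c(50L, 100L), c(50L, 100L))
    expect_identical(c(pl@x0, pl@y0, pl@cropX, pl@cropY), rep(0L, 4))
    # mixed case: wider but shorter
    pl <- samplePlacement(c(50L, 100L), c(20L, 130L))
    expect_identical(pl@x0, 0L)
    expect_true(pl@cropX <= 30L && pl@cropY == 0L && pl@y0 <= 30L)
})

test_that("oversized overlays are cropped to the preview window", {
    pv <- randomPreview(20, 20, 74)
    ov <- randomOverlay(30, 25, 75)
    pl <- placement(cropX = 3L, cropY = 5L)
    res <- composeOverlay(pv, ov, pl)
    expected <- bruteCompose(previewImage(pv), overlayPatch(ov),
                             0L, 0L, 3L, 5L)
    expect_identical(previewImage(res$sample), expected)
    expect_error(composeOverlay(pv, ov, placement(x0 = 1L, cropX = 3L,
                                                  cropY = 5L)),
                 "invalid placement")
})

test_that("disjoint overlays compose order-independently", {
    pv <- randomPreview(40, 40, 76)
    o1 <- randomOverlay(8, 8, 77)
    o2 <- randomOverlay(8, 8, 78)
    p1 <- placement(x0 = 2L, y0 = 2L)
    p2 <- placement(x0 = 25L, y0 = 25L)
    ab <- composeOverlay(composeOverlay(pv, o1, p1)$sample, o2, p2)$sample
    ba <- composeOverlay(composeOverlay(pv, o2, p2)$sample, o1, p1)$sample
    expect_identical(previewImage(ab), previewImage(ba))
})

test_that("augmentSample is deterministic and fully recorded", {
    pv <- generateCleanPreview(fixtureSpec(dims = c(64L, 96L), seed = 5L))
    bank <- smallBank()
    cfg <- augmentationConfig()
    r1 <- augmentSample(pv, bank, cfg, seed = 404L)
    r2 <- augmentSample(pv, bank, cfg, seed = 404L)
    expect_identical(previewImage(r1$sample), previewImage(r2$sample))
    expect_identical(length(r1$records), length(r2$records))
    expect_identical(tissueMask(r1$sample), tissueMask(pv))
    # changed pixels are inside the union footprint
    diffAny <- (previewImage(r1$sample)[, , 1] != previewImage(pv)[, , 1]) |
               (previewImage(r1$sample)[, , 2] != previewImage(pv)[, , 2]) |
               (previewImage(r1$sample)[, , 3] != previewImage(pv)[, , 3])
    expect_true(all(r1$footprint[diffAny] > 0L))
    # replaying the records reproduces the augmented image bit-exactly
    cur <- pv
    for (rec in r1$records) cur <- replayRecord(cur, bank, rec)$sample
    expect_identical(previewImage(cur), previewImage(r1$sample))
})

test_that("zero-overlay augmentation is the identity", {
    pv <- randomPreview(24, 24, 79)
    cfg <- augmentationConfig(overlayCountRange = c(0L, 0L))
    res <- augmentSample(pv, smallBank(), cfg, seed = 1L)
    expect_identical(previewImage(res$sample), previewImage(pv))
    expect_length(res$records, 0L)
})

test_that("augmentation with an empty candidate pool errors out", {
    pv <- randomPreview(24, 24, 80)
    cfg <- augmentationConfig()
    expect_error(augmentSample(pv, artifactBank(), cfg, seed = 1L),
                 "no overlay category")
    # exclusions can empty the pool for a sample type
    cfgEx <- augmentationConfig(
        categoryWeights = c(felt_pen = 1, bubble = 0, dirt = 0,
                            brand_mark = 0),
        exclusions = list(smear = "felt_pen"))
    expect_error(augmentSample(pv, smallBank(), cfgEx, seed = 1L,
                               sampleType = "smear"),
                 "no overlay category")
})
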