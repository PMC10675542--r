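test_that("scaling follows the floor(dim * factor + 0.5) rule", {
    o <- randomOverlay(10, 10, 41)
    expect_identical(scaleOverlay(o, 1.0), o)
    s <- scaleOverlay(o, 0.75)
    expect_identical(dim(overlayMask(s)), c(8L, 8L))   # 7.5 rounds to 8
    s2 <- scaleOverlay(o, 1.25)
    expect_identical(dim(overlayMask(s2)), c(13L, 13L)) # 12.5 rounds to 13
    o2 <- randomOverlay(7, 13, 42)
    for (f in c(0.8, 1.1, 1.21)) {
        sc <- scaleOverlay(o2, f)
        expect_identical(dim(overlayMask(sc)),
                         c(max(1L, as.integer(floor(7 * f + 0.5))),
                           max(1L, as.integer(floor(13 * f + 0.5)))))
        expect_true(validObject(sc))
    }
    expect_error(scaleOverlay(o, 0), "positive")
    expect_error(scaleOverlay(o, -1), "positive")
})

test_that("90-degree rotation is the exact index permutation", {
    o <- randomOverlay(9, 14, 43)
    r <- rotateOverlay(o, 90L)
    expect_identical(dim(overlayMask(r)), c(14L, 9L))
    expect_identical(overlayMask(r), bruteRot90cw(overlayMask(o)))
    for (ch in 1:3)
        expect_identical(r@patch[, , ch], bruteRot90cw(o@patch[, , ch]))
    expect_identical(sum(overlayMask(r) > 0L), sum(overlayMask(o) > 0L))
})

test_that("rotation identities and involutions hold", {
    o <- randomOverlay(11, 8, 44)
    expect_identical(rotateOverlay(o, 0L), o)
    r180 <- rotateOverlay(rotateOverlay(o, 180L), 180L)
    expect_identical(overlayPatch(r180), overlayPatch(o))
    expect_identical(overlayMask(r180), overlayMask(o))
    r <- rotateOverlay(rotateOverlay(rotateOverlay(rotateOverlay(o, 90L),
                                                   90L), 90L), 90L)
    expect_identical(overlayPatch(r), overlayPatch(o))
    expect_error(rotateOverlay(o, 360), "\\[0, 359\\]")
    expect_error(rotateOverlay(o, -5), "\\[0, 359\\]")
})

test_that("general-angle rotation expands the canvas and stays valid", {
    o <- randomOverlay(20, 30, 45, density = 0.7)
    for (ang in c(37L, 120L, 301L)) {
        r <- rotateOverlay(o, ang)
        expect_true(all(dim(overlayMask(r)) >= 1L))
        expect_true(validObject(r))
        # canvas expanded: rotated bounding box can't be smaller than both dims
        expect_gte(prod(dim(overlayMask(r))), prod(dim(overlayMask(o))))
    }
})

test_that("mirroring is an involution and 'both' composes the two axes", {
    o <- randomOverlay(12, 9, 46)
    for (ax in c("horizontal", "vertical", "both")) {
        m2 <- mirrorOverlay(mirrorOverlay(o, ax), ax)
        expect_identical(overlayPatch(m2), overlayPatch(o))
        expect_identical(overlayMask(m2), overlayMask(o))
        expect_identical(sum(overlayMask(mirrorOverlay(o, ax)) > 0L),
                         sum(overlayMask(o) > 0L))
    }
    expect_identical(
        overlayPatch(mirrorOverlay(o, "both")),
        overlayPatch(mirrorOverlay(mirrorOverlay(o, "horizontal"),
                                   "vertical")))
    expect_identical(mirrorOverlay(o, "none"), o)
})

test_that("hue replacement preserves saturation and value within 1 level", {
    o <- generateSyntheticArtifact("felt_pen", c(30L, 30L), seed = 7L)
    fg <- overlayMask(o) > 0L
    before <- grDevices::rgb2hsv(overlayPatch(o)[, , 1][fg],
                                 overlayPatch(o)[, , 2][fg],
                                 overlayPatch(o)[, , 3][fg],
                                 maxColorValue = 255)
    for (hue in c(0L, 45L, 120L, 180L)) {
        h <- hueSet(o, hue)
        px <- overlayPatch(h)
        after <- grDevices::rgb2hsv(px[, , 1][fg], px[, , 2][fg],
                                    px[, , 3][fg], maxColorValue = 255)
        # S and V compared on the 8-bit scale: within +-1 intensity level
        expect_lte(max(abs(round(after[3, ] * 255) -
                           round(before[3, ] * 255))), 1)
        expect_lte(max(abs(round(after[2, ] * 255) -
                           round(before[2, ] * 255))), 1)
        # hue actually lands where asked (circular distance, half-degrees)
        dh <- abs(after[1, ] * 180 - (hue %% 180))
        expect_lte(max(pmin(dh, 180 - dh)), 1)
        # untouched outside the mask
        for (ch in 1:3)
            expect_identical(px[, , ch][!fg], overlayPatch(o)[, , ch][!fg])
    }
    expect_error(hueSet(o, 181), "\\[0, 180\\]")
})

test_that("hue replacement is idempotent to within one intensity level", {
    o <- generateSyntheticArtifact("felt_pen", c(24L, 24L), seed = 9L)
    once <- hueSet(o, 60L)
    twice <- hueSet(once, 60L)
    expect_lte(max(abs(overlayPatch(twice) - overlayPatch(once))), 1L)
})

test_that("gray pixels are unchanged by hue replacement", {
    patch <- array(120L, c(8, 8, 3))                 # saturation 0
    mask <- matrix(255L, 8, 8)
    o <- artifactOverlay(patch, mask, "felt_pen")
    for (hue in c(0L, 90L, 179L))
        expect_identical(overlayPatch(hueSet(o, hue)), overlayPatch(o))
})

test_that("scratches only touch line pixels inside the mask and zero them at factor 0", {
    patch <- array(55L, c(5, 5, 3))                  # uniform strength 200
    mask <- matrix(255L, 5, 5)
    o <- artifactOverlay(patch, mask, "felt_pen")
    s <- addScratches(o, count = 1L, factor = 0, seed = 17L)
    changed <- overlayPatch(s)[, , 1] != overlayPatch(o)[, , 1]
    expect_true(any(changed))                        # a line crossed the mask
    expect_true(all(overlayPatch(s)[, , 1][changed] == 255L))
    expect_true(all(overlayPatch(s)[, , 2][changed] == 255L))
    # count 0 is the identity
    expect_identical(addScratches(o, 0L), o)
    expect_error(addScratches(o, -1L), "non-negative")
})

test_that("scratch attenuation equals a manual 3x3 mean convolution", {
    o <- randomOverlay(15, 15, 48, density = 0.9)
    f <- 0.15
    s <- addScratches(o, count = 2L, factor = f, seed = 23L)
    # recover line pixels: exactly those that changed are on-line & masked;
    # rebuild the expected value with an independent padded convolution
    fg <- overlayMask(o) > 0L
    diffAny <- (overlayPatch(s)[, , 1] != overlayPatch(o)[, , 1]) |
               (overlayPatch(s)[, , 2] != overlayPatch(o)[, , 2]) |
               (overlayPatch(s)[, , 3] != overlayPatch(o)[, , 3])
    expect_true(all(fg[diffAny]))                    # never outside the mask
    # every changed pixel must satisfy s' = round(s * blurred_factor) with
    # blurred factor <= f (3x3 mean of a field bounded by f)
    sOld <- maskedStrength(o)
    sNew <- maskedStrength(s)
    expect_true(all(sNew <= sOld))
    expect_true(all(sNew[, , 1][diffAny] <=
                    ceiling(sOld[, , 1][diffAny] * f)))
})

test_that("perlin fading only lightens, respects the mask, and is seeded", {
    o <- generateSyntheticArtifact("felt_pen", c(40L, 40L), seed = 11L)
    expect_identical(perlinFade(o, 0), o)
    f1 <- perlinFade(o, 0.8, seed = 5L)
    f2 <- perlinFade(o, 0.8, seed = 5L)
    expect_identical(overlayPatch(f1), overlayPatch(f2))
    fg <- overlayMask(o) > 0L
    expect_true(all(overlayPatch(f1) >= overlayPatch(o)))   # only lightens
    for (ch in 1:3)
        expect_identical(overlayPatch(f1)[, , ch][!fg],
                         overlayPatch(o)[, , ch][!fg])
    f3 <- perlinFade(o, 0.8, seed = 6L)
    expect_false(identical(overlayPatch(f1), overlayPatch(f3)))
    expect_error(perlinFade(o, 1.5), "\\[0, 1\\]")
})

test_that("perlin fields are deterministic, in range, and respect options", {
    a <- perlinField(32, 48, 4, seed = 3L)
    b <- perlinField(32, 48, 4, seed = 3L)
    expect_identical(a, b)
    expect_gte(min(a), 0); expect_lte(max(a), 1)
    expect_identical(range(a), c(0, 1))              # normalized
    th <- perlinField(32, 48, 4, seed = 3L, threshold = 0.4)
    expect_true(all(th[th > 0] >= 0.4))
})

test_that("intensity scaling multiplies strength inside the mask", {
    patch <- array(55L, c(6, 6, 3))
    mask <- matrix(0L, 6, 6); mask[2:5, 2:5] <- 255L
    o <- artifactOverlay(patch, mask, "felt_pen")
    s <- intensityScale(o, 0.5)
    fg <- mask > 0L
    expect_true(all(overlayPatch(s)[, , 1][fg] == 155L))  # 255 - 0.5*200
    expect_true(all(overlayPatch(s)[, , 1][!fg] == 255L))
    expect_identical(intensityScale(o, 1), o)
    expect_error(intensityScale(o, 0), "\\(0, 1\\]")
    expect_error(intensityScale(o, 1.2), "\\(0, 1\\]")
})

test_that("parameter sampling respects category policy and determinism", {
    cfg <- augmentationConfig()
    set.seed(99)
    pFelt <- sampleParams(cfg, "felt_pen")
    set.seed(99)
    pFelt2 <- sampleParams(cfg, "felt_pen")
    expect_identical(pFelt, pFelt2)
    set.seed(100)
    pBub <- sampleParams(cfg, "bubble")
    expect_true(is.na(pBub@hueValue))
    expect_identical(pBub@scratchCount, 0L)
    expect_identical(pBub@perlinWeight, 0)
    expect_identical(pBub@intensityFactor, 1)
    allOff <- augmentationConfig(enabled = c(scale = FALSE, rotate = FALSE,
        mirror = FALSE, hue = FALSE, scratch = FALSE, perlin = FALSE,
        intensity = FALSE))
    expect_identical(sampleParams(allOff, "felt_pen"), identityParams())
})

test_that("identity parameters reproduce the overlay bit-exactly", {
    o <- randomOverlay(14, 17, 51, category = "felt_pen")
    expect_identical(applyChain(o, identityParams()), o)
})

test_that("geometric-only chains permute masked pixels exactly", {
    o <- randomOverlay(10, 16, 52, category = "felt_pen", density = 0.5)
    p <- identityParams()
    p@rotationAngle <- 90L
    p@mirrorAxis <- "horizontal"
    tr <- applyChain(o, p)
    expect_identical(sum(overlayMask(tr) > 0L), sum(overlayMask(o) > 0L))
    getRGB <- function(ov) {
        fg <- overlayMask(ov) > 0L
        cbind(overlayPatch(ov)[, , 1][fg], overlayPatch(ov)[, , 2][fg],
              overlayPatch(ov)[, , 3][fg])
    }
    a <- getRGB(o); b <- getRGB(tr)
    expect_identical(a[order(a[, 1], a[, 2], a[, 3]), ],
                     b[order(b[, 1], b[, 2], b[, 3]), ])
})

test_that("random transform chains preserve all overlay invariants", {
    cfg <- augmentationConfig()
    set.seed(123)
    for (i in 1:12) {
        cat_i <- sample(artifactCategories(), 1)
        o <- generateSyntheticArtifact(cat_i, c(24L, 28L),
                                       seed = sample.int(10000L, 1))
        tr <- applyChain(o, sampleParams(cfg, cat_i))
        expect_true(validObject(tr))
        bg <- overlayMask(tr) == 0L
        for (ch in 1:3)
            expect_true(all(overlayPatch(tr)[, , ch][bg] == 255L))
    }
})
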