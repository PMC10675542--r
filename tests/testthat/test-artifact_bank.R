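test_that("extraction matches a brute-force 8-connected component oracle", {
    for (seed in c(11, 12, 13)) {
        set.seed(seed)
        mask <- matrix(sample(c(0L, 255L), 40 * 30, replace = TRUE,
                              prob = c(0.8, 0.2)), 40, 30)
        src <- randomPreview(40, 30, seed + 100, withMask = FALSE)
        src <- slidePreview(previewImage(src), mask, id = "src")
        got <- extractArtifacts(src, "dirt", minArea = 1L)
        lab <- bruteLabel8(mask)
        expect_length(got, max(lab))
        # no pixel lost or duplicated at minArea = 1
        expect_identical(sum(vapply(got, function(o)
            sum(overlayMask(o) > 0L), numeric(1))), as.numeric(sum(mask > 0L)))
        # each overlay's mask area matches one oracle component
        expect_setequal(
            vapply(got, function(o) sum(overlayMask(o) > 0L), numeric(1)),
            as.numeric(tabulate(lab[lab > 0])))
    }
})

test_that("a single square component crops to its box plus 2-pixel margin", {
    img <- array(200L, c(100, 100, 3))
    mask <- matrix(0L, 100, 100)
    mask[31:40, 21:30] <- 255L        # 10x10 square at (x=20, y=30), 0-based
    src <- slidePreview(img, mask, id = "sq")
    got <- extractArtifacts(src, "brand_mark")
    expect_length(got, 1L)
    expect_identical(dim(overlayMask(got[[1]])), c(14L, 14L))
    expect_identical(sum(overlayMask(got[[1]]) > 0L), 100L)
})

test_that("empty masks and small components are handled", {
    img <- array(128L, c(20, 20, 3))
    src <- slidePreview(img, matrix(0L, 20, 20), id = "empty")
    expect_identical(extractArtifacts(src, "dirt"), list())
    mask <- matrix(0L, 20, 20)
    mask[3, 3] <- 255L                 # single speck below default minArea
    src <- slidePreview(img, mask, id = "speck")
    expect_identical(extractArtifacts(src, "dirt"), list())
    expect_length(extractArtifacts(src, "dirt", minArea = 1L), 1L)
})

test_that("two disjoint squares come back in row-major order", {
    img <- array(90L, c(60, 60, 3))
    mask <- matrix(0L, 60, 60)
    mask[5:9, 40:44] <- 255L           # upper right
    mask[30:34, 5:9] <- 255L           # lower left
    got <- extractArtifacts(slidePreview(img, mask, id = "two"), "dirt")
    expect_length(got, 2L)
    # first overlay is the one whose top-left corner comes first row-major
    expect_identical(overlayId(got[[1]]), "two-dirt-001")
    expect_identical(dim(overlayMask(got[[1]])), c(9L, 9L))
})

test_that("diagonal-only chains stay one component (8-connectivity)", {
    img <- array(0L, c(12, 12, 3))
    mask <- matrix(0L, 12, 12)
    for (k in 1:8) mask[k, k] <- 255L
    got <- extractArtifacts(slidePreview(img, mask, id = "diag"), "felt_pen",
                            minArea = 1L)
    expect_length(got, 1L)
    expect_identical(sum(overlayMask(got[[1]]) > 0L), 8L)
})

test_that("extracted overlays are canonical white outside the mask", {
    src <- randomPreview(30, 30, 21)
    got <- extractArtifacts(src, "dirt", minArea = 1L)
    for (o in got) {
        bg <- overlayMask(o) == 0L
        for (ch in 1:3)
            expect_true(all(overlayPatch(o)[, , ch][bg] == 255L))
    }
})

test_that("bank save/load round-trips including the empty bank", {
    dir <- withr::local_tempdir()
    b <- smallBank()
    saveBank(b, dir)
    b2 <- loadBank(dir)
    expect_identical(length(b2), length(b))
    for (i in seq_along(overlays(b))) {
        expect_identical(overlayPatch(overlays(b2)[[i]]),
                         overlayPatch(overlays(b)[[i]]))
        expect_identical(overlayMask(overlays(b2)[[i]]),
                         overlayMask(overlays(b)[[i]]))
        expect_identical(overlayCategory(overlays(b2)[[i]]),
                         overlayCategory(overlays(b)[[i]]))
    }
    empty <- withr::local_tempdir()
    saveBank(artifactBank(), empty)
    expect_identical(length(loadBank(empty)), 0L)
})

test_that("corrupt manifests are reported precisely", {
    dir <- withr::local_tempdir()
    saveBank(smallBank(), dir)
    entries <- jsonlite::read_json(file.path(dir, "manifest.json"))
    entries[[2]]$category <- NULL
    jsonlite::write_json(entries, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE)
    expect_error(loadBank(dir), "entry 2")
    saveBank(smallBank(), dir)
    file.remove(list.files(dir, pattern = "\\.mask\\.png$",
                           recursive = TRUE, full.names = TRUE)[1])
    expect_error(loadBank(dir), "missing.*mask\\.png")
    expect_error(loadBank(withr::local_tempdir()), "manifest")
})

test_that("re-compositing an extracted overlay reproduces its source", {
    # white-background source with one painted artifact
    img <- array(255L, c(50, 70, 3))
    mask <- matrix(0L, 50, 70)
    set.seed(31)
    mask[20:35, 30:50][matrix(runif(16 * 21) < 0.6, 16, 21)] <- 255L
    fg <- which(mask > 0L, arr.ind = TRUE)
    for (ch in 1:3)
        img[cbind(fg, ch)] <- sample.int(200L, nrow(fg), replace = TRUE) - 1L
    src <- slidePreview(img, mask, id = "paint")
    got <- extractArtifacts(src, "dirt", minArea = 1L,
                            splitComponents = FALSE)
    expect_length(got, 1L)
    o <- got[[1]]
    r0 <- min(fg[, 1]) - 2L; c0 <- min(fg[, 2]) - 2L
    blank <- slidePreview(array(255L, c(50, 70, 3)), mask, id = "blank")
    res <- composeOverlay(blank, o, placement(x0 = c0 - 1L, y0 = r0 - 1L))
    out <- previewImage(res$sample)
    expect_identical(out[cbind(fg, rep(1L, nrow(fg)))],
                     img[cbind(fg, rep(1L, nrow(fg)))])
    for (ch in 1:3)
        expect_identical(out[cbind(fg, rep(ch, nrow(fg)))],
                         img[cbind(fg, rep(ch, nrow(fg)))])
})
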