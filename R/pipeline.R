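# Batch orchestration: resize + split preparation, and end-to-end augmented
# dataset generation with hierarchical seeding (master seed + sample-id hash
# -> per-sample stream), so serial and parallel runs produce identical
# trees.

resizeSample <- function(sample, dims) {
    M <- as.integer(dims[1]); N <- as.integer(dims[2])
    img <- fromEBImageRGB(EBImage::resize(asEBImageRGB(sample@image),
                                          w = N, h = M,
                                          filter = "bilinear"))
    mask <- if (is.null(sample@mask)) NULL
            else fromEBImageGray(EBImage::resize(asEBImageGray(sample@mask),
                                                 w = N, h = M,
                                                 filter = "none"))
    new("SlidePreview", image = img, mask = mask, id = sample@id)
}

#' Prepare a dataset: resize and split
#'
#' Reads every multilayer TIF in \code{inputDir}, resizes images bilinearly
#' and masks nearest-neighbour (then re-binarized) to the target dimensions
#' (default 512 x 1024), writes the results to \code{outputDir}, and splits
#' the ids into training and validation sets at the given ratio (default
#' 80:20) after a seeded shuffle: \code{floor(n * ratio)} ids train, the
#' remainder validate. An optional held-out test fraction is removed before
#' the shuffle.
#'
#' @param inputDir directory of .tif multilayer annotation files.
#' @param outputDir directory for the resized copies (created; \code{NULL}
#'   skips writing).
#' @param dims target c(height, width).
#' @param ratio training fraction of the (non-test) data.
#' @param seed integer seed for the shuffle.
#' @param testFraction fraction held out before preprocessing (default 0).
#' @return List with \code{train}, \code{validation} and \code{test} id
#'   vectors, \code{ratio} and \code{files}.
#' @export
prepareDataset <- function(inputDir, outputDir = NULL,
                           dims = c(512L, 1024L), ratio = 0.8, seed = 1L,
                           testFraction = 0) {
    files <- sort(list.files(inputDir, pattern = "\\.tiff?$",
                             full.names = TRUE, ignore.case = TRUE))
    if (!length(files)) stop("no .tif files found in ", inputDir)
    stopifnot(ratio > 0, ratio < 1, testFraction >= 0, testFraction < 1)
    ids <- tools::file_path_sans_ext(basename(files))
    withSeed(seed, {
        perm <- sample(length(ids))
        nTest <- floor(length(ids) * testFraction)
        testIds <- ids[perm[seq_len(nTest)]]
        rest <- perm[setdiff(seq_along(perm), seq_len(nTest))]
        nTrain <- floor(length(rest) * ratio)
        trainIds <- ids[rest[seq_len(nTrain)]]
        valIds <- ids[rest[setdiff(seq_along(rest), seq_len(nTrain))]]
    })
    outFiles <- files
    if (!is.null(outputDir)) {
        dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
        keep <- !(ids %in% testIds)
        outFiles <- character(0)
        for (i in which(keep)) {
            sm <- resizeSample(readMultilayerTif(files[i]), dims)
            out <- file.path(outputDir, basename(files[i]))
            writeMultilayerTif(sm, out)
            outFiles <- c(outFiles, out)
        }
    }
    list(train = sort(trainIds), validation = sort(valIds),
         test = sort(testIds), ratio = ratio, files = outFiles)
}

#' Run overlay augmentation over a dataset
#'
#' For every multilayer TIF in \code{inputDir}, writes the original and
#' \code{copies} augmented variants to \code{outputDir} (originals are
#' always co-emitted: augmentation extends the training set, it does not
#' replace it). Each augmented variant keeps the tissue mask byte-identical
#' to its source, and is accompanied by its artifact footprint mask
#' (\code{<id>.aug<k>.footprint.png}) and a JSON-lines provenance file
#' (\code{records.jsonl}). A run log (\code{run.json}) stores the master
#' seed, a config fingerprint and counts. Per-sample seeds are derived
#' hierarchically, so reruns with the same seed and config are bit
#' identical.
#'
#' @param inputDir directory of multilayer TIFs.
#' @param bank an \linkS4class{ArtifactBank} or a bank directory path.
#' @param config an \linkS4class{AugmentationConfig}.
#' @param outputDir output directory (created).
#' @param copies augmented variants per input sample (m >= 0).
#' @param sampleTypes optional named character vector id -> sample type,
#'   matched against \code{config@exclusions}.
#' @return Invisibly, a list with \code{written} (paths), \code{log} (run
#'   log path) and \code{records} (provenance path).
#' @export
runAugmentation <- function(inputDir, bank, config, outputDir,
                            copies = 1L, sampleTypes = NULL) {
    stopifnot(is(config, "AugmentationConfig"), copies >= 0L)
    if (is.character(bank)) bank <- loadBank(bank)
    files <- sort(list.files(inputDir, pattern = "\\.tiff?$",
                             full.names = TRUE, ignore.case = TRUE))
    if (!length(files)) stop("no .tif files found in ", inputDir)
    # fail before any writes if the config asks for unavailable categories
    if (copies > 0L && config@overlayCountRange[2] > 0L) {
        avail <- categoriesPresent(bank)
        wanted <- names(config@categoryWeights)[config@categoryWeights > 0]
        if (!length(intersect(wanted, avail)))
            stop("configuration requests categories (",
                 paste(wanted, collapse = ", "),
                 ") but the bank only has: ",
                 if (length(avail)) paste(avail, collapse = ", ")
                 else "none")
    }
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    recPath <- file.path(outputDir, "records.jsonl")
    recCon <- file(recPath, open = "wt")
    on.exit(close(recCon), add = TRUE)
    written <- character(0)
    nAug <- 0L
    for (f in files) {
        sm <- readMultilayerTif(f)
        orig <- file.path(outputDir, basename(f))
        writeMultilayerTif(sm, orig)
        written <- c(written, orig)
        stype <- if (!is.null(sampleTypes)) unname(sampleTypes[sm@id])
                 else NULL
        for (k in seq_len(copies)) {
            sd <- deriveSeed(config@seed, paste0(sm@id, "#", k))
            res <- augmentSample(sm, bank, config, seed = sd,
                                 sampleType = stype)
            augId <- sprintf("%s.aug%02d", sm@id, k)
            augPath <- file.path(outputDir, paste0(augId, ".tif"))
            aug <- res$sample
            aug@id <- augId
            writeMultilayerTif(aug, augPath)
            png::writePNG(res$footprint / 255,
                          file.path(outputDir,
                                    paste0(augId, ".footprint.png")))
            line <- jsonlite::toJSON(
                list(id = augId, source = sm@id, seed = sd,
                     overlays = lapply(res$records, recordToList)),
                auto_unbox = TRUE, null = "null")
            writeLines(line, recCon)
            written <- c(written, augPath)
            nAug <- nAug + 1L
        }
    }
    logPath <- file.path(outputDir, "run.json")
    jsonlite::write_json(list(seed = config@seed,
                              config_hash = configFingerprint(config),
                              inputs = length(files), copies = copies,
                              augmented = nAug),
                         logPath, auto_unbox = TRUE, pretty = TRUE)
    invisible(list(written = written, log = logPath, records = recPath))
}

# Stable fingerprint of a configuration (djb2 over its JSON serialization).
configFingerprint <- function(config) {
    sl <- slotNames(config)
    vals <- lapply(sl, function(s) slot(config, s))
    names(vals) <- sl
    json <- jsonlite::toJSON(vals, auto_unbox = TRUE, digits = 10,
                             force = TRUE)
    sprintf("%08x", deriveSeed(5381L, json))
}
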