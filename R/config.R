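#' Build an augmentation configuration
#'
#' Defaults reproduce the published method: every transform enabled, scale
#' factor uniform in \[0.75, 1.25\], integer rotation angle in \[0, 359\],
#' mirror axis drawn from \{none, horizontal, vertical, both\}, hue in
#' \[0, 180\], 1--10 scratch lines with factor in \[0, 0.2\], Perlin fade
#' weight in \[0, 1\] (frequency 4, normalized, no threshold), intensity
#' factor \code{sqrt(U(0.3, 0.7))}, and 1--3 overlays per augmented sample
#' with equal category weights. Content transforms apply to felt-pen
#' overlays only unless \code{contentCategories} says otherwise.
#'
#' @param enabled named logical over
#'   \code{c("scale","rotate","mirror","hue","scratch","perlin","intensity")};
#'   unnamed entries keep their defaults (all TRUE).
#' @param scaleRange,rotationRange,hueRange,scratchCountRange,
#'   scratchFactorRange,perlinWeightRange,intensityURange length-2 sampling
#'   ranges.
#' @param perlinOctaves,perlinThreshold,perlinNormalize Perlin field
#'   settings.
#' @param overlayCountRange inclusive range of overlays per sample.
#' @param contentCategories categories eligible for content transforms.
#' @param categoryWeights named non-negative weights over categories.
#' @param exclusions named list mapping sample types to excluded categories.
#' @param seed master seed for pipeline runs.
#' @return An \linkS4class{AugmentationConfig}.
#' @export
augmentationConfig <- function(enabled = NULL,
                               scaleRange = c(0.75, 1.25),
                               rotationRange = c(0L, 359L),
                               hueRange = c(0L, 180L),
                               scratchCountRange = c(1L, 10L),
                               scratchFactorRange = c(0, 0.2),
                               perlinWeightRange = c(0, 1),
                               intensityURange = c(0.3, 0.7),
                               perlinOctaves = 4,
                               perlinThreshold = NA_real_,
                               perlinNormalize = TRUE,
                               overlayCountRange = c(1L, 3L),
                               contentCategories = "felt_pen",
                               categoryWeights = NULL,
                               exclusions = list(),
                               seed = 1L) {
    en <- c(scale = TRUE, rotate = TRUE, mirror = TRUE, hue = TRUE,
            scratch = TRUE, perlin = TRUE, intensity = TRUE)
    if (!is.null(enabled)) {
        stopifnot(all(names(enabled) %in% names(en)))
        en[names(enabled)] <- enabled
    }
    if (is.null(categoryWeights))
        categoryWeights <- stats::setNames(rep(1, 4), artifactCategories())
    new("AugmentationConfig", enabled = en,
        scaleRange = as.numeric(scaleRange),
        rotationRange = as.integer(rotationRange),
        hueRange = as.integer(hueRange),
        scratchCountRange = as.integer(scratchCountRange),
        scratchFactorRange = as.numeric(scratchFactorRange),
        perlinWeightRange = as.numeric(perlinWeightRange),
        intensityURange = as.numeric(intensityURange),
        perlinOctaves = perlinOctaves, perlinThreshold = perlinThreshold,
        perlinNormalize = perlinNormalize,
        overlayCountRange = as.integer(overlayCountRange),
        contentCategories = contentCategories,
        categoryWeights = categoryWeights, exclusions = exclusions,
        seed = as.integer(seed))
}

#' Read an augmentation configuration from a YAML or JSON file
#'
#' Keys mirror the \code{\link{augmentationConfig}} arguments (snake_case
#' accepted), e.g. \code{scale: [0.75, 1.25]}, \code{rotation: [0, 359]},
#' \code{hue: [0, 180]}, \code{scratch_factor: [0.0, 0.2]},
#' \code{intensity_u: [0.3, 0.7]}.
#'
#' @param path path to a .yaml/.yml or .json file.
#' @return An \linkS4class{AugmentationConfig}.
#' @export
readAugmentationConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
           else jsonlite::read_json(path, simplifyVector = TRUE)
    pick <- function(...) {
        for (k in c(...)) if (!is.null(raw[[k]])) return(raw[[k]])
        NULL
    }
    args <- list(
        enabled = { e <- pick("enabled"); if (is.null(e)) NULL else
            stats::setNames(as.logical(unlist(e)), names(unlist(e))) },
        scaleRange = pick("scale", "scale_range"),
        rotationRange = pick("rotation", "rotation_range"),
        hueRange = pick("hue", "hue_range"),
        scratchCountRange = pick("scratch_count", "scratch_count_range"),
        scratchFactorRange = pick("scratch_factor", "scratch_factor_range"),
        perlinWeightRange = pick("perlin_weight", "perlin_weight_range"),
        intensityURange = pick("intensity_u", "intensity_u_range"),
        perlinOctaves = pick("perlin_octaves"),
        perlinThreshold = pick("perlin_threshold"),
        perlinNormalize = pick("perlin_normalize"),
        overlayCountRange = pick("overlay_count", "overlay_count_range"),
        contentCategories = pick("content_categories"),
        categoryWeights = { w <- pick("category_weights")
            if (is.null(w)) NULL else unlist(w) },
        exclusions = pick("exclusions"),
        seed = pick("seed"))
    args <- Filter(Negate(is.null), args)
    if (is.null(args$exclusions) && !is.null(pick("exclusions")))
        args$exclusions <- pick("exclusions")
    do.call(augmentationConfig, args)
}
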