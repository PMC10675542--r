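# Binary segmentation metrics between predicted and ground-truth masks:
# sensitivity = TP/(TP+FN), precision = TP/(TP+FP),
# F1 = 2TP/(2TP+FP+FN), IoU = TP/(TP+FP+FN). Foreground = positive.

#' Pixel confusion counts between two binary masks
#'
#' @param pred,truth binary masks of equal dimensions (matrices in
#'   \{0, 255\}, 0/1, or logical; anything > 127 after
#'   \code{\link{binarizeMask}} counts as foreground).
#' @return A \linkS4class{ConfusionCounts}.
#' @export
confusionCounts <- function(pred, truth) {
    if (!identical(dim(pred), dim(truth)))
        stop(sprintf("mask dimensions differ: pred %s vs truth %s",
                     paste(dim(pred), collapse = " x "),
                     paste(dim(truth), collapse = " x ")))
    p <- binarizeMask(pred) > 0L
    t <- binarizeMask(truth) > 0L
    new("ConfusionCounts",
        tp = as.numeric(sum(p & t)), fp = as.numeric(sum(p & !t)),
        tn = as.numeric(sum(!p & !t)), fn = as.numeric(sum(!p & t)))
}

# metric = num/den with the zero-denominator convention: 0 by default
# ("worst case"), or 1 when both masks are empty and empty = "one".
.ratio <- function(num, den, bothEmpty, empty) {
    if (den == 0) return(if (empty == "one" && bothEmpty) 1 else 0)
    num / den
}

#' @describeIn ConfusionCounts-class sensitivity (recall) TP/(TP+FN).
#' @param empty convention when a metric's denominator is 0: \code{"zero"}
#'   (default) or \code{"one"} when both masks are empty.
#' @param ... passed on.
#' @export
setMethod("sensitivity", "ConfusionCounts",
    function(x, empty = c("zero", "one"), ...) {
        empty <- match.arg(empty)
        .ratio(x@tp, x@tp + x@fn, x@tp + x@fp + x@fn == 0, empty)
    })

#' @describeIn ConfusionCounts-class precision TP/(TP+FP).
#' @export
setMethod("precision", "ConfusionCounts",
    function(x, empty = c("zero", "one"), ...) {
        empty <- match.arg(empty)
        .ratio(x@tp, x@tp + x@fp, x@tp + x@fp + x@fn == 0, empty)
    })

#' @describeIn ConfusionCounts-class F1 score 2TP/(2TP+FP+FN), the harmonic
#'   mean of sensitivity and precision.
#' @export
setMethod("f1Score", "ConfusionCounts",
    function(x, empty = c("zero", "one"), ...) {
        empty <- match.arg(empty)
        .ratio(2 * x@tp, 2 * x@tp + x@fp + x@fn, x@tp + x@fp + x@fn == 0,
               empty)
    })

#' @describeIn ConfusionCounts-class intersection over union TP/(TP+FP+FN).
#' @export
setMethod("iou", "ConfusionCounts",
    function(x, empty = c("zero", "one"), ...) {
        empty <- match.arg(empty)
        .ratio(x@tp, x@tp + x@fp + x@fn, x@tp + x@fp + x@fn == 0, empty)
    })

#' All four metrics for one mask pair
#'
#' @param pred,truth binary masks of equal dimensions.
#' @param empty zero-denominator convention, see
#'   \code{\link{sensitivity,ConfusionCounts-method}}.
#' @return List with \code{counts} (\linkS4class{ConfusionCounts}) and the
#'   numeric \code{sensitivity}, \code{precision}, \code{f1}, \code{iou}.
#' @export
segMetrics <- function(pred, truth, empty = c("zero", "one")) {
    empty <- match.arg(empty)
    cc <- confusionCounts(pred, truth)
    list(counts = cc,
         sensitivity = sensitivity(cc, empty = empty),
         precision = precision(cc, empty = empty),
         f1 = f1Score(cc, empty = empty),
         iou = iou(cc, empty = empty))
}

#' Per-category mean and standard deviation of segmentation metrics
#'
#' Mirrors the per-category evaluation design used to validate tissue
#' detection: per-image metrics aggregated as mean and standard deviation
#' within each artifact category. The default deviation is the population
#' form (divide by n); pooled-pixel metrics (counts summed before the
#' ratios) are available as an alternative aggregation.
#'
#' @param pairs list of lists with elements \code{pred}, \code{truth} and
#'   \code{category}.
#' @param sd \code{"population"} (default) or \code{"sample"}.
#' @param pooled if TRUE, additionally pool pixel counts per category and
#'   report pooled metrics.
#' @param categories optional expected category set; expected categories
#'   with no pairs are dropped from the report with a warning.
#' @param empty zero-denominator convention.
#' @return A data.frame with one row per category: \code{category},
#'   \code{n}, then \code{<metric>_mean} and \code{<metric>_sd} for
#'   sensitivity, precision, f1 and iou (plus \code{<metric>_pooled} when
#'   requested).
#' @export
evaluateByCategory <- function(pairs, sd = c("population", "sample"),
                               pooled = FALSE, categories = NULL,
                               empty = c("zero", "one")) {
    sd <- match.arg(sd)
    empty <- match.arg(empty)
    stopifnot(length(pairs) >= 1L)
    cats <- vapply(pairs, `[[`, character(1), "category")
    if (!is.null(categories)) {
        missing <- setdiff(categories, cats)
        if (length(missing))
            warning("no pairs for category: ",
                    paste(missing, collapse = ", "), call. = FALSE)
    }
    per <- lapply(pairs, function(p)
        segMetrics(p$pred, p$truth, empty = empty))
    metrics <- c("sensitivity", "precision", "f1", "iou")
    sdev <- function(v) {
        if (sd == "population") sqrt(mean((v - mean(v))^2))
        else stats::sd(v)
    }
    rows <- lapply(sort(unique(cats)), function(cc) {
        sel <- per[cats == cc]
        row <- list(category = cc, n = length(sel))
        for (m in metrics) {
            v <- vapply(sel, `[[`, numeric(1), m)
            row[[paste0(m, "_mean")]] <- mean(v)
            row[[paste0(m, "_sd")]] <- if (length(v) > 1 || sd ==
                                           "population") sdev(v) else 0
        }
        if (pooled) {
            cs <- lapply(sel, `[[`, "counts")
            tot <- new("ConfusionCounts",
                       tp = sum(vapply(cs, function(x) x@tp, numeric(1))),
                       fp = sum(vapply(cs, function(x) x@fp, numeric(1))),
                       tn = sum(vapply(cs, function(x) x@tn, numeric(1))),
                       fn = sum(vapply(cs, function(x) x@fn, numeric(1))))
            row$sensitivity_pooled <- sensitivity(tot, empty = empty)
            row$precision_pooled <- precision(tot, empty = empty)
            row$f1_pooled <- f1Score(tot, empty = empty)
            row$iou_pooled <- iou(tot, empty = empty)
        }
        as.data.frame(row, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
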