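#' Sample a 2-D Perlin gradient-noise field
#'
#' Classic lattice gradient noise with quintic fade interpolation. The
#' \code{frequency} argument is the number of lattice cells spanned by the
#' longer image axis (non-integral values allowed), matching the convention
#' of common Perlin libraries where a higher frequency yields finer noise.
#'
#' @param nrow,ncol field dimensions in pixels.
#' @param frequency lattice cells across the longer axis (default 4).
#' @param seed integer seed for the gradient directions; \code{NULL} uses the
#'   current RNG stream.
#' @param normalize if TRUE (default) min-max rescale the field to \[0, 1\];
#'   otherwise shift raw values by +0.5 and clamp to \[0, 1\].
#' @param threshold optional cutoff in \[0, 1\]: values strictly below it are
#'   zeroed after rescaling (sharpens the fade-region edges).
#' @return Numeric \code{nrow x ncol} matrix with values in \[0, 1\].
#' @export
perlinField <- function(nrow, ncol, frequency = 4, seed = NULL,
                        normalize = TRUE, threshold = NA_real_) {
    stopifnot(nrow >= 1, ncol >= 1, frequency > 0)
    long <- max(nrow, ncol)
    # pixel centres in lattice units
    uy <- (seq_len(nrow) - 0.5) / long * frequency
    ux <- (seq_len(ncol) - 0.5) / long * frequency
    ny <- floor(max(uy)) + 2L   # lattice nodes needed per axis
    nx <- floor(max(ux)) + 2L
    theta <- withSeed(seed, matrix(stats::runif(ny * nx, 0, 2 * pi), ny, nx))
    gx <- cos(theta)
    gy <- sin(theta)

    i0 <- floor(uy); j0 <- floor(ux)           # cell indices (0-based)
    dy <- uy - i0;   dx <- ux - j0             # in-cell coordinates
    fade <- function(t) t * t * t * (t * (t * 6 - 15) + 10)
    wy <- fade(dy); wx <- fade(dx)

    # dot(gradient at corner (a, b), displacement) for the full pixel grid
    corner <- function(a, b) {
        gi <- cbind(rep(i0 + a + 1L, times = ncol),
                    rep(j0 + b + 1L, each = nrow))
        ddx <- matrix(rep(dx - b, each = nrow), nrow, ncol)
        ddy <- matrix(rep(dy - a, times = ncol), nrow, ncol)
        matrix(gx[gi], nrow, ncol) * ddx + matrix(gy[gi], nrow, ncol) * ddy
    }
    n00 <- corner(0, 0); n01 <- corner(0, 1)
    n10 <- corner(1, 0); n11 <- corner(1, 1)
    WX <- matrix(rep(wx, each = nrow), nrow, ncol)
    WY <- matrix(rep(wy, times = ncol), nrow, ncol)
    top <- n00 + WX * (n01 - n00)
    bot <- n10 + WX * (n11 - n10)
    field <- top + WY * (bot - top)

    if (normalize) {
        rng <- range(field)
        field <- if (diff(rng) > 0) (field - rng[1]) / diff(rng)
                 else matrix(0.5, nrow, ncol)
    } else {
        field <- pmin(pmax(field + 0.5, 0), 1)
    }
    if (!is.na(threshold)) field[field < threshold] <- 0
    field
}
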