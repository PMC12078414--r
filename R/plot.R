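#' @include pipeline.R
NULL

#' Side-by-side Ramachandran heat maps
#'
#' Renders a reference distribution (left) and a prediction (right) with a
#' shared color scale defined by the reference range; predicted bins
#' exceeding that range are flagged by an overlaid marker.
#'
#' @param reference,predicted \linkS4class{RamachandranGrid} objects of
#'   equal resolution
#' @param main overall title (e.g. residue label)
#' @return invisibly, the shared color breaks
#' @export
plotRamachandranComparison <- function(reference, predicted, main = "") {
    if (resolution(reference) != resolution(predicted))
        stop("grids must share a resolution")
    ctr <- gridBinCenters(resolution(reference))
    rng <- range(gridProbs(reference))
    breaks <- seq(rng[1], rng[2], length.out = 65)
    pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
    op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
    on.exit(graphics::par(op))
    draw <- function(g, label) {
        m <- gridProbs(g)
        over <- m > rng[2]
        graphics::image(ctr, ctr, pmin(m, rng[2]), zlim = rng, breaks = breaks,
                        col = pal, xlab = expression(phi), ylab = expression(psi),
                        main = paste(main, label), useRaster = TRUE)
        if (any(over)) {
            idx <- which(over, arr.ind = TRUE)
            graphics::points(ctr[idx[, 1]], ctr[idx[, 2]], pch = 4,
                             col = "red", cex = 0.5)
        }
    }
    draw(reference, "reference")
    draw(predicted, "predicted")
    invisible(breaks)
}

#' L-curve plot
#'
#' @param lc result of \code{\link{lCurve}}
#' @return invisibly, the points
#' @export
plotLCurve <- function(lc) {
    pts <- lc$points
    if (is.null(pts)) stop("no L-curve points (default mode was used)")
    graphics::plot(pts$chi2, pts$dkl, log = "xy", type = "b",
                   xlab = expression(chi^2), ylab = expression(D[KL]))
    sel <- which.min(abs(pts$T - lc$selected))
    graphics::points(pts$chi2[sel], pts$dkl[sel], pch = 19, col = "red")
    graphics::text(pts$chi2, pts$dkl, labels = signif(pts$T, 2), pos = 4,
                   cex = 0.7)
    invisible(pts)
}
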