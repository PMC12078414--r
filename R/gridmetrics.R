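#' @include maxent.R
NULL

#' Histogram a dihedral time series onto the Ramachandran grid
#'
#' Pairs (phi, psi) are entered into square bins (10 x 10 degrees by
#' default) on the half-open domain [-180, 180): an angle of exactly -180
#' lands in the first bin and +180 wraps onto it.
#'
#' @param series a \linkS4class{DihedralSeries}
#' @param residue which residue (column) to histogram
#' @param resolution bin width (deg)
#' @return a \linkS4class{RamachandranGrid}
#' @export
ramachandranHistogram <- function(series, residue = 1L, resolution = 10) {
    col <- match(residue, series@residues)
    if (is.na(col)) stop("residue ", residue, " not in the series")
    phi <- .wrap180(series@phi[, col])
    psi <- .wrap180(series@psi[, col])
    if (!length(phi)) stop("empty dihedral series")
    nb <- as.integer(round(360 / resolution))
    i <- floor((phi + 180) / resolution) + 1L
    j <- floor((psi + 180) / resolution) + 1L
    m <- matrix(tabulate((j - 1L) * nb + i, nbins = nb * nb), nb, nb)
    ramachandranGrid(m, resolution)
}

#' Coarsen a Ramachandran grid
#'
#' Probability-conserving block aggregation, e.g. from the 1-degree
#' inversion grid to the 10-degree reporting grid.
#'
#' @param grid a \linkS4class{RamachandranGrid}
#' @param targetResolution coarser resolution (deg); must be a multiple of
#'   the source resolution and divide 360
#' @return a \linkS4class{RamachandranGrid}
#' @export
#' @examples
#' g <- standInCoilPrior(resolution = 2)
#' coarsen(g, 10)
coarsen <- function(grid, targetResolution) {
    res <- resolution(grid)
    f <- targetResolution / res
    if (abs(f - round(f)) > 1e-9 || 360 %% targetResolution != 0)
        stop("target resolution must be a multiple of the source resolution")
    f <- as.integer(round(f))
    if (f == 1L) return(grid)
    m <- gridProbs(grid)
    nb <- nrow(m) %/% f
    gi <- rep(seq_len(nb), each = f)
    coarse <- t(rowsum(t(rowsum(m, gi)), gi))
    dimnames(coarse) <- NULL
    ramachandranGrid(coarse, targetResolution, normalize = FALSE)
}

#' Jensen-Shannon divergence between two Ramachandran grids
#'
#' D_JS(p || r) = 0.5 * sum p log2(p/m) + 0.5 * sum r log2(r/m) with m the
#' element-wise average. Base-2 logarithms scale the result to [0, 1]: 0
#' for identical distributions, 1 for completely non-overlapping ones.
#' Empty bins follow the convention 0 * log2(0 / x) = 0.
#'
#' @param p,r \linkS4class{RamachandranGrid} objects of equal resolution
#' @return divergence in bits, within [0, 1]
#' @export
#' @examples
#' g <- standInCoilPrior(resolution = 10)
#' jsDivergence(g, g)  # 0
jsDivergence <- function(p, r) {
    if (resolution(p) != resolution(r))
        stop("grids must share a resolution")
    pv <- as.vector(gridProbs(p))
    rv <- as.vector(gridProbs(r))
    mv <- 0.5 * (pv + rv)
    term <- function(a) {
        i <- a > 0
        sum(a[i] * log2(a[i] / mv[i]))
    }
    0.5 * (term(pv) + term(rv))
}

#' Mass of each named basin under a distribution
#'
#' Assigns every bin to its nearest basin center (wrapped angular
#' distance) and sums the probability per basin — a simple way to read
#' conformational propensities off a grid.
#'
#' @param grid a \linkS4class{RamachandranGrid}
#' @param basins basin data.frame (columns basin, phi, psi)
#' @return named numeric of basin masses (sums to 1)
#' @export
basinWeights <- function(grid, basins = canonicalBasins()) {
    ctr <- gridBinCenters(resolution(grid))
    g <- expand.grid(phi = ctr, psi = ctr)
    dwrap <- function(a, b) abs(.wrap180(a - b))
    d <- sapply(seq_len(nrow(basins)), function(j)
        dwrap(g$phi, basins$phi[j])^2 + dwrap(g$psi, basins$psi[j])^2)
    nearest <- max.col(-d)
    w <- vapply(seq_len(nrow(basins)), function(j)
        sum(gridProbs(grid)[nearest == j]), numeric(1))
    stats::setNames(w, basins$basin)
}
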