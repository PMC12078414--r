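#' @include tcf.R
NULL

#' Extract a dipolar unit-vector series from a coordinate trajectory
#'
#' @param coords coordinate set (named list of n x 3 matrices keyed
#'   "atom@residue", as produced by \code{\link{chainCoordinates}} or
#'   \code{\link{buildFragment}})
#' @param atoms character(2) atom names, vector points from the first to
#'   the second
#' @param residues integer(2) residue indices (recycled if length 1)
#' @param dt frame spacing (s)
#' @return a \linkS4class{VectorTrajectory} carrying distances (Angstrom)
#' @export
dipoleSeries <- function(coords, atoms, residues, dt) {
    residues <- rep_len(residues, 2L)
    a <- fragmentAtom(coords, atoms[1], residues[1])
    b <- fragmentAtom(coords, atoms[2], residues[2])
    d <- b - a
    r <- .rowNorm(d)
    new("VectorTrajectory", vectors = d / r, distances = r, dt = dt)
}

#' Extract CSA principal-axis series from a coordinate trajectory
#'
#' Builds the instantaneous tensor frame at every frame from the
#' plane-defining bonds and returns the xx and yy axes as vector series
#' (zz never enters rate expressions: only in-plane anisotropies
#' sigma_kk - sigma_zz with k = x, y are nonzero).
#'
#' @param coords coordinate set
#' @param csa a \linkS4class{CsaTensor}
#' @param residue residue index of the CSA nucleus
#' @param dt frame spacing (s)
#' @return list of \linkS4class{VectorTrajectory}: \code{xx}, \code{yy}
#' @export
csaAxisSeries <- function(coords, csa, residue, dt) {
    fr <- csaFrame(coords, csa, residue)
    list(xx = new("VectorTrajectory", vectors = fr$xx,
                  distances = numeric(), dt = dt),
         yy = new("VectorTrajectory", vectors = fr$yy,
                  distances = numeric(), dt = dt))
}

# all component vector series a registered kind needs at a residue:
# list of list(a=, b=, label=, weighted=) ready for crossTcf
.kindSeries <- function(kind, coords, residue, dt, csas) {
    ps <- kind@participants
    side <- lapply(ps, function(p) {
        if (p$type == "dipole") {
            list(dd = dipoleSeries(coords, p$atoms, residue + p$offsets, dt))
        } else {
            csaAxisSeries(coords, csas[[p$nucleus]], residue + p$offset, dt)
        }
    })
    weighted <- kind@distanceMode == "instantaneous"
    out <- list()
    for (l1 in names(side[[1]])) for (l2 in names(side[[2]])) {
        lab <- if (kind@mechanismClass == "CSA/CSA") paste(l1, l2, sep = ".")
               else if (kind@mechanismClass == "DD/DD") "dd"
               else if (l1 == "dd") l2 else l1
        out[[lab]] <- list(a = side[[1]][[l1]], b = side[[2]][[l2]],
                           weighted = weighted)
    }
    out
}

#' Does a rate kind involve the backbone amide proton?
#'
#' Used by the blended-proxy normalization mode, which applies the blend
#' only to remote rates comprising HN-specific dynamics.
#'
#' @param kind a \linkS4class{RateKind} or rate id
#' @return logical
#' @export
kindInvolvesHN <- function(kind) {
    if (is.character(kind)) kind <- ccrRateKinds(kind)[[1]]
    any(vapply(kind@participants, function(p)
        p$type == "dipole" && "HN" %in% p$atoms, logical(1)))
}
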