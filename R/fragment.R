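#' @include constants.R
NULL

# --- row-wise 3-vector helpers (n x 3 matrices throughout) ------------------

.rowNorm <- function(m) sqrt(rowSums(m * m))

.normalizeRows <- function(m) m / .rowNorm(m)

.crossRows <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.dotRows <- function(a, b) rowSums(a * b)

.asRows <- function(v, n) {
    if (is.matrix(v)) {
        if (nrow(v) == n) v else matrix(v, n, 3, byrow = TRUE)
    } else matrix(v, n, 3, byrow = TRUE)
}

#' Measure a dihedral angle
#'
#' Returns the torsion p1-p2-p3-p4 in degrees in (-180, 180], IUPAC sign
#' convention. Inputs are length-3 vectors or n x 3 matrices (vectorized).
#'
#' @param p1,p2,p3,p4 positions
#' @return angle(s) in degrees
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
    n <- max(NROW(p1), NROW(p2), NROW(p3), NROW(p4), 1L)
    p1 <- .asRows(p1, n); p2 <- .asRows(p2, n)
    p3 <- .asRows(p3, n); p4 <- .asRows(p4, n)
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- .crossRows(b1, b2)
    n2 <- .crossRows(b2, b3)
    m1 <- .crossRows(n1, .normalizeRows(b2))
    ang <- atan2(.dotRows(m1, n2), .dotRows(n1, n2)) * 180 / pi
    if (n == 1L) ang[1L] else ang
}

#' Measure a bond angle
#'
#' Angle at p2 of the triple p1-p2-p3, degrees.
#' @param p1,p2,p3 positions (vectors or n x 3 matrices)
#' @return angle(s) in degrees
#' @export
bondAngle <- function(p1, p2, p3) {
    n <- max(NROW(p1), NROW(p2), NROW(p3), 1L)
    p1 <- .asRows(p1, n); p2 <- .asRows(p2, n); p3 <- .asRows(p3, n)
    u <- .normalizeRows(p1 - p2)
    v <- .normalizeRows(p3 - p2)
    ang <- acos(pmin(1, pmax(-1, .dotRows(u, v)))) * 180 / pi
    if (n == 1L) ang[1L] else ang
}

# Place atom D given reference atoms A-B-C, a bond length C-D, the bond
# angle B-C-D and the torsion A-B-C-D (degrees). Vectorized over frames:
# A, B, C are n x 3 (or single rows recycled), torsion may be length n.
.placeAtom <- function(A, B, C, bond, angle, torsion) {
    n <- max(NROW(A), NROW(B), NROW(C), length(torsion), length(angle), 1L)
    A <- .asRows(A, n); B <- .asRows(B, n); C <- .asRows(C, n)
    th <- angle * pi / 180
    ta <- torsion * pi / 180
    bc <- .normalizeRows(C - B)
    n1 <- .normalizeRows(.crossRows(bc, B - A))
    m1 <- .crossRows(bc, n1)
    d <- bond * cbind(-cos(th),
                      sin(th) * cos(ta),
                      sin(th) * sin(ta))
    C + d[, 1] * bc + d[, 2] * m1 + d[, 3] * n1
}

.fragmentAtomNames <- c("N@-1", "CA@-1", "C@-1", "O@-1",
                        "N@0", "HN@0", "CA@0", "HA@0", "C@0", "O@0",
                        "N@1", "HN@1", "CA@1")

#' Extract an atom's coordinates from a coordinate set
#'
#' @param coords a coordinate set as returned by \code{\link{buildFragment}}
#'   or \code{\link{chainCoordinates}} (a named list of n x 3 matrices)
#' @param atom atom name ("N", "HN", "CA", "HA", "C", "O")
#' @param offset residue offset (fragment) or residue index (chain)
#' @return an n x 3 coordinate matrix
#' @export
fragmentAtom <- function(coords, atom, offset = 0L) {
    key <- paste0(atom, "@", offset)
    if (is.null(coords[[key]]))
        stop("unknown atom requested: ", key)
    coords[[key]]
}

#' Build a rigid three-residue backbone fragment
#'
#' Constructs Cartesian coordinates of the backbone atoms spanning residues
#' i-1, i, i+1 for given central dihedrals (phi_i, psi_i), with every other
#' internal coordinate fixed by the rigid geometry (omega trans). Vectorized:
#' \code{phi} and \code{psi} may be equal-length vectors, in which case each
#' returned atom is an n x 3 matrix with one row per (phi, psi) pair.
#'
#' The atom set covers everything any registered CCR interference needs:
#' N/CA/C/O of residue i-1, the full backbone of residue i, and N/HN/CA of
#' residue i+1. Atoms are keyed "name@offset", e.g. "C@-1", "HA@0".
#'
#' @param phi,psi central-residue dihedrals (deg) in [-180, 180)
#' @param geometry a \linkS4class{BackboneGeometry}
#' @return named list of n x 3 coordinate matrices (Angstrom)
#' @export
#' @examples
#' frag <- buildFragment(-60, -45)
#' fragmentAtom(frag, "CA", 0)
buildFragment <- function(phi, psi, geometry = defaultBackboneGeometry()) {
    stopifnot(length(phi) == length(psi))
    if (any(phi < -180 | phi >= 180 | psi < -180 | psi >= 180))
        stop("phi and psi must lie in [-180, 180)")
    n <- length(phi)
    b <- geometry@bonds; a <- geometry@angles
    one <- function(v) matrix(v, n, 3, byrow = TRUE)

    # peptide plane (i-1 -> i) fixed in the lab frame, z = 0
    Ni  <- one(c(0, 0, 0))
    CAi <- one(c(b[["N-CA"]], 0, 0))
    th <- a[["C-N-CA"]] * pi / 180
    Cm1 <- one(b[["C-N"]] * c(cos(th), sin(th), 0))

    Om1  <- .placeAtom(CAi, Ni, Cm1, b[["C-O"]], a[["N-C-O"]], 0)
    CAm1 <- .placeAtom(CAi, Ni, Cm1, b[["CA-C"]], a[["CA-C-N"]], geometry@omega)
    Nm1  <- .placeAtom(Ni, Cm1, CAm1, b[["N-CA"]], a[["N-CA-C"]], geometry@psiPrev)
    HNi  <- .placeAtom(Om1, Cm1, Ni, b[["N-HN"]], a[["C-N-HN"]], 180)

    Ci  <- .placeAtom(Cm1, Ni, CAi, b[["CA-C"]], a[["N-CA-C"]], phi)
    HAi <- .placeAtom(Cm1, Ni, CAi, b[["CA-HA"]], a[["N-CA-HA"]],
                      phi + geometry@haTorsionOffset)
    Np1 <- .placeAtom(Ni, CAi, Ci, b[["C-N"]], a[["CA-C-N"]], psi)
    Oi  <- .placeAtom(Ni, CAi, Ci, b[["C-O"]], a[["CA-C-O"]], psi + 180)
    CAp1 <- .placeAtom(CAi, Ci, Np1, b[["N-CA"]], a[["C-N-CA"]], geometry@omega)
    HNp1 <- .placeAtom(Oi, Ci, Np1, b[["N-HN"]], a[["C-N-HN"]], 180)

    out <- list(Nm1, CAm1, Cm1, Om1, Ni, HNi, CAi, HAi, Ci, Oi, Np1, HNp1, CAp1)
    names(out) <- .fragmentAtomNames
    out
}

#' Orthonormal CSA principal-axis frame from coordinates
#'
#' The zz eigenvector is the unit normal of the plane instantaneously
#' spanned by the tensor's two frame bonds (C'-N and C'-O for the carbonyl;
#' N-HN and N-C' for the amide nitrogen). xx lies in the plane at the
#' tensor's angle alpha from the reference bond (rotated about zz,
#' right-handed); yy completes the right-handed triad.
#'
#' @param coords coordinate set (fragment or chain)
#' @param csa a \linkS4class{CsaTensor}
#' @param offset residue offset/index of the CSA nucleus
#' @return list with n x 3 matrices \code{xx}, \code{yy}, \code{zz}
#' @export
csaFrame <- function(coords, csa, offset = 0L) {
    if (csa@nucleus == "C") {
        org <- fragmentAtom(coords, "C", offset)
        b1 <- fragmentAtom(coords, "N", offset + 1L) - org
        b2 <- fragmentAtom(coords, "O", offset) - org
    } else {
        org <- fragmentAtom(coords, "N", offset)
        b1 <- fragmentAtom(coords, "HN", offset) - org
        b2 <- fragmentAtom(coords, "C", offset - 1L) - org
    }
    nrm <- .crossRows(b1, b2)
    ln <- .rowNorm(nrm)
    if (any(ln < 1e-10 * .rowNorm(b1) * .rowNorm(b2)))
        stop("degenerate CSA frame: plane-defining bonds are colinear")
    zz <- nrm / ln
    ref <- .normalizeRows(b1)
    al <- csa@alpha * pi / 180
    # Rodrigues rotation of the in-plane reference about zz by alpha
    xx <- ref * cos(al) + .crossRows(zz, ref) * sin(al)
    yy <- .crossRows(zz, xx)
    list(xx = xx, yy = yy, zz = zz)
}

# Apply one rotation matrix (3 x 3) to every atom of a coordinate set.
.rotateCoords <- function(coords, R) {
    lapply(coords, function(m) m %*% t(R))
}
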