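#' @include prefactors.R
NULL

#' Bin centers of the standard Ramachandran grid
#'
#' Centers at -180 + resolution/2 + k * resolution over the half-open
#' domain [-180, 180).
#'
#' @param resolution bin width (deg); must divide 360
#' @return numeric vector of bin centers
#' @export
gridBinCenters <- function(resolution) {
    if (360 %% resolution != 0) stop("360 must be divisible by resolution")
    seq(-180 + resolution / 2, 180 - resolution / 2, by = resolution)
}

# unit-vector (and distance) series of one participant, from a coordinate
# set; `base` shifts the declared residue offsets (0 for fragments, the
# residue index for chains)
.participantVectors <- function(p, coords, csas, base = 0L) {
    if (p$type == "dipole") {
        a <- fragmentAtom(coords, p$atoms[1], base + p$offsets[1])
        b <- fragmentAtom(coords, p$atoms[2], base + p$offsets[2])
        d <- b - a
        r <- .rowNorm(d)
        list(list(v = d / r, r = r, weight = 1, label = "dd"))
    } else {
        fr <- csaFrame(coords, csas[[p$nucleus]], base + p$offset)
        list(list(v = fr$xx, r = NULL, weight = 1, label = "xx"),
             list(v = fr$yy, r = NULL, weight = 1, label = "yy"))
    }
}

# amplitude of `kind` evaluated on an existing coordinate set (one value
# per row/frame); the workhorse behind buildRateSurface
.amplitudeFromCoords <- function(kind, coords, constants, geometry, csas,
                                 base = 0L) {
    pref <- prefactor(kind, constants, geometry, csas)
    ps <- kind@participants
    v1 <- .participantVectors(ps[[1]], coords, csas, base)
    v2 <- .participantVectors(ps[[2]], coords, csas, base)
    n <- nrow(v1[[1]]$v)
    out <- numeric(n)
    for (c1 in v1) for (c2 in v2) {
        lab <- if (pref$class == "CSA/CSA") paste(c1$label, c2$label, sep = ".")
               else if (pref$class == "DD/CSA") {
                   if (c1$label == "dd") c2$label else c1$label
               } else "dd"
        term <- pref$components[[lab]] * legendreP2(.dotRows(c1$v, c2$v))
        if (!pref$includesDistance) {
            # instantaneous-distance kind: geometry-determined r^3 here
            r <- if (!is.null(c1$r)) c1$r else c2$r
            term <- term / (r * 1e-10)^3
        }
        out <- out + term
    }
    out
}

#' Structural amplitude A_Gamma of a CCR rate at given dihedrals
#'
#' The static component of a rate: the sum over mechanism components of
#' prefactor times P2 of the cosine of the projection angle between the two
#' interaction vectors, evaluated on the rigid model backbone rotated to
#' (phi, psi). Multiplying A_Gamma by an effective correlation time (s)
#' gives the rate (s^-1). For the two known-amplitude kinds the result is
#' independent of (phi, psi) because both vectors lie in one rigid peptide
#' plane.
#'
#' @param kind a \linkS4class{RateKind} or a rate id string
#' @param phi,psi dihedrals (deg), vectorized
#' @param geometry,csas,constants model parameters
#' @return numeric vector of amplitudes (s^-1 per unit correlation time)
#' @export
#' @examples
#' structuralAmplitude("NHN_CAHA", -60, -45)
structuralAmplitude <- function(kind, phi, psi,
                                geometry = defaultBackboneGeometry(),
                                csas = list(C = defaultCsaTensor("C"),
                                            N = defaultCsaTensor("N")),
                                constants = physicalConstants()) {
    if (is.character(kind)) kind <- ccrRateKinds(kind)[[1]]
    coords <- buildFragment(phi, psi, geometry)
    .amplitudeFromCoords(kind, coords, constants, geometry, csas)
}

#' Tabulate structural-amplitude surfaces on the Ramachandran grid
#'
#' \code{buildRateSurfaces} builds all requested surfaces from a single
#' batch of fragments (one per grid bin), which is considerably faster than
#' building kinds one at a time; \code{buildRateSurface} is the single-kind
#' convenience wrapper. Default resolution is 1 degree (360 x 360 bins).
#'
#' @param kinds list of \linkS4class{RateKind} (default: all ten)
#' @param kind one \linkS4class{RateKind} or rate id
#' @param resolution grid resolution (deg); must divide 360
#' @param geometry,csas,constants model parameters
#' @return named list of \linkS4class{RateSurface} (or a single surface)
#' @export
#' @examples
#' s <- buildRateSurface("NHN_CAHA", resolution = 30)
#' surfaceValues(s)[1, 1]
buildRateSurfaces <- function(kinds = ccrRateKinds(), resolution = 1,
                              geometry = defaultBackboneGeometry(),
                              csas = list(C = defaultCsaTensor("C"),
                                          N = defaultCsaTensor("N")),
                              constants = physicalConstants()) {
    centers <- gridBinCenters(resolution)
    nb <- length(centers)
    grid <- expand.grid(phi = centers, psi = centers)  # phi varies fastest
    coords <- buildFragment(grid$phi, grid$psi, geometry)
    out <- lapply(kinds, function(k) {
        vals <- .amplitudeFromCoords(k, coords, constants, geometry, csas)
        new("RateSurface", rateId = k@id, resolution = resolution,
            values = matrix(vals, nb, nb), B0 = constants@B0)
    })
    names(out) <- vapply(kinds, rateId, character(1))
    out
}

#' @rdname buildRateSurfaces
#' @export
buildRateSurface <- function(kind, resolution = 1,
                             geometry = defaultBackboneGeometry(),
                             csas = list(C = defaultCsaTensor("C"),
                                         N = defaultCsaTensor("N")),
                             constants = physicalConstants()) {
    if (is.character(kind)) kind <- ccrRateKinds(kind)[[1]]
    buildRateSurfaces(list(kind), resolution, geometry, csas, constants)[[1]]
}

#' Known amplitudes of the two dynamical-proxy rates
#'
#' The N_i CSA / N_i-HN_i and C'_i CSA / C'_i-CA_i interferences pair two
#' mechanisms rigidly fixed in the same peptide plane, so their amplitudes
#' are conformation-independent constants: the tensor-dipole projection
#' angles are set by the rigid geometry alone (for the nitrogen rate only
#' the xx projection contributes because sigma_yy = sigma_zz). Dividing the
#' measured rates by these constants turns them into residue-resolved
#' correlation times.
#'
#' @param constants,geometry,csas model parameters
#' @return named numeric: \code{N_NHN} and \code{C_CCA} amplitudes
#'   (s^-1 per unit correlation time)
#' @export
#' @examples
#' knownAmplitudes()
knownAmplitudes <- function(constants = physicalConstants(),
                            geometry = defaultBackboneGeometry(),
                            csas = list(C = defaultCsaTensor("C"),
                                        N = defaultCsaTensor("N"))) {
    kinds <- ccrRateKinds(c("N_NHN", "C_CCA"))
    vapply(kinds, function(k)
        structuralAmplitude(k, -60, -45, geometry, csas, constants),
        numeric(1))
}
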