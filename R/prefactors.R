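#' @include rate-registry.R
NULL

# mean inter-nuclear distance (Angstrom) of a dipole participant, from the
# rigid geometry; NA for the non-bonded HA-HN pair (instantaneous mode)
.dipoleMeanDistance <- function(p, geometry) {
    key <- paste(sort(p$atoms), collapse = "-")
    lookup <- c("HN-N" = "N-HN", "CA-HA" = "CA-HA", "C-CA" = "CA-C",
                "C-N" = "C-N", "C-O" = "C-O")
    g <- lookup[key]
    if (is.na(g)) return(NA_real_)
    unname(geometry@bonds[[g]])
}

#' Physical prefactor(s) of one CCR interference
#'
#' Returns the constant factors multiplying each component P2 term of a
#' rate, in s^-2 (so that multiplying by a correlation integral in seconds
#' yields s^-1):
#' \itemize{
#'   \item DD/DD: a single component,
#'     (2/5) (mu0 hbar / 4 pi)^2 gamma_a gamma_b gamma_c gamma_d
#'     / (r_ab^3 r_cd^3), with mean distances in the denominator;
#'   \item DD/CSA: one component per k = x, y:
#'     (4/15) (mu0 hbar / 4 pi) gamma_a gamma_b gamma_u B0
#'     (sigma_kk - sigma_zz) / r_ab^3 (ppm converted to absolute here);
#'   \item CSA/CSA: one component per (k, l) pair:
#'     (8/45) gamma_u gamma_v B0^2 (sigma_kk - sigma_zz)(sigma_ll - sigma_zz).
#' }
#' For the instantaneous-distance kind the dipolar 1/r^3 is \emph{not}
#' folded in (\code{includesDistance = FALSE}); it travels with the time
#' correlation function instead.
#'
#' @param kind a \linkS4class{RateKind}
#' @param constants a \linkS4class{PhysicalConstants}
#' @param geometry a \linkS4class{BackboneGeometry} (mean distances)
#' @param csas named list of \linkS4class{CsaTensor} ("C", "N")
#' @return list with \code{components} (named numeric, s^-2),
#'   \code{includesDistance}, and \code{class}
#' @export
#' @examples
#' prefactor(ccrRateKinds("NHN_CAHA")[[1]])
prefactor <- function(kind, constants = physicalConstants(),
                      geometry = defaultBackboneGeometry(),
                      csas = list(C = defaultCsaTensor("C"),
                                  N = defaultCsaTensor("N"))) {
    dd <- constants@mu0 * constants@hbar / (4 * pi)
    ps <- kind@participants
    isDip <- vapply(ps, function(p) p$type == "dipole", logical(1))
    if (kind@mechanismClass == "DD/DD") {
        r <- vapply(ps, .dipoleMeanDistance, numeric(1), geometry = geometry)
        if (anyNA(r)) stop("DD/DD kinds require fixed mean distances")
        g <- prod(vapply(ps, function(p)
            prod(vapply(p$atoms, .gammaOf, numeric(1), constants = constants)),
            numeric(1)))
        val <- (2 / 5) * dd^2 * g / prod((r * 1e-10)^3)
        return(list(components = c(dd = val), includesDistance = TRUE,
                    class = kind@mechanismClass))
    }
    if (kind@mechanismClass == "DD/CSA") {
        dip <- ps[isDip][[1]]
        cs <- ps[!isDip][[1]]
        csa <- csas[[cs$nucleus]]
        if (is.null(csa)) stop("missing CSA tensor for nucleus ", cs$nucleus)
        gab <- prod(vapply(dip$atoms, .gammaOf, numeric(1), constants = constants))
        gu <- .gammaOf(cs$nucleus, constants)
        base <- (4 / 15) * dd * gab * gu * constants@B0
        dsig <- (csa@sigma[1:2] - csa@sigma[3]) * 1e-6
        comp <- base * dsig
        names(comp) <- c("xx", "yy")
        if (kind@distanceMode == "instantaneous")
            return(list(components = comp, includesDistance = FALSE,
                        class = kind@mechanismClass))
        r <- .dipoleMeanDistance(dip, geometry)
        if (is.na(r)) stop("no mean distance available for dipole ",
                           paste(dip$atoms, collapse = "-"))
        list(components = comp / (r * 1e-10)^3, includesDistance = TRUE,
             class = kind@mechanismClass)
    } else {
        csaU <- csas[[ps[[1]]$nucleus]]
        csaV <- csas[[ps[[2]]$nucleus]]
        if (is.null(csaU) || is.null(csaV))
            stop("missing CSA tensor for CSA/CSA kind ", kind@id)
        gu <- .gammaOf(ps[[1]]$nucleus, constants)
        gv <- .gammaOf(ps[[2]]$nucleus, constants)
        base <- (8 / 45) * gu * gv * constants@B0^2
        du <- (csaU@sigma[1:2] - csaU@sigma[3]) * 1e-6
        dv <- (csaV@sigma[1:2] - csaV@sigma[3]) * 1e-6
        comp <- base * as.vector(outer(du, dv))
        names(comp) <- c("xx.xx", "yy.xx", "xx.yy", "yy.yy")
        list(components = comp, includesDistance = TRUE,
             class = kind@mechanismClass)
    }
}
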