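#' @include fragment.R
NULL

.dip <- function(a, ia, b, ib)
    list(type = "dipole", atoms = c(a, b), offsets = c(ia, ib))
.csaP <- function(nucleus, offset)
    list(type = "csa", nucleus = nucleus, offset = offset)

.makeKind <- function(id, class, p1, p2, distanceMode = "fixed-mean",
                      amplitudeKnown = FALSE) {
    new("RateKind", id = id, mechanismClass = class,
        participants = list(p1, p2), distanceMode = distanceMode,
        amplitudeKnown = amplitudeKnown)
}

#' Registry of the ten CCR interferences
#'
#' Eight "remote" rates whose two mechanisms share no spin, making their
#' amplitudes functions of the backbone dihedrals (phi_i, psi_i), plus the
#' two known-amplitude rates used as dynamical proxies:
#'
#' \describe{
#'   \item{NHN_CAHA}{DD/DD, N_i-HN_i with CA_i-HA_i (phi-sensitive)}
#'   \item{CAHA_NHN1}{DD/DD, CA_i-HA_i with N_{i+1}-HN_{i+1} (psi-sensitive)}
#'   \item{NHN_NHN1}{DD/DD, sequential amide dipoles (phi and psi)}
#'   \item{HAHN1_C}{DD/CSA, the non-bonded HA_i-HN_{i+1} dipole with the
#'     C'_i CSA; the only kind using instantaneous distances}
#'   \item{NHN_C}{DD/CSA, N_i-HN_i with the C'_i CSA}
#'   \item{CAHA_Cm1}{DD/CSA, CA_i-HA_i with the C'_{i-1} CSA}
#'   \item{CAHA_N1}{DD/CSA, CA_i-HA_i with the N_{i+1} CSA}
#'   \item{Cm1_C}{CSA/CSA, sequential carbonyl tensors}
#'   \item{N_NHN}{DD/CSA within one peptide plane: N_i CSA with N_i-HN_i;
#'     amplitude known, defines tau(N,NHN)}
#'   \item{C_CCA}{DD/CSA within one plane: C'_i CSA with C'_i-CA_i;
#'     amplitude known, defines tau(C',C'CA)}
#' }
#'
#' The registry is the contract: each entry declares its mechanism class,
#' participants and distance mode, and all amplitude/rate math is driven off
#' these declarations, so correcting an entry never touches math code.
#'
#' @param ids optional character vector to subset/reorder
#' @return named list of \linkS4class{RateKind} objects
#' @export
#' @examples
#' names(ccrRateKinds())
#' ccrRateKinds("N_NHN")[[1]]
ccrRateKinds <- function(ids = NULL) {
    reg <- list(
        NHN_CAHA = .makeKind("NHN_CAHA", "DD/DD",
                             .dip("N", 0L, "HN", 0L), .dip("CA", 0L, "HA", 0L)),
        CAHA_NHN1 = .makeKind("CAHA_NHN1", "DD/DD",
                              .dip("CA", 0L, "HA", 0L), .dip("N", 1L, "HN", 1L)),
        NHN_NHN1 = .makeKind("NHN_NHN1", "DD/DD",
                             .dip("N", 0L, "HN", 0L), .dip("N", 1L, "HN", 1L)),
        HAHN1_C = .makeKind("HAHN1_C", "DD/CSA",
                            .dip("HA", 0L, "HN", 1L), .csaP("C", 0L),
                            distanceMode = "instantaneous"),
        NHN_C = .makeKind("NHN_C", "DD/CSA",
                          .dip("N", 0L, "HN", 0L), .csaP("C", 0L)),
        CAHA_Cm1 = .makeKind("CAHA_Cm1", "DD/CSA",
                             .dip("CA", 0L, "HA", 0L), .csaP("C", -1L)),
        CAHA_N1 = .makeKind("CAHA_N1", "DD/CSA",
                            .dip("CA", 0L, "HA", 0L), .csaP("N", 1L)),
        Cm1_C = .makeKind("Cm1_C", "CSA/CSA",
                          .csaP("C", -1L), .csaP("C", 0L)),
        N_NHN = .makeKind("N_NHN", "DD/CSA",
                          .dip("N", 0L, "HN", 0L), .csaP("N", 0L),
                          amplitudeKnown = TRUE),
        C_CCA = .makeKind("C_CCA", "DD/CSA",
                          .dip("C", 0L, "CA", 0L), .csaP("C", 0L),
                          amplitudeKnown = TRUE)
    )
    if (is.null(ids)) return(reg)
    missing <- setdiff(ids, names(reg))
    if (length(missing))
        stop("unknown rate kind(s): ", paste(missing, collapse = ", "))
    reg[ids]
}

#' Ids of the eight remote (unknown-amplitude) rates
#' @return character vector
#' @export
remoteRateIds <- function() {
    reg <- ccrRateKinds()
    names(reg)[!vapply(reg, function(k) k@amplitudeKnown, logical(1))]
}

# gyromagnetic ratio of one atom name
.gammaOf <- function(atom, constants) {
    switch(substr(atom, 1, 1),
           "H" = constants@gammaH,
           "C" = constants@gammaC,
           "N" = constants@gammaN,
           stop("no gyromagnetic ratio for atom ", atom))
}
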