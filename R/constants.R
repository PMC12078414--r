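#' @include AllGenerics.R
NULL

#' Second-order Legendre polynomial
#'
#' P2(x) = 1.5 x^2 - 0.5. Its root at x = 1/sqrt(3) corresponds to the magic
#' angle 54.7356 deg: an interaction pair whose projection angle sits there
#' contributes no CCR amplitude.
#'
#' @param x cosine of a projection angle (any numeric)
#' @return P2(x)
#' @export
#' @examples
#' legendreP2(1)            # parallel vectors: 1
#' legendreP2(1 / sqrt(3))  # magic angle: 0
legendreP2 <- function(x) 1.5 * x * x - 0.5

#' Static field from the proton operational frequency
#'
#' @param mhz 1H Larmor frequency in MHz (e.g. 800)
#' @param gammaH proton gyromagnetic ratio (rad s^-1 T^-1)
#' @return B0 in Tesla
#' @export
b0FromMHz <- function(mhz, gammaH = 267.52218744e6) {
    2 * pi * mhz * 1e6 / gammaH
}

#' Physical constants (CODATA values, 800 MHz by default)
#'
#' @param B0 static field in Tesla; the default corresponds to an 800 MHz
#'   spectrometer
#' @return a \linkS4class{PhysicalConstants} object
#' @export
#' @examples
#' physicalConstants()
physicalConstants <- function(B0 = b0FromMHz(800)) {
    new("PhysicalConstants",
        gammaH = 267.52218744e6,
        gammaC = 67.2828e6,
        gammaN = -27.116e6,
        mu0 = 4 * pi * 1e-7,
        hbar = 1.054571817e-34,
        B0 = B0)
}

#' Average backbone CSA tensors
#'
#' The carbonyl (C') tensor has principal values (249.4, 191.1, 87.9) ppm
#' with the xx eigenvector 37 deg from the C'-N bond; the amide nitrogen
#' tensor is effectively axial with sigma_xx - sigma_zz = 170 ppm
#' (sigma_yy - sigma_zz = 0, so only the xx projection contributes) and the
#' xx eigenvector 20 deg from the N-HN bond. zz is normal to the peptide
#' plane spanned by the two frameRule bonds. alpha is measured as a
#' right-handed rotation about zz = unit(b1 x b2), which sweeps the
#' reference bond b1 towards b2 for positive angles.
#'
#' @param nucleus "C" (carbonyl) or "N" (amide nitrogen)
#' @return a \linkS4class{CsaTensor}
#' @export
#' @examples
#' defaultCsaTensor("C")
#' defaultCsaTensor("N")
defaultCsaTensor <- function(nucleus = c("C", "N")) {
    nucleus <- match.arg(nucleus)
    if (nucleus == "C") {
        new("CsaTensor", sigma = c(249.4, 191.1, 87.9), alpha = 37,
            frameRule = c("C-N", "C-O"), nucleus = "C")
    } else {
        new("CsaTensor", sigma = c(170, 0, 0), alpha = 20,
            frameRule = c("N-HN", "N-C'"), nucleus = "N")
    }
}

#' Standard rigid peptide internal coordinates
#'
#' Canonical backbone bond lengths and angles with a trans peptide bond
#' (omega = 180 deg). The amide and alpha proton distances default to 1.01
#' and 1.09 Angstrom. All values can be overridden, e.g. from a geometry
#' config file, without touching any math code.
#'
#' @param bonds,angles named numeric overrides merged over the defaults
#' @param omega peptide torsion (deg)
#' @param haTorsionOffset HA torsion (deg) relative to phi
#' @param psiPrev frozen psi of the flanking previous residue (deg)
#' @return a \linkS4class{BackboneGeometry}
#' @export
#' @examples
#' defaultBackboneGeometry()
#' defaultBackboneGeometry(bonds = c("N-HN" = 1.02))
defaultBackboneGeometry <- function(bonds = numeric(), angles = numeric(),
                                    omega = 180, haTorsionOffset = -121.9,
                                    psiPrev = 135) {
    b <- c("N-CA" = 1.458, "CA-C" = 1.525, "C-N" = 1.329, "C-O" = 1.231,
           "N-HN" = 1.01, "CA-HA" = 1.09)
    a <- c("N-CA-C" = 111.0, "CA-C-N" = 116.2, "C-N-CA" = 121.7,
           "CA-C-O" = 120.8, "N-C-O" = 123.0, "C-N-HN" = 119.2,
           "N-CA-HA" = 108.0)
    b[names(bonds)] <- bonds
    a[names(angles)] <- angles
    new("BackboneGeometry", bonds = b, angles = a, omega = omega,
        haTorsionOffset = haTorsionOffset, psiPrev = psiPrev)
}
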