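#' @import methods
NULL

.wrap180 <- function(x) {
    # map angles (deg) into [-180, 180)
    y <- (x + 180) %% 360 - 180
    y[y >= 180] <- -180
    y
}

#' Physical constants for CCR rate prefactors
#'
#' Gyromagnetic ratios are signed (rad s^-1 T^-1); \code{gammaN} is negative
#' for 15N. \code{B0} is the static magnetic field in Tesla.
#'
#' @slot gammaH,gammaC,gammaN gyromagnetic ratios (rad s^-1 T^-1)
#' @slot mu0 vacuum permeability (T^2 m^3 J^-1)
#' @slot hbar reduced Planck constant (J s)
#' @slot B0 static field (T)
#' @export
setClass("PhysicalConstants",
    representation(gammaH = "numeric", gammaC = "numeric", gammaN = "numeric",
                   mu0 = "numeric", hbar = "numeric", B0 = "numeric"),
    validity = function(object) {
        msg <- character()
        if (object@gammaN >= 0) msg <- c(msg, "gammaN must be negative (15N)")
        if (!(object@gammaH > object@gammaC && object@gammaC > 0))
            msg <- c(msg, "expected gammaH > gammaC > 0")
        if (object@B0 <= 0) msg <- c(msg, "B0 must be positive")
        if (length(msg)) msg else TRUE
    })

#' Chemical shift anisotropy tensor
#'
#' Principal values in ppm and the in-plane angle \code{alpha} (degrees)
#' between the reference bond and the xx eigenvector. \code{frameRule} names
#' the two bonds whose instantaneous span defines the peptide-plane normal
#' (the zz eigenvector), e.g. \code{c("C-N", "C-O")} for the carbonyl tensor.
#'
#' @slot sigma numeric(3): (sigma_xx, sigma_yy, sigma_zz) in ppm
#' @slot alpha angle (deg) from the reference bond (first of frameRule) to xx
#' @slot frameRule character(2): plane-defining bonds, reference bond first
#' @slot nucleus "C" or "N"
#' @export
setClass("CsaTensor",
    representation(sigma = "numeric", alpha = "numeric",
                   frameRule = "character", nucleus = "character"),
    validity = function(object) {
        msg <- character()
        if (length(object@sigma) != 3L)
            msg <- c(msg, "sigma must have 3 principal values")
        if (is.unsorted(rev(object@sigma)))
            msg <- c(msg, "expected sigma_xx >= sigma_yy >= sigma_zz")
        if (length(object@frameRule) != 2L)
            msg <- c(msg, "frameRule must name two plane-defining bonds")
        if (length(msg)) msg else TRUE
    })

#' Rigid model-backbone internal coordinates
#'
#' Bond lengths in Angstrom, bond angles in degrees. The peptide torsion
#' omega is fixed (trans, 180 deg); phi and psi of the central residue are
#' the only conformational degrees of freedom of a fragment. Flanking
#' torsions (psiPrev for residue i-1) are frozen at reference values.
#'
#' @slot bonds named numeric: "N-CA","CA-C","C-N","C-O","N-HN","CA-HA" (A)
#' @slot angles named numeric: backbone bond angles (deg)
#' @slot omega peptide torsion (deg), 180 by default
#' @slot haTorsionOffset torsion offset (deg) of HA relative to phi
#' @slot psiPrev frozen psi of the preceding residue (deg)
#' @export
setClass("BackboneGeometry",
    representation(bonds = "numeric", angles = "numeric", omega = "numeric",
                   haTorsionOffset = "numeric", psiPrev = "numeric"),
    validity = function(object) {
        need <- c("N-CA", "CA-C", "C-N", "C-O", "N-HN", "CA-HA")
        msg <- character()
        if (!all(need %in% names(object@bonds)))
            msg <- c(msg, paste("bonds must include",
                                paste(setdiff(need, names(object@bonds)), collapse = ", ")))
        if (any(object@bonds <= 0)) msg <- c(msg, "all bond lengths must be > 0")
        if (length(msg)) msg else TRUE
    })

#' Declarative description of one CCR interference
#'
#' A rate kind pairs two relaxation mechanisms of rank 2: a dipolar vector
#' (two nuclei) or a CSA tensor (one nucleus). Atom names use "N", "HN",
#' "CA", "HA", "C", "O" with residue offsets relative to the central residue.
#'
#' @slot id rate identifier
#' @slot mechanismClass "DD/DD", "DD/CSA" or "CSA/CSA"
#' @slot participants list of two mechanisms; a dipole is
#'   \code{list(type="dipole", atoms=c(a,b), offsets=c(i,j))}, a CSA is
#'   \code{list(type="csa", nucleus="C"|"N", offset=i)}
#' @slot distanceMode "fixed-mean" or "instantaneous"
#' @slot amplitudeKnown TRUE only for the two dynamical-proxy rates
#' @export
setClass("RateKind",
    representation(id = "character", mechanismClass = "character",
                   participants = "list", distanceMode = "character",
                   amplitudeKnown = "logical"),
    validity = function(object) {
        msg <- character()
        if (!object@mechanismClass %in% c("DD/DD", "DD/CSA", "CSA/CSA"))
            msg <- c(msg, "unknown mechanism class")
        if (length(object@participants) != 2L)
            msg <- c(msg, "exactly two participating mechanisms required")
        ndip <- sum(vapply(object@participants, function(p) p$type == "dipole", logical(1)))
        want <- c("DD/DD" = 2L, "DD/CSA" = 1L, "CSA/CSA" = 0L)[object@mechanismClass]
        if (!is.na(want) && ndip != want)
            msg <- c(msg, "participants inconsistent with mechanism class")
        if (!object@distanceMode %in% c("fixed-mean", "instantaneous"))
            msg <- c(msg, "distanceMode must be fixed-mean or instantaneous")
        if (length(msg)) msg else TRUE
    })

#' Structural-amplitude surface of one CCR rate
#'
#' Tabulated A_Gamma(phi, psi) in s^-1 per second of correlation time, with
#' all physical prefactors included. Rows index phi bins, columns psi bins;
#' bin centers follow the package grid convention
#' (-180 + resolution/2 + k * resolution, half-open domain [-180, 180)).
#'
#' @slot rateId rate identifier
#' @slot resolution grid resolution (deg)
#' @slot values matrix of amplitudes (s^-2 * s = s^-1 per unit tau)
#' @slot B0 field (T) the prefactors were computed at
#' @export
setClass("RateSurface",
    representation(rateId = "character", resolution = "numeric",
                   values = "matrix", B0 = "numeric"),
    validity = function(object) {
        n <- as.integer(round(360 / object@resolution))
        msg <- character()
        if (360 %% object@resolution != 0)
            msg <- c(msg, "360 must be divisible by resolution")
        if (!all(dim(object@values) == c(n, n)))
            msg <- c(msg, "values must be (360/res) x (360/res)")
        if (!all(is.finite(object@values)))
            msg <- c(msg, "surface values must be finite")
        if (length(msg)) msg else TRUE
    })

#' Unit-vector time series
#'
#' A motional vector sampled at fixed spacing \code{dt} (s), optionally with
#' the instantaneous inter-nuclear distance r(t) (Angstrom) for
#' distance-weighted correlation.
#'
#' @slot vectors n x 3 matrix of unit vectors
#' @slot distances numeric(0) or numeric(n), positive (Angstrom)
#' @slot dt frame spacing (s)
#' @export
setClass("VectorTrajectory",
    representation(vectors = "matrix", distances = "numeric", dt = "numeric"),
    validity = function(object) {
        msg <- character()
        if (ncol(object@vectors) != 3L) msg <- c(msg, "vectors must be n x 3")
        if (object@dt <= 0) msg <- c(msg, "dt must be positive")
        nrm <- sqrt(rowSums(object@vectors^2))
        if (any(abs(nrm - 1) > 1e-8)) msg <- c(msg, "vectors must be unit length (1e-8)")
        nd <- length(object@distances)
        if (nd && nd != nrow(object@vectors))
            msg <- c(msg, "distances must be empty or one per frame")
        if (nd && any(object@distances <= 0)) msg <- c(msg, "distances must be positive")
        if (length(msg)) msg else TRUE
    })

#' Time correlation function
#'
#' C(t) at lags 0, dt, 2 dt, ...; the amplitude is C(0), the first entry.
#'
#' @slot values C(t) at each lag
#' @slot dt lag spacing (s)
#' @export
setClass("Tcf",
    representation(values = "numeric", dt = "numeric"),
    validity = function(object) {
        msg <- character()
        if (!length(object@values)) msg <- c(msg, "empty TCF")
        if (object@dt <= 0) msg <- c(msg, "dt must be positive")
        if (length(msg)) msg else TRUE
    })

#' Per-residue backbone dihedral time series
#'
#' phi and psi in degrees, wrapped to [-180, 180); one column per residue.
#'
#' @slot phi,psi n x R matrices (deg)
#' @slot dt frame spacing (s)
#' @slot residues residue indices labelling the columns
#' @export
setClass("DihedralSeries",
    representation(phi = "matrix", psi = "matrix", dt = "numeric",
                   residues = "integer"),
    validity = function(object) {
        msg <- character()
        if (!identical(dim(object@phi), dim(object@psi)))
            msg <- c(msg, "phi and psi must have identical dimensions")
        if (length(object@residues) != ncol(object@phi))
            msg <- c(msg, "one residue label per column required")
        rng <- range(object@phi, object@psi)
        if (rng[1] < -180 || rng[2] >= 180)
            msg <- c(msg, "angles must lie in [-180, 180)")
        if (object@dt <= 0) msg <- c(msg, "dt must be positive")
        if (length(msg)) msg else TRUE
    })

#' Discrete probability distribution over (phi, psi) bins
#'
#' Rows index phi, columns psi; bin centers at -180 + res/2 + k res.
#'
#' @slot resolution bin width (deg)
#' @slot probs (360/res) x (360/res) matrix, nonnegative, summing to 1
#' @export
setClass("RamachandranGrid",
    representation(resolution = "numeric", probs = "matrix"),
    validity = function(object) {
        n <- as.integer(round(360 / object@resolution))
        msg <- character()
        if (360 %% object@resolution != 0)
            msg <- c(msg, "360 must be divisible by resolution")
        if (!all(dim(object@probs) == c(n, n)))
            msg <- c(msg, "probs must be (360/res) x (360/res)")
        if (any(object@probs < 0)) msg <- c(msg, "probabilities must be >= 0")
        if (abs(sum(object@probs) - 1) > 1e-10)
            msg <- c(msg, "probabilities must sum to 1 (1e-10)")
        if (length(msg)) msg else TRUE
    })

#' Generative description of a synthetic dihedral ensemble
#'
#' Each residue hops between Ramachandran basins as a continuous-time Markov
#' process (mean dwell \code{exchangeTime}); within a basin the angles jitter
#' as a wrapped Ornstein-Uhlenbeck process with stationary spread
#' \code{basins$spread} and relaxation time \code{jitterTime}. The whole
#' chain additionally tumbles isotropically with correlation time
#' \code{tauRot} (the rank-2 decay time 1/(6 D_r)).
#'
#' @slot basins list, one data.frame per residue with columns
#'   phi, psi, spread (deg) and weight
#' @slot exchangeTime mean basin dwell time (s)
#' @slot jitterTime intra-basin jitter relaxation time (s)
#' @slot tauRot global tumbling time (s); Inf disables tumbling
#' @slot nFrames,dt number of frames and spacing (s)
#' @slot seed random seed recorded in all outputs
#' @export
setClass("EnsembleSpec",
    representation(basins = "list", exchangeTime = "numeric",
                   jitterTime = "numeric", tauRot = "numeric",
                   nFrames = "integer", dt = "numeric", seed = "integer"),
    validity = function(object) {
        msg <- character()
        for (b in object@basins) {
            if (!all(c("phi", "psi", "spread", "weight") %in% names(b))) {
                msg <- c(msg, "each basin table needs phi, psi, spread, weight")
                break
            }
            if (any(b$weight < 0) || abs(sum(b$weight) - 1) > 1e-8) {
                msg <- c(msg, "basin weights must be >= 0 and sum to 1")
                break
            }
        }
        if (object@exchangeTime <= 0 || object@jitterTime <= 0 || object@tauRot <= 0)
            msg <- c(msg, "all time scales must be > 0")
        if (object@dt <= 0 || object@nFrames < 1L)
            msg <- c(msg, "need dt > 0 and nFrames >= 1")
        if (length(msg)) msg else TRUE
    })

#' The ten CCR observables of one residue
#'
#' Rates in s^-1 keyed by rate id, the two dynamical-proxy correlation times
#' and their blend, plus (in simulation mode) the true per-rate correlation
#' times and structural amplitudes as diagnostics.
#'
#' @slot residue residue index
#' @slot rates named numeric, Gamma in s^-1 for every registered kind
#' @slot tauNNH,tauCCCA,tauOpt proxy correlation times (s)
#' @slot trueTau,trueA optional named diagnostics (simulation only)
#' @slot flags character notes, e.g. single-plane proxy fallback
#' @export
setClass("ResidueRateSet",
    representation(residue = "integer", rates = "numeric", tauNNH = "numeric",
                   tauCCCA = "numeric", tauOpt = "numeric", trueTau = "numeric",
                   trueA = "numeric", flags = "character"),
    validity = function(object) {
        msg <- character()
        if (is.null(names(object@rates)))
            msg <- c(msg, "rates must be named by rate id")
        if (length(msg)) msg else TRUE
    })

#' Result of one MaxEnt/MAP inversion
#'
#' @slot grid the posterior RamachandranGrid
#' @slot chi2 final misfit sum
#' @slot dkl Kullback-Leibler divergence to the prior (nats)
#' @slot temperature regularization temperature used
#' @slot iterations solver iterations (dual function evaluations)
#' @slot converged logical convergence flag
#' @slot lambda dual variables, one per rate
#' @export
setClass("CcrFit",
    representation(grid = "RamachandranGrid", chi2 = "numeric", dkl = "numeric",
                   temperature = "numeric", iterations = "integer",
                   converged = "logical", lambda = "numeric"))
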