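#' @include trajectory-vectors.R
NULL

#' Compute one CCR rate from a coordinate trajectory
#'
#' Assembles the rate as prefactor times the integrated (component-weighted)
#' time correlation function: Gamma = sum_k c_k J_k(0), with instantaneous
#' distances in the TCF denominator only for the registered
#' instantaneous-distance kind. Also returns the rate's true effective
#' correlation time tau (integral of the amplitude-normalized weighted TCF)
#' and the true structural component A = Gamma / tau — diagnostics that are
#' only accessible in a simulation context.
#'
#' @param kind a \linkS4class{RateKind} or rate id
#' @param coords coordinate trajectory (named list of n x 3 matrices)
#' @param residue residue index the kind is anchored at
#' @param dt frame spacing (s)
#' @param upperBound TCF integration bound (s); 10 ns default (disordered),
#'   use 20 ns for slowly tumbling folded proteins
#' @param constants,geometry,csas model parameters
#' @param tumblingTau analytic isotropic tumbling time (s) applied to the
#'   internal TCFs via \code{\link{applyTumblingDecay}}; use when the
#'   trajectory is rotation-free. NA (default) when the trajectory already
#'   tumbles explicitly.
#' @param tailThreshold convergence check: warn when the weighted TCF at
#'   the bound retains more than this fraction of its initial correlation
#' @return list: \code{gamma} (s^-1), \code{tau} (s), \code{a} (s^-2 * s),
#'   \code{converged}, \code{tailFraction}
#' @export
computeRate <- function(kind, coords, residue, dt, upperBound = 10e-9,
                        constants = physicalConstants(),
                        geometry = defaultBackboneGeometry(),
                        csas = list(C = defaultCsaTensor("C"),
                                    N = defaultCsaTensor("N")),
                        tumblingTau = NA_real_,
                        tailThreshold = 0.01) {
    if (is.character(kind)) kind <- ccrRateKinds(kind)[[1]]
    pref <- prefactor(kind, constants, geometry, csas)
    series <- .kindSeries(kind, coords, residue, dt, csas)
    gamma <- 0
    comp <- list()
    for (lab in names(series)) {
        if (pref$components[[lab]] == 0) next
        s <- series[[lab]]
        tc <- crossTcf(s$a, s$b, maxLag = upperBound,
                       distanceWeighting = s$weighted)
        if (!is.na(tumblingTau)) tc <- applyTumblingDecay(tc, tumblingTau)
        comp[[lab]] <- tc
        gamma <- gamma + pref$components[[lab]] * integrateTcf(tc, upperBound)
    }
    # weighted TCF for the rate's own correlation time; weights proportional
    # to the prefactor components, so Gamma = A * tau holds exactly
    wtcf <- if (length(comp) == 1L) comp[[1L]] else {
        w <- pref$components[names(comp)]
        vals <- 0
        for (lab in names(comp)) vals <- vals + w[[lab]] * comp[[lab]]@values
        new("Tcf", values = vals, dt = dt)
    }
    tau <- correlationTime(wtcf, upperBound)
    tail <- abs(wtcf@values[length(wtcf@values)] / wtcf@values[1L])
    if (tail > tailThreshold)
        warning("TCF for ", kind@id, " at residue ", residue,
                " not converged: |C(t_max)|/C(0) = ", signif(tail, 3))
    list(gamma = gamma, tau = tau, a = gamma / tau,
         converged = tail <= tailThreshold, tailFraction = tail)
}

#' Dynamical proxy correlation times
#'
#' \code{proxyTauNNH} averages the known-amplitude nitrogen rate over the
#' two peptide planes encompassing residue i
#' (Gamma at i and i + 1, divided by twice the known amplitude);
#' \code{proxyTauCCCA} does the same with the carbonyl rate at i - 1 and i.
#' A missing neighbour triggers the flagged single-plane fallback.
#' \code{proxyTauOpt} blends the two, by default
#' 0.7 tau(C',C'CA) + 0.3 tau(N,NHN).
#'
#' @param gammaI,gammaNeighbor the known-amplitude rates (s^-1) of the two
#'   planes; \code{gammaNeighbor = NA} invokes the single-plane fallback
#' @param A the known amplitude (s^-2 * s), see \code{\link{knownAmplitudes}}
#' @return tau in seconds (for the fallback, with attribute
#'   \code{singlePlane = TRUE})
#' @export
proxyTauNNH <- function(gammaI, gammaNeighbor, A) {
    if (is.na(gammaNeighbor)) {
        out <- gammaI / A
        attr(out, "singlePlane") <- TRUE
        return(out)
    }
    (gammaI + gammaNeighbor) / (2 * A)
}

#' @rdname proxyTauNNH
#' @export
proxyTauCCCA <- proxyTauNNH

#' @rdname proxyTauNNH
#' @param tauCCCA,tauNNH the two proxy times (s)
#' @param weights blend weights, (C'C'CA, NNHN)
#' @export
proxyTauOpt <- function(tauCCCA, tauNNH, weights = c(0.7, 0.3)) {
    weights[1] * as.numeric(tauCCCA) + weights[2] * as.numeric(tauNNH)
}

#' Compute the full per-residue CCR rate sets along a chain
#'
#' Evaluates all ten registered interferences for every requested residue of
#' a coordinate trajectory, then forms the two dynamical-proxy correlation
#' times (averaging the known-amplitude rates of the two encompassing
#' peptide planes) and their blend. Residues whose neighbouring plane is
#' outside the trajectory get the flagged single-plane fallback and are
#' excluded from default reporting downstream.
#'
#' @param coords coordinate trajectory from \code{\link{chainCoordinates}}
#'   (after tumbling)
#' @param residues residues to process; default: all with complete
#'   i - 1 .. i + 1 atom support
#' @param dt frame spacing (s)
#' @param upperBound TCF integration bound (s)
#' @param constants,geometry,csas model parameters
#' @param tumblingTau analytic tumbling time (s) for rotation-free
#'   trajectories; NA for explicitly tumbled ones
#' @return list of \linkS4class{ResidueRateSet}
#' @export
computeChainRates <- function(coords, residues = NULL, dt,
                              upperBound = 10e-9,
                              constants = physicalConstants(),
                              geometry = defaultBackboneGeometry(),
                              csas = list(C = defaultCsaTensor("C"),
                                          N = defaultCsaTensor("N")),
                              tumblingTau = NA_real_) {
    avail <- .residueRange(coords)
    if (is.null(residues)) residues <- (avail[1] + 1L):(avail[2] - 1L)
    kinds <- ccrRateKinds()
    ka <- knownAmplitudes(constants, geometry, csas)
    cache <- new.env(parent = emptyenv())
    rateAt <- function(id, res) {
        key <- paste0(id, "#", res)
        if (!is.null(cache[[key]])) return(cache[[key]])
        cache[[key]] <- computeRate(kinds[[id]], coords, res, dt, upperBound,
                                    constants, geometry, csas, tumblingTau)
        cache[[key]]
    }
    lapply(residues, function(i) {
        rr <- lapply(names(kinds), function(id) rateAt(id, i))
        names(rr) <- names(kinds)
        flags <- character()
        nn1 <- tryCatch(rateAt("N_NHN", i + 1L)$gamma, error = function(e) NA_real_)
        cc0 <- tryCatch(rateAt("C_CCA", i - 1L)$gamma, error = function(e) NA_real_)
        tauN <- proxyTauNNH(rr[["N_NHN"]]$gamma, nn1, ka[["N_NHN"]])
        tauC <- proxyTauCCCA(rr[["C_CCA"]]$gamma, cc0, ka[["C_CCA"]])
        if (isTRUE(attr(tauN, "singlePlane")) ||
            isTRUE(attr(tauC, "singlePlane")))
            flags <- c(flags, "single-plane proxy")
        if (any(!vapply(rr, `[[`, logical(1), "converged")))
            flags <- c(flags, "unconverged TCF")
        new("ResidueRateSet", residue = as.integer(i),
            rates = vapply(rr, `[[`, numeric(1), "gamma"),
            tauNNH = as.numeric(tauN), tauCCCA = as.numeric(tauC),
            tauOpt = proxyTauOpt(tauC, tauN),
            trueTau = vapply(rr, `[[`, numeric(1), "tau"),
            trueA = vapply(rr, `[[`, numeric(1), "a"),
            flags = flags)
    })
}

# residue index range covered by a chain coordinate set
.residueRange <- function(coords) {
    res <- suppressWarnings(
        as.integer(sub("^.*@", "", names(coords))))
    range(res, na.rm = TRUE)
}

#' Approximate structural components by proxy normalization
#'
#' Divides each remote rate by a dynamical proxy correlation time to
#' approximate its structural component A_Gamma. In "opt" mode the blended
#' time applies to remote rates involving the amide proton; the carbonyl
#' proxy is used for the rest. "true" uses the per-rate simulation
#' diagnostics (simulation mode only).
#'
#' @param rrs a \linkS4class{ResidueRateSet}
#' @param proxy "ccca" (default, the paper's recommended choice), "nnh",
#'   "opt" or "true"
#' @return named numeric of approximated A_Gamma, remote rates only
#' @export
normalizeRates <- function(rrs, proxy = c("ccca", "nnh", "opt", "true")) {
    proxy <- match.arg(proxy)
    ids <- remoteRateIds()
    tau <- proxyTauFor(rrs, proxy)
    if (any(!is.finite(tau)) || any(tau <= 0))
        stop("nonpositive or missing proxy correlation time")
    rrs@rates[ids] / tau
}

#' Per-rate correlation times implied by a proxy choice
#'
#' The effective correlation time assigned to each remote rate under a
#' normalization mode: the chosen proxy time for "ccca"/"nnh", the blend
#' for amide-proton rates in "opt" mode, or the simulation-truth values.
#'
#' @param rrs a \linkS4class{ResidueRateSet}
#' @param proxy "ccca", "nnh", "opt" or "true"
#' @return named numeric (s), one entry per remote rate
#' @export
proxyTauFor <- function(rrs, proxy = c("ccca", "nnh", "opt", "true")) {
    proxy <- match.arg(proxy)
    ids <- remoteRateIds()
    tau <- switch(proxy,
        ccca = rep(rrs@tauCCCA, length(ids)),
        nnh = rep(rrs@tauNNH, length(ids)),
        opt = ifelse(vapply(ids, kindInvolvesHN, logical(1)),
                     rrs@tauOpt, rrs@tauCCCA),
        true = rrs@trueTau[ids])
    stats::setNames(tau, ids)
}

#' Proxy-quality diagnostic: approximated vs. true structural components
#'
#' Pools all remote rates of all residues, plots (conceptually) the true
#' A_Gamma = Gamma / tau_Gamma against the proxy-normalized Gamma / tau and
#' reports the least-squares slope of a line through the origin
#' (sum(xy) / sum(x^2)) and the coefficient of determination of that fit.
#' Requires simulation-truth diagnostics on the rate sets.
#'
#' @param rateSets list of \linkS4class{ResidueRateSet}
#' @param proxy proxy choice passed to \code{\link{normalizeRates}}
#' @return list: \code{slope}, \code{r2}, \code{n}, and the pooled
#'   \code{x} (true) and \code{y} (approximated) vectors
#' @export
proxyDiagnostic <- function(rateSets, proxy = "ccca") {
    x <- unlist(lapply(rateSets, function(r) r@trueA[remoteRateIds()]))
    y <- unlist(lapply(rateSets, function(r) normalizeRates(r, proxy)))
    if (length(x) < 2L) stop("need at least two points for the diagnostic")
    slope <- sum(x * y) / sum(x * x)
    r2 <- 1 - sum((y - slope * x)^2) / sum((y - mean(y))^2)
    list(slope = slope, r2 = r2, n = length(x), x = x, y = y)
}
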