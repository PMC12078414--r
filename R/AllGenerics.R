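#' @include AllClasses.R
NULL

#' Accessors
#'
#' Small accessor generics for the package's S4 containers; slots are never
#' reached into directly by user code.
#'
#' @param x an object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("resolution", function(x) standardGeneric("resolution"))
#' @rdname accessors
#' @export
setMethod("resolution", "RamachandranGrid", function(x) x@resolution)
#' @rdname accessors
#' @export
setMethod("resolution", "RateSurface", function(x) x@resolution)

#' @rdname accessors
#' @export
setGeneric("gridProbs", function(x) standardGeneric("gridProbs"))
#' @rdname accessors
#' @export
setMethod("gridProbs", "RamachandranGrid", function(x) x@probs)

#' @rdname accessors
#' @export
setGeneric("surfaceValues", function(x) standardGeneric("surfaceValues"))
#' @rdname accessors
#' @export
setMethod("surfaceValues", "RateSurface", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("rateId", function(x) standardGeneric("rateId"))
#' @rdname accessors
#' @export
setMethod("rateId", "RateSurface", function(x) x@rateId)
#' @rdname accessors
#' @export
setMethod("rateId", "RateKind", function(x) x@id)

#' @rdname accessors
#' @export
setGeneric("tcfValues", function(x) standardGeneric("tcfValues"))
#' @rdname accessors
#' @export
setMethod("tcfValues", "Tcf", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))
#' @rdname accessors
#' @export
setMethod("amplitude", "Tcf", function(x) x@values[1L])

#' @rdname accessors
#' @export
setGeneric("sampleInterval", function(x) standardGeneric("sampleInterval"))
#' @rdname accessors
#' @export
setMethod("sampleInterval", "Tcf", function(x) x@dt)
#' @rdname accessors
#' @export
setMethod("sampleInterval", "VectorTrajectory", function(x) x@dt)
#' @rdname accessors
#' @export
setMethod("sampleInterval", "DihedralSeries", function(x) x@dt)

#' @rdname accessors
#' @export
setGeneric("maxLag", function(x) standardGeneric("maxLag"))
#' @rdname accessors
#' @export
setMethod("maxLag", "Tcf", function(x) (length(x@values) - 1L) * x@dt)

#' @rdname accessors
#' @export
setGeneric("residueIndex", function(x) standardGeneric("residueIndex"))
#' @rdname accessors
#' @export
setMethod("residueIndex", "ResidueRateSet", function(x) x@residue)

#' @rdname accessors
#' @export
setGeneric("rateValues", function(x) standardGeneric("rateValues"))
#' @rdname accessors
#' @export
setMethod("rateValues", "ResidueRateSet", function(x) x@rates)

#' @rdname accessors
#' @export
setGeneric("proxyTaus", function(x) standardGeneric("proxyTaus"))
#' @rdname accessors
#' @export
setMethod("proxyTaus", "ResidueRateSet", function(x)
    c(nnh = x@tauNNH, ccca = x@tauCCCA, opt = x@tauOpt))

#' @rdname accessors
#' @export
setGeneric("trueTaus", function(x) standardGeneric("trueTaus"))
#' @rdname accessors
#' @export
setMethod("trueTaus", "ResidueRateSet", function(x) x@trueTau)

#' @rdname accessors
#' @export
setGeneric("trueAmplitudes", function(x) standardGeneric("trueAmplitudes"))
#' @rdname accessors
#' @export
setMethod("trueAmplitudes", "ResidueRateSet", function(x) x@trueA)

#' @rdname accessors
#' @export
setGeneric("posteriorGrid", function(x) standardGeneric("posteriorGrid"))
#' @rdname accessors
#' @export
setMethod("posteriorGrid", "CcrFit", function(x) x@grid)

#' @rdname accessors
#' @export
setGeneric("fitDiagnostics", function(x) standardGeneric("fitDiagnostics"))
#' @rdname accessors
#' @export
setMethod("fitDiagnostics", "CcrFit", function(x)
    list(chi2 = x@chi2, dkl = x@dkl, temperature = x@temperature,
         iterations = x@iterations, converged = x@converged, lambda = x@lambda))

setMethod("show", "RamachandranGrid", function(object) {
    n <- nrow(object@probs)
    mx <- which(object@probs == max(object@probs), arr.ind = TRUE)[1, ]
    ctr <- -180 + object@resolution / 2 + (mx - 1L) * object@resolution
    cat(sprintf("RamachandranGrid: %d x %d bins (%g deg), mode near (%g, %g)\n",
                n, n, object@resolution, ctr[1], ctr[2]))
})

setMethod("show", "RateSurface", function(object) {
    cat(sprintf("RateSurface '%s': %d x %d (%g deg), range [%.3g, %.3g] s^-1 per s\n",
                object@rateId, nrow(object@values), ncol(object@values),
                object@resolution, min(object@values), max(object@values)))
})

setMethod("show", "Tcf", function(object) {
    cat(sprintf("Tcf: %d lags, dt = %.3g s, C(0) = %.4g\n",
                length(object@values), object@dt, object@values[1L]))
})

setMethod("show", "VectorTrajectory", function(object) {
    cat(sprintf("VectorTrajectory: %d frames, dt = %.3g s%s\n",
                nrow(object@vectors), object@dt,
                if (length(object@distances)) ", with distances" else ""))
})

setMethod("show", "DihedralSeries", function(object) {
    cat(sprintf("DihedralSeries: %d frames x %d residues, dt = %.3g s\n",
                nrow(object@phi), ncol(object@phi), object@dt))
})

setMethod("show", "ResidueRateSet", function(object) {
    cat(sprintf("ResidueRateSet residue %d: %d rates; tau(NNH) = %.3g ns, tau(CCCA) = %.3g ns\n",
                object@residue, length(object@rates),
                object@tauNNH * 1e9, object@tauCCCA * 1e9))
    if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "CcrFit", function(object) {
    cat(sprintf("CcrFit: T = %g, chi2 = %.4g, D_KL = %.4g nats, %s (%d evals)\n",
                object@temperature, object@chi2, object@dkl,
                if (object@converged) "converged" else "NOT converged",
                object@iterations))
})

setMethod("show", "RateKind", function(object) {
    cat(sprintf("RateKind '%s' (%s)%s\n", object@id, object@mechanismClass,
                if (object@amplitudeKnown) " [known amplitude]" else ""))
})

setMethod("show", "EnsembleSpec", function(object) {
    cat(sprintf(paste0("EnsembleSpec: %d residues, %d frames @ %.3g ps; ",
                       "exchange %.3g ns, jitter %.3g ns, tauRot %.3g ns, seed %d\n"),
                length(object@basins), object@nFrames, object@dt * 1e12,
                object@exchangeTime * 1e9, object@jitterTime * 1e9,
                object@tauRot * 1e9, object@seed))
})
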