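#' @include io.R
NULL

#' Pipeline entry points
#'
#' The five steps of the CCR-to-Ramachandran workflow as directly callable
#' functions (the shell script under \code{inst/scripts/ccr-tool.R} is a
#' thin argument-parsing wrapper around them). Every step is deterministic
#' given its inputs and seed, and each returns a provenance record
#' (parameters, seed, package version) alongside its results.
#'
#' @name pipeline
NULL

.provenance <- function(cfg, seed = NULL) {
    list(package = "dihedralCCR",
         version = as.character(utils::packageVersion("dihedralCCR")),
         seed = seed %||% cfg$seed,
         b0_T = cfg$constants@B0,
         tmax_s = cfg$upperBound,
         proxy = cfg$proxy,
         temperature = cfg$temperature,
         resolution = cfg$resolution)
}

#' @rdname pipeline
#' @param config a configuration list from \code{\link{readRunConfig}}
#' @param outDir directory for the surface files (created if needed);
#'   NULL skips writing
#' @return \code{ccrSurfaces}: named list of \linkS4class{RateSurface}
#'   (attribute "provenance")
#' @export
ccrSurfaces <- function(config = readRunConfig(), outDir = NULL) {
    ss <- buildRateSurfaces(resolution = config$resolution,
                            geometry = config$geometry, csas = config$csas,
                            constants = config$constants)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        for (id in names(ss))
            writeRateSurface(ss[[id]], file.path(outDir, paste0(id, ".tsv")))
    }
    attr(ss, "provenance") <- .provenance(config)
    ss
}

#' @rdname pipeline
#' @param coords coordinate trajectory (e.g. from \code{\link{ccrSimulate}})
#' @param dt frame spacing (s)
#' @param residues residues to process (NULL: all fully supported)
#' @param tumblingTau analytic tumbling time (s) when \code{coords} is
#'   rotation-free; NA when it already tumbles explicitly
#' @return \code{ccrRates}: list of \linkS4class{ResidueRateSet}
#' @export
ccrRates <- function(coords, dt, residues = NULL, config = readRunConfig(),
                     tumblingTau = NA_real_) {
    if (!length(coords)) stop("empty coordinate selection")
    rs <- computeChainRates(coords, residues, dt,
                            upperBound = config$upperBound,
                            constants = config$constants,
                            geometry = config$geometry, csas = config$csas,
                            tumblingTau = tumblingTau)
    attr(rs, "provenance") <- .provenance(config)
    rs
}

#' @rdname pipeline
#' @param rateSets list of \linkS4class{ResidueRateSet}
#' @param prior prior \linkS4class{RamachandranGrid}; NULL uses the
#'   stand-in coil prior at the configured resolution
#' @param surfaces surfaces (NULL: built from the config)
#' @param lcurveTemperatures optional ladder; when given, the temperature
#'   is selected per residue by L-curve instead of the configured default
#' @param dropFlagged exclude residues whose proxies needed the
#'   single-plane terminal fallback (reported in \code{skipped});
#'   TCF-convergence flags are informational and do not exclude
#' @return \code{ccrInfer}: list with \code{fits} (named by residue),
#'   \code{skipped}, \code{errors} and \code{provenance}; a failing
#'   residue is isolated, not fatal
#' @export
ccrInfer <- function(rateSets, prior = NULL, surfaces = NULL,
                     config = readRunConfig(), lcurveTemperatures = NULL,
                     dropFlagged = TRUE) {
    if (is.null(surfaces)) surfaces <- ccrSurfaces(config)
    if (is.null(prior)) prior <- standInCoilPrior(config$resolution)
    keep <- vapply(rateSets, function(r)
        !(dropFlagged && "single-plane proxy" %in% r@flags), logical(1))
    skipped <- vapply(rateSets[!keep], residueIndex, integer(1))
    fits <- list()
    errors <- list()
    for (r in rateSets[keep]) {
        key <- as.character(residueIndex(r))
        res <- tryCatch({
            ids <- remoteRateIds()
            tau <- proxyTauFor(r, config$proxy)
            prob <- ccrProblem(r@rates[ids], surfaces, tau, prior,
                               temperature = config$temperature)
            if (!is.null(lcurveTemperatures)) {
                sel <- lCurve(prob, lcurveTemperatures)$selected
                prob$temperature <- sel
            }
            maxentMap(prob)
        }, error = function(e) e)
        if (inherits(res, "error")) errors[[key]] <- conditionMessage(res)
        else fits[[key]] <- res
    }
    list(fits = fits, skipped = skipped, errors = errors,
         provenance = .provenance(config))
}

#' @rdname pipeline
#' @param predicted named list of \linkS4class{RamachandranGrid} or
#'   \linkS4class{CcrFit} (names: residues)
#' @param reference matching named list of reference grids
#' @param resolution comparison resolution (deg), 10 by default
#' @return \code{ccrCompare}: data.frame (residue, js) plus the mean as
#'   attribute "meanJS"
#' @export
ccrCompare <- function(predicted, reference, resolution = 10) {
    ids <- intersect(names(predicted), names(reference))
    if (!length(ids)) stop("no matching residues between the two sets")
    js <- vapply(ids, function(i) {
        p <- predicted[[i]]
        if (is(p, "CcrFit")) p <- posteriorGrid(p)
        jsDivergence(coarsen(p, resolution),
                     coarsen(reference[[i]], resolution))
    }, numeric(1))
    out <- data.frame(residue = as.integer(ids), js = unname(js))
    attr(out, "meanJS") <- mean(js)
    out
}

#' @rdname pipeline
#' @param spec an \linkS4class{EnsembleSpec}
#' @param truthResolution resolution of the analytic truth grids
#' @param explicitTumbling rotate the frames by an explicit rotational
#'   random walk (\code{\link{applyTumbling}}). The default keeps the
#'   trajectory rotation-free and records the spec's tumbling time in
#'   \code{tumblingTau} for the noise-free analytic treatment downstream.
#' @return \code{ccrSimulate}: list with \code{coords}, \code{series},
#'   \code{truth} (named by residue), \code{tumblingTau} (NA when the
#'   frames tumble explicitly), \code{spec} and \code{provenance}
#' @export
ccrSimulate <- function(spec, config = readRunConfig(),
                        truthResolution = 10, explicitTumbling = FALSE) {
    sim <- sampleDihedralSeries(spec, resolution = truthResolution)
    coords <- chainCoordinates(sim$series, config$geometry)
    tumblingTau <- spec@tauRot
    if (explicitTumbling) {
        coords <- applyTumbling(coords, spec@tauRot, spec@dt,
                                seed = spec@seed + 1L)
        tumblingTau <- NA_real_
    }
    truth <- sim$truth
    names(truth) <- as.character(seq_along(truth))
    list(coords = coords, series = sim$series, truth = truth,
         tumblingTau = tumblingTau, spec = spec,
         provenance = c(.provenance(config, seed = spec@seed),
                        nFrames = spec@nFrames, dt = spec@dt))
}
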