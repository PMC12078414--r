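# a small static-conformer chain shared by several tests: TCFs are exact,
# so trajectories only need to span the lag window
staticChain <- function(phi, psi, nFrames = 12000L, dt = 1e-12) {
    R <- length(phi)
    basins <- lapply(seq_len(R), function(r)
        data.frame(basin = "x", phi = phi[r], psi = psi[r],
                   spread = 0, weight = 1))
    spec <- ensembleSpec(basins = basins, nFrames = nFrames, dt = dt,
                         tauRot = 2e-9, seed = 5L)
    sim <- sampleDihedralSeries(spec)
    list(coords = chainCoordinates(sim$series), spec = spec)
}

test_that("a static conformer under analytic tumbling reproduces the rigid-rotor closed form", {
    taur <- 2e-9
    ch <- staticChain(c(-70, -63, -120), c(150, -43, 140))
    rs <- suppressWarnings(
        computeChainRates(ch$coords, residues = 2L, dt = 1e-12,
                          upperBound = 10e-9, tumblingTau = taur))[[1]]
    trunc <- 1 - exp(-10e-9 / taur)
    for (id in names(rateValues(rs))) {
        expect_equal(rateValues(rs)[[id]],
                     structuralAmplitude(id, -63, -43) * taur * trunc,
                     tolerance = 1e-6)
    }
    expect_equal(rs@tauNNH, taur * trunc, tolerance = 1e-6)
    expect_equal(rs@tauCCCA, taur * trunc, tolerance = 1e-6)
    # proxy normalization recovers the forward-model surfaces
    aHat <- normalizeRates(rs, "ccca")
    for (id in remoteRateIds())
        expect_equal(aHat[[id]], structuralAmplitude(id, -63, -43),
                     tolerance = 0.01)
})

test_that("doubling B0 doubles DD/CSA rates and quadruples CSA/CSA rates", {
    ch <- staticChain(c(-70, -63, -120), c(150, -43, 140), nFrames = 11000L)
    args <- list(coords = ch$coords, residue = 2L, dt = 1e-12,
                 upperBound = 10e-9, tumblingTau = 2e-9)
    for (id in c("NHN_C", "Cm1_C", "NHN_CAHA")) {
        g1 <- do.call(computeRate, c(list(kind = id), args))$gamma
        g2 <- do.call(computeRate, c(list(kind = id), args,
                      list(constants = physicalConstants(2 * b0FromMHz(800)))))$gamma
        fac <- switch(ccrRateKinds(id)[[1]]@mechanismClass,
                      "DD/CSA" = 2, "CSA/CSA" = 4, "DD/DD" = 1)
        expect_equal(g2 / g1, fac, tolerance = 1e-10)
    }
})

test_that("unconverged TCF tails are flagged through the warning channel", {
    ch <- staticChain(-63, -43, nFrames = 6000L)
    # no tumbling decay at all: C(t) stays at its plateau, clearly unconverged
    expect_warning(
        computeRate("NHN_CAHA", ch$coords, 1L, 1e-12, upperBound = 5e-9),
        "not converged")
})

test_that("proxy times average the two peptide planes with a flagged fallback", {
    expect_equal(proxyTauNNH(2, 4, 1), 3)
    expect_equal(proxyTauNNH(6e-9 * 2, 6e-9 * 2, 2), 6e-9)
    single <- proxyTauCCCA(4, NA, 2)
    expect_equal(as.numeric(single), 2)
    expect_true(isTRUE(attr(single, "singlePlane")))
})

test_that("the optimal proxy is the fixed 0.7/0.3 blend and is linear", {
    expect_equal(proxyTauOpt(1, 0), 0.7)
    expect_equal(proxyTauOpt(0, 1), 0.3)
    expect_equal(proxyTauOpt(3e-9, 3e-9), 3e-9)
    expect_equal(proxyTauOpt(2 * 1e-9, 2 * 2e-9),
                 2 * proxyTauOpt(1e-9, 2e-9), tolerance = 1e-15)
})

test_that("normalization undoes a matched proxy exactly and scales inversely", {
    g <- stats::setNames(seq(0.5, 5, length.out = 10), names(ccrRateKinds()))
    tauTrue <- stats::setNames(rep(2e-9, 10), names(g))
    rrs <- new("ResidueRateSet", residue = 1L, rates = g,
               tauNNH = 2e-9, tauCCCA = 2e-9, tauOpt = 2e-9,
               trueTau = tauTrue, trueA = g / 2e-9, flags = character())
    expect_equal(normalizeRates(rrs, "true"), g[remoteRateIds()] / 2e-9)
    # proxy = c * tau_true scales every approximated amplitude by 1/c
    rrs2 <- rrs; rrs2@tauCCCA <- 2e-9 * 1.6
    expect_equal(unname(normalizeRates(rrs2, "ccca") / normalizeRates(rrs, "ccca")),
                 rep(1 / 1.6, 8), tolerance = 1e-12)
    rrs3 <- rrs; rrs3@tauCCCA <- -1
    expect_error(normalizeRates(rrs3, "ccca"), "nonpositive")
})

test_that("blended mode applies the blend only to amide-proton rates", {
    hn <- vapply(remoteRateIds(), kindInvolvesHN, logical(1))
    expect_true(any(hn) && !all(hn))
    g <- stats::setNames(rep(1, 10), names(ccrRateKinds()))
    rrs <- new("ResidueRateSet", residue = 1L, rates = g,
               tauNNH = 1e-9, tauCCCA = 3e-9, tauOpt = proxyTauOpt(3e-9, 1e-9),
               trueTau = numeric(), trueA = numeric(), flags = character())
    tau <- proxyTauFor(rrs, "opt")
    expect_equal(unname(tau[hn]), rep(0.7 * 3e-9 + 0.3 * 1e-9, sum(hn)))
    expect_equal(unname(tau[!hn]), rep(3e-9, sum(!hn)))
})

test_that("the proxy diagnostic matches the closed-form through-origin fit", {
    mk <- function(x, y) {
        ids <- names(ccrRateKinds())
        g <- stats::setNames(c(y, 1, 1), ids)       # 8 remote + 2 known
        new("ResidueRateSet", residue = 1L, rates = g, tauNNH = 1,
            tauCCCA = 1, tauOpt = 1,
            trueTau = stats::setNames(rep(1, 10), ids),
            trueA = stats::setNames(c(x, 1, 1), ids), flags = character())
    }
    # identical cloud: slope 1, R2 = 1
    d <- proxyDiagnostic(list(mk(1:8, 1:8)), "ccca")
    expect_equal(d$slope, 1); expect_equal(d$r2, 1)
    # y = 2x: slope 2, R2 = 1
    d2 <- proxyDiagnostic(list(mk(1:8, 2 * (1:8))), "ccca")
    expect_equal(d2$slope, 2); expect_equal(d2$r2, 1)
    # noisy cloud: slope equals sum(xy)/sum(x^2)
    set.seed(42)
    x <- rnorm(8, sd = 2); y <- 1.3 * x + rnorm(8, sd = 0.3)
    d3 <- proxyDiagnostic(list(mk(x, y)), "ccca")
    expect_equal(d3$slope, slopeThroughOriginRef(x, y), tolerance = 1e-12)
})

test_that("structure/dynamics separation survives uniform scaling", {
    ids <- names(ccrRateKinds())
    g <- stats::setNames(rnorm(10, 3), ids)
    rrs <- new("ResidueRateSet", residue = 1L, rates = g, tauNNH = 2e-9,
               tauCCCA = 2e-9, tauOpt = 2e-9, trueTau = numeric(),
               trueA = numeric(), flags = character())
    c0 <- 1.7
    rrs2 <- rrs
    rrs2@rates <- g * c0
    rrs2@tauCCCA <- 2e-9 * c0
    expect_equal(normalizeRates(rrs2, "ccca"), normalizeRates(rrs, "ccca"),
                 tolerance = 1e-12)
})

test_that("rate tables round-trip losslessly", {
    ch <- staticChain(c(-70, -63, -120), c(150, -43, 140), nFrames = 11000L)
    rs <- suppressWarnings(
        computeChainRates(ch$coords, residues = 2L, dt = 1e-12,
                          upperBound = 10e-9, tumblingTau = 2e-9))
    path <- tempfile(fileext = ".tsv")
    writeRateTable(rs, path)
    back <- readRateTable(path)
    expect_length(back, 1L)
    expect_equal(rateValues(back[[1]]), rateValues(rs[[1]]), tolerance = 1e-12)
    expect_equal(proxyTaus(back[[1]]), proxyTaus(rs[[1]]), tolerance = 1e-9)
    expect_equal(trueAmplitudes(back[[1]]), trueAmplitudes(rs[[1]]),
                 tolerance = 1e-9)
})
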