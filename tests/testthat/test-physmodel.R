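test_that("fragment construction round-trips its internal coordinates", {
    geom <- defaultBackboneGeometry()
    for (pp in list(c(-63, -43), c(-120, 140), c(57, 47), c(-75, 145))) {
        fr <- buildFragment(pp[1], pp[2], geom)
        expect_equal(dihedralAngle(fr[["C@-1"]], fr[["N@0"]], fr[["CA@0"]],
                                   fr[["C@0"]]), pp[1], tolerance = 1e-10)
        expect_equal(dihedralAngle(fr[["N@0"]], fr[["CA@0"]], fr[["C@0"]],
                                   fr[["N@1"]]), pp[2], tolerance = 1e-10)
        expect_equal(abs(dihedralAngle(fr[["CA@0"]], fr[["C@0"]], fr[["N@1"]],
                                       fr[["CA@1"]])), 180, tolerance = 1e-9)
        expect_equal(sqrt(sum((fr[["HN@0"]] - fr[["N@0"]])^2)),
                     geom@bonds[["N-HN"]], tolerance = 1e-12)
        expect_equal(sqrt(sum((fr[["HA@0"]] - fr[["CA@0"]])^2)),
                     geom@bonds[["CA-HA"]], tolerance = 1e-12)
        expect_equal(bondAngle(fr[["N@0"]], fr[["CA@0"]], fr[["C@0"]]),
                     geom@angles[["N-CA-C"]], tolerance = 1e-10)
    }
})

test_that("fragment agrees with an independent internal-coordinate builder", {
    geom <- defaultBackboneGeometry()
    fr <- buildFragment(-180, -180, geom)
    # rebuild C@0, N@1, CA@1 step by step with the reference builder
    C0 <- zmatPlaceRef(as.vector(fr[["C@-1"]]), as.vector(fr[["N@0"]]),
                       as.vector(fr[["CA@0"]]), geom@bonds[["CA-C"]],
                       geom@angles[["N-CA-C"]], -180)
    N1 <- zmatPlaceRef(as.vector(fr[["N@0"]]), as.vector(fr[["CA@0"]]), C0,
                       geom@bonds[["C-N"]], geom@angles[["CA-C-N"]], -180)
    CA1 <- zmatPlaceRef(as.vector(fr[["CA@0"]]), C0, N1,
                        geom@bonds[["N-CA"]], geom@angles[["C-N-CA"]], 180)
    expect_equal(as.vector(fr[["C@0"]]), C0, tolerance = 1e-10)
    expect_equal(as.vector(fr[["N@1"]]), N1, tolerance = 1e-10)
    dPkg <- sqrt(sum((fr[["CA@1"]] - fr[["CA@0"]])^2))
    dRef <- sqrt(sum((CA1 - as.vector(fr[["CA@0"]]))^2))
    expect_equal(dPkg, dRef, tolerance = 1e-10)
})

test_that("unknown atoms are reported by name", {
    fr <- buildFragment(-60, -45)
    expect_error(fragmentAtom(fr, "CB", 0), "CB@0")
})

test_that("CSA frames have the printed geometry", {
    fr <- buildFragment(-63, -43)
    unit <- function(v) v / sqrt(sum(v^2))
    # carbonyl tensor: zz normal to the C'N/C'O plane, xx 37 deg from C'N
    cfr <- csaFrame(fr, defaultCsaTensor("C"), 0L)
    vCN <- unit(fr[["N@1"]] - fr[["C@0"]])
    vCO <- unit(fr[["O@0"]] - fr[["C@0"]])
    expect_lt(abs(sum(cfr$zz * vCN)), 1e-12)
    expect_lt(abs(sum(cfr$zz * vCO)), 1e-12)
    expect_equal(acos(sum(cfr$xx * vCN)) * 180 / pi, 37, tolerance = 1e-9)
    # nitrogen tensor: xx 20 deg from the NH bond
    nfr <- csaFrame(fr, defaultCsaTensor("N"), 0L)
    vNH <- unit(fr[["HN@0"]] - fr[["N@0"]])
    expect_equal(acos(sum(nfr$xx * vNH)) * 180 / pi, 20, tolerance = 1e-9)
    # right-handed orthonormal triads
    for (f in list(cfr, nfr)) {
        expect_equal(sum(f$xx * f$yy), 0, tolerance = 1e-12)
        expect_equal(as.vector(dihedralCCR:::.crossRows(f$xx, f$yy)),
                     as.vector(f$zz), tolerance = 1e-12)
    }
})

test_that("degenerate CSA planes are rejected", {
    fr <- buildFragment(-60, -45)
    fr[["O@0"]] <- fr[["C@0"]] + 2 * (fr[["N@1"]] - fr[["C@0"]])  # colinear
    expect_error(csaFrame(fr, defaultCsaTensor("C"), 0L), "colinear")
})

test_that("DD/DD prefactor matches a hand-evaluated CODATA expression", {
    kind <- ccrRateKinds("NHN_CAHA")[[1]]
    pf <- prefactor(kind)
    gH <- 267.52218744e6; gC <- 67.2828e6; gN <- -27.116e6
    dd <- 1e-7 * 1.054571817e-34
    expected <- (2 / 5) * dd^2 * (gN * gH) * (gC * gH) /
        ((1.01e-10)^3 * (1.09e-10)^3)
    expect_equal(unname(pf$components[["dd"]]), expected, tolerance = 1e-12)
    expect_lt(expected, 0)  # signed gamma_N carries through
})

test_that("zeroing any gyromagnetic ratio kills a dipolar prefactor", {
    cst <- physicalConstants()
    cst@gammaC <- 1e-30  # effectively zero while keeping validity
    pf <- prefactor(ccrRateKinds("NHN_CAHA")[[1]], constants = cst)
    expect_lt(abs(pf$components[["dd"]]),
              1e-30 * abs(prefactor(ccrRateKinds("NHN_CAHA")[[1]])$components[["dd"]]))
})

test_that("CSA prefactor components scale with the ppm anisotropies", {
    pf <- prefactor(ccrRateKinds("NHN_C")[[1]])
    # ratio of components is exactly the ratio of (sigma_kk - sigma_zz)
    expect_equal(unname(pf$components[["xx"]] / pf$components[["yy"]]),
                 (249.4 - 87.9) / (191.1 - 87.9), tolerance = 1e-12)
    # doubling B0 doubles DD/CSA components, quadruples CSA/CSA
    cst2 <- physicalConstants(B0 = 2 * physicalConstants()@B0)
    pf2 <- prefactor(ccrRateKinds("NHN_C")[[1]], constants = cst2)
    expect_equal(unname(pf2$components / pf$components), c(2, 2))
    pc <- prefactor(ccrRateKinds("Cm1_C")[[1]])
    pc2 <- prefactor(ccrRateKinds("Cm1_C")[[1]], constants = cst2)
    expect_equal(unname(pc2$components / pc$components), rep(4, 4))
})

test_that("registry declares eight remote and two known-amplitude kinds", {
    reg <- ccrRateKinds()
    expect_length(reg, 10L)
    known <- vapply(reg, function(k) k@amplitudeKnown, logical(1))
    expect_identical(sum(known), 2L)
    expect_setequal(names(reg)[known], c("N_NHN", "C_CCA"))
    expect_length(remoteRateIds(), 8L)
    inst <- vapply(reg, function(k) k@distanceMode == "instantaneous", logical(1))
    expect_identical(names(reg)[inst], "HAHN1_C")
    expect_error(ccrRateKinds("NOPE"), "NOPE")
})

test_that("P2 has its root at the magic angle and bounds amplitudes", {
    expect_lt(abs(legendreP2(1 / sqrt(3))), 1e-10)
    expect_equal(legendreP2(1), 1)
    expect_equal(legendreP2(cos(20 * pi / 180)), 0.8245, tolerance = 1e-4)
    # DD/DD amplitudes bounded by prefactor * [-0.5, 1]
    s <- buildRateSurface("NHN_CAHA", resolution = 20)
    pf <- prefactor(ccrRateKinds("NHN_CAHA")[[1]])$components[["dd"]]
    rng <- range(surfaceValues(s) / pf)   # pf < 0 flips order, range() copes
    expect_gte(rng[1], -0.5 - 1e-12)
    expect_lte(rng[2], 1 + 1e-12)
})

test_that("structural amplitudes are invariant under global rotation", {
    phi <- c(-63, -120, 57); psi <- c(-43, 140, 47)
    fr <- buildFragment(phi, psi)
    th <- 0.7; ax <- c(1, 2, -1) / sqrt(6)
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    frR <- dihedralCCR:::.rotateCoords(fr, R)
    for (id in names(ccrRateKinds())) {
        k <- ccrRateKinds(id)[[1]]
        a0 <- dihedralCCR:::.amplitudeFromCoords(
            k, fr, physicalConstants(), defaultBackboneGeometry(),
            list(C = defaultCsaTensor("C"), N = defaultCsaTensor("N")))
        a1 <- dihedralCCR:::.amplitudeFromCoords(
            k, frR, physicalConstants(), defaultBackboneGeometry(),
            list(C = defaultCsaTensor("C"), N = defaultCsaTensor("N")))
        expect_lt(max(abs(a1 - a0) / (abs(a0) + 1e-9)), 1e-10)
    }
})

test_that("swapping the two interaction mechanisms leaves amplitudes unchanged", {
    for (id in c("NHN_CAHA", "NHN_C", "Cm1_C")) {
        k <- ccrRateKinds(id)[[1]]
        ks <- k
        ks@participants <- rev(k@participants)
        phi <- c(-63, -120); psi <- c(-43, 140)
        expect_equal(structuralAmplitude(ks, phi, psi),
                     structuralAmplitude(k, phi, psi), tolerance = 1e-12)
    }
})

test_that("rate surfaces tabulate the pointwise amplitude and are periodic", {
    s <- buildRateSurface("CAHA_NHN1", resolution = 30)
    ctr <- gridBinCenters(30)
    v <- surfaceValues(s)
    for (idx in list(c(2, 5), c(7, 11), c(1, 1))) {
        expect_equal(v[idx[1], idx[2]],
                     structuralAmplitude("CAHA_NHN1", ctr[idx[1]], ctr[idx[2]]),
                     tolerance = 1e-12)
    }
    # periodicity: amplitude at -180 equals the limit from +180
    aLeft <- structuralAmplitude("CAHA_NHN1", -180, -180)
    aRight <- structuralAmplitude("CAHA_NHN1", -179.999999, -179.999999)
    expect_equal(aLeft, aRight, tolerance = 1e-6)
    # known-amplitude kinds are flat and match knownAmplitudes()
    ka <- knownAmplitudes()
    for (id in c("N_NHN", "C_CCA")) {
        sv <- surfaceValues(buildRateSurface(id, resolution = 45))
        expect_lt(diff(range(sv)) / abs(mean(sv)), 1e-10)
        expect_equal(mean(sv), unname(ka[[id]]), tolerance = 1e-12)
    }
})

test_that("uniform-distribution averages match brute-force surface means", {
    ss <- toySurfaces(resolution = 15)
    u <- ramachandranGrid(matrix(1, 24, 24), 15)
    for (id in remoteRateIds()) {
        expect_equal(predictedRate(u, ss[[id]], 2e-9),
                     2e-9 * mean(surfaceValues(ss[[id]])), tolerance = 1e-12)
    }
})
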