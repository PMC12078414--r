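test_that("a single zero-spread basin gives a constant series at its center", {
    spec <- ensembleSpec(basins = data.frame(basin = "x", phi = -63, psi = -43,
                                             spread = 0, weight = 1),
                         nResidues = 2L, nFrames = 500L, seed = 2L)
    out <- sampleDihedralSeries(spec)
    expect_true(all(out$series@phi == -63))
    expect_true(all(out$series@psi == -43))
    # the analytic truth grid is a point mass in the right bin
    tg <- gridProbs(out$truth[[1]])
    expect_equal(sum(tg > 0), 1L)
    expect_equal(max(tg), 1)
})

test_that("sampling is bit-identical under a fixed seed", {
    spec <- ensembleSpec(nResidues = 2L, nFrames = 2000L, seed = 42L)
    a <- sampleDihedralSeries(spec)
    b <- sampleDihedralSeries(spec)
    expect_identical(a$series@phi, b$series@phi)
    expect_identical(a$series@psi, b$series@psi)
    spec2 <- ensembleSpec(nResidues = 2L, nFrames = 2000L, seed = 43L)
    expect_false(identical(sampleDihedralSeries(spec2)$series@phi,
                           a$series@phi))
})

test_that("long-run basin occupancies match the analytic mixture", {
    basins <- canonicalBasins(weights = c(0.7, 0, 0.3, 0),
                              spread = c(10, 10, 10, 10))
    basins <- basins[basins$weight > 0, ]
    spec <- ensembleSpec(basins = list(basins), exchangeTime = 1e-9,
                         jitterTime = 5e-11, nFrames = 200000L, dt = 1e-12,
                         seed = 6L)
    out <- sampleDihedralSeries(spec)
    # classify frames by psi: beta near +135, alphaR near -43
    inBeta <- abs(out$series@psi[, 1] - 135) < 60
    nEff <- spec@nFrames * spec@dt / spec@exchangeTime  # independent dwells
    expect_equal(mean(inBeta), 0.7, tolerance = 3 * sqrt(0.21 / nEff) / 0.7)
    # empirical histogram close to the analytic truth grid
    h <- ramachandranHistogram(out$series, 1L, 10)
    expect_lt(jsDivergence(h, out$truth[[1]]), 0.05)
})

test_that("chain coordinates round-trip the dihedral series", {
    spec <- ensembleSpec(nResidues = 4L, nFrames = 50L, seed = 3L)
    out <- sampleDihedralSeries(spec)
    coords <- chainCoordinates(out$series)
    for (r in 1:4) {
        phiM <- dihedralAngle(coords[[paste0("C@", r - 1)]],
                              coords[[paste0("N@", r)]],
                              coords[[paste0("CA@", r)]],
                              coords[[paste0("C@", r)]])
        psiM <- dihedralAngle(coords[[paste0("N@", r)]],
                              coords[[paste0("CA@", r)]],
                              coords[[paste0("C@", r)]],
                              coords[[paste0("N@", r + 1)]])
        expect_equal(phiM, out$series@phi[, r], tolerance = 1e-8)
        expect_equal(psiM, out$series@psi[, r], tolerance = 1e-8)
    }
    # rigid bonds: lengths constant across frames
    d <- sqrt(rowSums((coords[["CA@2"]] - coords[["N@2"]])^2))
    expect_lt(diff(range(d)), 1e-10)
})

test_that("chain and fragment builders agree at matching angles", {
    geom <- defaultBackboneGeometry()
    phi <- c(-120, -63, 57); psi <- c(140, -43, 47)
    ser <- new("DihedralSeries", phi = matrix(phi, 1), psi = matrix(psi, 1),
               dt = 1e-12, residues = 1:3)
    ch <- chainCoordinates(ser, geom)
    fr <- buildFragment(phi[2], psi[2], geom)
    # compare all pairwise distances among the shared atom set around residue 2
    atoms <- list(c("C", 1), c("O", 1), c("N", 2), c("HN", 2), c("CA", 2),
                  c("HA", 2), c("C", 2), c("O", 2), c("N", 3), c("HN", 3),
                  c("CA", 3))
    frAtoms <- list(c("C", -1), c("O", -1), c("N", 0), c("HN", 0), c("CA", 0),
                    c("HA", 0), c("C", 0), c("O", 0), c("N", 1), c("HN", 1),
                    c("CA", 1))
    for (i in seq_along(atoms)) for (j in seq_len(i - 1)) {
        dc <- sqrt(sum((ch[[paste0(atoms[[i]][1], "@", atoms[[i]][2])]][1, ] -
                        ch[[paste0(atoms[[j]][1], "@", atoms[[j]][2])]][1, ])^2))
        df <- sqrt(sum((fr[[paste0(frAtoms[[i]][1], "@", frAtoms[[i]][2])]][1, ] -
                        fr[[paste0(frAtoms[[j]][1], "@", frAtoms[[j]][2])]][1, ])^2))
        expect_equal(dc, df, tolerance = 1e-8)
    }
})

test_that("tumbling preserves internal geometry and is a no-op at infinite tau", {
    spec <- ensembleSpec(nResidues = 2L, nFrames = 400L, seed = 4L)
    coords <- chainCoordinates(sampleDihedralSeries(spec)$series)
    expect_identical(applyTumbling(coords, Inf, 1e-12), coords)
    tum <- applyTumbling(coords, 2e-9, 1e-12, seed = 5L)
    d0 <- sqrt(rowSums((coords[["CA@2"]] - coords[["N@1"]])^2))
    d1 <- sqrt(rowSums((tum[["CA@2"]] - tum[["N@1"]])^2))
    expect_equal(d1, d0, tolerance = 1e-10)
})

test_that("the tumbling auto-TCF decays with the requested correlation time", {
    n <- 150000L; dt <- 1e-12; taur <- 1.5e-9
    coords <- list("A@1" = matrix(0, n, 3),
                   "B@1" = matrix(rep(c(0, 0, 1), n), n, byrow = TRUE))
    tum <- applyTumbling(coords, taur, dt, seed = 10L)
    v <- dipoleSeries(tum, c("A", "B"), c(1, 1), dt)
    tc <- crossTcf(v, v, maxLag = 3e-9)
    # fit the log-decay over the first two tau
    t <- (0:3000) * dt
    sel <- 2:2500
    fit <- stats::lm(log(tcfValues(tc)[sel]) ~ t[sel])
    expect_equal(-1 / coef(fit)[[2]], taur, tolerance = 0.15)
})

test_that("synthetic forward rates honor their noise model and ground truth", {
    ss <- toySurfaces(resolution = 10)
    p <- standInCoilPrior(resolution = 10)
    # zero noise, point distribution: surface value times tau
    nb <- 36L
    m <- matrix(0, nb, nb); m[7, 8] <- 1
    pt <- ramachandranGrid(m, 10, normalize = FALSE)
    rr <- syntheticRates(pt, 2.5e-9, ss, noise = 0, seed = 1L)
    ctr <- gridBinCenters(10)
    for (id in remoteRateIds())
        expect_equal(rateValues(rr)[[id]],
                     2.5e-9 * structuralAmplitude(id, ctr[7], ctr[8]),
                     tolerance = 1e-10)
    # fixed seed reproducibility
    r1 <- syntheticRates(p, 3e-9, ss, noise = 0.5, seed = 9L)
    r2 <- syntheticRates(p, 3e-9, ss, noise = 0.5, seed = 9L)
    expect_identical(rateValues(r1), rateValues(r2))
    # noise sigma verified by the sample variance over 1000 draws
    g0 <- rateValues(syntheticRates(p, 3e-9, ss, noise = 0, seed = 1L))
    draws <- vapply(1:1000, function(s)
        rateValues(syntheticRates(p, 3e-9, ss, noise = 0.4,
                                  seed = s))[["NHN_CAHA"]], numeric(1))
    expect_equal(sd(draws - g0[["NHN_CAHA"]]), 0.4, tolerance = 0.1)
    expect_equal(mean(draws), g0[["NHN_CAHA"]], tolerance = 0.05)
})

test_that("ensemble specs validate their invariants", {
    expect_error(ensembleSpec(basins = data.frame(basin = "x", phi = 0,
                                                  psi = 0, spread = 5,
                                                  weight = 0.5),
                              nResidues = 1L),
                 "sum to 1")
    expect_error(ensembleSpec(nResidues = 2L, exchangeTime = -1), "> 0")
})
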