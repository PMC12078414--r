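#' @include rates.R
NULL

#' Canonical Ramachandran basins
#'
#' The four regions populated by disordered backbones: beta-sheet,
#' polyproline-II, right-handed alpha-helix and left-handed helix, with
#' representative centers and angular spreads. Weights are normalized.
#'
#' @param weights numeric(4): populations of (beta, ppii, alphaR, alphaL)
#' @param spread optional numeric(4) overriding the default spreads (deg)
#' @return data.frame with columns basin, phi, psi, spread, weight
#' @export
#' @examples
#' canonicalBasins()
canonicalBasins <- function(weights = c(0.30, 0.35, 0.30, 0.05),
                            spread = c(25, 20, 15, 13)) {
    stopifnot(length(weights) == 4L, all(weights >= 0), sum(weights) > 0)
    data.frame(basin = c("beta", "ppii", "alphaR", "alphaL"),
               phi = c(-135, -75, -63, 57),
               psi = c(135, 145, -43, 47),
               spread = spread,
               weight = weights / sum(weights))
}

#' Per-residue variations of the canonical basin populations
#'
#' Generates one basin table per residue by perturbing the canonical coil
#' weights on the log scale (deterministic for a given seed), emulating the
#' residue-to-residue variation of local structure propensities along a
#' disordered chain. Every residue keeps all four basins populated.
#'
#' @param nResidues chain length
#' @param sd log-scale perturbation strength
#' @param seed random seed
#' @param minWeight floor applied before renormalization
#' @return list of basin data.frames, one per residue
#' @export
#' @examples
#' sapply(variedCanonicalBasins(3, seed = 1), function(b) b$weight)
variedCanonicalBasins <- function(nResidues, sd = 0.6, seed = 1L,
                                  minWeight = 0.02) {
    set.seed(seed)
    base <- canonicalBasins()
    lapply(seq_len(nResidues), function(r) {
        w <- exp(log(base$weight) + stats::rnorm(4, sd = sd))
        w <- pmax(w / sum(w), minWeight)
        b <- base
        b$weight <- w / sum(w)
        b
    })
}

#' Construct an ensemble specification
#'
#' @param basins list with one basin data.frame per residue (see
#'   \code{\link{canonicalBasins}}), or a single data.frame recycled
#' @param nResidues chain length when \code{basins} is a single data.frame
#' @param exchangeTime mean basin dwell time (s)
#' @param jitterTime intra-basin jitter relaxation time (s)
#' @param tauRot isotropic tumbling time (s)
#' @param nFrames,dt sampling
#' @param seed random seed
#' @return an \linkS4class{EnsembleSpec}
#' @export
ensembleSpec <- function(basins = canonicalBasins(), nResidues = 10L,
                         exchangeTime = 5e-9, jitterTime = 0.1e-9,
                         tauRot = 3e-9, nFrames = 1e6L, dt = 1e-12,
                         seed = 1L) {
    if (is.data.frame(basins)) basins <- rep(list(basins), nResidues)
    new("EnsembleSpec", basins = basins, exchangeTime = exchangeTime,
        jitterTime = jitterTime, tauRot = tauRot,
        nFrames = as.integer(nFrames), dt = dt, seed = as.integer(seed))
}

# probability mass of a wrapped normal in each grid bin (exact, via pnorm
# over +-2 wraps; a point mass lands in the bin containing its center)
.wrappedNormBinProb <- function(resolution, mu, sigma) {
    nb <- as.integer(round(360 / resolution))
    lo <- -180 + (0:(nb - 1L)) * resolution
    hi <- lo + resolution
    if (sigma < 1e-9) {
        p <- numeric(nb)
        idx <- floor((.wrap180(mu) + 180) / resolution) + 1L
        p[idx] <- 1
        return(p)
    }
    p <- 0
    for (k in -2:2)
        p <- p + stats::pnorm(hi + 360 * k, mu, sigma) -
                 stats::pnorm(lo + 360 * k, mu, sigma)
    p / sum(p)
}

#' Analytic Ramachandran distribution of a basin mixture
#'
#' The exact stationary distribution implied by a basin table: a weighted
#' mixture of wrapped Gaussians, integrated bin-wise (not a sampled
#' histogram), so recovery targets are independent of sampling noise.
#'
#' @param basins basin data.frame (phi, psi, spread, weight)
#' @param resolution grid resolution (deg)
#' @return a \linkS4class{RamachandranGrid}
#' @export
#' @examples
#' trueBasinGrid(canonicalBasins(), resolution = 10)
trueBasinGrid <- function(basins, resolution = 10) {
    nb <- as.integer(round(360 / resolution))
    m <- matrix(0, nb, nb)
    for (j in seq_len(nrow(basins))) {
        pphi <- .wrappedNormBinProb(resolution, basins$phi[j], basins$spread[j])
        ppsi <- .wrappedNormBinProb(resolution, basins$psi[j], basins$spread[j])
        m <- m + basins$weight[j] * outer(pphi, ppsi)
    }
    new("RamachandranGrid", resolution = resolution, probs = m / sum(m))
}

#' Sample a synthetic dihedral time series
#'
#' Each residue performs continuous-time Markov jumps between its basins
#' (exponential dwell with mean \code{exchangeTime}; at each event the
#' basin is redrawn from the stationary weights) plus wrapped-Gaussian
#' jitter: an Ornstein-Uhlenbeck process with unit stationary variance and
#' relaxation time \code{jitterTime}, scaled by the current basin's spread.
#' The marginal distribution of each residue is therefore exactly the
#' analytic basin mixture of \code{\link{trueBasinGrid}}.
#'
#' @param spec an \linkS4class{EnsembleSpec}
#' @param resolution resolution (deg) of the returned truth grids
#' @return list: \code{series} (\linkS4class{DihedralSeries}), \code{truth}
#'   (list of \linkS4class{RamachandranGrid}, one per residue), \code{seed}
#' @export
#' @examples
#' out <- sampleDihedralSeries(ensembleSpec(nFrames = 1000, nResidues = 2))
#' out$series
sampleDihedralSeries <- function(spec, resolution = 10) {
    set.seed(spec@seed)
    n <- spec@nFrames
    R <- length(spec@basins)
    phi <- matrix(0, n, R)
    psi <- matrix(0, n, R)
    rho <- exp(-spec@dt / spec@jitterTime)
    innov <- sqrt(1 - rho^2)
    for (r in seq_len(R)) {
        b <- spec@basins[[r]]
        # basin path: event times from exponential dwells, basins redrawn
        # from the stationary weights at each event
        total <- n * spec@dt
        nev <- stats::qpois(1 - 1e-12, total / spec@exchangeTime) + 10L
        times <- cumsum(stats::rexp(nev, rate = 1 / spec@exchangeTime))
        times <- times[times < total]
        ids <- sample.int(nrow(b), length(times) + 1L, replace = TRUE,
                          prob = b$weight)
        path <- ids[findInterval(seq_len(n) * spec@dt - spec@dt, c(0, times))]
        # unit-variance OU jitter, stationary start
        ou <- function() {
            e <- stats::rnorm(n)
            as.numeric(stats::filter(innov * e, rho, method = "recursive",
                                     init = stats::rnorm(1)))
        }
        phi[, r] <- .wrap180(b$phi[path] + b$spread[path] * ou())
        psi[, r] <- .wrap180(b$psi[path] + b$spread[path] * ou())
    }
    series <- new("DihedralSeries", phi = phi, psi = psi, dt = spec@dt,
                  residues = seq_len(R))
    truth <- lapply(spec@basins, trueBasinGrid, resolution = resolution)
    list(series = series, truth = truth, seed = spec@seed)
}

#' Build chain coordinates from a dihedral time series
#'
#' Internal-to-Cartesian reconstruction of an all-backbone chain, frame by
#' frame (vectorized over frames), with rigid internal coordinates and
#' trans peptide bonds; phi_r and psi_r of every residue are taken from the
#' series. A virtual carbonyl (residue 0) seeds the chain so that residue
#' 1 has a defined phi, and N/HN/CA of residue R+1 are appended so that
#' terminal peptide-plane interferences are well defined.
#'
#' @param series a \linkS4class{DihedralSeries}
#' @param geometry a \linkS4class{BackboneGeometry}
#' @return named list of n x 3 matrices keyed "atom@residue"
#' @export
chainCoordinates <- function(series, geometry = defaultBackboneGeometry()) {
    n <- nrow(series@phi)
    R <- ncol(series@phi)
    b <- geometry@bonds; a <- geometry@angles
    one <- function(v) matrix(v, n, 3, byrow = TRUE)
    at <- list()
    put <- function(atom, res, m) at[[paste0(atom, "@", res)]] <<- m
    # seed: residue-0 carbonyl plane in the lab frame
    put("N", 1L, one(c(0, 0, 0)))
    put("CA", 1L, one(c(b[["N-CA"]], 0, 0)))
    th <- a[["C-N-CA"]] * pi / 180
    put("C", 0L, one(b[["C-N"]] * c(cos(th), sin(th), 0)))
    put("O", 0L, .placeAtom(at[["CA@1"]], at[["N@1"]], at[["C@0"]],
                            b[["C-O"]], a[["N-C-O"]], 0))
    for (r in seq_len(R)) {
        Cm <- at[[paste0("C@", r - 1L)]]
        Om <- at[[paste0("O@", r - 1L)]]
        Nr <- at[[paste0("N@", r)]]
        CAr <- at[[paste0("CA@", r)]]
        put("HN", r, .placeAtom(Om, Cm, Nr, b[["N-HN"]], a[["C-N-HN"]], 180))
        Cr <- .placeAtom(Cm, Nr, CAr, b[["CA-C"]], a[["N-CA-C"]],
                         series@phi[, r])
        put("C", r, Cr)
        put("HA", r, .placeAtom(Cm, Nr, CAr, b[["CA-HA"]], a[["N-CA-HA"]],
                                series@phi[, r] + geometry@haTorsionOffset))
        Np <- .placeAtom(Nr, CAr, Cr, b[["C-N"]], a[["CA-C-N"]],
                         series@psi[, r])
        put("N", r + 1L, Np)
        put("O", r, .placeAtom(Nr, CAr, Cr, b[["C-O"]], a[["CA-C-O"]],
                               series@psi[, r] + 180))
        put("CA", r + 1L, .placeAtom(CAr, Cr, Np, b[["N-CA"]], a[["C-N-CA"]],
                                     geometry@omega))
    }
    put("HN", R + 1L, .placeAtom(at[[paste0("O@", R)]], at[[paste0("C@", R)]],
                                 at[[paste0("N@", R + 1L)]],
                                 b[["N-HN"]], a[["C-N-HN"]], 180))
    at
}

# quaternion product, vectorized over rows of n x 4 matrices
.quatMul <- function(q, p) {
    cbind(q[, 1] * p[, 1] - q[, 2] * p[, 2] - q[, 3] * p[, 3] - q[, 4] * p[, 4],
          q[, 1] * p[, 2] + q[, 2] * p[, 1] + q[, 3] * p[, 4] - q[, 4] * p[, 3],
          q[, 1] * p[, 3] - q[, 2] * p[, 4] + q[, 3] * p[, 1] + q[, 4] * p[, 2],
          q[, 1] * p[, 4] + q[, 2] * p[, 3] - q[, 3] * p[, 2] + q[, 4] * p[, 1])
}

#' Apply isotropic rotational diffusion to a coordinate trajectory
#'
#' Rotates every frame by the running product of small random rotations
#' (rotation-vector increments with per-axis variance 2 D_r dt, D_r =
#' 1 / (6 tauRot)), i.e. an isotropic rotational random walk whose rank-2
#' orientational TCF decays as exp(-t / tauRot). Internal geometry is
#' untouched. \code{tauRot = Inf} returns the trajectory unchanged.
#'
#' @param coords coordinate trajectory (named list of n x 3 matrices)
#' @param tauRot rank-2 rotational correlation time (s)
#' @param dt frame spacing (s)
#' @param seed seed for the rotational noise
#' @return coordinate trajectory of the same shape
#' @export
applyTumbling <- function(coords, tauRot, dt, seed = 1L) {
    if (!is.finite(tauRot)) return(coords)
    stopifnot(tauRot > 0)
    n <- nrow(coords[[1]])
    set.seed(seed)
    sig <- sqrt(2 * dt / (6 * tauRot))
    d <- matrix(stats::rnorm(3 * n, sd = sig), n, 3)
    ang <- .rowNorm(d)
    ax <- d / ang
    q <- cbind(cos(ang / 2), sin(ang / 2) * ax)
    # cumulative composition by a vectorized prefix scan (log2(n) passes)
    step <- 1L
    while (step < n) {
        idx <- (step + 1L):n
        q[idx, ] <- .quatMul(q[idx - step, , drop = FALSE],
                             q[idx, , drop = FALSE])
        step <- step * 2L
    }
    w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
    # rows of the rotation matrix R(t), applied as v' = R v per frame
    r11 <- 1 - 2 * (y * y + z * z); r12 <- 2 * (x * y - w * z); r13 <- 2 * (x * z + w * y)
    r21 <- 2 * (x * y + w * z); r22 <- 1 - 2 * (x * x + z * z); r23 <- 2 * (y * z - w * x)
    r31 <- 2 * (x * z - w * y); r32 <- 2 * (y * z + w * x); r33 <- 1 - 2 * (x * x + y * y)
    lapply(coords, function(m) {
        cbind(r11 * m[, 1] + r12 * m[, 2] + r13 * m[, 3],
              r21 * m[, 1] + r22 * m[, 2] + r23 * m[, 3],
              r31 * m[, 1] + r32 * m[, 2] + r33 * m[, 3])
    })
}

#' Forward-generate a synthetic per-residue rate set
#'
#' Produces the ten rates a residue with dihedral distribution \code{p}
#' and per-rate correlation times \code{taus} would show:
#' Gamma_j = tau_j * sum(p * A_j) plus Gaussian noise. Ground truth (the
#' taus and noiseless structural components) is recorded in the
#' diagnostics slots; the proxy times are derived from the noisy
#' known-amplitude rates exactly as an experiment would.
#'
#' @param p a \linkS4class{RamachandranGrid}
#' @param taus correlation times (s): scalar or named per rate id
#' @param surfaces named list of \linkS4class{RateSurface} for all kinds
#' @param noise Gaussian rate noise sigma (s^-1)
#' @param seed seed for the noise
#' @param residue residue index to record
#' @param constants,geometry,csas parameters for the known amplitudes
#' @return a \linkS4class{ResidueRateSet}
#' @export
syntheticRates <- function(p, taus, surfaces, noise = 0, seed = 1L,
                           residue = 1L,
                           constants = physicalConstants(),
                           geometry = defaultBackboneGeometry(),
                           csas = list(C = defaultCsaTensor("C"),
                                       N = defaultCsaTensor("N"))) {
    set.seed(seed)
    ids <- names(surfaces)
    if (length(taus) == 1L && is.null(names(taus)))
        taus <- stats::setNames(rep(taus, length(ids)), ids)
    pv <- as.vector(gridProbs(p))
    a <- vapply(ids, function(id) {
        s <- surfaces[[id]]
        if (resolution(s) != resolution(p)) stop("resolution mismatch for ", id)
        sum(pv * as.vector(surfaceValues(s)))
    }, numeric(1))
    g <- a * taus[ids] + stats::rnorm(length(ids), sd = noise)
    names(g) <- ids
    ka <- knownAmplitudes(constants, geometry, csas)
    tauN <- g[["N_NHN"]] / ka[["N_NHN"]]
    tauC <- g[["C_CCA"]] / ka[["C_CCA"]]
    new("ResidueRateSet", residue = as.integer(residue), rates = g,
        tauNNH = tauN, tauCCCA = tauC, tauOpt = proxyTauOpt(tauC, tauN),
        trueTau = taus[ids], trueA = a, flags = character())
}

#' Stand-in random-coil prior
#'
#' A broad, strictly positive four-basin mixture (beta, polyproline-II,
#' alpha, left-handed) standing in for a residue-unspecific random-coil
#' Ramachandran prior. Bins below the floor \code{eps} are clamped before
#' normalization so Kullback-Leibler terms stay finite.
#'
#' @param resolution grid resolution (deg)
#' @param weights basin weights (beta, ppii, alphaR, alphaL)
#' @param spread basin spreads (deg); broader than typical single-residue
#'   distributions, as befits a prior
#' @param eps probability floor
#' @return a \linkS4class{RamachandranGrid}
#' @export
#' @examples
#' standInCoilPrior(resolution = 10)
standInCoilPrior <- function(resolution = 1,
                             weights = c(0.28, 0.34, 0.30, 0.08),
                             spread = c(35, 30, 25, 20), eps = 1e-12) {
    g <- trueBasinGrid(canonicalBasins(weights, spread), resolution)
    m <- pmax(gridProbs(g), eps)
    new("RamachandranGrid", resolution = resolution, probs = m / sum(m))
}
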