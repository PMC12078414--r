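#' @include synthgen.R
NULL

#' Construct a Ramachandran grid
#'
#' @param probs matrix of (possibly unnormalized) nonnegative bin masses
#' @param resolution bin width (deg)
#' @param normalize divide by the total mass (default TRUE)
#' @return a \linkS4class{RamachandranGrid}
#' @export
ramachandranGrid <- function(probs, resolution, normalize = TRUE) {
    if (normalize) probs <- probs / sum(probs)
    new("RamachandranGrid", resolution = resolution, probs = probs)
}

#' Rate predicted from a dihedral distribution
#'
#' The forward model: Gamma(p) = tau * sum_(phi,psi) p * A(phi,psi) —
#' linear in p.
#'
#' @param p a \linkS4class{RamachandranGrid}
#' @param surface the rate's \linkS4class{RateSurface}
#' @param tau effective correlation time (s)
#' @return predicted rate (s^-1)
#' @export
#' @examples
#' s <- buildRateSurface("NHN_CAHA", resolution = 30)
#' u <- ramachandranGrid(matrix(1, 12, 12), 30)
#' predictedRate(u, s, 3e-9)  # tau * mean amplitude
predictedRate <- function(p, surface, tau) {
    if (resolution(p) != resolution(surface))
        stop("grid and surface resolutions differ")
    tau * sum(gridProbs(p) * surfaceValues(surface))
}

#' Assemble a MaxEnt inversion problem
#'
#' Bundles the observed remote rates, their uncertainties (1 s^-1 each by
#' default), the per-rate effective correlation times from the dynamical
#' proxy, the amplitude surfaces and the prior.
#'
#' @param gammas named numeric of observed remote rates (s^-1)
#' @param surfaces named list of \linkS4class{RateSurface} covering them
#' @param taus per-rate correlation times (s): scalar or named
#' @param prior a \linkS4class{RamachandranGrid}, strictly positive
#' @param sigmas rate uncertainties (s^-1): scalar or named
#' @param temperature regularization temperature T
#' @return a list of class "ccrProblem"
#' @export
ccrProblem <- function(gammas, surfaces, taus, prior, sigmas = 1,
                       temperature = 1) {
    ids <- names(gammas)
    if (is.null(ids) || !all(ids %in% names(surfaces)))
        stop("every observed rate needs a matching surface")
    res <- resolution(prior)
    A <- vapply(ids, function(id) {
        s <- surfaces[[id]]
        if (resolution(s) != res)
            stop("surface resolution differs from the prior for ", id)
        as.vector(surfaceValues(s))
    }, numeric(length(gridProbs(prior))))
    if (length(taus) == 1L && is.null(names(taus)))
        taus <- stats::setNames(rep(taus, length(ids)), ids)
    if (any(!is.finite(taus)) || any(taus <= 0))
        stop("correlation times must be positive and finite")
    if (length(sigmas) == 1L && is.null(names(sigmas)))
        sigmas <- stats::setNames(rep(sigmas, length(ids)), ids)
    q <- as.vector(gridProbs(prior))
    structure(list(gammas = gammas, ids = ids,
                   C = sweep(A, 2, taus[ids], `*`),  # tau_j A_j per bin
                   sigmas = sigmas[ids], q = q, resolution = res,
                   temperature = temperature),
              class = "ccrProblem")
}

#' MaxEnt objective function
#'
#' T * D_KL(p || q) + 0.5 * sum_j ((Gamma_j(p) - Gamma_j) / sigma_j)^2,
#' with D_KL in nats. Infinite if p has mass where the prior has none.
#'
#' @param p a \linkS4class{RamachandranGrid} (or probability vector)
#' @param problem a problem from \code{\link{ccrProblem}}
#' @return scalar objective value
#' @export
maxentObjective <- function(p, problem) {
    pv <- if (is(p, "RamachandranGrid")) as.vector(gridProbs(p)) else p
    pos <- pv > 0
    if (any(pos & problem$q <= 0)) return(Inf)
    dkl <- sum(pv[pos] * log(pv[pos] / problem$q[pos]))
    pred <- as.vector(crossprod(problem$C, pv))
    problem$temperature * dkl +
        0.5 * sum(((pred - problem$gammas) / problem$sigmas)^2)
}

# dual objective (to be maximized) and its gradient; lam has one entry per
# rate. p(lam) = q * exp(-(1/T) C lam) / Z.
.dualPieces <- function(lam, problem) {
    s <- as.vector(problem$C %*% lam) / problem$temperature
    s <- s - min(s)
    w <- problem$q * exp(-s)
    Z <- sum(w)
    p <- w / Z
    pred <- as.vector(crossprod(problem$C, p))
    list(p = p, pred = pred)
}

.dualValue <- function(lam, problem) {
    T <- problem$temperature
    s <- as.vector(problem$C %*% lam) / T
    m <- min(s)
    logZ <- log(sum(problem$q * exp(-(s - m)))) - m
    # maximize: -T logZ - lam.Gamma - 0.5 sum sigma^2 lam^2; optim minimizes
    -(-T * logZ - sum(lam * problem$gammas) -
      0.5 * sum(problem$sigmas^2 * lam^2))
}

.dualGrad <- function(lam, problem) {
    pieces <- .dualPieces(lam, problem)
    -(pieces$pred - problem$gammas - problem$sigmas^2 * lam)
}

#' Maximum a posteriori (MaxEnt) inversion of a rate set
#'
#' Minimizes T * D_KL(p || q) + chi^2 / 2 over the probability simplex.
#' Stationarity gives p proportional to q * exp(-(1/T) sum_j lambda_j
#' tau_j A_j) with lambda_j = (Gamma_j(p) - Gamma_j) / sigma_j^2, so the
#' problem is solved in the dual: a smooth concave maximization in as many
#' variables as there are rates, handled by BFGS with analytic gradient
#' (deterministic, initialized at lambda = 0, i.e. p = q). The returned
#' distribution is feasible by construction (nonnegative, normalized).
#'
#' @param problem from \code{\link{ccrProblem}}
#' @param init optional initial lambda (one per rate)
#' @param maxit BFGS iteration cap
#' @param tol gradient tolerance for the convergence flag
#' @return a \linkS4class{CcrFit}
#' @export
maxentMap <- function(problem, init = NULL, maxit = 500L, tol = 1e-6) {
    m <- length(problem$gammas)
    lam0 <- if (is.null(init)) numeric(m) else init
    opt <- stats::optim(lam0, fn = .dualValue, gr = .dualGrad,
                        problem = problem, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-14))
    # polish with a damped fixed-point pass on the stationarity condition
    lam <- opt$par
    for (k in seq_len(200L)) {
        pieces <- .dualPieces(lam, problem)
        lamNew <- (pieces$pred - problem$gammas) / problem$sigmas^2
        if (max(abs(lamNew - lam)) < 1e-12 * (1 + max(abs(lam)))) {
            lam <- lamNew
            break
        }
        lam <- lam + 0.5 * (lamNew - lam)
    }
    if (.dualValue(lam, problem) > .dualValue(opt$par, problem))
        lam <- opt$par
    pieces <- .dualPieces(lam, problem)
    grad <- pieces$pred - problem$gammas - problem$sigmas^2 * lam
    p <- pieces$p
    nb <- as.integer(round(360 / problem$resolution))
    pos <- p > 0
    dkl <- sum(p[pos] * log(p[pos] / problem$q[pos]))
    chi2 <- sum(((pieces$pred - problem$gammas) / problem$sigmas)^2)
    new("CcrFit",
        grid = new("RamachandranGrid", resolution = problem$resolution,
                   probs = matrix(p / sum(p), nb, nb)),
        chi2 = chi2, dkl = dkl, temperature = problem$temperature,
        iterations = as.integer(opt$counts[1]),
        converged = max(abs(grad)) < tol * (1 + max(abs(problem$gammas))),
        lambda = stats::setNames(lam, problem$ids))
}

#' Temperature selection by L-curve
#'
#' Solves the MAP problem over a ladder of temperatures (by default 0.01 to
#' 3, log-spaced) and records (T, chi^2, D_KL). The corner is the point of
#' maximum discrete curvature on the (log chi^2, log D_KL) curve; a
#' degenerate (flat) curve falls back to T = 1 with a warning. With
#' \code{default = TRUE} the scan is bypassed entirely and T = 1 is
#' selected, the package's reporting default.
#'
#' @param problem from \code{\link{ccrProblem}}
#' @param temperatures temperature ladder (>= 3 values)
#' @param default bypass and return T = 1
#' @return list: \code{points} (data.frame T, chi2, dkl) and
#'   \code{selected}
#' @export
lCurve <- function(problem,
                   temperatures = exp(seq(log(0.01), log(3), length.out = 12)),
                   default = FALSE) {
    if (default) return(list(points = NULL, selected = 1))
    if (length(temperatures) < 3L) stop("need at least 3 temperatures")
    temperatures <- sort(temperatures, decreasing = TRUE)
    pts <- lapply(temperatures, function(T) {
        pr <- problem; pr$temperature <- T
        fit <- maxentMap(pr)
        c(T = T, chi2 = fit@chi2, dkl = fit@dkl)
    })
    pts <- as.data.frame(do.call(rbind, pts))
    ok <- pts$chi2 > 1e-12 & pts$dkl > 1e-12
    if (sum(ok) < 3L || diff(range(log(pts$chi2[ok]))) < 1e-6) {
        warning("degenerate L-curve; falling back to T = 1")
        return(list(points = pts, selected = 1))
    }
    x <- log(pts$chi2[ok]); y <- log(pts$dkl[ok])
    k <- .mengerCurvature(x, y)
    sel <- pts$T[ok][which.max(k) + 1L]
    list(points = pts, selected = sel)
}

# discrete curvature of consecutive point triples (Menger): for interior
# points 2..(n-1); returns n-2 values
.mengerCurvature <- function(x, y) {
    n <- length(x)
    i <- 2:(n - 1)
    ax <- x[i - 1]; ay <- y[i - 1]
    bx <- x[i]; by <- y[i]
    cx <- x[i + 1]; cy <- y[i + 1]
    area2 <- abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay))
    dab <- sqrt((bx - ax)^2 + (by - ay)^2)
    dbc <- sqrt((cx - bx)^2 + (cy - by)^2)
    dac <- sqrt((cx - ax)^2 + (cy - ay)^2)
    2 * area2 / (dab * dbc * dac + 1e-300)
}
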