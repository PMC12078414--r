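#' @include surfaces.R
NULL

#' Construct a unit-vector time series
#'
#' @param vectors n x 3 matrix (normalized internally unless already unit)
#' @param dt frame spacing (s)
#' @param distances optional inter-nuclear distances r(t) (Angstrom)
#' @return a \linkS4class{VectorTrajectory}
#' @export
vectorTrajectory <- function(vectors, dt, distances = numeric()) {
    new("VectorTrajectory", vectors = .normalizeRows(vectors),
        distances = as.numeric(distances), dt = dt)
}

# the six unique second-moment products x2,y2,z2,xy,xz,yz whose weighted sum
# reconstructs (a.b)^2; off-diagonal weights 2
.p2Products <- function(v) {
    cbind(v[, 1]^2, v[, 2]^2, v[, 3]^2,
          v[, 1] * v[, 2], v[, 1] * v[, 3], v[, 2] * v[, 3])
}

.p2Weights <- c(1, 1, 1, 2, 2, 2)

#' Cross time correlation function of two vector series
#'
#' Computes C(t) = < P2(a(0) . b(t)) > by FFT cross-correlation of the six
#' second-moment component series (convolution theorem), with unbiased
#' per-lag normalization (each lag divided by its number of contributing
#' time origins). The two series are also correlated in reversed order
#' (b(0) . a(t)) and the returned TCF is the average of the two, which
#' improves sampling and makes the estimator symmetric in its arguments.
#'
#' With \code{distanceWeighting}, the correlated quantity is
#' P2(a(0) . b(t)) / (r_a(0)^3 r_b(t)^3) with distances in meters (both
#' series must carry distances); this is the integrand of the dipolar rate
#' expressions when instantaneous distances are retained.
#'
#' @param a,b \linkS4class{VectorTrajectory} objects of equal length and dt
#' @param maxLag largest lag (s); defaults to 10 ns
#' @param distanceWeighting logical
#' @return a \linkS4class{Tcf}
#' @export
#' @examples
#' v <- vectorTrajectory(matrix(rep(c(1, 0, 0), 10), 10, byrow = TRUE), 1e-12)
#' tcfValues(crossTcf(v, v, maxLag = 5e-12))  # constant vector: all ones
crossTcf <- function(a, b, maxLag = 10e-9, distanceWeighting = FALSE) {
    n <- nrow(a@vectors)
    if (nrow(b@vectors) != n) stop("trajectories must have equal length")
    if (abs(a@dt - b@dt) > 1e-18) stop("trajectories must share dt")
    L <- as.integer(round(maxLag / a@dt))
    if (L > n - 1L) stop("max lag exceeds the trajectory span")
    ua <- ub <- NULL
    if (distanceWeighting) {
        # sides without stored distances (e.g. CSA principal axes) get unit
        # weights: Eq-10-type rates carry 1/r^3 on the dipole side only
        if (!length(a@distances) && !length(b@distances))
            stop("distance weighting requires distances on at least one trajectory")
        ua <- if (length(a@distances)) (a@distances * 1e-10)^-3 else rep(1, n)
        ub <- if (length(b@distances)) (b@distances * 1e-10)^-3 else rep(1, n)
    }
    cc <- .rawCrossCorr(.p2Products(a@vectors), .p2Products(b@vectors),
                        ua, ub, L)
    norm <- n - 0:L
    if (distanceWeighting) {
        vals <- (1.5 * cc$prod - 0.5 * cc$wt) / norm
    } else {
        vals <- 1.5 * cc$prod / norm - 0.5
    }
    new("Tcf", values = vals, dt = a@dt)
}

# Symmetrized raw correlation sums via one zero-padded FFT pass.
# Pa, Pb: n x 6 product matrices; ua, ub: optional weight series.
# Returns forward+reverse-averaged sums (not normalized):
#   prod[l+1] = 0.5 * sum_s ( Pa(s) Pb(s+l) + Pb(s) Pa(s+l) ) . w2
#   wt[l+1]   = same for the weight series (all-ones if NULL)
.rawCrossCorr <- function(Pa, Pb, ua, ub, L) {
    n <- nrow(Pa)
    if (!is.null(ua)) {
        Pa <- Pa * ua
        Pb <- Pb * ub
    }
    nf <- stats::nextn(n + L + 1L, factors = c(2, 3, 5))
    pad <- function(m) rbind(m, matrix(0, nf - n, ncol(m)))
    FA <- stats::mvfft(pad(Pa))
    FB <- stats::mvfft(pad(Pb))
    H <- (Conj(FA) * FB) %*% .p2Weights
    if (!is.null(ua)) {
        Fua <- stats::fft(c(ua, numeric(nf - n)))
        Fub <- stats::fft(c(ub, numeric(nf - n)))
        Hu <- Conj(Fua) * Fub
    }
    s <- Re(stats::fft(H, inverse = TRUE)) / nf
    # index l+1 holds the forward lag l, index nf+1-l the reversed lag l
    fwd <- s[1:(L + 1L)]
    rev <- c(s[1L], s[nf - seq_len(L) + 1L])
    out <- list(prod = (fwd + rev) / 2)
    if (!is.null(ua)) {
        su <- Re(stats::fft(Hu, inverse = TRUE)) / nf
        out$wt <- (su[1:(L + 1L)] + c(su[1L], su[nf - seq_len(L) + 1L])) / 2
    }
    out
}

#' Component weights of a CSA tensor
#'
#' The in-plane anisotropies (sigma_kk - sigma_zz), k = x, y, in ppm: the
#' weights with which component TCFs combine into a CSA-dependent rate.
#'
#' @param csa a \linkS4class{CsaTensor}
#' @return named numeric, ppm
#' @export
#' @examples
#' csaComponentWeights(defaultCsaTensor("C"))  # 161.5, 103.2
csaComponentWeights <- function(csa) {
    w <- csa@sigma[1:2] - csa@sigma[3]
    names(w) <- c("xx", "yy")
    w
}

#' Combine CSA component TCFs into a weighted TCF
#'
#' DD/CSA rates are linear combinations of component TCFs weighted by
#' (sigma_kk - sigma_zz); CSA/CSA rates carry the double sum with products
#' of the two tensors' anisotropies. Component names must be "xx"/"yy"
#' (DD/CSA) or "xx.xx", "yy.xx", "xx.yy", "yy.yy" (CSA/CSA).
#'
#' @param componentTcfs named list of \linkS4class{Tcf}
#' @param csa the (first) \linkS4class{CsaTensor}
#' @param csa2 second tensor for CSA/CSA combinations
#' @return a \linkS4class{Tcf} (weights in ppm, or ppm^2 for CSA/CSA)
#' @export
csaWeightedTcf <- function(componentTcfs, csa, csa2 = NULL) {
    if (is.null(csa2)) {
        w <- csaComponentWeights(csa)
    } else {
        w <- as.vector(outer(csaComponentWeights(csa),
                             csaComponentWeights(csa2)))
        names(w) <- c("xx.xx", "yy.xx", "xx.yy", "yy.yy")
    }
    need <- names(w)[w != 0]
    if (!all(need %in% names(componentTcfs)))
        stop("missing component TCF(s): ",
             paste(setdiff(need, names(componentTcfs)), collapse = ", "))
    if (!length(componentTcfs)) stop("no component TCFs supplied")
    dts <- vapply(componentTcfs, function(x) x@dt, numeric(1))
    lens <- vapply(componentTcfs, function(x) length(x@values), integer(1))
    if (length(unique(dts)) != 1L || length(unique(lens)) != 1L)
        stop("component TCFs must share dt and length")
    vals <- numeric(lens[1L])
    for (k in need) vals <- vals + w[[k]] * componentTcfs[[k]]@values
    new("Tcf", values = vals, dt = dts[1L])
}

#' Apply analytic isotropic tumbling to a TCF
#'
#' Multiplies an internal-motion TCF by exp(-t / tauRot), the rank-2
#' orientational decay of isotropic rotational diffusion. This is the
#' standard way to endow a rotation-free trajectory with global tumbling:
#' internal motion and overall rotation are statistically independent, so
#' their correlation functions factorize. Compared with simulating an
#' explicit rotational random walk, the analytic factor adds no
#' Monte-Carlo noise of its own, which matters because the finite-length
#' noise floor of a simulated-tumbling TCF tail is what limits the
#' accuracy of small-amplitude rates.
#'
#' @param tcf a \linkS4class{Tcf} of internal motion
#' @param tauRot rank-2 rotational correlation time (s); Inf is a no-op
#' @return a \linkS4class{Tcf}
#' @export
#' @examples
#' tc <- new("Tcf", values = rep(0.4, 1001), dt = 1e-11)
#' integrateTcf(applyTumblingDecay(tc, 2e-9), 1e-8) / 0.4  # ~ tau_rot
applyTumblingDecay <- function(tcf, tauRot) {
    if (!is.finite(tauRot)) return(tcf)
    stopifnot(tauRot > 0)
    t <- (seq_along(tcf@values) - 1L) * tcf@dt
    new("Tcf", values = tcf@values * exp(-t / tauRot), dt = tcf@dt)
}

#' Zero-frequency spectral density: integrate a TCF
#'
#' Trapezoidal numerical integral of C(t) from 0 to \code{upperBound} at the
#' native lag spacing. Numerical integration is used deliberately instead of
#' (multi-)exponential fits, which are prone to introducing artifacts.
#'
#' @param tcf a \linkS4class{Tcf}
#' @param upperBound integration bound (s); must not exceed the stored lags
#' @return J(0) in seconds (times the TCF's own units)
#' @export
#' @examples
#' tc <- new("Tcf", values = exp(-(0:10000) / 1000), dt = 1e-12)
#' integrateTcf(tc, 10e-9) * 1e9  # ~ 1 ns
integrateTcf <- function(tcf, upperBound = maxLag(tcf)) {
    k <- as.integer(round(upperBound / tcf@dt))
    if (k > length(tcf@values) - 1L)
        stop("upper bound exceeds the available lags (TCF truncated at ",
             format(maxLag(tcf)), " s)")
    v <- tcf@values[1:(k + 1L)]
    tcf@dt * (sum(v) - 0.5 * (v[1L] + v[k + 1L]))
}

#' Effective correlation time of a TCF
#'
#' The integral of the amplitude-normalized TCF (C(t)/C(0)) up to
#' \code{upperBound}. For CSA-weighted TCFs, pass the weighted TCF so the
#' normalization uses the weighted amplitude.
#'
#' @param tcf a \linkS4class{Tcf}
#' @param upperBound integration bound (s)
#' @return tau in seconds
#' @export
correlationTime <- function(tcf, upperBound = maxLag(tcf)) {
    c0 <- tcf@values[1L]
    if (abs(c0) < .Machine$double.eps)
        stop("zero amplitude: correlation time undefined")
    integrateTcf(new("Tcf", values = tcf@values / c0, dt = tcf@dt), upperBound)
}
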