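# Independent oracles used across the suite. These deliberately avoid the
# package's own numerical paths.

p2ref <- function(x) 1.5 * x^2 - 0.5

# brute-force O(N^2-ish) TCF estimator: per-lag loops over time origins,
# forward and reversed averaged, unbiased normalization
directTcf <- function(a, b, nLags, weighted = FALSE) {
    va <- a@vectors; vb <- b@vectors
    n <- nrow(va)
    ua <- if (weighted && length(a@distances)) (a@distances * 1e-10)^-3 else rep(1, n)
    ub <- if (weighted && length(b@distances)) (b@distances * 1e-10)^-3 else rep(1, n)
    vapply(0:(nLags - 1L), function(l) {
        s <- seq_len(n - l)
        dot1 <- rowSums(va[s, , drop = FALSE] * vb[s + l, , drop = FALSE])
        dot2 <- rowSums(vb[s, , drop = FALSE] * va[s + l, , drop = FALSE])
        if (weighted) {
            0.5 * (mean(p2ref(dot1) * ua[s] * ub[s + l]) +
                   mean(p2ref(dot2) * ub[s] * ua[s + l]))
        } else {
            0.5 * (mean(p2ref(dot1)) + mean(p2ref(dot2)))
        }
    }, numeric(1))
}

randomUnitVectors <- function(n) {
    m <- matrix(rnorm(3 * n), n, 3)
    m / sqrt(rowSums(m^2))
}

# independent internal-to-Cartesian placement built from explicit
# axis-angle rotation matrices (Rodrigues form), not the package's local
# NeRF frame construction
zmatPlaceRef <- function(A, B, C, bond, angleDeg, torsionDeg) {
    rotmat <- function(axis, theta) {
        axis <- axis / sqrt(sum(axis^2))
        K <- matrix(c(0, axis[3], -axis[2],
                      -axis[3], 0, axis[1],
                      axis[2], -axis[1], 0), 3, 3)
        diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
    }
    cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                               u[3] * v[1] - u[1] * v[3],
                               u[1] * v[2] - u[2] * v[1])
    bc <- (C - B); bc <- bc / sqrt(sum(bc^2))
    d0 <- -bc                               # extend along the C->B direction
    ax1 <- cross3(bc, B - A)                # plane normal
    if (sqrt(sum(ax1^2)) < 1e-12) stop("colinear reference")
    ax1 <- ax1 / sqrt(sum(ax1^2))
    d1 <- as.vector(rotmat(ax1, angleDeg * pi / 180) %*% d0)   # open the bond angle
    d2 <- as.vector(rotmat(bc, -torsionDeg * pi / 180) %*% d1) # dial the torsion
    C + bond * d2
}

# closed-form least-squares slope through the origin
slopeThroughOriginRef <- function(x, y) sum(x * y) / sum(x * x)

# direct evaluation of the base-2 Jensen-Shannon formula on two vectors
jsRef <- function(p, r) {
    m <- (p + r) / 2
    f <- function(a) ifelse(a > 0, a * log2(a / m), 0)
    0.5 * sum(f(p)) + 0.5 * sum(f(r))
}

# small standard problem used by several maxent tests
toySurfaces <- function(resolution = 10) buildRateSurfaces(resolution = resolution)
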