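#' @include gridmetrics.R
NULL

# self-describing plain-text numeric container: '# key: value' header lines
# followed by a whitespace-delimited matrix
.writeMatrixFile <- function(m, path, attrs) {
    con <- file(path, "w")
    on.exit(close(con))
    for (k in names(attrs))
        writeLines(sprintf("# %s: %s", k, format(attrs[[k]], digits = 17)), con)
    utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

.readMatrixFile <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^#", lines)
    attrs <- list()
    for (l in lines[hdr]) {
        kv <- sub("^#\\s*", "", l)
        k <- sub(":.*$", "", kv)
        v <- trimws(sub("^[^:]*:", "", kv))
        attrs[[k]] <- v
    }
    m <- as.matrix(utils::read.table(text = lines[-hdr]))
    dimnames(m) <- NULL
    list(matrix = m, attrs = attrs)
}

#' Read and write Ramachandran grids and rate surfaces
#'
#' Grids and surfaces round-trip through a self-describing plain-text
#' format: '# key: value' header lines (resolution, rate id, field) above
#' a whitespace-delimited matrix with phi along rows.
#'
#' @param x object to write
#' @param path file path
#' @return the read object, or (invisibly) the path when writing
#' @name gridIO
NULL

#' @rdname gridIO
#' @export
writeRamachandranGrid <- function(x, path) {
    .writeMatrixFile(gridProbs(x), path,
                     list(type = "RamachandranGrid",
                          resolution_deg = resolution(x)))
}

#' @rdname gridIO
#' @export
readRamachandranGrid <- function(path) {
    f <- .readMatrixFile(path)
    ramachandranGrid(f$matrix, as.numeric(f$attrs$resolution_deg),
                     normalize = TRUE)
}

#' @rdname gridIO
#' @export
writeRateSurface <- function(x, path) {
    .writeMatrixFile(surfaceValues(x), path,
                     list(type = "RateSurface", rate_id = rateId(x),
                          resolution_deg = resolution(x), B0_T = x@B0))
}

#' @rdname gridIO
#' @export
readRateSurface <- function(path) {
    f <- .readMatrixFile(path)
    new("RateSurface", rateId = f$attrs$rate_id,
        resolution = as.numeric(f$attrs$resolution_deg),
        values = f$matrix, B0 = as.numeric(f$attrs$B0_T))
}

#' Read and write per-residue rate tables
#'
#' Delimited text with columns residue, rate_id, gamma_per_s, sigma,
#' tau_nnh_ns, tau_ccca_ns, tau_opt_ns and (when available) tau_true_ns,
#' a_true_per_s; round-trips losslessly.
#'
#' @param rateSets list of \linkS4class{ResidueRateSet}
#' @param path file path
#' @param sigma recorded uncertainty column (s^-1)
#' @return data.frame (reading) or invisible path (writing)
#' @name rateTableIO
NULL

#' @rdname rateTableIO
#' @export
writeRateTable <- function(rateSets, path, sigma = 1) {
    rows <- lapply(rateSets, function(r) {
        data.frame(residue = r@residue, rate_id = names(r@rates),
                   gamma_per_s = unname(r@rates), sigma = sigma,
                   tau_nnh_ns = r@tauNNH * 1e9,
                   tau_ccca_ns = r@tauCCCA * 1e9,
                   tau_opt_ns = r@tauOpt * 1e9,
                   tau_true_ns = if (length(r@trueTau))
                       unname(r@trueTau[names(r@rates)] * 1e9) else NA_real_,
                   a_true_per_s = if (length(r@trueA))
                       unname(r@trueA[names(r@rates)]) else NA_real_,
                   flags = paste(r@flags, collapse = ";"))
    })
    df <- do.call(rbind, rows)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname rateTableIO
#' @export
readRateTable <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    split(df, df$residue) |> lapply(function(d) {
        rates <- stats::setNames(d$gamma_per_s, d$rate_id)
        tt <- if (all(is.na(d$tau_true_ns))) numeric() else
            stats::setNames(d$tau_true_ns * 1e-9, d$rate_id)
        ta <- if (all(is.na(d$a_true_per_s))) numeric() else
            stats::setNames(d$a_true_per_s, d$rate_id)
        fl <- unique(d$flags)
        fl <- fl[!is.na(fl) & nzchar(fl)]
        new("ResidueRateSet", residue = d$residue[1], rates = rates,
            tauNNH = d$tau_nnh_ns[1] * 1e-9,
            tauCCCA = d$tau_ccca_ns[1] * 1e-9,
            tauOpt = d$tau_opt_ns[1] * 1e-9,
            trueTau = tt, trueA = ta,
            flags = if (length(fl)) unlist(strsplit(fl, ";")) else character())
    })
}

#' Read a run configuration
#'
#' YAML with explicit units; recognized keys include b0_mhz, tmax_ns,
#' proxy, temperature, resolution, geometry (bond/angle overrides, deg and
#' Angstrom), csa overrides and seed. Unspecified keys fall back to the
#' package defaults.
#'
#' @param path YAML file
#' @return list with \code{constants}, \code{geometry}, \code{csas},
#'   \code{upperBound}, \code{proxy}, \code{temperature},
#'   \code{resolution}, \code{seed}, and the raw config
#' @export
readRunConfig <- function(path = NULL) {
    raw <- if (is.null(path)) list() else yaml::read_yaml(path)
    geom <- defaultBackboneGeometry(
        bonds = unlist(raw$geometry$bonds) %||% numeric(),
        angles = unlist(raw$geometry$angles) %||% numeric())
    csas <- list(C = defaultCsaTensor("C"), N = defaultCsaTensor("N"))
    if (!is.null(raw$csa$C$sigma)) csas$C@sigma <- as.numeric(raw$csa$C$sigma)
    if (!is.null(raw$csa$C$alpha)) csas$C@alpha <- as.numeric(raw$csa$C$alpha)
    if (!is.null(raw$csa$N$sigma)) csas$N@sigma <- as.numeric(raw$csa$N$sigma)
    if (!is.null(raw$csa$N$alpha)) csas$N@alpha <- as.numeric(raw$csa$N$alpha)
    list(constants = physicalConstants(b0FromMHz(raw$b0_mhz %||% 800)),
         geometry = geom, csas = csas,
         upperBound = (raw$tmax_ns %||% 10) * 1e-9,
         proxy = raw$proxy %||% "ccca",
         temperature = raw$temperature %||% 1,
         resolution = raw$resolution %||% 1,
         seed = as.integer(raw$seed %||% 1L),
         raw = raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
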