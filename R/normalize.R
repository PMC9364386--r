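## Between-array normalization core: beta computation, reference quantile
## normalization, Infinium type I/II intensity-mode alignment, and the
## dasen-style composite.

.betaFromChannels <- function(meth, unmeth, offset = 100) {
    if (offset < 0) stop("offset must be non-negative")
    denom <- meth + unmeth + offset
    beta <- meth / denom
    beta[!is.na(denom) & denom == 0] <- NA_real_
    beta
}

#' Compute methylation beta values
#'
#' Beta for each probe/sample is \eqn{M / (M + U + offset)} with the
#' conventional offset of 100 stabilizing low-intensity probes and keeping
#' values strictly below 1. A cell missing in either channel gives a missing
#' beta; with \code{offset = 0}, a cell with \eqn{M = U = 0} is undefined and
#' also returned missing.
#'
#' @param x a [MethylIntensitySet-class] (raw or corrected).
#' @param offset non-negative intensity offset (default 100).
#' @return numeric matrix of betas (probes x samples), values in [0, 1).
#' @examples
#' m <- matrix(c(0, 100, 900), 3, 1,
#'             dimnames = list(paste0("cg", 1:3), "s1"))
#' u <- matrix(0, 3, 1, dimnames = dimnames(m))
#' ann <- data.frame(probe_id = rownames(m), chromosome = "1",
#'                   design_type = "II")
#' computeBeta(MethylIntensitySet(m, u, ann))  # 0, 0.5, 0.9
#' @export
computeBeta <- function(x, offset = 100) {
    stopifnot(methods::is(x, "MethylIntensitySet"))
    .betaFromChannels(meth(x), unmeth(x), offset)
}

#' Reference quantile normalization
#'
#' Forces every column (sample) onto a common reference distribution. When
#' \code{reference} is absent it is the per-rank mean of the column-sorted
#' values, computed over rows complete in all samples. Each column's values
#' are then replaced by the reference values at their within-column ranks;
#' tied values share the mean of the reference values their ranks span.
#' Columns with missing cells are mapped by interpolating the reference at
#' fractional ranks rescaled to the reference length, so for complete data
#' every column ends up with an identical sorted multiset.
#'
#' @param m numeric matrix (rows = features, columns = samples); \code{NA}
#'   allowed, preserved in place.
#' @param reference optional non-decreasing numeric vector to map onto;
#'   required when \code{m} has a single column.
#' @return matrix of the same shape and dimnames.
#' @examples
#' quantileNormalize(cbind(a = c(1, 2, 3), b = c(3, 4, 5)))  # both 2,3,4
#' @export
quantileNormalize <- function(m, reference = NULL) {
    m <- as.matrix(m)
    if (is.null(reference)) {
        if (ncol(m) < 2L)
            stop("need >= 2 samples to build a reference distribution")
        complete <- stats::complete.cases(m)
        if (sum(complete) < 1L)
            stop("no rows complete across all samples; supply a reference")
        sorted <- apply(m[complete, , drop = FALSE], 2L, sort)
        reference <- rowMeans(matrix(sorted, ncol = ncol(m)))
    } else {
        reference <- as.numeric(reference)
        if (is.unsorted(reference))
            stop("reference must be non-decreasing")
    }
    k <- length(reference)
    out <- m
    for (j in seq_len(ncol(m))) {
        x <- m[, j]
        ok <- which(!is.na(x))
        L <- length(ok)
        if (L == 0L)
            stop("column with all values missing: ",
                 if (is.null(colnames(m))) j else colnames(m)[j])
        xs <- x[ok]
        ord <- order(xs)
        pos <- if (L == 1L) (k + 1) / 2
               else 1 + (seq_len(L) - 1) * (k - 1) / (L - 1)
        vals <- if (k == 1L) rep(reference, L)
                else stats::approx(seq_len(k), reference, xout = pos)$y
        ## tied input values share the mean of the reference values their
        ## ranks span; tied runs are consecutive after sorting
        runs <- rle(xs[ord])
        if (any(runs$lengths > 1L)) {
            ends <- cumsum(runs$lengths)
            sums <- cumsum(vals)[ends]
            gm <- diff(c(0, sums)) / runs$lengths
            vals <- rep.int(gm, runs$lengths)
        }
        res <- numeric(L)
        res[ord] <- vals
        out[ok, j] <- res
    }
    out
}

.firstDensityMode <- function(v, gridPoints = 512L, relFloor = 0.01) {
    v <- v[!is.na(v)]
    d <- stats::density(v, kernel = "gaussian", bw = "nrd0", n = gridPoints)
    y <- d$y
    peaks <- which(diff(sign(diff(y))) < 0) + 1L
    peaks <- peaks[y[peaks] > relFloor * max(y)]
    if (!length(peaks)) peaks <- which.max(y)
    i <- peaks[1L]
    x0 <- d$x[i]
    ## parabolic refinement of the peak position: the fixed grid quantizes
    ## the mode to the grid step, which is coarse when the intensity range
    ## is dominated by a long upper tail
    if (i > 1L && i < length(y)) {
        denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
        if (denom < 0) {
            step <- d$x[2L] - d$x[1L]
            x0 <- x0 + 0.5 * step * (y[i - 1L] - y[i + 1L]) / denom
        }
    }
    x0
}

#' Align Infinium type I and type II intensity distributions
#'
#' Per sample, an additive offset shifts type I intensities so that the
#' location of their lowest-intensity density mode (Gaussian-kernel KDE,
#' Silverman bandwidth, 512-point grid; first local maximum exceeding 1% of
#' the peak density) matches the type II mode — the background-anchoring
#' step a dasen-style pipeline applies before quantile normalization. When a
#' chip row is known for every sample, the raw per-sample offsets are
#' replaced by their least-squares linear fit against chip row, smoothing
#' the offset over the physical position on the chip. Output intensities are
#' floored at 0.
#'
#' @param m numeric matrix (probes x samples).
#' @param designType character vector ("I"/"II") of length \code{nrow(m)}.
#' @param chipRow optional integer vector of length \code{ncol(m)}.
#' @param minProbes refuse when either design type has fewer probes than
#'   this (density estimate unstable); lower deliberately to override.
#' @return matrix of the same shape with type I values shifted.
#' @export
alignTypeDistributions <- function(m, designType, chipRow = NULL,
                                   minProbes = 50L) {
    m <- as.matrix(m)
    stopifnot(length(designType) == nrow(m))
    isI <- designType == "I"
    if (sum(isI) < minProbes || sum(!isI) < minProbes)
        stop(sprintf(
            "fewer than %d probes of one design type (I: %d, II: %d); %s",
            minProbes, sum(isI), sum(!isI),
            "lower 'minProbes' to override"))
    offsets <- vapply(seq_len(ncol(m)), function(j) {
        .firstDensityMode(m[!isI, j]) - .firstDensityMode(m[isI, j])
    }, numeric(1))
    if (!is.null(chipRow) && !anyNA(chipRow)) {
        stopifnot(length(chipRow) == ncol(m))
        if (length(unique(chipRow)) >= 2L)
            offsets <- unname(stats::fitted(stats::lm(offsets ~ chipRow)))
    }
    m[isI, ] <- pmax(sweep(m[isI, , drop = FALSE], 2L, offsets, "+"), 0)
    m
}

#' dasen-style between-array normalization
#'
#' The composite normalizer: per channel (M, U), type I intensities are
#' background-aligned to type II ([alignTypeDistributions()]), then each
#' design type is quantile-normalized across samples separately
#' ([quantileNormalize()]); betas are recomputed from the corrected
#' intensities. \code{probeScope = "all"} is the classic mixed behaviour in
#' which sex-chromosome probes join the quantile pool — the source of the
#' sex bias this package exists to avoid; \code{"autosomes_only"} restricts
#' everything to autosomal probes (the result then contains only autosomal
#' probes) and is step one of [adjustedNormalize()].
#'
#' @param x a [MethylIntensitySet-class].
#' @param probeScope \code{"all"} or \code{"autosomes_only"}.
#' @param offset beta offset, see [computeBeta()].
#' @param alignTypes logical; skip the type I/II alignment when FALSE
#'   (plain per-type quantile normalization).
#' @param useChipRow logical; when TRUE and \code{colData} carries a
#'   complete \code{chipRow}, alignment offsets are regressed on it.
#' @param minTypeProbes passed to [alignTypeDistributions()].
#' @return a [MethylNormResult-class].
#' @export
dasenNormalize <- function(x, probeScope = c("all", "autosomes_only"),
                           offset = 100, alignTypes = TRUE,
                           useChipRow = TRUE, minTypeProbes = 50L) {
    stopifnot(methods::is(x, "MethylIntensitySet"))
    probeScope <- match.arg(probeScope)
    if (probeScope == "autosomes_only")
        x <- x[chromosomeGroup(x) == "autosome", ]
    dt <- designType(x)
    cr <- if (useChipRow) chipRow(x) else NULL
    correct <- function(mat) {
        if (alignTypes)
            mat <- alignTypeDistributions(mat, dt, chipRow = cr,
                                          minProbes = minTypeProbes)
        for (ty in unique(dt)) {
            sel <- dt == ty
            mat[sel, ] <- quantileNormalize(mat[sel, , drop = FALSE])
        }
        mat
    }
    mC <- correct(meth(x))
    uC <- correct(unmeth(x))
    .newNormResult(x, mC, uC,
                   methodId = if (alignTypes) sprintf("dasen[%s]", probeScope)
                              else sprintf("quantile[%s]", probeScope),
                   parameters = list(offset = offset,
                                     probeScope = probeScope,
                                     alignTypes = alignTypes))
}

#' @rdname dasenNormalize
#' @details \code{quantileOnlyNormalize(x, ...)} is the same pipeline
#'   without the type I/II alignment step.
#' @param ... passed on to \code{dasenNormalize}.
#' @export
quantileOnlyNormalize <- function(x, probeScope = c("all", "autosomes_only"),
                                  offset = 100, ...) {
    dasenNormalize(x, probeScope = probeScope, offset = offset,
                   alignTypes = FALSE, ...)
}
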