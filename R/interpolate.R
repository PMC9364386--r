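## Rank interpolation of sex-chromosome probes against the autosomal
## raw -> corrected mapping, and the composite adjusted normalizer.

#' Estimate fractional ranks of sex-probe values within an autosomal
#' distribution
#'
#' The autosomal raw values define an empirical value-to-rank map (ascending
#' sort; tied values share their average rank). Each query value receives a
#' fractional rank by piecewise-linear interpolation between the bracketing
#' autosomal values; queries below the autosomal minimum are clamped to rank
#' 1 and above the maximum to rank k (the number of non-missing autosomal
#' values), with clamp flags reported.
#'
#' @param rawAutosomal numeric vector with >= 2 non-missing values.
#' @param rawSex numeric vector of query values (\code{NA} gives \code{NA}).
#' @return list with \code{rank} (numeric, in [1, k]), logical
#'   \code{clampedLow}/\code{clampedHigh}, and \code{k}.
#' @examples
#' estimateRanks(c(10, 20, 30), c(20, 15, 5))$rank  # 2.0 1.5 1.0
#' @export
estimateRanks <- function(rawAutosomal, rawSex) {
    av <- rawAutosomal[!is.na(rawAutosomal)]
    if (length(av) < 2L)
        stop("need >= 2 non-missing autosomal values")
    k <- length(av)
    r <- rank(av, ties.method = "average")
    o <- order(av)
    ux <- av[o]
    ur <- r[o]
    dup <- duplicated(ux)
    ux <- ux[!dup]
    ur <- ur[!dup]
    out <- rep(NA_real_, length(rawSex))
    low <- high <- rep(FALSE, length(rawSex))
    ok <- !is.na(rawSex)
    if (any(ok)) {
        q <- rawSex[ok]
        est <- if (length(ux) == 1L) rep(ur, length(q))
               else stats::approx(ux, ur, xout = q, rule = 2)$y
        lo <- q < ux[1L]
        hi <- q > ux[length(ux)]
        est[lo] <- 1
        est[hi] <- k
        out[ok] <- est
        low[ok] <- lo
        high[ok] <- hi
    }
    list(rank = out, clampedLow = low, clampedHigh = high, k = k)
}

#' Build the rank-to-corrected-value quantile function
#'
#' Sorts the corrected autosomal values ascending and returns the function
#' \eqn{F} mapping a (possibly fractional) rank \eqn{r \in [1, k]} to a
#' corrected value by linear interpolation between the values at ranks
#' \eqn{\lfloor r \rfloor} and \eqn{\lceil r \rceil}; integer ranks return
#' the sorted value itself. Ranks outside \eqn{[1, k]} are clamped.
#'
#' @param correctedAutosomal numeric vector with >= 2 non-missing values.
#' @return a function of one numeric argument, with attributes
#'   \code{sortedCorrected} and \code{k}.
#' @examples
#' F <- buildQuantileFunction(c(200, 100))
#' F(1.5)  # 150
#' @export
buildQuantileFunction <- function(correctedAutosomal) {
    sc <- sort(correctedAutosomal, na.last = NA)
    k <- length(sc)
    if (k < 2L) stop("need >= 2 non-missing corrected values")
    f <- function(r) {
        r <- pmin(pmax(r, 1), k)
        stats::approx(seq_len(k), sc, xout = r)$y
    }
    attr(f, "sortedCorrected") <- sc
    attr(f, "k") <- k
    f
}

#' Interpolate corrected values for sex-chromosome probes
#'
#' Composition of [estimateRanks()] and [buildQuantileFunction()]: every sex
#' probe's raw value is placed at a fractional rank within the autosomal raw
#' distribution, then that rank is read off the sorted corrected autosomal
#' values. A sex probe whose raw value coincides with a uniquely-ranked
#' autosomal probe's receives exactly that probe's corrected value (for a
#' rank-preserving step-one normalizer); out-of-range values receive the
#' extreme corrected values.
#'
#' @param rawAutosomal,correctedAutosomal equal-length vectors, pairwise
#'   aligned by probe (corrected value of the probe with that raw value).
#' @param rawSex numeric vector of raw sex-probe values.
#' @return numeric vector of corrected sex values (\code{NA} where
#'   \code{rawSex} is missing).
#' @examples
#' interpolateSexValues(c(10, 20), c(100, 200), 15)  # 150
#' @export
interpolateSexValues <- function(rawAutosomal, correctedAutosomal, rawSex) {
    if (length(rawAutosomal) != length(correctedAutosomal))
        stop("raw and corrected autosomal vectors must have equal length")
    ok <- !is.na(rawAutosomal) & !is.na(correctedAutosomal)
    rk <- estimateRanks(rawAutosomal[ok], rawSex)
    f <- buildQuantileFunction(correctedAutosomal[ok])
    out <- rep(NA_real_, length(rawSex))
    has <- !is.na(rk$rank)
    out[has] <- f(rk$rank[has])
    out
}

#' Two-step sex-unbiased normalization (interpolatedXY strategy)
#'
#' Step one normalizes the autosomal probes alone with the named base
#' normalizer; step two assigns every sex-chromosome probe a corrected
#' intensity by rank interpolation ([interpolateSexValues()]) against the
#' autosomal raw-to-corrected mapping. Interpolation runs independently
#' within each stratum of channel (M, U) x Infinium design type (I, II),
#' per sample, and betas are recomputed from the corrected intensities.
#' Sample sex is never consulted, so the method needs no prior sex
#' annotation and cannot leak X-inactivation structure into autosomes.
#'
#' @param x a [MethylIntensitySet-class] covering autosomal and
#'   sex-chromosome probes.
#' @param normalizer \code{"dasen"} (type alignment + per-type quantile
#'   normalization), \code{"quantile"} (per-type quantile normalization
#'   only), or \code{"plugin"}.
#' @param plugin when \code{normalizer = "plugin"}, a
#'   \code{function(m, ...)} applied to each autosomal (channel x design
#'   type) stratum matrix (probes x samples), returning the corrected
#'   matrix of the same shape — the seam by which any quantile-based base
#'   normalizer can be adjusted.
#' @param offset beta offset, see [computeBeta()].
#' @param minAutosomal minimum autosomal probes required in any stratum
#'   containing sex probes (interpolation needs a dense autosomal grid);
#'   lower deliberately for toy data.
#' @param ... passed to [dasenNormalize()] (e.g. \code{useChipRow},
#'   \code{minTypeProbes}).
#' @return a [MethylNormResult-class]; \code{interpolatedProbes(result)}
#'   lists every sex-chromosome probe, and the autosomal rows are
#'   bit-identical to \code{dasenNormalize(x, "autosomes_only")} for the
#'   dasen base.
#' @export
adjustedNormalize <- function(x, normalizer = c("dasen", "quantile", "plugin"),
                              plugin = NULL, offset = 100,
                              minAutosomal = 1000L, ...) {
    stopifnot(methods::is(x, "MethylIntensitySet"))
    normalizer <- match.arg(normalizer)
    grp <- chromosomeGroup(x)
    isAuto <- grp == "autosome"
    dt <- designType(x)
    for (ty in unique(dt[!isAuto])) {
        nAuto <- sum(isAuto & dt == ty)
        if (nAuto < minAutosomal)
            stop(sprintf(
                "stratum (type %s) has %d autosomal probes (< %d); %s", ty,
                nAuto, minAutosomal,
                "use normalizer='quantile' on pooled types or lower 'minAutosomal'"))
    }
    auto <- x[isAuto, ]
    step1 <- switch(normalizer,
        dasen = dasenNormalize(auto, probeScope = "all", offset = offset, ...),
        quantile = quantileOnlyNormalize(auto, probeScope = "all",
                                         offset = offset, ...),
        plugin = {
            if (!is.function(plugin))
                stop("normalizer='plugin' requires a plugin function")
            .pluginNormalize(auto, plugin, offset = offset)
        })
    mC <- meth(x)
    uC <- unmeth(x)
    mC[isAuto, ] <- meth(step1)[rownames(auto), ]
    uC[isAuto, ] <- unmeth(step1)[rownames(auto), ]
    for (channel in c("meth", "unmeth")) {
        rawAll <- if (channel == "meth") meth(x) else unmeth(x)
        corAll <- if (channel == "meth") mC else uC
        for (ty in unique(dt[!isAuto])) {
            aSel <- isAuto & dt == ty
            sSel <- !isAuto & dt == ty
            for (j in seq_len(ncol(x))) {
                corAll[sSel, j] <- interpolateSexValues(
                    rawAll[aSel, j], corAll[aSel, j], rawAll[sSel, j])
            }
        }
        if (channel == "meth") mC <- corAll else uC <- corAll
    }
    .newNormResult(x, mC, uC,
                   methodId = paste0("adjusted-",
                                     if (normalizer == "dasen") "dasen"
                                     else if (normalizer == "quantile")
                                         "quantile" else "plugin"),
                   interpolated = rownames(x)[!isAuto],
                   parameters = list(offset = offset,
                                     normalizer = normalizer,
                                     minAutosomal = minAutosomal))
}

.pluginNormalize <- function(auto, plugin, offset = 100) {
    dt <- designType(auto)
    correct <- function(mat) {
        for (ty in unique(dt)) {
            sel <- dt == ty
            res <- plugin(mat[sel, , drop = FALSE])
            if (!identical(dim(res), dim(mat[sel, , drop = FALSE])))
                stop("plugin must return a matrix of the input shape")
            mat[sel, ] <- res
        }
        mat
    }
    .newNormResult(auto, correct(meth(auto)), correct(unmeth(auto)),
                   methodId = "plugin[all]",
                   parameters = list(offset = offset))
}
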