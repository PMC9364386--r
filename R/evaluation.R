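## Evaluation protocols: single-sex gold standard for interpolation
## accuracy, per-CpG sex EWAS with Bonferroni correction, saDMP overlap.

#' Single-sex gold-standard evaluation of the interpolation step
#'
#' In a single-sex group there is no between-sex pattern difference, so sex
#' chromosomes may legitimately be normalized together with the autosomes:
#' that run (base normalizer, \code{probeScope = "all"}) provides reference
#' corrected betas for the sex-chromosome probes. The candidate run is the
#' adjusted two-step normalizer on the same samples. Per sample, the RMSE
#' between candidate and reference betas is reported over X-linked and over
#' Y-linked probes, grouped into the four categories female/male x X/Y.
#' Female-Y values are background noise (females carry no Y), so that
#' category is reported for completeness only.
#'
#' @param x a [MethylIntensitySet-class] with per-sample sex in
#'   \code{colData}; samples are split by sex internally and each sex group
#'   present must have >= 2 samples.
#' @param normalizer base normalizer, \code{"dasen"} or \code{"quantile"}.
#' @param offset beta offset, see [computeBeta()].
#' @param minAutosomal passed to [adjustedNormalize()].
#' @param minTypeProbes,useChipRow passed to [dasenNormalize()].
#' @return list with \code{perSample} (data.frame: sample, sex, chromosome,
#'   category, rmse), \code{summary} (per-category mean, sd, n) and
#'   \code{methodId}.
#' @export
singleSexGoldStandard <- function(x, normalizer = c("dasen", "quantile"),
                                  offset = 100, minAutosomal = 1000L,
                                  minTypeProbes = 50L, useChipRow = TRUE) {
    stopifnot(methods::is(x, "MethylIntensitySet"))
    normalizer <- match.arg(normalizer)
    sex <- sampleSex(x)
    if (is.null(sex) || anyNA(sex))
        stop("per-sample sex is required for the gold-standard protocol")
    grp <- chromosomeGroup(x)
    per <- list()
    for (s in intersect(c("female", "male"), unique(sex))) {
        g <- x[, sex == s]
        if (ncol(g) < 2L) {
            warning("fewer than 2 ", s, " samples; group skipped")
            next
        }
        ref <- if (normalizer == "dasen")
            dasenNormalize(g, probeScope = "all", offset = offset,
                           minTypeProbes = minTypeProbes,
                           useChipRow = useChipRow)
        else quantileOnlyNormalize(g, probeScope = "all", offset = offset)
        cand <- adjustedNormalize(g, normalizer = normalizer,
                                  offset = offset,
                                  minAutosomal = minAutosomal,
                                  minTypeProbes = minTypeProbes,
                                  useChipRow = useChipRow)
        bRef <- betaValues(ref)
        bCand <- betaValues(cand)
        for (chrom in c("X", "Y")) {
            sel <- grp == chrom
            if (!any(sel)) next
            per[[paste(s, chrom)]] <- data.frame(
                sample = colnames(g), sex = s, chromosome = chrom,
                category = paste(s, chrom, sep = "_"),
                rmse = vapply(seq_len(ncol(g)), function(j)
                    as.numeric(rmse(bCand[sel, j], bRef[sel, j])),
                    numeric(1)))
        }
    }
    if (!length(per)) stop("no evaluable single-sex group")
    perSample <- do.call(rbind, per)
    rownames(perSample) <- NULL
    agg <- lapply(split(perSample$rmse, perSample$category), function(v)
        data.frame(mean = mean(v), sd = stats::sd(v), n = length(v)))
    summary <- do.call(rbind, agg)
    summary <- data.frame(category = rownames(summary), summary,
                          row.names = NULL)
    list(perSample = perSample, summary = summary,
         methodId = paste0("adjusted-", normalizer, " vs ",
                           normalizer, "[all]"))
}

#' Per-CpG sex EWAS (two-group F-test, Bonferroni)
#'
#' For each probe, methylation beta is regressed on sex (a two-level
#' factor); the F statistic with (1, n - 2) degrees of freedom is the
#' standard linear-model test for a binary covariate, with no further
#' covariates. Probes with zero variance across samples are skipped and
#' flagged. Significance is Bonferroni-corrected: a probe is significant
#' when p < alpha / (number of probes tested). Direction is the sign of
#' (mean female beta - mean male beta).
#'
#' @param beta numeric matrix (probes x samples) or a
#'   [MethylNormResult-class].
#' @param sex per-sample labels ("female"/"male"); taken from the result
#'   object when NULL.
#' @param alpha family-wise error target (default 0.05).
#' @param scope \code{"all"} or \code{"autosomes"}; restricting to
#'   autosomes requires annotation (a result object, or \code{annotation}).
#' @param annotation optional data.frame as from [readAnnotation()].
#' @return data.frame with one row per probe: \code{probe},
#'   \code{meanFemale}, \code{meanMale}, \code{delta} (female - male),
#'   \code{fStat}, \code{pValue}, \code{tested}, \code{significant},
#'   \code{direction} ("higher_in_females"/"higher_in_males"). Attributes:
#'   \code{alpha}, \code{nTested}, \code{bonferroniThreshold},
#'   \code{nSignificant}, \code{directionCounts}.
#' @export
sexEWAS <- function(beta, sex = NULL, alpha = 0.05,
                    scope = c("all", "autosomes"), annotation = NULL) {
    scope <- match.arg(scope)
    if (methods::is(beta, "MethylNormResult")) {
        if (is.null(sex)) sex <- sampleSex(beta)
        grp <- chromosomeGroup(beta)
        beta <- betaValues(beta)
    } else {
        beta <- as.matrix(beta)
        grp <- NULL
    }
    if (scope == "autosomes") {
        if (is.null(grp)) {
            if (is.null(annotation))
                stop("scope='autosomes' needs annotation")
            ann <- .normalizeAnnotation(annotation)
            chr <- as.character(ann[rownames(beta), "chromosome"])
            grp <- factor(ifelse(chr %in% c("X", "Y"), chr, "autosome"),
                          levels = c("autosome", "X", "Y"))
        }
        beta <- beta[grp == "autosome", , drop = FALSE]
    }
    if (is.null(sex)) stop("per-sample sex labels are required")
    stopifnot(length(sex) == ncol(beta))
    fIdx <- sex == "female"
    mIdx <- sex == "male"
    nf <- sum(fIdx)
    nm <- sum(mIdx)
    if (nf < 2L || nm < 2L) stop("need >= 2 samples of each sex")
    n <- nf + nm
    bf <- beta[, fIdx, drop = FALSE]
    bm <- beta[, mIdx, drop = FALSE]
    muF <- rowMeans(bf)
    muM <- rowMeans(bm)
    mu <- (nf * muF + nm * muM) / n
    ssTot <- rowSums((beta[, fIdx | mIdx, drop = FALSE] - mu)^2)
    ssBetween <- nf * (muF - mu)^2 + nm * (muM - mu)^2
    ssWithin <- pmax(ssTot - ssBetween, 0)
    tested <- !is.na(ssTot) & ssTot > 0
    fStat <- rep(NA_real_, nrow(beta))
    p <- rep(NA_real_, nrow(beta))
    fStat[tested] <- (ssBetween[tested] / 1) /
        (ssWithin[tested] / (n - 2))
    p[tested] <- stats::pf(fStat[tested], 1, n - 2, lower.tail = FALSE)
    ## ssWithin == 0 with ssBetween > 0: infinite F, p = 0
    p[tested & ssWithin == 0] <- 0
    nTested <- sum(tested)
    thr <- alpha / max(nTested, 1L)
    significant <- tested & !is.na(p) & p < thr
    direction <- ifelse(muF > muM, "higher_in_females", "higher_in_males")
    out <- data.frame(
        probe = if (is.null(rownames(beta))) as.character(seq_len(nrow(beta)))
                else rownames(beta),
        meanFemale = muF, meanMale = muM, delta = muF - muM,
        fStat = fStat, pValue = p, tested = tested,
        significant = significant, direction = direction,
        row.names = NULL)
    attr(out, "alpha") <- alpha
    attr(out, "nTested") <- nTested
    attr(out, "bonferroniThreshold") <- thr
    attr(out, "nSignificant") <- sum(significant)
    attr(out, "directionCounts") <- table(direction[significant])
    out
}

#' Compare the saDMP sets of two EWAS runs
#'
#' Counts shared and run-specific Bonferroni-significant probes between two
#' [sexEWAS()] results over the same probe universe, and decomposes each
#' subset by direction (higher in females vs males).
#'
#' @param a,b data.frames returned by [sexEWAS()] on the same probes.
#' @return list with \code{nShared}, \code{nAOnly}, \code{nBOnly}, and
#'   \code{byDirection}, a data.frame with rows shared/a_only/b_only and
#'   columns \code{higher_in_females}, \code{higher_in_males}.
#' @export
compareSaDMPs <- function(a, b) {
    if (!setequal(a$probe, b$probe))
        stop("probe universes differ between the two EWAS results")
    b <- b[match(a$probe, b$probe), ]
    sigA <- a$probe[a$significant]
    sigB <- b$probe[b$significant]
    shared <- intersect(sigA, sigB)
    aOnly <- setdiff(sigA, sigB)
    bOnly <- setdiff(sigB, sigA)
    dirCount <- function(ids, src) {
        d <- src$direction[match(ids, src$probe)]
        c(higher_in_females = sum(d == "higher_in_females"),
          higher_in_males = sum(d == "higher_in_males"))
    }
    byDirection <- rbind(shared = dirCount(shared, a),
                         a_only = dirCount(aOnly, a),
                         b_only = dirCount(bOnly, b))
    list(nShared = length(shared), nAOnly = length(aOnly),
         nBOnly = length(bOnly),
         byDirection = as.data.frame(byDirection))
}
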