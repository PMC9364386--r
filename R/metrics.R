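## Quantitative yardsticks: RMSE, total variance (divisor n), and the
## sex-explained fraction of variance, per chromosome group.

#' Root mean squared error between two beta vectors
#'
#' \eqn{\sqrt{\frac{1}{m}\sum_i (\beta_i - \hat\beta_i)^2}} over the pairs
#' non-missing in both vectors; the number of dropped pairs is attached as
#' attribute \code{nDropped}.
#'
#' @param beta,betaRef equal-length numeric vectors.
#' @return non-negative scalar.
#' @examples
#' rmse(c(0.2, 0.4), c(0.1, 0.3))  # 0.1
#' @export
rmse <- function(beta, betaRef) {
    if (length(beta) != length(betaRef))
        stop("vectors must have equal length")
    ok <- !is.na(beta) & !is.na(betaRef)
    if (!any(ok)) stop("no overlapping non-missing pairs")
    out <- sqrt(mean((beta[ok] - betaRef[ok])^2))
    attr(out, "nDropped") <- sum(!ok)
    out
}

.perProbeVariance <- function(beta) {
    ## population-style (divisor n) variance per probe over non-missing
    ## samples; probes with < 2 non-missing samples get NA
    n <- rowSums(!is.na(beta))
    mu <- rowMeans(beta, na.rm = TRUE)
    ss <- rowSums((beta - mu)^2, na.rm = TRUE)
    v <- ss / n
    v[n < 2L] <- NA_real_
    v
}

#' Total variance of a beta matrix
#'
#' Per-probe population variance (divisor n, using the per-probe number of
#' non-missing samples) averaged over probes:
#' \eqn{V_{total} = \frac{1}{n}\frac{1}{m}\sum_i\sum_j
#' (\beta_{ij} - \bar\beta_j)^2}. Probes with fewer than 2 non-missing
#' samples are dropped (count in attribute \code{nDroppedProbes}).
#'
#' @param beta numeric matrix, probes x samples, >= 2 samples.
#' @return non-negative scalar.
#' @export
totalVariance <- function(beta) {
    beta <- as.matrix(beta)
    if (ncol(beta) < 2L) stop("need >= 2 samples")
    v <- .perProbeVariance(beta)
    keep <- !is.na(v)
    if (!any(keep)) stop("no probe with >= 2 non-missing samples")
    out <- mean(v[keep])
    attr(out, "nDroppedProbes") <- sum(!keep)
    out
}

#' Sex-explained fraction of variance
#'
#' \eqn{F_{sex} = V_{sex}/V_{total} = 1 - \frac{n_f V_{total,f} +
#' n_m V_{total,m}}{(n_f + n_m) V_{total}}}, where the within-sex total
#' variances use within-sex probe means. With divisor-n variances this is
#' exactly the between-sex fraction of the total sum of squares, so it lies
#' in [0, 1]. Probes lacking >= 2 non-missing samples in either sex group
#' are excluded from all terms (count reported).
#'
#' @param beta numeric matrix, probes x samples.
#' @param sex character vector ("female"/"male") of length \code{ncol(beta)}.
#' @return list with \code{fSex}, \code{vTotal}, \code{vTotalFemales},
#'   \code{vTotalMales}, \code{nFemales}, \code{nMales}, \code{nProbes},
#'   \code{nDroppedProbes}, and \code{perCpGVariance} (list of per-sex
#'   per-probe variance vectors, for boxplot-style summaries).
#' @examples
#' b <- matrix(c(0.2, 0.4, 0.6, 0.8), 1)
#' sexExplainedFraction(b, c("female", "female", "male", "male"))$fSex  # 0.8
#' @export
sexExplainedFraction <- function(beta, sex) {
    beta <- as.matrix(beta)
    stopifnot(length(sex) == ncol(beta))
    fIdx <- which(sex == "female")
    mIdx <- which(sex == "male")
    if (length(fIdx) < 2L || length(mIdx) < 2L)
        stop("need >= 2 samples of each sex (single-sex data: use totalVariance)")
    vF <- .perProbeVariance(beta[, fIdx, drop = FALSE])
    vM <- .perProbeVariance(beta[, mIdx, drop = FALSE])
    keep <- !is.na(vF) & !is.na(vM)
    if (!any(keep)) stop("no probe usable in both sex groups")
    b <- beta[keep, c(fIdx, mIdx), drop = FALSE]
    vTot <- .perProbeVariance(b)
    vTotal <- mean(vTot)
    if (vTotal <= 0)
        stop("total variance is zero; sex-explained fraction undefined")
    nf <- length(fIdx)
    nm <- length(mIdx)
    vTotalF <- mean(vF[keep])
    vTotalM <- mean(vM[keep])
    fSex <- 1 - (nf * vTotalF + nm * vTotalM) / ((nf + nm) * vTotal)
    list(fSex = fSex, vTotal = vTotal,
         vTotalFemales = vTotalF, vTotalMales = vTotalM,
         nFemales = nf, nMales = nm,
         nProbes = sum(keep), nDroppedProbes = sum(!keep),
         perCpGVariance = list(female = vF[keep], male = vM[keep]))
}

#' Per-chromosome-group variance report
#'
#' Computes [totalVariance()] and [sexExplainedFraction()] within each
#' chromosome group (autosomes, X, Y); empty groups are omitted with a
#' warning. The per-sex per-CpG variance vectors behind each row are
#' attached as attribute \code{perCpGVariance}.
#'
#' @param beta numeric matrix (probes x samples) or a
#'   [MethylNormResult-class].
#' @param annotation data.frame as from [readAnnotation()], or NULL when
#'   \code{beta} is a result object carrying its own annotation.
#' @param sex per-sample sex labels, or NULL to take them from the result
#'   object.
#' @return data.frame with one row per group: \code{group}, \code{nProbes},
#'   \code{nFemales}, \code{nMales}, \code{vTotal}, \code{vTotalFemales},
#'   \code{vTotalMales}, \code{fSex}.
#' @export
varianceReport <- function(beta, annotation = NULL, sex = NULL) {
    if (methods::is(beta, "MethylNormResult")) {
        if (is.null(sex)) sex <- sampleSex(beta)
        grp <- chromosomeGroup(beta)
        beta <- betaValues(beta)
    } else {
        if (is.null(annotation))
            stop("annotation required when beta is a bare matrix")
        ann <- .normalizeAnnotation(annotation)
        missing <- setdiff(rownames(beta), rownames(ann))
        if (length(missing))
            stop("annotation missing probes: ", .headIds(missing))
        chr <- as.character(ann[rownames(beta), "chromosome"])
        grp <- factor(ifelse(chr == "X", "X",
                             ifelse(chr == "Y", "Y", "autosome")),
                      levels = c("autosome", "X", "Y"))
    }
    if (is.null(sex)) stop("per-sample sex labels are required")
    rows <- list()
    perCpG <- list()
    for (g in levels(grp)) {
        sel <- grp == g
        if (!any(sel)) {
            warning("no probes in group ", g, "; omitted")
            next
        }
        res <- sexExplainedFraction(beta[sel, , drop = FALSE], sex)
        label <- if (g == "autosome") "autosomes" else g
        rows[[label]] <- data.frame(
            group = label, nProbes = res$nProbes,
            nFemales = res$nFemales, nMales = res$nMales,
            vTotal = res$vTotal, vTotalFemales = res$vTotalFemales,
            vTotalMales = res$vTotalMales, fSex = res$fSex)
        perCpG[[label]] <- res$perCpGVariance
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "perCpGVariance") <- perCpG
    out
}
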