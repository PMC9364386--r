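## Seeded generator of synthetic Infinium-style intensity datasets with the
## structure the normalizer must face: bimodal autosomal betas, intermediate
## female-X betas (X inactivation), male-only Y signal with female-Y
## background, per-sample per-channel technical factors and a type I
## intensity shift. Ground truth (pre-technical betas) is retained.

#' Simulation configuration
#'
#' Builds and validates the parameter list for [simulateDataset()]. The
#' defaults emulate a desk-scale 450k-like design: 50k autosomal probes with
#' 1.2k X and 120 Y probes (~2.6% sex-probe share, matching the array's
#' few-percent share), 72% type II probes, log-normal total intensity with
#' median 5000, three-component bimodal autosomal beta mixture, intermediate
#' female-X betas (mean 0.45, concentration 20) from X inactivation, male
#' X/Y betas bimodal like autosomes, female-Y total intensity at 5% of the
#' autosomal scale (background/non-specific hybridization), per-sample
#' per-channel log-normal technical factors (sdlog 0.15) and a +500 additive
#' type I intensity shift.
#'
#' @param nFemale,nMale sample counts.
#' @param nAuto,nX,nY probe counts per chromosome group.
#' @param typeIIFraction fraction of probes that are Infinium type II.
#' @param autoMixWeights,autoMixMeans,autoMixConc weights, means and
#'   concentrations of the Beta-mixture for autosomal (and male X/Y) base
#'   betas; weights must sum to 1.
#' @param femaleXMean,femaleXConc Beta parameters of female X base betas.
#' @param maleXMixWeights,maleXMixMeans,maleXMixConc Beta-mixture for male X
#'   (and male Y) base betas: dominated by a low-methylation component,
#'   since the single active X is largely unmethylated at array CpGs.
#' @param maleXIntensityFactor,maleYIntensityFactor total-intensity scale of
#'   male X and male Y cells (0.5 by default: one copy instead of two).
#' @param femaleYShape1,femaleYShape2 Beta parameters of the (meaningless)
#'   female Y betas.
#' @param femaleYScale female-Y total-intensity scale relative to autosomal.
#' @param bioNoiseSd per-sample logit-normal jitter sd on true betas.
#' @param intensityMedian,intensitySdLog log-normal total-intensity model.
#' @param backgroundIntensity additive per-channel background level
#'   (non-specific hybridization); observed signal never drops below it on
#'   average, which anchors the low-intensity density mode.
#' @param techSdMeth,techSdUnmeth sdlog of the per-sample multiplicative
#'   technical factor, per channel.
#' @param typeIShift additive intensity shift applied to type I probes.
#' @param noiseSd additive Gaussian intensity noise sd (floored at 0).
#' @param nSexEffectAuto number of autosomal probes with a true sex effect.
#' @param deltaBeta true effect size (female minus male) at those probes.
#' @param seed integer seed; all randomness flows from it.
#' @return validated list of class \code{SimConfig}.
#' @export
simConfig <- function(nFemale = 10L, nMale = 10L,
                      nAuto = 50000L, nX = 1200L, nY = 120L,
                      typeIIFraction = 0.72,
                      autoMixWeights = c(0.45, 0.10, 0.45),
                      autoMixMeans = c(0.08, 0.50, 0.88),
                      autoMixConc = c(25, 8, 25),
                      femaleXMean = 0.45, femaleXConc = 20,
                      maleXMixWeights = c(0.80, 0.20),
                      maleXMixMeans = c(0.08, 0.80),
                      maleXMixConc = c(25, 15),
                      maleXIntensityFactor = 0.5,
                      maleYIntensityFactor = 0.5,
                      femaleYShape1 = 1.5, femaleYShape2 = 6,
                      femaleYScale = 0.05,
                      bioNoiseSd = 0.1,
                      intensityMedian = 5000, intensitySdLog = 0.5,
                      backgroundIntensity = 300,
                      techSdMeth = 0.15, techSdUnmeth = 0.15,
                      typeIShift = 500,
                      noiseSd = 50,
                      nSexEffectAuto = 0L, deltaBeta = 0.2,
                      seed = 1L) {
    cfg <- list(nFemale = as.integer(nFemale), nMale = as.integer(nMale),
                nAuto = as.integer(nAuto), nX = as.integer(nX),
                nY = as.integer(nY),
                typeIIFraction = typeIIFraction,
                autoMixWeights = autoMixWeights,
                autoMixMeans = autoMixMeans, autoMixConc = autoMixConc,
                femaleXMean = femaleXMean, femaleXConc = femaleXConc,
                maleXMixWeights = maleXMixWeights,
                maleXMixMeans = maleXMixMeans,
                maleXMixConc = maleXMixConc,
                maleXIntensityFactor = maleXIntensityFactor,
                maleYIntensityFactor = maleYIntensityFactor,
                femaleYShape1 = femaleYShape1,
                femaleYShape2 = femaleYShape2,
                femaleYScale = femaleYScale,
                bioNoiseSd = bioNoiseSd,
                intensityMedian = intensityMedian,
                intensitySdLog = intensitySdLog,
                backgroundIntensity = backgroundIntensity,
                techSdMeth = techSdMeth, techSdUnmeth = techSdUnmeth,
                typeIShift = typeIShift, noiseSd = noiseSd,
                nSexEffectAuto = as.integer(nSexEffectAuto),
                deltaBeta = deltaBeta, seed = as.integer(seed))
    bad <- character(0)
    counts <- c("nFemale", "nMale", "nAuto", "nX", "nY", "nSexEffectAuto")
    for (f in counts) if (is.na(cfg[[f]]) || cfg[[f]] < 0L) bad <- c(bad, f)
    if (abs(sum(cfg$autoMixWeights) - 1) > 1e-8) bad <- c(bad, "autoMixWeights")
    if (abs(sum(cfg$maleXMixWeights) - 1) > 1e-8) bad <- c(bad, "maleXMixWeights")
    if (cfg$maleXIntensityFactor < 0 || cfg$maleYIntensityFactor < 0)
        bad <- c(bad, "maleXIntensityFactor/maleYIntensityFactor")
    if (length(cfg$autoMixMeans) != length(cfg$autoMixWeights) ||
        length(cfg$autoMixConc) != length(cfg$autoMixWeights))
        bad <- c(bad, "autoMixMeans/autoMixConc")
    if (cfg$typeIIFraction < 0 || cfg$typeIIFraction > 1)
        bad <- c(bad, "typeIIFraction")
    if (abs(cfg$deltaBeta) >= 1) bad <- c(bad, "deltaBeta")
    if (cfg$nSexEffectAuto > cfg$nAuto) bad <- c(bad, "nSexEffectAuto")
    for (f in c("femaleYScale", "bioNoiseSd", "intensityMedian",
                "intensitySdLog", "backgroundIntensity", "techSdMeth",
                "techSdUnmeth", "noiseSd"))
        if (cfg[[f]] < 0) bad <- c(bad, f)
    if (length(bad))
        stop("invalid simulation config field(s): ",
             paste(unique(bad), collapse = ", "))
    structure(cfg, class = "SimConfig")
}

.rmixbeta <- function(n, weights, means, conc) {
    comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
    stats::rbeta(n, means[comp] * conc[comp], (1 - means[comp]) * conc[comp])
}

.clampBeta <- function(b) pmin(pmax(b, 1e-6), 1 - 1e-6)

#' Simulate a synthetic methylation intensity dataset
#'
#' Generative model: each probe draws a base beta from its group- and
#' sex-appropriate distribution (autosomal probes share a base beta across
#' sexes; the designated sex-effect probes add +/- deltaBeta/2 by sex; X
#' and Y probes have sex-specific bases). Per sample, the true beta is the
#' base plus logit-normal biological jitter. Total intensity per cell is
#' log-normal, shifted additively for type I probes and scaled down to
#' background level for female Y cells; channels are M = beta * T * fM and
#' U = (1 - beta) * T * fU with per-sample per-channel technical factors
#' fM, fU, plus additive Gaussian noise, floored at 0. The same seed gives
#' bit-identical output.
#'
#' @param cfg a [simConfig()] object.
#' @return list of class \code{SimulatedMethylData}: \code{data}
#'   (a [MethylIntensitySet-class] with annotation and sample sheet),
#'   \code{trueBeta} (probes x samples, pre-technical), \code{annotation}
#'   and \code{sampleSheet} data.frames, \code{technicalFactors}
#'   (per sample: \code{fMeth}, \code{fUnmeth}), \code{sexEffectProbes},
#'   and \code{config}.
#' @export
simulateDataset <- function(cfg = simConfig()) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed)
    nS <- cfg$nFemale + cfg$nMale
    nP <- cfg$nAuto + cfg$nX + cfg$nY
    if (nS == 0L || nP == 0L) stop("empty design: no samples or no probes")
    sampleIds <- sprintf("s%03d", seq_len(nS))
    sex <- c(rep("female", cfg$nFemale), rep("male", cfg$nMale))
    probeIds <- sprintf("cg%07d", seq_len(nP))
    chromosome <- c(as.character(sample.int(22L, cfg$nAuto, replace = TRUE)),
                    rep("X", cfg$nX), rep("Y", cfg$nY))
    group <- c(rep("autosome", cfg$nAuto), rep("X", cfg$nX),
               rep("Y", cfg$nY))
    design <- ifelse(stats::runif(nP) < cfg$typeIIFraction, "II", "I")
    chipRowVals <- sample.int(6L, nS, replace = TRUE)

    ## base betas: columns female / male
    baseF <- baseM <- numeric(nP)
    auto <- .rmixbeta(cfg$nAuto, cfg$autoMixWeights, cfg$autoMixMeans,
                      cfg$autoMixConc)
    baseF[group == "autosome"] <- auto
    baseM[group == "autosome"] <- auto
    effectProbes <- character(0)
    if (cfg$nSexEffectAuto > 0L) {
        idx <- sample.int(cfg$nAuto, cfg$nSexEffectAuto)
        baseF[idx] <- baseF[idx] + cfg$deltaBeta / 2
        baseM[idx] <- baseM[idx] - cfg$deltaBeta / 2
        effectProbes <- probeIds[idx]
    }
    baseF[group == "X"] <- stats::rbeta(cfg$nX,
        cfg$femaleXMean * cfg$femaleXConc,
        (1 - cfg$femaleXMean) * cfg$femaleXConc)
    baseM[group == "X"] <- .rmixbeta(cfg$nX, cfg$maleXMixWeights,
                                     cfg$maleXMixMeans, cfg$maleXMixConc)
    baseF[group == "Y"] <- stats::rbeta(cfg$nY, cfg$femaleYShape1,
                                        cfg$femaleYShape2)
    baseM[group == "Y"] <- .rmixbeta(cfg$nY, cfg$maleXMixWeights,
                                     cfg$maleXMixMeans, cfg$maleXMixConc)
    baseF <- .clampBeta(baseF)
    baseM <- .clampBeta(baseM)

    base <- matrix(0, nP, nS)
    base[, sex == "female"] <- baseF
    base[, sex == "male"] <- baseM
    jitter <- matrix(stats::rnorm(nP * nS, 0, cfg$bioNoiseSd), nP, nS)
    trueBeta <- .clampBeta(stats::plogis(stats::qlogis(base) + jitter))
    dimnames(trueBeta) <- list(probeIds, sampleIds)

    totalI <- matrix(stats::rlnorm(nP * nS, log(cfg$intensityMedian),
                                   cfg$intensitySdLog), nP, nS)
    totalI[design == "I", ] <- totalI[design == "I", ] + cfg$typeIShift
    if (cfg$nY > 0L && cfg$nFemale > 0L)
        totalI[group == "Y", sex == "female"] <-
            totalI[group == "Y", sex == "female"] * cfg$femaleYScale
    ## copy-number dosage: one X and one Y in males
    if (cfg$nX > 0L && cfg$nMale > 0L)
        totalI[group == "X", sex == "male"] <-
            totalI[group == "X", sex == "male"] * cfg$maleXIntensityFactor
    if (cfg$nY > 0L && cfg$nMale > 0L)
        totalI[group == "Y", sex == "male"] <-
            totalI[group == "Y", sex == "male"] * cfg$maleYIntensityFactor
    fMeth <- stats::rlnorm(nS, 0, cfg$techSdMeth)
    fUnmeth <- stats::rlnorm(nS, 0, cfg$techSdUnmeth)
    meth <- trueBeta * totalI
    unmeth <- (1 - trueBeta) * totalI
    meth <- sweep(meth, 2L, fMeth, "*") + cfg$backgroundIntensity
    unmeth <- sweep(unmeth, 2L, fUnmeth, "*") + cfg$backgroundIntensity
    if (cfg$noiseSd > 0) {
        meth <- meth + matrix(stats::rnorm(nP * nS, 0, cfg$noiseSd), nP, nS)
        unmeth <- unmeth + matrix(stats::rnorm(nP * nS, 0, cfg$noiseSd),
                                  nP, nS)
    }
    meth <- pmax(meth, 0)
    unmeth <- pmax(unmeth, 0)
    dimnames(meth) <- dimnames(unmeth) <- list(probeIds, sampleIds)

    annotation <- data.frame(probe_id = probeIds, chromosome = chromosome,
                             design_type = design)
    sheet <- data.frame(sample_id = sampleIds, sex = sex,
                        chip_row = chipRowVals)
    mset <- MethylIntensitySet(meth, unmeth, annotation, sheet)
    structure(list(data = mset, trueBeta = trueBeta,
                   annotation = annotation, sampleSheet = sheet,
                   technicalFactors = data.frame(
                       sample_id = sampleIds, fMeth = fMeth,
                       fUnmeth = fUnmeth),
                   sexEffectProbes = effectProbes,
                   config = cfg),
              class = "SimulatedMethylData")
}

#' @export
print.SimulatedMethylData <- function(x, ...) {
    cat("SimulatedMethylData (seed ", x$config$seed, ")\n", sep = "")
    show(x$data)
    if (length(x$sexEffectProbes))
        cat("  true autosomal sex effect at", length(x$sexEffectProbes),
            "probes (deltaBeta =", x$config$deltaBeta, ")\n")
    invisible(x)
}

#' Split a simulated dataset into single-sex subsets
#'
#' Column subsets by sex with all components (intensities, true betas,
#' technical factors, sheet) kept consistent; a subset for an absent sex is
#' returned as \code{NULL} with a warning.
#'
#' @param sim a [simulateDataset()] result.
#' @return named list with elements \code{female} and \code{male}.
#' @export
makeSingleSexSubsets <- function(sim) {
    stopifnot(inherits(sim, "SimulatedMethylData"))
    out <- list()
    for (s in c("female", "male")) {
        keep <- sim$sampleSheet$sex == s
        if (!any(keep)) {
            warning("no ", s, " samples; subset empty")
            out[[s]] <- NULL
            next
        }
        ids <- sim$sampleSheet$sample_id[keep]
        out[[s]] <- structure(list(
            data = sim$data[, ids],
            trueBeta = sim$trueBeta[, ids, drop = FALSE],
            annotation = sim$annotation,
            sampleSheet = sim$sampleSheet[keep, , drop = FALSE],
            technicalFactors = sim$technicalFactors[keep, , drop = FALSE],
            sexEffectProbes = sim$sexEffectProbes,
            config = sim$config), class = "SimulatedMethylData")
    }
    out
}
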