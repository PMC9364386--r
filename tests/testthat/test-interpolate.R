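test_that("rank estimation interpolates, ties average, extremes clamp", {
    r <- estimateRanks(c(10, 20, 30), c(20, 15, 5, 35))
    expect_equal(r$rank, c(2.0, 1.5, 1.0, 3.0))
    expect_identical(r$clampedLow, c(FALSE, FALSE, TRUE, FALSE))
    expect_identical(r$clampedHigh, c(FALSE, FALSE, FALSE, TRUE))
    # tied autosomal values share their average rank
    expect_equal(estimateRanks(c(10, 20, 20, 30), 20)$rank, 2.5)
    # missing queries give missing ranks, not errors
    expect_equal(estimateRanks(c(1, 2), c(NA, 1.5))$rank, c(NA, 1.5))
    expect_error(estimateRanks(c(1, NA), 1), ">= 2")
})

test_that("quantile function interpolates sorted corrected values", {
    F <- buildQuantileFunction(c(200, 100))
    expect_equal(F(1.5), 150)
    expect_equal(F(c(1, 2)), c(100, 200))
    F3 <- buildQuantileFunction(c(0, 10, 40))
    expect_equal(F3(2.25), 17.5)
    expect_error(buildQuantileFunction(3), ">= 2")
})

test_that("sex-value interpolation composes rank and quantile maps", {
    expect_equal(interpolateSexValues(c(10, 20), c(100, 200), 15), 150)
    # coincidence: query equal to a uniquely-ranked autosomal raw value
    # returns exactly that probe's corrected value
    raw <- c(3, 1, 7, 5)
    corr <- raw^2 + 1   # any monotone correction
    expect_identical(interpolateSexValues(raw, corr, raw), corr)
    # clamping to the corrected range
    expect_equal(interpolateSexValues(c(10, 20), c(100, 200), c(0, 99)),
                 c(100, 200))
    expect_error(interpolateSexValues(1:3, 1:2, 1), "equal length")
})

test_that("interpolation is monotone and range-contained on random instances", {
    set.seed(21)
    for (i in 1:100) {
        nA <- sample(5:60, 1)
        rawA <- rnorm(nA, 0, 10)
        corrA <- sort(rnorm(nA))[rank(rawA)]   # monotone in rawA
        rawS <- rnorm(20, 0, 15)
        out <- interpolateSexValues(rawA, corrA, rawS)
        ord <- order(rawS)
        expect_true(all(diff(out[ord]) >= -1e-12))
        expect_true(all(out >= min(corrA) & out <= max(corrA)))
    }
})

test_that("adjusted normalization: step-one contract and sex-blindness", {
    x <- toyIntensitySet(nAuto = 400, nX = 20, nY = 8, nSamples = 4,
                         seed = 31, sex = c("female", "male"))
    adj <- adjustedNormalize(x, "dasen", minAutosomal = 50,
                             minTypeProbes = 10)
    auto <- chromosomeGroup(x) == "autosome"
    step1 <- dasenNormalize(x, "autosomes_only", minTypeProbes = 10)
    expect_identical(meth(adj)[auto, ], meth(step1))
    expect_identical(unmeth(adj)[auto, ], unmeth(step1))
    expect_setequal(interpolatedProbes(adj), rownames(x)[!auto])

    # permuting the sexes leaves the output bit-identical
    x2 <- x
    SummarizedExperiment::colData(x2)$sex <-
        rev(SummarizedExperiment::colData(x)$sex)
    adj2 <- adjustedNormalize(x2, "dasen", minAutosomal = 50,
                              minTypeProbes = 10)
    expect_identical(betaValues(adj2), betaValues(adj))

    # stratum floor is enforced with actionable advice
    expect_error(adjustedNormalize(x, "dasen", minAutosomal = 1000),
                 "autosomal probes")
})

test_that("sex probes never influence autosomal output (and do under mixed)", {
    x <- toyIntensitySet(nAuto = 400, nX = 20, nY = 8, nSamples = 4,
                         seed = 32)
    auto <- chromosomeGroup(x) == "autosome"
    # replace all sex-probe intensities by arbitrary values
    m2 <- meth(x); u2 <- unmeth(x)
    set.seed(1)
    m2[!auto, ] <- rlnorm(sum(!auto) * ncol(x), 9, 1)
    u2[!auto, ] <- rlnorm(sum(!auto) * ncol(x), 9, 1)
    ann <- data.frame(probe_id = rownames(x),
                      chromosome = as.character(
                          SummarizedExperiment::rowData(x)$chromosome),
                      design_type = designType(x))
    xAlt <- MethylIntensitySet(m2, u2, ann)

    adj <- adjustedNormalize(x, "dasen", minAutosomal = 50,
                             minTypeProbes = 10)
    adjAlt <- adjustedNormalize(xAlt, "dasen", minAutosomal = 50,
                                minTypeProbes = 10)
    expect_identical(meth(adj)[auto, ], meth(adjAlt)[auto, ])
    expect_identical(betaValues(adj)[auto, ], betaValues(adjAlt)[auto, ])

    # the mixed normalizer leaks sex-probe values into autosomes
    mix <- dasenNormalize(x, "all", minTypeProbes = 10)
    mixAlt <- dasenNormalize(xAlt, "all", minTypeProbes = 10)
    expect_gt(max(abs(betaValues(mix)[auto, ] -
                      betaValues(mixAlt)[auto, ])), 0)
})

test_that("full-pipeline coincidence: duplicated sex probes reproduce autosomal betas", {
    x <- toyIntensitySet(nAuto = 300, nX = 0, nY = 0, nSamples = 3,
                         seed = 33)
    # craft sex probes that duplicate the raw M and U of autosomal probes
    # of the same design type
    dt <- designType(x)
    pickI <- which(dt == "I")[1:5]
    pickII <- which(dt == "II")[1:5]
    sexIds <- sprintf("sex%02d", 1:10)
    m <- rbind(meth(x), meth(x)[c(pickI, pickII), ])
    u <- rbind(unmeth(x), unmeth(x)[c(pickI, pickII), ])
    rownames(m) <- rownames(u) <- c(rownames(x), sexIds)
    ann <- data.frame(
        probe_id = rownames(m),
        chromosome = c(as.character(
            SummarizedExperiment::rowData(x)$chromosome),
            rep(c("X", "Y"), 5)),
        design_type = c(dt, dt[c(pickI, pickII)]))
    x2 <- MethylIntensitySet(m, u, ann)
    adj <- adjustedNormalize(x2, "dasen", minAutosomal = 50,
                             minTypeProbes = 10)
    b <- betaValues(adj)
    expect_equal(b[sexIds, ], b[rownames(x)[c(pickI, pickII)], ],
                 ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("plugin normalizers slot into step one per stratum", {
    x <- toyIntensitySet(nAuto = 200, nX = 10, nY = 4, nSamples = 3,
                         seed = 34)
    # identity plugin: corrected = raw, so interpolation must return values
    # inside the raw autosomal range of each stratum
    adj <- adjustedNormalize(x, "plugin", plugin = function(m) m,
                             minAutosomal = 50)
    auto <- chromosomeGroup(x) == "autosome"
    expect_identical(meth(adj)[auto, ], meth(x)[auto, ])
    dt <- designType(x)
    for (ty in c("I", "II")) {
        sel <- !auto & dt == ty
        aSel <- auto & dt == ty
        for (j in seq_len(ncol(x))) {
            expect_true(all(meth(adj)[sel, j] >= min(meth(x)[aSel, j]) &
                            meth(adj)[sel, j] <= max(meth(x)[aSel, j])))
        }
    }
    expect_error(adjustedNormalize(x, "plugin", minAutosomal = 50),
                 "plugin")
})
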