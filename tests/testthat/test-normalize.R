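test_that("beta formula matches the offset-100 definition", {
    ids <- c("cg1", "cg2", "cg3")
    m <- matrix(c(0, 100, 900), 3, 1, dimnames = list(ids, "s1"))
    u <- matrix(0, 3, 1, dimnames = dimnames(m))
    ann <- data.frame(probe_id = ids, chromosome = "1", design_type = "II")
    x <- MethylIntensitySet(m, u, ann)
    expect_equal(as.vector(computeBeta(x)), c(0, 0.5, 0.9))
    expect_error(computeBeta(x, offset = -1), "non-negative")
    # offset 0 with M = U = 0 is undefined -> missing
    expect_true(is.na(computeBeta(x, offset = 0)[1, 1]))
    # missing channel propagates
    m[2, 1] <- NA
    x2 <- MethylIntensitySet(m, u, ann)
    expect_true(is.na(computeBeta(x2)[2, 1]))
})

test_that("quantile normalization maps columns onto per-rank means", {
    m <- cbind(a = c(1, 2, 3), b = c(3, 4, 5))
    expect_equal(quantileNormalize(m),
                 cbind(a = c(2, 3, 4), b = c(2, 3, 4)))
    # identical columns are a fixed point
    m2 <- cbind(c(1, 2, 3), c(1, 2, 3))
    expect_equal(quantileNormalize(m2), m2)
    # ties share the mean of the reference values they span
    expect_equal(as.vector(quantileNormalize(matrix(c(5, 5), 2, 1),
                                             reference = c(10, 20))),
                 c(15, 15))
    expect_error(
        quantileNormalize(cbind(bad = c(NA, NA), ok = c(1, 2)),
                          reference = c(1, 2)),
        "all values missing: bad")
    # no complete rows and no reference is unrecoverable
    expect_error(quantileNormalize(cbind(c(NA, 1), c(2, NA))),
                 "complete")
})

test_that("quantile normalization is idempotent, rank- and mean-preserving", {
    set.seed(7)
    for (i in 1:5) {
        m <- matrix(rlnorm(1000 * 6, 8, 0.5), 1000, 6)
        q1 <- quantileNormalize(m)
        # sorted columns identical across samples
        sorted <- apply(q1, 2, sort)
        expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
        # idempotence
        expect_lt(max(abs(quantileNormalize(q1) - q1)), 1e-12)
        # rank preservation within each sample
        for (j in seq_len(ncol(m)))
            expect_identical(order(q1[, j]), order(m[, j]))
        # grand mean preserved
        expect_lt(abs(mean(q1) - mean(m)), 1e-9)
    }
})

test_that("quantile normalization agrees with limma on complete data", {
    skip_if_not_installed("limma")
    set.seed(11)
    m <- matrix(rlnorm(500 * 5, 8, 0.7), 500, 5)
    expect_equal(quantileNormalize(m),
                 limma::normalizeQuantiles(m, ties = TRUE),
                 tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("type I/II alignment recovers a pure shift and honours chip rows", {
    set.seed(3)
    n <- 4000
    design <- rep(c("I", "II"), each = n / 2)
    base <- rlnorm(n / 2, log(2000), 0.4)
    # identically distributed types: offsets ~ 0
    m0 <- matrix(c(base, base), n, 3) * matrix(rlnorm(n * 3, 0, 0.02), n, 3)
    a0 <- alignTypeDistributions(m0, design)
    shift0 <- abs(mean(a0[design == "I", 1] - m0[design == "I", 1]))
    expect_lt(shift0, 0.01 * diff(range(m0)))

    # type I shifted by +500: recovered offset ~ -500 (within 5%)
    m1 <- m0
    m1[design == "I", ] <- m1[design == "I", ] + 500
    a1 <- alignTypeDistributions(m1, design)
    off <- mean(a1[design == "I", 1] - m1[design == "I", 1])
    expect_lt(abs(off + 500), 25)

    # offsets exactly linear in chip row: regression is a fixed point
    chipRow <- c(1L, 2L, 3L)
    a2 <- alignTypeDistributions(m1, design, chipRow = chipRow)
    offs <- colMeans(a2[design == "I", ] - m1[design == "I", ])
    fit <- lm(offs ~ chipRow)
    expect_lt(max(abs(fitted(fit) - offs)), 1e-6)

    expect_error(alignTypeDistributions(m0[1:60, ], design[1:60]),
                 "fewer than 50")
})

test_that("dasen fixes identical samples up to type alignment and equalizes distributions", {
    x <- toyIntensitySet(nAuto = 300, nX = 12, nY = 6, nSamples = 2,
                         seed = 9)
    # duplicate one sample: QN of identical columns is the identity,
    # so any change comes from the type I alignment offset alone
    m <- meth(x)[, c(1, 1)]
    u <- unmeth(x)[, c(1, 1)]
    colnames(m) <- colnames(u) <- c("s1", "s2")
    ann <- data.frame(probe_id = rownames(m),
                      chromosome = as.character(
                          SummarizedExperiment::rowData(x)$chromosome),
                      design_type = designType(x))
    dup <- MethylIntensitySet(m, u, ann)
    res <- dasenNormalize(dup, probeScope = "all", minTypeProbes = 10)
    isII <- designType(dup) == "II"
    expect_equal(meth(res)[isII, ], m[isII, ], tolerance = 1e-12)

    # after dasen, sorted corrected values identical across samples per type
    x6 <- toyIntensitySet(nAuto = 400, nX = 12, nY = 6, nSamples = 6,
                          seed = 10)
    r6 <- dasenNormalize(x6, "all", minTypeProbes = 10)
    for (ty in c("I", "II")) {
        s <- apply(meth(r6)[designType(x6) == ty, ], 2, sort)
        expect_lt(max(abs(s - s[, 1])), 1e-9)
    }
    # betas recomputed from corrected intensities with the offset
    expect_equal(betaValues(r6),
                 meth(r6) / (meth(r6) + unmeth(r6) + 100))
})

test_that("autosomes-only dasen equals dasen on a sex-probe-free input", {
    x <- toyIntensitySet(nAuto = 300, nX = 15, nY = 5, nSamples = 4,
                         seed = 12)
    a <- dasenNormalize(x, "autosomes_only", minTypeProbes = 10)
    deleted <- x[chromosomeGroup(x) == "autosome", ]
    b <- dasenNormalize(deleted, "all", minTypeProbes = 10)
    expect_identical(meth(a), meth(b))
    expect_identical(unmeth(a), unmeth(b))
    expect_identical(betaValues(a), betaValues(b))
    # scope contract: sex probes absent from the result
    expect_false(any(chromosomeGroup(a) != "autosome"))
})
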