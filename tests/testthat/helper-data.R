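# Small in-code fixtures shared across test files.

# A deterministic toy MethylIntensitySet: nAuto autosomal + nX X + nY Y
# probes, both design types, lognormal-ish intensities.
toyIntensitySet <- function(nAuto = 200, nX = 10, nY = 4, nSamples = 6,
                            seed = 42, sex = NULL) {
    set.seed(seed)
    nP <- nAuto + nX + nY
    ids <- sprintf("cg%05d", seq_len(nP))
    samples <- sprintf("s%02d", seq_len(nSamples))
    chrom <- c(sample(as.character(1:22), nAuto, replace = TRUE),
               rep("X", nX), rep("Y", nY))
    design <- rep_len(c("I", "II"), nP)
    meth <- matrix(rlnorm(nP * nSamples, log(3000), 0.6), nP, nSamples,
                   dimnames = list(ids, samples))
    unmeth <- matrix(rlnorm(nP * nSamples, log(3000), 0.6), nP, nSamples,
                     dimnames = list(ids, samples))
    ann <- data.frame(probe_id = ids, chromosome = chrom,
                      design_type = design)
    sheet <- NULL
    if (!is.null(sex))
        sheet <- data.frame(sample_id = samples,
                            sex = rep_len(sex, nSamples))
    MethylIntensitySet(meth, unmeth, ann, sheet)
}

writeValueTsv <- function(m, path) {
    interpXY::writeBetaTable(m, path)
    path
}
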