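#' @include AllGenerics.R
NULL

#' MethylIntensitySet: paired methylated/unmethylated intensities
#'
#' Container for raw (or corrected) Infinium array intensities. Extends
#' \linkS4class{SummarizedExperiment} with two mandatory assays, \code{meth}
#' (methylated channel, M) and \code{unmeth} (unmethylated channel, U), a
#' per-probe annotation in \code{rowData} (\code{chromosome} in
#' \code{c(1:22, "X", "Y")}, Infinium \code{designType} in \code{c("I","II")})
#' and optional per-sample metadata in \code{colData} (\code{sex} in
#' \code{c("female","male")}, integer \code{chipRow}).
#'
#' Intensities must be finite and non-negative; \code{NA} cells are allowed
#' and propagate as missing betas.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @aliases MethylIntensitySet-class
#' @seealso [MethylIntensitySet()] for construction from matrices,
#'   [readIntensityPair()] for construction from TSV files.
#' @export
setClass("MethylIntensitySet", contains = "SummarizedExperiment")

.CHROMOSOMES <- c(as.character(1:22), "X", "Y")

.validMethylIntensitySet <- function(object) {
    msg <- NULL
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("meth", "unmeth") %in% an))
        return("assays must include 'meth' and 'unmeth'")
    m <- SummarizedExperiment::assay(object, "meth")
    u <- SummarizedExperiment::assay(object, "unmeth")
    if (!identical(dim(m), dim(u)))
        msg <- c(msg, "'meth' and 'unmeth' must share dimensions")
    for (nm in c("meth", "unmeth")) {
        a <- SummarizedExperiment::assay(object, nm)
        if (any(a < 0, na.rm = TRUE))
            msg <- c(msg, sprintf("negative values in '%s' assay", nm))
        if (any(is.infinite(a)))
            msg <- c(msg, sprintf("non-finite values in '%s' assay", nm))
    }
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("chromosome", "designType") %in% colnames(rd)))
        return(c(msg, "rowData must carry 'chromosome' and 'designType'"))
    chr <- as.character(rd$chromosome)
    if (anyNA(chr) || !all(chr %in% .CHROMOSOMES))
        msg <- c(msg, "chromosome must be one of 1..22, X, Y (no NA)")
    dt <- as.character(rd$designType)
    if (anyNA(dt) || !all(dt %in% c("I", "II")))
        msg <- c(msg, "designType must be 'I' or 'II' (no NA)")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "probe ids (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    cd <- SummarizedExperiment::colData(object)
    if ("sex" %in% colnames(cd)) {
        sx <- as.character(cd$sex)
        if (!all(sx[!is.na(sx)] %in% c("female", "male")))
            msg <- c(msg, "sex must be 'female' or 'male'")
    }
    if (is.null(msg)) TRUE else msg
}

setValidity("MethylIntensitySet", .validMethylIntensitySet)

#' Construct a MethylIntensitySet
#'
#' Assembles aligned methylated/unmethylated matrices, a probe annotation and
#' an optional sample sheet into a validated [MethylIntensitySet-class].
#' Probes and samples are matched by name: the annotation must cover every
#' probe of the matrices and the sample sheet (when given) every sample.
#'
#' @param meth,unmeth numeric matrices (probes x samples) with identical
#'   dimnames; non-negative, \code{NA} allowed.
#' @param annotation a data.frame/DataFrame with columns \code{probe_id},
#'   \code{chromosome}, \code{design_type} (as returned by
#'   [readAnnotation()]), or with rownames as probe ids and columns
#'   \code{chromosome}, \code{designType}.
#' @param sampleSheet optional data.frame with columns \code{sample_id},
#'   \code{sex} and optionally \code{chip_row}.
#' @return A [MethylIntensitySet-class].
#' @examples
#' m <- matrix(1:6 * 100, 3, 2, dimnames = list(paste0("cg", 1:3), c("s1","s2")))
#' ann <- data.frame(probe_id = paste0("cg", 1:3),
#'                   chromosome = c("1", "X", "2"),
#'                   design_type = c("II", "II", "I"))
#' mset <- MethylIntensitySet(m, m + 50, ann)
#' chromosomeGroup(mset)
#' @export
MethylIntensitySet <- function(meth, unmeth, annotation, sampleSheet = NULL) {
    meth <- as.matrix(meth)
    unmeth <- as.matrix(unmeth)
    if (!identical(dimnames(meth), dimnames(unmeth)))
        stop("'meth' and 'unmeth' must have identical dimnames")
    ann <- .normalizeAnnotation(annotation)
    missing <- setdiff(rownames(meth), rownames(ann))
    if (length(missing))
        stop("annotation missing probes: ", .headIds(missing))
    ann <- ann[rownames(meth), , drop = FALSE]
    cd <- S4Vectors::DataFrame(row.names = colnames(meth))
    if (!is.null(sampleSheet)) {
        ss <- .normalizeSampleSheet(sampleSheet)
        missing <- setdiff(colnames(meth), rownames(ss))
        if (length(missing))
            stop("sample sheet missing samples: ", .headIds(missing))
        cd <- ss[colnames(meth), , drop = FALSE]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(meth = meth, unmeth = unmeth),
        rowData = ann, colData = cd)
    methods::new("MethylIntensitySet", se)
}

.normalizeAnnotation <- function(annotation) {
    a <- as.data.frame(annotation)
    if ("probe_id" %in% colnames(a)) {
        if (anyDuplicated(a$probe_id))
            stop("duplicate probe_id in annotation: ",
                 .headIds(unique(a$probe_id[duplicated(a$probe_id)])))
        rownames(a) <- a$probe_id
        a$probe_id <- NULL
    }
    if ("design_type" %in% colnames(a)) {
        a$designType <- a$design_type
        a$design_type <- NULL
    }
    if (!all(c("chromosome", "designType") %in% colnames(a)))
        stop("annotation needs columns chromosome and design_type")
    a$chromosome <- canonicalChromosome(as.character(a$chromosome))
    a$designType <- as.character(a$designType)
    S4Vectors::DataFrame(a[, c("chromosome", "designType"), drop = FALSE])
}

.normalizeSampleSheet <- function(sheet) {
    s <- as.data.frame(sheet)
    if ("sample_id" %in% colnames(s)) {
        if (anyDuplicated(s$sample_id))
            stop("duplicate sample_id in sample sheet")
        rownames(s) <- s$sample_id
        s$sample_id <- NULL
    }
    if ("chip_row" %in% colnames(s)) {
        s$chipRow <- as.integer(s$chip_row)
        s$chip_row <- NULL
    }
    if ("sex" %in% colnames(s)) s$sex <- as.character(s$sex)
    S4Vectors::DataFrame(s)
}

.headIds <- function(ids, n = 5) {
    out <- paste(utils::head(ids, n), collapse = ", ")
    if (length(ids) > n) out <- paste0(out, ", ... (", length(ids), " total)")
    out
}

#' Canonicalize chromosome labels
#'
#' Accepts both \code{"chrX"} and \code{"X"} dialects (and \code{"chr7"} /
#' \code{"7"}); returns bare labels. Unknown labels are returned unchanged so
#' the caller can reject or count them.
#'
#' @param x character vector of chromosome labels.
#' @return character vector of bare labels (\code{"1"}..\code{"22"},
#'   \code{"X"}, \code{"Y"} for recognized input).
#' @export
canonicalChromosome <- function(x) {
    x <- as.character(x)
    x <- sub("^chr", "", x, ignore.case = TRUE)
    toupper(x)
}

#' MethylNormResult: output of a between-array normalization
#'
#' A [MethylIntensitySet-class] whose \code{meth}/\code{unmeth} assays hold
#' corrected intensities, plus a \code{beta} assay recomputed from them with
#' the stored offset, the method identifier, the set of probes whose values
#' were obtained by rank interpolation (empty for non-adjusted methods) and
#' the normalization parameters.
#'
#' @slot methodId single string, e.g. \code{"adjusted-dasen"}.
#' @slot interpolatedProbes character vector of probe ids (always a subset of
#'   the sex-chromosome probes of the annotation).
#' @slot normParameters named list of parameters (always includes
#'   \code{offset}).
#' @aliases MethylNormResult-class
#' @export
setClass("MethylNormResult",
    contains = "MethylIntensitySet",
    slots = c(methodId = "character",
              interpolatedProbes = "character",
              normParameters = "list"))

.validMethylNormResult <- function(object) {
    msg <- NULL
    if (length(object@methodId) != 1L)
        msg <- c(msg, "methodId must be a single string")
    if (!"beta" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "missing 'beta' assay")
    else {
        b <- SummarizedExperiment::assay(object, "beta")
        if (any(b < 0 | b >= 1, na.rm = TRUE))
            msg <- c(msg, "beta values must lie in [0, 1)")
    }
    sexProbes <- rownames(object)[chromosomeGroup(object) != "autosome"]
    if (!all(object@interpolatedProbes %in% sexProbes))
        msg <- c(msg, "interpolatedProbes must be sex-chromosome probes")
    if (is.null(msg)) TRUE else msg
}

setValidity("MethylNormResult", .validMethylNormResult)

.newNormResult <- function(template, meth, unmeth, methodId,
                           interpolated = character(0),
                           parameters = list()) {
    offset <- if (is.null(parameters$offset)) 100 else parameters$offset
    beta <- .betaFromChannels(meth, unmeth, offset)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(meth = meth, unmeth = unmeth, beta = beta),
        rowData = SummarizedExperiment::rowData(template)[rownames(meth), ,
                                                          drop = FALSE],
        colData = SummarizedExperiment::colData(template))
    methods::new("MethylNormResult", methods::new("MethylIntensitySet", se),
                 methodId = methodId,
                 interpolatedProbes = interpolated,
                 normParameters = parameters)
}

## ---- accessors ----

#' @describeIn MethylIntensitySet methylated-channel matrix.
#' @param object a \code{MethylIntensitySet}.
#' @export
setMethod("meth", "MethylIntensitySet", function(object)
    SummarizedExperiment::assay(object, "meth"))

#' @describeIn MethylIntensitySet unmethylated-channel matrix.
#' @export
setMethod("unmeth", "MethylIntensitySet", function(object)
    SummarizedExperiment::assay(object, "unmeth"))

#' @describeIn MethylIntensitySet factor with levels autosome/X/Y per probe.
#' @export
setMethod("chromosomeGroup", "MethylIntensitySet", function(object) {
    chr <- as.character(SummarizedExperiment::rowData(object)$chromosome)
    g <- ifelse(chr == "X", "X", ifelse(chr == "Y", "Y", "autosome"))
    factor(g, levels = c("autosome", "X", "Y"))
})

#' @describeIn MethylIntensitySet Infinium design type ("I"/"II") per probe.
#' @export
setMethod("designType", "MethylIntensitySet", function(object)
    as.character(SummarizedExperiment::rowData(object)$designType))

#' @describeIn MethylIntensitySet per-sample sex labels (or NULL).
#' @export
setMethod("sampleSex", "MethylIntensitySet", function(object) {
    cd <- SummarizedExperiment::colData(object)
    if ("sex" %in% colnames(cd)) as.character(cd$sex) else NULL
})

#' @describeIn MethylIntensitySet per-sample chip row (or NULL).
#' @export
setMethod("chipRow", "MethylIntensitySet", function(object) {
    cd <- SummarizedExperiment::colData(object)
    if ("chipRow" %in% colnames(cd)) as.integer(cd$chipRow) else NULL
})

#' @describeIn MethylNormResult beta matrix recomputed from corrected
#'   intensities.
#' @param object a \code{MethylNormResult}.
#' @export
setMethod("betaValues", "MethylNormResult", function(object, ...)
    SummarizedExperiment::assay(object, "beta"))

#' @describeIn MethylNormResult normalization method identifier.
#' @export
setMethod("methodId", "MethylNormResult", function(object) object@methodId)

#' @describeIn MethylNormResult probes corrected by rank interpolation.
#' @export
setMethod("interpolatedProbes", "MethylNormResult",
          function(object) object@interpolatedProbes)

#' @describeIn MethylNormResult parameter list of the run.
#' @export
setMethod("normParameters", "MethylNormResult",
          function(object) object@normParameters)

setMethod("show", "MethylIntensitySet", function(object) {
    cg <- table(chromosomeGroup(object))
    cat(sprintf("%s: %d probes x %d samples\n", class(object),
                nrow(object), ncol(object)))
    cat(sprintf("  probes: %d autosomal, %d X, %d Y; type II fraction %.2f\n",
                cg[["autosome"]], cg[["X"]], cg[["Y"]],
                mean(designType(object) == "II")))
    sx <- sampleSex(object)
    if (!is.null(sx))
        cat(sprintf("  samples: %d female, %d male\n",
                    sum(sx == "female", na.rm = TRUE),
                    sum(sx == "male", na.rm = TRUE)))
    invisible(object)
})

setMethod("show", "MethylNormResult", function(object) {
    methods::callNextMethod()
    cat(sprintf("  method: %s; %d interpolated probes\n",
                object@methodId, length(object@interpolatedProbes)))
    invisible(object)
})
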