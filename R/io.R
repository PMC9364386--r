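## Delimited-table I/O. Convention: tab-separated, first column probe_id,
## missing-value token "NA", full float precision on write.

.readTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                      check.names = FALSE, stringsAsFactors = FALSE)
}

.readValueTable <- function(path) {
    d <- .readTable(path)
    if (ncol(d) < 1L) stop("empty table: ", path)
    ids <- as.character(d[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate probe_id in ", path, ": ",
             .headIds(unique(ids[duplicated(ids)])))
    m <- as.matrix(d[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
        if (length(m)) {
            conv <- suppressWarnings(matrix(as.numeric(m), nrow(m)))
            bad <- which(!is.na(m) & is.na(conv), arr.ind = TRUE)
            if (nrow(bad))
                stop(sprintf(
                    "non-numeric cell in %s at row %d (probe %s), column '%s'",
                    path, bad[1, 1], ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
        }
        m <- matrix(suppressWarnings(as.numeric(m)), nrow(m), ncol(m),
                    dimnames = dimnames(m))
    }
    storage.mode(m) <- "double"
    rownames(m) <- ids
    m
}

#' Read a methylated/unmethylated intensity table pair
#'
#' Both files are TSV with header \code{probe_id} followed by sample columns.
#' The two tables must cover the same probe and sample sets (in any order);
#' they are aligned to the shared order of the methylated table. Negative
#' intensities are rejected.
#'
#' @param methPath,unmethPath paths to the methylated and unmethylated
#'   channel tables.
#' @return list with numeric matrices \code{meth} and \code{unmeth}
#'   (probes x samples, identical dimnames). Combine with an annotation via
#'   [MethylIntensitySet()].
#' @export
readIntensityPair <- function(methPath, unmethPath) {
    m <- .readValueTable(methPath)
    u <- .readValueTable(unmethPath)
    onlyM <- setdiff(rownames(m), rownames(u))
    onlyU <- setdiff(rownames(u), rownames(m))
    if (length(onlyM) || length(onlyU))
        stop("probe sets differ between channels; only in meth: [",
             .headIds(onlyM), "]; only in unmeth: [", .headIds(onlyU), "]")
    sOnlyM <- setdiff(colnames(m), colnames(u))
    sOnlyU <- setdiff(colnames(u), colnames(m))
    if (length(sOnlyM) || length(sOnlyU))
        stop("sample sets differ between channels; only in meth: [",
             .headIds(sOnlyM), "]; only in unmeth: [", .headIds(sOnlyU), "]")
    u <- u[rownames(m), colnames(m), drop = FALSE]
    if (any(m < 0, na.rm = TRUE) || any(u < 0, na.rm = TRUE))
        stop("negative intensities are not allowed")
    list(meth = m, unmeth = u)
}

#' Read a probe annotation table
#'
#' TSV with header \code{probe_id}, \code{chromosome}, \code{design_type}.
#' Chromosome labels are canonicalized (\code{"chrX"} -> \code{"X"}); rows on
#' chromosomes outside 1..22/X/Y (e.g. multi-mapping or control probes) are
#' dropped with a message reporting the count.
#'
#' @param path path to the annotation TSV.
#' @return data.frame with columns \code{probe_id}, \code{chromosome},
#'   \code{design_type}.
#' @export
readAnnotation <- function(path) {
    d <- .readTable(path)
    need <- c("probe_id", "chromosome", "design_type")
    if (!all(need %in% colnames(d)))
        stop("annotation must have columns: ", paste(need, collapse = ", "))
    d$probe_id <- as.character(d$probe_id)
    if (anyDuplicated(d$probe_id))
        stop("duplicate probe_id in annotation: ",
             .headIds(unique(d$probe_id[duplicated(d$probe_id)])))
    d$chromosome <- canonicalChromosome(d$chromosome)
    keep <- d$chromosome %in% .CHROMOSOMES
    if (any(!keep))
        message(sum(!keep), " probes on unsupported chromosomes dropped")
    d <- d[keep, , drop = FALSE]
    d$design_type <- as.character(d$design_type)
    bad <- setdiff(unique(d$design_type), c("I", "II"))
    if (length(bad))
        stop("unknown design_type value(s): ", paste(bad, collapse = ", "))
    if (anyNA(d$design_type) || anyNA(d$chromosome))
        stop("annotation has missing chromosome or design_type")
    rownames(d) <- NULL
    d[, need]
}

#' Read a sample sheet
#'
#' TSV with header \code{sample_id}, \code{sex} and optionally
#' \code{chip_row}. Sex is required by the variance/evaluation entry points
#' but not by the adjusted normalization itself.
#'
#' @param path path to the sample sheet TSV.
#' @return data.frame with columns \code{sample_id}, \code{sex} and, when
#'   present, \code{chip_row}.
#' @export
readSampleSheet <- function(path) {
    d <- .readTable(path)
    if (!"sample_id" %in% colnames(d))
        stop("sample sheet must have a sample_id column")
    d$sample_id <- as.character(d$sample_id)
    if (anyDuplicated(d$sample_id)) stop("duplicate sample_id in sample sheet")
    if ("sex" %in% colnames(d)) {
        d$sex <- as.character(d$sex)
        bad <- setdiff(unique(d$sex[!is.na(d$sex)]), c("female", "male"))
        if (length(bad))
            stop("sex must be 'female'/'male'; found: ",
                 paste(bad, collapse = ", "))
    }
    if ("chip_row" %in% colnames(d)) {
        d$chip_row <- as.integer(d$chip_row)
        if (any(d$chip_row < 1L, na.rm = TRUE))
            stop("chip_row must be >= 1")
    }
    rownames(d) <- NULL
    d
}

#' Write / read a beta (or intensity) value table
#'
#' Writes a probes-x-samples matrix as TSV (\code{probe_id} first column,
#' \code{NA} for missing) at full double precision so values round-trip
#' bitwise through [readBetaTable()]. Lines starting with \code{#} may carry
#' provenance and are skipped on read.
#'
#' @param beta numeric matrix (probes x samples) with dimnames.
#' @param path output path.
#' @param comment optional character vector written as \code{#}-prefixed
#'   header lines.
#' @return \code{writeBetaTable}: invisibly, the path.
#' @export
writeBetaTable <- function(beta, path, comment = NULL) {
    beta <- as.matrix(beta)
    con <- file(path, open = "wt")
    on.exit(close(con))
    if (length(comment))
        writeLines(paste0("# ", comment), con)
    writeLines(paste(c("probe_id", colnames(beta)), collapse = "\t"), con)
    if (nrow(beta)) {
        body <- apply(beta, 2, function(x)
            ifelse(is.na(x), "NA", sprintf("%.17g", x)))
        body <- matrix(body, nrow = nrow(beta))
        lines <- do.call(paste,
                         c(list(rownames(beta)), asplit(body, 2), sep = "\t"))
        writeLines(lines, con)
    }
    invisible(path)
}

#' @rdname writeBetaTable
#' @return \code{readBetaTable}: numeric matrix with probe ids as rownames.
#' @export
readBetaTable <- function(path) {
    .readValueTable(path)
}
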