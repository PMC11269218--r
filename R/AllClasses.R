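## Central data containers. Loci are rows, samples (or accessions) columns,
## following the SummarizedExperiment convention; the genotype value is the
## count of the SNP (alternate) allele in {0, 1, 2}, NA = missing.

.SAMPLE_TYPES <- c("individual", "seq_pool")

#' GenotypeDataset: diploid biallelic SNP calls with locus and sample metadata
#'
#' Extends \linkS4class{SummarizedExperiment} with a single \code{"calls"}
#' assay (loci x samples) holding alternate-allele counts in \{0, 1, 2\} with
#' \code{NA} for missing. Row metadata carries the per-locus quality fields
#' used by the filter cascade (\code{allele_id}, \code{rep_avg},
#' \code{avg_depth}, \code{callrate}); column metadata carries
#' \code{sample_id}, \code{accession_id}, \code{sample_type} (one of
#' \code{"individual"}, \code{"seq_pool"}) and an optional
#' \code{replicate_group} linking technical replicates.
#'
#' @export
setClass("GenotypeDataset", contains = "SummarizedExperiment")

setValidity("GenotypeDataset", function(object) {
    msg <- character()
    if (!"calls" %in% SummarizedExperiment::assayNames(object))
        return("assay 'calls' is required")
    m <- assay(object, "calls")
    bad <- m[!is.na(m)]
    if (length(bad) && !all(bad %in% c(0, 1, 2)))
        msg <- c(msg, "calls must be in {0, 1, 2, NA}")
    if (nrow(object) > 0 &&
        (is.null(rownames(object)) || anyDuplicated(rownames(object))))
        msg <- c(msg, "loci must have unique allele_id rownames")
    if (ncol(object) > 0 &&
        (is.null(colnames(object)) || anyDuplicated(colnames(object))))
        msg <- c(msg, "samples must have unique sample_id colnames")
    rd <- rowData(object)
    for (f in c("rep_avg", "avg_depth", "callrate"))
        if (!f %in% colnames(rd)) msg <- c(msg, paste0("rowData lacks ", f))
    if ("rep_avg" %in% colnames(rd)) {
        v <- rd$rep_avg
        if (any(v < 0 | v > 1, na.rm = TRUE))
            msg <- c(msg, "rep_avg must lie in [0, 1]")
    }
    if ("callrate" %in% colnames(rd)) {
        v <- rd$callrate
        if (any(v < 0 | v > 1, na.rm = TRUE))
            msg <- c(msg, "callrate must lie in [0, 1]")
    }
    if ("avg_depth" %in% colnames(rd)) {
        if (any(rd$avg_depth < 0, na.rm = TRUE))
            msg <- c(msg, "avg_depth must be >= 0")
    }
    cd <- colData(object)
    if ("sample_type" %in% colnames(cd)) {
        v <- cd$sample_type
        if (any(!is.na(v) & !v %in% .SAMPLE_TYPES))
            msg <- c(msg, "sample_type must be 'individual' or 'seq_pool'")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypeDataset
#'
#' @param calls numeric matrix, loci x samples, values in \{0, 1, 2, NA\}
#'   (count of the alternate allele). Rownames are allele ids, colnames sample
#'   ids; both required and unique.
#' @param locusMeta optional data.frame with per-locus columns among
#'   \code{rep_avg}, \code{avg_depth}, \code{callrate}; missing columns are
#'   filled with \code{NA} except \code{callrate}, which is computed from
#'   \code{calls} when absent.
#' @param sampleMeta optional data.frame with per-sample columns among
#'   \code{accession_id}, \code{sample_type}, \code{replicate_group}.
#' @return a \linkS4class{GenotypeDataset}
#' @examples
#' m <- matrix(c(0, 1, 2, NA), 2, 2,
#'             dimnames = list(c("L1", "L2"), c("S1", "S2")))
#' gd <- GenotypeDataset(m)
#' calls(gd)
#' @export
GenotypeDataset <- function(calls, locusMeta = NULL, sampleMeta = NULL) {
    if (!is.matrix(calls)) calls <- as.matrix(calls)
    storage.mode(calls) <- "double"
    if (nrow(calls) > 0 && is.null(rownames(calls)))
        stop("calls must have allele_id rownames")
    if (ncol(calls) > 0 && is.null(colnames(calls)))
        stop("calls must have sample_id colnames")
    nL <- nrow(calls)
    rd <- DataFrame(
        rep_avg   = rep(NA_real_, nL),
        avg_depth = rep(NA_real_, nL),
        callrate  = if (ncol(calls) > 0) rowMeans(!is.na(calls))
                    else rep(NA_real_, nL),
        row.names = rownames(calls))
    if (!is.null(locusMeta)) {
        for (f in intersect(c("rep_avg", "avg_depth", "callrate"),
                            colnames(locusMeta)))
            rd[[f]] <- as.numeric(locusMeta[[f]])
    }
    cd <- DataFrame(
        sample_id       = colnames(calls),
        accession_id    = rep(NA_character_, ncol(calls)),
        sample_type     = rep("individual", ncol(calls)),
        replicate_group = rep(NA_character_, ncol(calls)),
        row.names = colnames(calls))
    if (!is.null(sampleMeta)) {
        for (f in intersect(c("accession_id", "sample_type",
                              "replicate_group"), colnames(sampleMeta)))
            cd[[f]] <- as.character(sampleMeta[[f]])
    }
    new("GenotypeDataset",
        SummarizedExperiment(assays = list(calls = calls),
                             rowData = rd, colData = cd))
}

#' ReadCountTable: per-allele sequencing read counts for pooled samples
#'
#' Extends \linkS4class{SummarizedExperiment} with two assays, \code{"ref"}
#' and \code{"alt"} (loci x samples), holding non-negative integer read
#' counts for the reference and alternate allele at each locus.
#'
#' @export
setClass("ReadCountTable", contains = "SummarizedExperiment")

setValidity("ReadCountTable", function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("ref", "alt") %in% an))
        return("assays 'ref' and 'alt' are required")
    for (a in c("ref", "alt")) {
        m <- assay(object, a)
        if (any(m < 0, na.rm = TRUE))
            msg <- c(msg, paste0(a, " counts must be >= 0"))
        if (any(m != round(m), na.rm = TRUE))
            msg <- c(msg, paste0(a, " counts must be integers"))
    }
    if (nrow(object) > 0 &&
        (is.null(rownames(object)) || anyDuplicated(rownames(object))))
        msg <- c(msg, "loci must have unique allele_id rownames")
    if (ncol(object) > 0 &&
        (is.null(colnames(object)) || anyDuplicated(colnames(object))))
        msg <- c(msg, "samples must have unique sample_id colnames")
    if (length(msg)) msg else TRUE
})

#' Construct a ReadCountTable
#'
#' @param refReads,altReads non-negative integer matrices of identical shape
#'   (loci x samples) with allele_id rownames and sample_id colnames.
#' @return a \linkS4class{ReadCountTable}
#' @examples
#' r <- matrix(30, 1, 1, dimnames = list("L1", "P1"))
#' a <- matrix(10, 1, 1, dimnames = list("L1", "P1"))
#' ct <- ReadCountTable(r, a)
#' refReads(ct)
#' @export
ReadCountTable <- function(refReads, altReads) {
    refReads <- as.matrix(refReads); altReads <- as.matrix(altReads)
    storage.mode(refReads) <- "double"; storage.mode(altReads) <- "double"
    if (!identical(dim(refReads), dim(altReads)))
        stop("refReads and altReads must have identical dimensions")
    if (!identical(dimnames(refReads), dimnames(altReads)))
        stop("refReads and altReads must share dimnames")
    if (is.null(rownames(refReads)) || is.null(colnames(refReads)))
        stop("count matrices need allele_id rownames and sample_id colnames")
    new("ReadCountTable",
        SummarizedExperiment(assays = list(ref = refReads, alt = altReads)))
}

#' AccessionFrequencyTable: accession-level alternate-allele frequencies
#'
#' The common currency for AFD, MRD and heterozygosity: a loci x accessions
#' matrix of alternate-allele frequencies \code{q} in [0, 1] (NA = missing),
#' a matching \code{support} matrix (total reads, or count of non-missing
#' individuals, behind each cell) and the provenance of the estimator.
#'
#' @slot freq numeric matrix, loci x accessions, entries in [0, 1] or NA.
#' @slot support numeric matrix of the same shape; >= 1 wherever freq present.
#' @slot provenance character, \code{"pooled_reads"} or
#'   \code{"genotype_based"}.
#' @export
setClass("AccessionFrequencyTable",
         representation(freq = "matrix", support = "matrix",
                        provenance = "character"))

setValidity("AccessionFrequencyTable", function(object) {
    msg <- character()
    f <- object@freq; s <- object@support
    if (!identical(dim(f), dim(s)))
        msg <- c(msg, "freq and support must have identical dimensions")
    if (any(f < 0 | f > 1, na.rm = TRUE))
        msg <- c(msg, "frequencies must lie in [0, 1]")
    ok <- !is.na(f)
    if (length(s) && any(ok & (is.na(s) | s < 1)))
        msg <- c(msg, "support must be >= 1 wherever freq is present")
    if (is.null(rownames(f)) || is.null(colnames(f)))
        msg <- c(msg, "freq needs allele_id rownames and accession colnames")
    if (!object@provenance %in% c("pooled_reads", "genotype_based"))
        msg <- c(msg, "provenance must be 'pooled_reads' or 'genotype_based'")
    if (length(msg)) msg else TRUE
})

#' Construct an AccessionFrequencyTable
#'
#' @param freq loci x accessions matrix of alternate-allele frequencies.
#' @param support matching matrix of per-cell support (reads or individuals).
#' @param provenance \code{"pooled_reads"} or \code{"genotype_based"}.
#' @return an \linkS4class{AccessionFrequencyTable}
#' @export
AccessionFrequencyTable <- function(freq, support, provenance) {
    freq <- as.matrix(freq); support <- as.matrix(support)
    dimnames(support) <- dimnames(freq)
    new("AccessionFrequencyTable", freq = freq, support = support,
        provenance = provenance)
}

#' MRDMatrix: pairwise modified Rogers distances
#'
#' Symmetric matrix of modified Rogers distances in [0, 1] with a matching
#' matrix recording how many pairwise-complete loci entered each entry.
#'
#' @slot mrd symmetric numeric matrix with zero diagonal, entries in [0, 1].
#' @slot nLociUsed integer matrix of pairwise-complete locus counts.
#' @export
setClass("MRDMatrix",
         representation(mrd = "matrix", nLociUsed = "matrix"))

setValidity("MRDMatrix", function(object) {
    m <- object@mrd
    msg <- character()
    if (nrow(m) != ncol(m) || !isSymmetric(unname(m), tol = 1e-8))
        msg <- c(msg, "mrd must be a symmetric square matrix")
    if (any(abs(diag(m)) > 1e-12, na.rm = TRUE))
        msg <- c(msg, "mrd must have a zero diagonal")
    if (any(m < -1e-12 | m > 1 + 1e-12, na.rm = TRUE))
        msg <- c(msg, "mrd entries must lie in [0, 1]")
    if (!identical(dim(m), dim(object@nLociUsed)))
        msg <- c(msg, "nLociUsed must match mrd dimensions")
    if (length(msg)) msg else TRUE
})
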