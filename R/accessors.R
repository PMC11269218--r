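## Accessors for the data containers. Slot access is never needed by users.

#' @rdname GenotypeDataset-class
#' @param x a poolstrat data object
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname GenotypeDataset-class
#' @export
setMethod("calls", "GenotypeDataset", function(x) assay(x, "calls"))

#' @rdname GenotypeDataset-class
#' @export
setGeneric("locusMeta", function(x) standardGeneric("locusMeta"))

#' @rdname GenotypeDataset-class
#' @export
setMethod("locusMeta", "GenotypeDataset", function(x) {
    d <- as.data.frame(rowData(x))
    data.frame(allele_id = rownames(x), d, row.names = NULL,
               stringsAsFactors = FALSE)
})

#' @rdname GenotypeDataset-class
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' @rdname GenotypeDataset-class
#' @export
setMethod("sampleMeta", "GenotypeDataset",
          function(x) as.data.frame(colData(x), row.names = NULL))

#' @rdname ReadCountTable-class
#' @param x a \linkS4class{ReadCountTable}
#' @export
setGeneric("refReads", function(x) standardGeneric("refReads"))

#' @rdname ReadCountTable-class
#' @export
setMethod("refReads", "ReadCountTable", function(x) assay(x, "ref"))

#' @rdname ReadCountTable-class
#' @export
setGeneric("altReads", function(x) standardGeneric("altReads"))

#' @rdname ReadCountTable-class
#' @export
setMethod("altReads", "ReadCountTable", function(x) assay(x, "alt"))

#' Total read depth per cell (ref + alt)
#' @rdname ReadCountTable-class
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @rdname ReadCountTable-class
#' @export
setMethod("totalReads", "ReadCountTable",
          function(x) assay(x, "ref") + assay(x, "alt"))

#' @rdname AccessionFrequencyTable-class
#' @param x an \linkS4class{AccessionFrequencyTable}
#' @export
setGeneric("freqMat", function(x) standardGeneric("freqMat"))

#' @rdname AccessionFrequencyTable-class
#' @export
setMethod("freqMat", "AccessionFrequencyTable", function(x) x@freq)

#' @rdname AccessionFrequencyTable-class
#' @export
setGeneric("supportMat", function(x) standardGeneric("supportMat"))

#' @rdname AccessionFrequencyTable-class
#' @export
setMethod("supportMat", "AccessionFrequencyTable", function(x) x@support)

#' @rdname AccessionFrequencyTable-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname AccessionFrequencyTable-class
#' @export
setMethod("provenance", "AccessionFrequencyTable", function(x) x@provenance)

#' @rdname AccessionFrequencyTable-class
#' @export
setGeneric("accessionIds", function(x) standardGeneric("accessionIds"))

#' @rdname AccessionFrequencyTable-class
#' @export
setMethod("accessionIds", "AccessionFrequencyTable",
          function(x) colnames(x@freq))

setMethod("dim", "AccessionFrequencyTable", function(x) dim(x@freq))

setMethod("show", "AccessionFrequencyTable", function(object) {
    cat("AccessionFrequencyTable:", nrow(object@freq), "loci x",
        ncol(object@freq), "accessions (", object@provenance, ")\n")
    cat("  missing cells:", sum(is.na(object@freq)), "\n")
})

#' Subset an AccessionFrequencyTable by loci / accessions
#' @param x an \linkS4class{AccessionFrequencyTable}
#' @param i,j locus and accession indices
#' @param ... ignored
#' @param drop ignored; dimensions are always kept
#' @export
setMethod("[", "AccessionFrequencyTable", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@freq))
    if (missing(j)) j <- seq_len(ncol(x@freq))
    AccessionFrequencyTable(x@freq[i, j, drop = FALSE],
                            x@support[i, j, drop = FALSE], x@provenance)
})

#' @rdname MRDMatrix-class
#' @param x an \linkS4class{MRDMatrix}
#' @export
setGeneric("nLociUsed", function(x) standardGeneric("nLociUsed"))

#' @rdname MRDMatrix-class
#' @export
setMethod("nLociUsed", "MRDMatrix", function(x) x@nLociUsed)

#' @rdname MRDMatrix-class
#' @param ... ignored
#' @export
setMethod("as.matrix", "MRDMatrix", function(x, ...) x@mrd)

setMethod("dim", "MRDMatrix", function(x) dim(x@mrd))

setMethod("show", "MRDMatrix", function(object) {
    off <- object@mrd[upper.tri(object@mrd)]
    cat("MRDMatrix:", nrow(object@mrd), "samples; mean off-diagonal MRD",
        if (length(off)) round(mean(off, na.rm = TRUE), 4) else NA, "\n")
})

setMethod("show", "GenotypeDataset", function(object) {
    ty <- table(colData(object)$sample_type)
    cat("GenotypeDataset:", nrow(object), "loci x", ncol(object), "samples (",
        paste(names(ty), as.integer(ty), collapse = ", "), ")\n")
    acc <- colData(object)$accession_id
    cat("  accessions:", length(unique(acc[!is.na(acc)])),
        "| missing calls:",
        round(100 * mean(is.na(assay(object, "calls"))), 2), "%\n")
})

setMethod("show", "ReadCountTable", function(object) {
    cat("ReadCountTable:", nrow(object), "loci x", ncol(object), "samples;",
        "mean depth", round(mean(totalReads(object), na.rm = TRUE), 1), "\n")
})
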