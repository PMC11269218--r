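## DArT-style CSV I/O. One-row SNP reports code the two-allele genotype in a
## single row per locus; the counts report carries per-allele read counts for
## pooled samples. No genome coordinates are modelled: loci are unordered,
## unlinked biallelic markers keyed by AlleleID.

.LOCUS_META_COLS <- c(AlleleID = "allele_id", RepAvg = "rep_avg",
                      AvgDepth = "avg_depth", CallRate = "callrate")

#' Genotype coding dialects for one-row reports
#'
#' Maps report codes to alternate-allele counts. \code{"dart_onerow"} is the
#' native DArT one-row coding (0 = reference homozygote, 1 = SNP homozygote,
#' 2 = heterozygote, \code{"-"} = missing); \code{"altcount"} is the plain
#' \{0, 1, 2, NA\} alternate-allele count coding.
#'
#' @return named list of dialect maps (named numeric vectors, code -> count).
#' @export
genotypeDialects <- function() {
    list(
        dart_onerow = c("0" = 0, "1" = 2, "2" = 1, "-" = NA_real_),
        altcount    = c("0" = 0, "1" = 1, "2" = 2, "NA" = NA_real_,
                        "-" = NA_real_, " " = NA_real_)
    )
}

.getDialect <- function(dialect) {
    dl <- genotypeDialects()
    if (is.character(dialect)) {
        if (!dialect %in% names(dl))
            stop("unknown dialect '", dialect, "'; available: ",
                 paste(names(dl), collapse = ", "))
        dl[[dialect]]
    } else dialect
}

#' Read a DArT-style one-row SNP genotype report
#'
#' @param path CSV file: a header row, one row per locus, an
#'   \code{AlleleID} column, optional \code{RepAvg}, \code{AvgDepth} and
#'   \code{CallRate} metadata columns, and one column per sample carrying
#'   genotype codes in the chosen dialect.
#' @param dialect name of a dialect in \code{\link{genotypeDialects}} (or a
#'   named code -> alternate-allele-count map). Default \code{"dart_onerow"}.
#' @return a \linkS4class{GenotypeDataset}. Metadata columns absent from the
#'   file are marked absent (\code{NA}); the locus call rate is computed from
#'   the calls when no \code{CallRate} column is present.
#' @export
readDartOneRow <- function(path, dialect = "dart_onerow") {
    map <- .getDialect(dialect)
    df <- read.csv(path, check.names = FALSE, colClasses = "character",
                   na.strings = NULL, fileEncoding = "UTF-8")
    if (!"AlleleID" %in% colnames(df))
        stop("report lacks an AlleleID column")
    if (anyDuplicated(df$AlleleID))
        stop("duplicated AlleleID: ",
             paste(unique(df$AlleleID[duplicated(df$AlleleID)]),
                   collapse = ", "))
    metaCols <- intersect(names(.LOCUS_META_COLS), colnames(df))
    sampleCols <- setdiff(colnames(df), metaCols)
    codes <- as.matrix(df[, sampleCols, drop = FALSE])
    calls <- matrix(NA_real_, nrow(df), length(sampleCols),
                    dimnames = list(df$AlleleID, sampleCols))
    known <- matrix(codes %in% c(names(map), "", "NA"), nrow = nrow(codes))
    if (!all(known)) {
        bad <- which(!known, arr.ind = TRUE)[1, ]
        stop("unknown genotype code '", codes[bad[1], bad[2]],
             "' at locus ", df$AlleleID[bad[1]],
             ", sample column '", sampleCols[bad[2]], "'")
    }
    idx <- codes != "" & codes != "NA"
    calls[idx] <- map[codes[idx]]
    lm <- data.frame(row.names = df$AlleleID)
    for (col in setdiff(metaCols, "AlleleID"))
        lm[[.LOCUS_META_COLS[[col]]]] <- suppressWarnings(as.numeric(df[[col]]))
    GenotypeDataset(calls, locusMeta = if (ncol(lm)) lm else NULL)
}

#' Write a GenotypeDataset as a one-row report
#'
#' Inverse of \code{\link{readDartOneRow}}: the written file read back with
#' the same dialect reproduces the calls and metadata exactly.
#'
#' @param ds a \linkS4class{GenotypeDataset}
#' @param path output CSV path
#' @param dialect coding dialect, as in \code{\link{readDartOneRow}}
#' @return \code{path}, invisibly
#' @export
writeDataset <- function(ds, path, dialect = "dart_onerow") {
    map <- .getDialect(dialect)
    inv <- setNames(names(map)[!is.na(map)], map[!is.na(map)])
    naCode <- names(map)[is.na(map)][1]
    m <- calls(ds)
    codes <- matrix(naCode, nrow(m), ncol(m), dimnames = dimnames(m))
    idx <- !is.na(m)
    codes[idx] <- inv[as.character(m[idx])]
    lm <- locusMeta(ds)
    out <- data.frame(AlleleID = if (is.null(rownames(m))) character(0)
                                 else rownames(m),
                      RepAvg = lm$rep_avg, AvgDepth = lm$avg_depth,
                      CallRate = lm$callrate, check.names = FALSE,
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(codes, stringsAsFactors = FALSE))
    write.csv(out, path, row.names = FALSE, quote = TRUE,
              fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a DArT-style per-allele read-count report
#'
#' Two layouts are supported. Wide (the layout the synthetic writer emits):
#' columns \code{AlleleID}, \code{Allele} (\code{"Ref"} or \code{"Alt"}) and
#' one integer column per sample, two rows per locus. Long: columns
#' \code{AlleleID}, \code{SampleID}, \code{RefReads}, \code{AltReads}, one
#' row per locus/sample pair.
#'
#' @param path CSV file
#' @param format \code{"auto"} (detect from columns), \code{"wide"} or
#'   \code{"long"}
#' @return a \linkS4class{ReadCountTable}
#' @export
readDartCounts <- function(path, format = c("auto", "wide", "long")) {
    format <- match.arg(format)
    df <- read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
    if (format == "auto")
        format <- if ("Allele" %in% colnames(df)) "wide" else "long"
    if (format == "wide") {
        if (!all(c("AlleleID", "Allele") %in% colnames(df)))
            stop("wide counts report needs AlleleID and Allele columns")
        sampleCols <- setdiff(colnames(df), c("AlleleID", "Allele"))
        refDf <- df[df$Allele == "Ref", , drop = FALSE]
        altDf <- df[df$Allele == "Alt", , drop = FALSE]
        if (anyDuplicated(refDf$AlleleID) || anyDuplicated(altDf$AlleleID))
            stop("duplicated AlleleID rows in counts report")
        onlyOne <- union(setdiff(refDf$AlleleID, altDf$AlleleID),
                         setdiff(altDf$AlleleID, refDf$AlleleID))
        if (length(onlyOne))
            stop("loci with only one allele row: ",
                 paste(utils::head(onlyOne, 5), collapse = ", "))
        ref <- as.matrix(refDf[, sampleCols, drop = FALSE])
        rownames(ref) <- refDf$AlleleID
        alt <- as.matrix(altDf[, sampleCols, drop = FALSE])
        rownames(alt) <- altDf$AlleleID
        alt <- alt[rownames(ref), , drop = FALSE]
    } else {
        need <- c("AlleleID", "SampleID", "RefReads", "AltReads")
        if (!all(need %in% colnames(df)))
            stop("long counts report needs columns ",
                 paste(need, collapse = ", "))
        loci <- unique(df$AlleleID); samples <- unique(df$SampleID)
        ref <- matrix(NA_real_, length(loci), length(samples),
                      dimnames = list(loci, samples))
        alt <- ref
        ref[cbind(match(df$AlleleID, loci), match(df$SampleID, samples))] <-
            df$RefReads
        alt[cbind(match(df$AlleleID, loci), match(df$SampleID, samples))] <-
            df$AltReads
        if (anyNA(ref) || anyNA(alt))
            stop("long counts report has missing locus/sample combinations")
    }
    if (any(ref < 0, na.rm = TRUE) || any(alt < 0, na.rm = TRUE))
        stop("negative read counts in ", path)
    ReadCountTable(ref, alt)
}

#' Write a ReadCountTable in the wide counts layout
#'
#' @param ct a \linkS4class{ReadCountTable}
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
writeCounts <- function(ct, path) {
    ref <- refReads(ct); alt <- altReads(ct)
    n <- nrow(ref)
    out <- data.frame(AlleleID = rep(rownames(ref), each = 2),
                      Allele = rep(c("Ref", "Alt"), n),
                      stringsAsFactors = FALSE)
    body <- matrix(0, 2 * n, ncol(ref), dimnames = list(NULL, colnames(ref)))
    body[seq(1, 2 * n, by = 2), ] <- ref
    body[seq(2, 2 * n, by = 2), ] <- alt
    out <- cbind(out, as.data.frame(body))
    write.csv(out, path, row.names = FALSE, quote = TRUE,
              fileEncoding = "UTF-8")
    invisible(path)
}

#' Read / write / validate a sample sheet
#'
#' A sample sheet maps samples to accessions: columns \code{sample_id},
#' \code{accession_id}, \code{sample_type} (\code{"individual"} or
#' \code{"seq_pool"}) and optional \code{replicate_group} and
#' \code{origin_region}.
#'
#' @param path CSV path
#' @return a validated data.frame
#' @export
readSampleSheet <- function(path) {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                   fileEncoding = "UTF-8")
    validateSampleSheet(df)
}

#' @rdname readSampleSheet
#' @param sheet a sample-sheet data.frame
#' @export
validateSampleSheet <- function(sheet) {
    need <- c("sample_id", "accession_id", "sample_type")
    if (!all(need %in% colnames(sheet)))
        stop("sample sheet needs columns ", paste(need, collapse = ", "))
    if (anyDuplicated(sheet$sample_id))
        stop("duplicated sample_id in sample sheet")
    if (any(!sheet$sample_type %in% .SAMPLE_TYPES))
        stop("sample_type must be one of ",
             paste(.SAMPLE_TYPES, collapse = ", "))
    if (!"replicate_group" %in% colnames(sheet))
        sheet$replicate_group <- NA_character_
    if (!"origin_region" %in% colnames(sheet))
        sheet$origin_region <- NA_character_
    sheet
}

#' @rdname readSampleSheet
#' @export
writeSampleSheet <- function(sheet, path) {
    write.csv(validateSampleSheet(sheet), path, row.names = FALSE,
              quote = TRUE, fileEncoding = "UTF-8")
    invisible(path)
}
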