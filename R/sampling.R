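## Construction of the three comparison datasets from one genotyped panel:
## the in-silico pool (all individuals, grouped by accession), the seq-pool
## samples (kept as-is, replicates never merged), and seeded single-plant
## subsets.

#' Annotate individual samples with their accession grouping
#'
#' The in-silico pool is the full individual-sample dataset analysed per
#' accession; no aggregation happens here, the accession grouping is simply
#' attached from the sample sheet.
#'
#' @param ds a \linkS4class{GenotypeDataset} of individual samples
#' @param sheet a sample sheet (see \code{\link{readSampleSheet}})
#' @return the dataset with \code{accession_id}/\code{sample_type} filled in
#' @export
buildInSilicoPool <- function(ds, sheet) {
    sheet <- validateSampleSheet(sheet)
    idx <- match(colnames(ds), sheet$sample_id)
    if (anyNA(idx))
        stop("samples missing from the sheet: ",
             paste(utils::head(colnames(ds)[is.na(idx)], 5), collapse = ", "))
    acc <- sheet$accession_id[idx]
    if (any(is.na(acc) | acc == ""))
        stop("individuals with no accession: ",
             paste(utils::head(colnames(ds)[is.na(acc) | acc == ""], 5),
                   collapse = ", "))
    colData(ds)$accession_id <- acc
    colData(ds)$sample_type <- sheet$sample_type[idx]
    colData(ds)$replicate_group <- as.character(sheet$replicate_group[idx])
    ds
}

#' Draw one random plant per accession
#'
#' Uniform seeded sampling of exactly one individual per accession. The same
#' seed always returns the same subset.
#'
#' @param ds a \linkS4class{GenotypeDataset} of individuals with
#'   \code{accession_id} set (see \code{\link{buildInSilicoPool}})
#' @param sheet optional sample sheet used to fill the grouping first
#' @param seed integer seed
#' @return a \linkS4class{GenotypeDataset} with one sample per accession,
#'   with the seed recorded in \code{metadata()$seed}
#' @export
sampleSinglePlants <- function(ds, sheet = NULL, seed) {
    if (!is.null(sheet)) ds <- buildInSilicoPool(ds, sheet)
    acc <- colData(ds)$accession_id
    if (all(is.na(acc))) stop("dataset has no accession grouping")
    accIds <- sort(unique(acc))
    chosen <- withr::with_seed(seed, vapply(accIds, function(a) {
        cand <- which(acc == a)
        if (!length(cand)) stop("accession '", a, "' has no individuals")
        cand[sample.int(length(cand), 1)]
    }, integer(1)))
    out <- ds[, chosen]
    metadata(out)$seed <- seed
    out
}

#' Repeated single-plant resampling runs
#'
#' \code{nRuns} independent seeded single-plant subsets; the per-run seed is
#' \code{baseSeed + run} and is recorded on each subset.
#'
#' @param ds a \linkS4class{GenotypeDataset} of individuals
#' @param sheet optional sample sheet
#' @param nRuns number of runs (default 10)
#' @param baseSeed integer base seed
#' @return list of \linkS4class{GenotypeDataset}s, names \code{run1..runN}
#' @export
resampleRuns <- function(ds, sheet = NULL, nRuns = 10, baseSeed = 1) {
    if (nRuns < 1) stop("nRuns must be >= 1")
    if (!is.null(sheet)) ds <- buildInSilicoPool(ds, sheet)
    runs <- lapply(seq_len(nRuns), function(i)
        sampleSinglePlants(ds, seed = baseSeed + i))
    names(runs) <- paste0("run", seq_len(nRuns))
    runs
}

#' Group technical replicate pools
#'
#' Seq-pool samples sharing a \code{replicate_group} are grouped; replicates
#' are kept as separate samples, never merged. Pools without a replicate
#' group form singleton groups.
#'
#' @param sheet a sample sheet
#' @return named list of sample-id character vectors, one per group
#' @export
linkReplicates <- function(sheet) {
    sheet <- validateSampleSheet(sheet)
    pools <- sheet[sheet$sample_type == "seq_pool", , drop = FALSE]
    key <- ifelse(is.na(pools$replicate_group) | pools$replicate_group == "",
                  pools$sample_id, pools$replicate_group)
    split(pools$sample_id, key)
}
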