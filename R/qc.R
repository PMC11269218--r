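## Quality-control statistics and the filter cascade. Filters run in a fixed
## documented order; the locus call rate is always recomputed on the samples
## of the dataset being filtered, so per-subset filtering matches filtering
## each split independently.

#' Configuration of the locus filter cascade
#'
#' Defaults are the study's filters: marker reproducibility (RepAvg) of 1,
#' average read depth between 5 and 100, locus call rate at least 0.75,
#' monomorphic loci removed. Set a threshold to \code{NA} to disable that
#' filter. Ties at a threshold are retained (all comparisons are inclusive),
#' so the call-rate boundary 0.75 keeps loci at exactly 0.75.
#'
#' @param repAvgMin minimum marker reproducibility (default 1)
#' @param depthMin,depthMax inclusive average read depth window (5, 100)
#' @param locusCallrateMin minimum locus call rate (default 0.75),
#'   recomputed on the dataset's current samples
#' @param dropMonomorphic remove loci where only one allele is observed
#'   (default TRUE)
#' @param dropAllMissing remove loci with no calls at all (default TRUE)
#' @return a validated list of class \code{"filterConfig"}
#' @export
filterConfig <- function(repAvgMin = 1, depthMin = 5, depthMax = 100,
                         locusCallrateMin = 0.75, dropMonomorphic = TRUE,
                         dropAllMissing = TRUE) {
    if (!is.na(repAvgMin) && (repAvgMin < 0 || repAvgMin > 1))
        stop("repAvgMin must lie in [0, 1]")
    if (!is.na(depthMin) && !is.na(depthMax) && depthMin > depthMax)
        stop("depthMin must be <= depthMax")
    if (!is.na(locusCallrateMin) &&
        (locusCallrateMin < 0 || locusCallrateMin > 1))
        stop("locusCallrateMin must lie in [0, 1]")
    structure(list(repAvgMin = repAvgMin, depthMin = depthMin,
                   depthMax = depthMax, locusCallrateMin = locusCallrateMin,
                   dropMonomorphic = isTRUE(dropMonomorphic),
                   dropAllMissing = isTRUE(dropAllMissing)),
              class = "filterConfig")
}

#' Per-locus call rate
#'
#' Fraction of non-missing calls per locus over the dataset's current
#' samples.
#'
#' @param ds a \linkS4class{GenotypeDataset} with >= 1 sample
#' @return named numeric vector in [0, 1]
#' @export
locusCallrate <- function(ds) {
    if (ncol(ds) < 1) stop("locusCallrate needs at least one sample")
    rowMeans(!is.na(calls(ds)))
}

#' Per-sample call rate
#'
#' @param ds a \linkS4class{GenotypeDataset} with >= 1 locus
#' @return named numeric vector in [0, 1]
#' @export
sampleCallrate <- function(ds) {
    if (nrow(ds) < 1) stop("sampleCallrate needs at least one locus")
    colMeans(!is.na(calls(ds)))
}

#' Per-locus minor allele frequency
#'
#' maf = min(p, 1 - p) where p is the mean alternate-allele frequency over
#' non-missing calls. Loci with no non-missing calls return \code{NA}.
#'
#' @param ds a \linkS4class{GenotypeDataset}
#' @return named numeric vector in [0, 0.5] (or NA)
#' @export
minorAlleleFrequency <- function(ds) {
    p <- rowMeans(calls(ds), na.rm = TRUE) / 2
    p[is.nan(p)] <- NA_real_
    pmin(p, 1 - p)
}

#' Flag monomorphic loci
#'
#' A locus is monomorphic iff exactly one allele is observed among its
#' non-missing calls (a heterozygous call shows both alleles). All-missing
#' loci return \code{NA}.
#'
#' @param ds a \linkS4class{GenotypeDataset}
#' @return named logical vector (NA for all-missing loci)
#' @export
isMonomorphic <- function(ds) {
    m <- calls(ds)
    altSeen <- rowSums(m > 0, na.rm = TRUE) > 0
    refSeen <- rowSums(m < 2, na.rm = TRUE) > 0
    anyCall <- rowSums(!is.na(m)) > 0
    out <- !(altSeen & refSeen)
    out[!anyCall] <- NA
    out
}

#' Apply the filter cascade
#'
#' Filters are applied in a fixed order: all-missing removal, marker
#' reproducibility, average depth window, locus call rate (recomputed on the
#' current samples), monomorphic removal. Filtering only removes loci; it
#' never alters surviving genotype values, and re-running the cascade on its
#' own output is the identity.
#'
#' @param ds a \linkS4class{GenotypeDataset}
#' @param cfg a \code{\link{filterConfig}}
#' @return list with \code{dataset} (the filtered
#'   \linkS4class{GenotypeDataset}) and \code{report} (data.frame with one
#'   row per filter: name, loci before, removed, after)
#' @export
applyFilters <- function(ds, cfg = filterConfig()) {
    steps <- list()
    addStep <- function(name, keep) {
        before <- nrow(ds)
        ds <<- ds[keep, ]
        steps[[length(steps) + 1L]] <<- data.frame(
            filter = name, loci_before = before,
            loci_removed = before - nrow(ds), loci_after = nrow(ds),
            stringsAsFactors = FALSE)
    }
    needMeta <- function(col) {
        v <- rowData(ds)[[col]]
        if (nrow(ds) > 0 && all(is.na(v)))
            stop("filter requires locus metadata column '", col,
                 "', which is absent")
        v
    }
    if (cfg$dropAllMissing)
        addStep("drop_all_missing", rowSums(!is.na(calls(ds))) > 0)
    if (!is.na(cfg$repAvgMin)) {
        v <- needMeta("rep_avg")
        addStep("rep_avg", !is.na(v) & v >= cfg$repAvgMin)
    }
    if (!is.na(cfg$depthMin) || !is.na(cfg$depthMax)) {
        v <- needMeta("avg_depth")
        lo <- if (is.na(cfg$depthMin)) -Inf else cfg$depthMin
        hi <- if (is.na(cfg$depthMax)) Inf else cfg$depthMax
        addStep("avg_depth", !is.na(v) & v >= lo & v <= hi)
    }
    if (!is.na(cfg$locusCallrateMin)) {
        cr <- if (ncol(ds) > 0) rowMeans(!is.na(calls(ds)))
              else rep(1, nrow(ds))
        addStep("locus_callrate", cr >= cfg$locusCallrateMin)
    }
    if (cfg$dropMonomorphic) {
        mono <- isMonomorphic(ds)
        addStep("monomorphic", !is.na(mono) & !mono)
    }
    report <- if (length(steps)) do.call(rbind, steps)
              else data.frame(filter = character(), loci_before = integer(),
                              loci_removed = integer(),
                              loci_after = integer())
    list(dataset = ds, report = report)
}

#' Keep only loci fully called within one accession
#'
#' Subsets the dataset to the samples of one accession and to the loci with
#' zero missing calls among them (the no-missing-within-accession subset on
#' which H and H' are computed).
#'
#' @param ds a \linkS4class{GenotypeDataset}
#' @param accession accession id present in \code{colData(ds)$accession_id}
#' @return a \linkS4class{GenotypeDataset}
#' @export
subsetNoMissingWithinAccession <- function(ds, accession) {
    sel <- which(colData(ds)$accession_id == accession)
    if (!length(sel))
        stop("accession '", accession, "' has no samples in the dataset")
    sub <- ds[, sel]
    sub[rowSums(is.na(calls(sub))) == 0, ]
}
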