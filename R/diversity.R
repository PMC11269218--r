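## Within-accession diversity (expected heterozygosity with and without
## monomorphic loci, polymorphic-site counts, homogeneity classification) and
## modified Rogers distances between allele-frequency vectors.

#' Expected heterozygosity of an accession
#'
#' He = 2pq per locus. H averages 2pq over the polymorphic loci only
#' (0 < q < 1); H' includes monomorphic loci, so H' <= H whenever both are
#' defined. With no polymorphic loci H is reported as 0 with \code{nLoci} 0.
#'
#' @param freq vector of alternate-allele frequencies on the accession's
#'   no-missing locus subset (NA cells are dropped)
#' @param includeMonomorphic if TRUE compute H' (all loci), else H
#'   (polymorphic loci only)
#' @return list with \code{value} and \code{nLoci} (loci used)
#' @export
expectedHet <- function(freq, includeMonomorphic = FALSE) {
    q <- freq[!is.na(freq)]
    if (!length(q)) stop("expectedHet: zero loci")
    if (!includeMonomorphic) q <- q[q > 0 & q < 1]
    if (!length(q)) return(list(value = 0, nLoci = 0L))
    list(value = mean(2 * q * (1 - q)), nLoci = length(q))
}

#' Polymorphic sites in a frequency vector
#'
#' A locus is polymorphic when both alleles are observed (0 < q < 1). A
#' single plant's calls scaled by 1/2 make this the heterozygous-call count,
#' so the same definition serves all three strategies.
#'
#' @param freq alternate-allele frequency vector (NA = missing)
#' @return list with \code{count} and \code{fraction} (of non-missing loci)
#' @export
polymorphicSites <- function(freq) {
    q <- freq[!is.na(freq)]
    n <- sum(q > 0 & q < 1)
    list(count = n, fraction = if (length(q)) n / length(q) else NA_real_)
}

#' Classify an accession as homogeneous or heterogeneous
#'
#' Homogeneous iff the fraction of homozygous (fixed, q in \{0, 1\}) loci
#' among the accession's non-missing loci strictly exceeds the threshold
#' (default 0.92).
#'
#' @param freq alternate-allele frequency vector
#' @param threshold homozygous-fraction cutoff (default 0.92, strict >)
#' @return \code{"homogeneous"} or \code{"heterogeneous"}
#' @export
classifyHomogeneity <- function(freq, threshold = 0.92) {
    q <- freq[!is.na(freq)]
    if (!length(q)) stop("classifyHomogeneity: zero loci")
    homFrac <- mean(q == 0 | q == 1)
    if (homFrac > threshold) "homogeneous" else "heterogeneous"
}

#' Per-accession diversity table
#'
#' For a \linkS4class{GenotypeDataset} of individuals, each accession is
#' first restricted to its no-missing locus subset
#' (\code{\link{subsetNoMissingWithinAccession}}) before frequencies are
#' computed; for an \linkS4class{AccessionFrequencyTable} (e.g. pooled
#' read-count frequencies), the non-missing cells of each accession column
#' are used.
#'
#' @param x a \linkS4class{GenotypeDataset} with accession grouping, or an
#'   \linkS4class{AccessionFrequencyTable}
#' @param label dataset label recorded in the output
#' @param threshold homogeneity threshold (default 0.92)
#' @return data.frame: accession, n_loci_all, n_polymorphic, H, H_prime,
#'   homozygous_fraction, homogeneity_class, dataset
#' @export
setGeneric("diversityTable",
           function(x, label = "dataset", threshold = 0.92)
               standardGeneric("diversityTable"))

.diversityRow <- function(q, accession, label, threshold) {
    q <- q[!is.na(q)]
    hp <- expectedHet(q, includeMonomorphic = TRUE)
    h <- expectedHet(q, includeMonomorphic = FALSE)
    ps <- polymorphicSites(q)
    data.frame(accession = accession, n_loci_all = length(q),
               n_polymorphic = ps$count, H = h$value, H_prime = hp$value,
               homozygous_fraction = 1 - ps$fraction,
               homogeneity_class = classifyHomogeneity(q, threshold),
               dataset = label, stringsAsFactors = FALSE)
}

#' @rdname diversityTable
#' @export
setMethod("diversityTable", "GenotypeDataset",
          function(x, label = "dataset", threshold = 0.92) {
    acc <- colData(x)$accession_id
    accIds <- unique(acc[!is.na(acc)])
    if (!length(accIds)) stop("dataset has no accession grouping")
    do.call(rbind, lapply(accIds, function(a) {
        sub <- subsetNoMissingWithinAccession(x, a)
        q <- rowMeans(calls(sub)) / 2
        .diversityRow(q, a, label, threshold)
    }))
})

#' @rdname diversityTable
#' @export
setMethod("diversityTable", "AccessionFrequencyTable",
          function(x, label = "dataset", threshold = 0.92) {
    f <- freqMat(x)
    do.call(rbind, lapply(colnames(f), function(a)
        .diversityRow(f[, a], a, label, threshold)))
})

#' Modified Rogers distance between two frequency vectors
#'
#' MRD = sqrt( (1 / 2L) * sum over the L pairwise-complete loci of the
#' squared per-allele frequency differences ). For biallelic loci the inner
#' two-allele sum is 2 (q_x - q_y)^2, so MRD = sqrt(mean((q_x - q_y)^2)),
#' bounded in [0, 1] with 1 attained when every locus is fixed for opposite
#' alleles.
#'
#' @param freqX,freqY alternate-allele frequency vectors aligned on the same
#'   loci
#' @return MRD in [0, 1]
#' @export
mrd <- function(freqX, freqY) {
    ok <- !is.na(freqX) & !is.na(freqY)
    if (!any(ok)) stop("mrd: no pairwise-complete loci")
    sqrt(mean((freqX[ok] - freqY[ok])^2))
}

#' All pairwise modified Rogers distances of a frequency table
#'
#' Distances use pairwise-complete loci; the per-pair locus count is
#' recorded. The complete-data case is computed with one matrix product.
#'
#' @param ft an \linkS4class{AccessionFrequencyTable}, or a loci x samples
#'   frequency matrix
#' @return an \linkS4class{MRDMatrix}
#' @export
mrdMatrix <- function(ft) {
    f <- if (is(ft, "AccessionFrequencyTable")) freqMat(ft) else as.matrix(ft)
    k <- ncol(f); L <- nrow(f)
    if (!anyNA(f)) {
        d <- as.matrix(dist(t(f))) / sqrt(L)
        nl <- matrix(L, k, k, dimnames = dimnames(d))
    } else {
        W <- !is.na(f)
        F0 <- f; F0[!W] <- 0
        sq <- F0^2
        nl <- crossprod(W)                      # pairwise-complete loci
        ss <- crossprod(sq, W) + crossprod(W, sq) - 2 * crossprod(F0)
        d <- sqrt(pmax(ss, 0) / nl)
        d[nl == 0] <- NA_real_
        dimnames(d) <- dimnames(nl) <- list(colnames(f), colnames(f))
    }
    diag(d) <- 0
    d <- (d + t(d)) / 2                          # kill fp asymmetry
    new("MRDMatrix", mrd = d, nLociUsed = nl)
}

#' Cross-strategy MRD per accession
#'
#' For accessions present in both tables, the MRD between the two versions
#' of the same accession, on the loci non-missing in both.
#'
#' @param tableA,tableB \linkS4class{AccessionFrequencyTable}s (or loci x
#'   accessions matrices) sharing accession ids
#' @return data.frame: accession, mrd, n_loci
#' @export
mrdCross <- function(tableA, tableB) {
    fa <- if (is(tableA, "AccessionFrequencyTable")) freqMat(tableA)
          else as.matrix(tableA)
    fb <- if (is(tableB, "AccessionFrequencyTable")) freqMat(tableB)
          else as.matrix(tableB)
    accs <- intersect(colnames(fa), colnames(fb))
    loci <- intersect(rownames(fa), rownames(fb))
    if (!length(accs) || !length(loci))
        stop("mrdCross: no common accessions or loci")
    do.call(rbind, lapply(accs, function(a) {
        x <- fa[loci, a]; y <- fb[loci, a]
        ok <- !is.na(x) & !is.na(y)
        data.frame(accession = a,
                   mrd = if (any(ok)) mrd(x, y) else NA_real_,
                   n_loci = sum(ok), stringsAsFactors = FALSE)
    }))
}
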