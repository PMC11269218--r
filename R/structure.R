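## Population-structure analyses on a distance matrix or frequency table:
## classical-scaling PCoA, complete-linkage clustering with a deterministic
## label order, and locus-bootstrap node support counted on unrooted
## bipartitions.

.distInput <- function(D) {
    if (is(D, "MRDMatrix")) D <- as.matrix(D)
    if (inherits(D, "dist")) D <- as.matrix(D)
    if (!is.matrix(D) || nrow(D) != ncol(D) ||
        !isSymmetric(unname(D), tol = 1e-8))
        stop("a symmetric square distance matrix is required")
    if (is.null(rownames(D)))
        dimnames(D) <- list(paste0("s", seq_len(nrow(D))),
                            paste0("s", seq_len(nrow(D))))
    D
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centres -D^2/2, eigendecomposes, and scales the eigenvectors by the
#' square roots of the positive eigenvalues. Explained-variance fractions are
#' taken over the positive eigenvalues; negative eigenvalues (non-Euclidean
#' distances) are reported and their axes dropped.
#'
#' @param D an \linkS4class{MRDMatrix}, \code{dist} or symmetric matrix
#' @param k number of axes to return (default 2)
#' @return list of class \code{"pcoaResult"}: \code{coordinates}
#'   (samples x k), \code{explained} (fraction per retained axis) and
#'   \code{eigenvalues} (all, including negatives)
#' @export
pcoa <- function(D, k = 2) {
    D <- .distInput(D)
    n <- nrow(D)
    k <- min(k, n - 1)
    sc <- cmdscale(as.dist(D), k = k, eig = TRUE)
    eig <- sc$eig
    pos <- eig[eig > sqrt(.Machine$double.eps) * max(abs(eig))]
    coords <- sc$points
    keep <- min(ncol(coords), length(pos))
    coords <- coords[, seq_len(keep), drop = FALSE]
    colnames(coords) <- paste0("Axis", seq_len(keep))
    structure(list(coordinates = coords,
                   explained = pos[seq_len(keep)] / sum(pos),
                   eigenvalues = eig),
              class = "pcoaResult")
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering by maximum inter-cluster distance. Labels are
#' put in lexicographic order before merging so that distance ties are
#' broken deterministically.
#'
#' @param D an \linkS4class{MRDMatrix}, \code{dist} or symmetric matrix
#' @return an \code{hclust} object
#' @export
completeLinkage <- function(D) {
    D <- .distInput(D)
    ord <- order(rownames(D))
    hclust(as.dist(D[ord, ord]), method = "complete")
}

#' Locus-bootstrap support for dendrogram nodes
#'
#' Resamples loci with replacement B times, rebuilds the MRD matrix and the
#' complete-linkage dendrogram, and scores each internal node of the
#' reference dendrogram by the percentage of replicates containing the same
#' bipartition of labels (trees compared unrooted).
#'
#' @param ft an \linkS4class{AccessionFrequencyTable} or loci x samples
#'   frequency matrix with >= 2 loci
#' @param B number of bootstrap replicates (default 1000)
#' @param seed integer seed for the resample indices
#' @return list: \code{hclust} (reference tree), \code{phylo} (as unrooted
#'   ape tree), \code{support} (percentage per internal node, in
#'   \code{phylo} node order)
#' @export
bootstrapSupport <- function(ft, B = 1000, seed = 1) {
    if (B < 1) stop("B must be >= 1")
    f <- if (is(ft, "AccessionFrequencyTable")) freqMat(ft) else as.matrix(ft)
    if (nrow(f) < 2) stop("bootstrapSupport needs >= 2 loci")
    ref <- completeLinkage(mrdMatrix(f))
    phy <- ape::as.phylo(ref)
    idx <- withr::with_seed(seed,
        matrix(sample.int(nrow(f), nrow(f) * B, replace = TRUE), ncol = B))
    bootTrees <- lapply(seq_len(B), function(b)
        ape::as.phylo(completeLinkage(mrdMatrix(f[idx[, b], , drop = FALSE]))))
    class(bootTrees) <- "multiPhylo"
    cnt <- ape::prop.clades(phy, bootTrees, rooted = FALSE)
    cnt[is.na(cnt)] <- 0
    list(hclust = ref, phylo = phy, support = 100 * cnt / B)
}

#' Support for a specific bipartition of the labels
#'
#' Convenience for checking e.g. the two-gene-pool split: the percentage of
#' an existing bootstrap result's replicates is looked up for the reference
#' node whose descendant tip set equals \code{labels} (or its complement).
#'
#' @param boot result of \code{\link{bootstrapSupport}}
#' @param labels character vector, one side of the bipartition
#' @return support percentage, or \code{NA} if the reference tree does not
#'   contain that bipartition
#' @export
bipartitionSupport <- function(boot, labels) {
    phy <- boot$phylo
    tips <- phy$tip.label
    other <- setdiff(tips, labels)
    bp <- ape::prop.part(phy)
    target <- sort(match(labels, tips))
    targetC <- sort(match(other, tips))
    for (i in seq_along(bp)) {
        s <- sort(bp[[i]])
        if (identical(s, target) || identical(s, targetC))
            return(boot$support[i])
    }
    NA_real_
}
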