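## Allele-frequency estimation under both pooling strategies and
## between-pool agreement: shared loci, private / fixed alleles with a
## quasi-Poisson analysis of deviance, AFD, and replicate concordance by
## read depth.

#' Naive pooled allele frequency from read counts
#'
#' The pool-seq estimator: q = alternate reads / total reads per locus and
#' pool sample; zero total reads gives a missing cell. Technical replicates
#' are collapsed per accession with the first replicate by default
#' (\code{collapse = "average"} averages the replicate frequencies;
#' \code{"none"} keeps one column per pool sample).
#'
#' @param counts a \linkS4class{ReadCountTable} of seq-pool samples
#' @param sheet a sample sheet mapping pool samples to accessions
#' @param collapse \code{"first"}, \code{"average"} or \code{"none"}
#' @return an \linkS4class{AccessionFrequencyTable} (provenance
#'   \code{"pooled_reads"}); support is the total read count per cell
#' @export
pooledFreqFromReads <- function(counts, sheet,
                                collapse = c("first", "average", "none")) {
    collapse <- match.arg(collapse)
    sheet <- validateSampleSheet(sheet)
    pools <- sheet[sheet$sample_type == "seq_pool" &
                   sheet$sample_id %in% colnames(counts), , drop = FALSE]
    if (!nrow(pools)) stop("no seq_pool samples found in the counts table")
    ref <- refReads(counts)[, pools$sample_id, drop = FALSE]
    alt <- altReads(counts)[, pools$sample_id, drop = FALSE]
    tot <- ref + alt
    q <- alt / tot
    q[tot == 0] <- NA_real_
    if (collapse == "none")
        return(AccessionFrequencyTable(q, tot, "pooled_reads"))
    accIds <- unique(pools$accession_id)
    qa <- matrix(NA_real_, nrow(q), length(accIds),
                 dimnames = list(rownames(q), accIds))
    sa <- qa
    for (a in accIds) {
        cols <- which(pools$accession_id == a)
        if (collapse == "first" || length(cols) == 1) {
            qa[, a] <- q[, cols[1]]
            sa[, a] <- tot[, cols[1]]
        } else {
            qs <- q[, cols, drop = FALSE]
            qa[, a] <- rowMeans(qs, na.rm = TRUE)
            qa[is.nan(qa[, a]), a] <- NA_real_
            sa[, a] <- rowSums(tot[, cols, drop = FALSE] *
                               !is.na(qs))
        }
    }
    AccessionFrequencyTable(qa, sa, "pooled_reads")
}

#' Genotype-based accession allele frequencies (in-silico pool)
#'
#' Per accession and locus, the reference-allele frequency is
#' p = f(AA) + f(AB)/2 over the non-missing individuals, equivalently
#' q = 1 - p = mean(calls)/2 with the alternate-allele-count coding. Cells
#' with no non-missing call are missing; support is the non-missing count.
#'
#' @param ds a \linkS4class{GenotypeDataset} of individuals with accession
#'   grouping set
#' @return an \linkS4class{AccessionFrequencyTable} (provenance
#'   \code{"genotype_based"})
#' @export
genotypeFreq <- function(ds) {
    acc <- colData(ds)$accession_id
    if (all(is.na(acc))) stop("dataset has no accession grouping")
    accIds <- unique(acc[!is.na(acc)])
    m <- calls(ds)
    q <- matrix(NA_real_, nrow(m), length(accIds),
                dimnames = list(rownames(m), accIds))
    s <- q
    for (a in accIds) {
        sub <- m[, which(acc == a), drop = FALSE]
        n <- rowSums(!is.na(sub))
        qa <- rowSums(sub, na.rm = TRUE) / (2 * n)
        qa[n == 0] <- NA_real_
        q[, a] <- qa
        s[, a] <- n
    }
    s[s == 0] <- NA_real_
    AccessionFrequencyTable(q, s, "genotype_based")
}

#' Loci shared between two frequency tables
#'
#' The intersection of the loci present (non-missing in at least one
#' accession) in each table, keyed by allele id.
#'
#' @param tableA,tableB \linkS4class{AccessionFrequencyTable}s
#' @return character vector of shared allele ids
#' @export
sharedLoci <- function(tableA, tableB) {
    presA <- rownames(freqMat(tableA))[rowSums(!is.na(freqMat(tableA))) > 0]
    presB <- rownames(freqMat(tableB))[rowSums(!is.na(freqMat(tableB))) > 0]
    intersect(presA, presB)
}

#' Private and fixed alleles between two versions of one accession
#'
#' On loci non-missing in both vectors: an allele is private to A when it is
#' present in A (segregating or fixed) but wholly absent in B, i.e. B is
#' monomorphic for the other allele; a fixed difference is a locus where the
#' two versions are fixed for opposite alleles. The categories are disjoint:
#' fixed differences are not also counted as private.
#'
#' @param freqA,freqB alternate-allele frequency vectors of the same
#'   accession under two strategies, aligned on the same loci
#' @return list with counts \code{private_a}, \code{private_b}, \code{fixed}
#'   and \code{shared_loci} (number of loci compared)
#' @export
privateAndFixed <- function(freqA, freqB) {
    ok <- !is.na(freqA) & !is.na(freqB)
    qa <- freqA[ok]; qb <- freqB[ok]
    fixed <- (qa == 1 & qb == 0) | (qa == 0 & qb == 1)
    privA <- (((qa > 0 & qb == 0) | (qa < 1 & qb == 1)) & !fixed)
    privB <- (((qb > 0 & qa == 0) | (qb < 1 & qa == 1)) & !fixed)
    list(private_a = sum(privA), private_b = sum(privB),
         fixed = sum(fixed), shared_loci = sum(ok))
}

#' Allele frequency difference (AFD) between two frequency vectors
#'
#' For biallelic loci the half-sum of absolute per-allele frequency
#' differences reduces to |q_A - q_B| per locus; AFD is its mean over the
#' shared (pairwise non-missing) loci and lies in [0, 1].
#'
#' @param freqA,freqB alternate-allele frequency vectors aligned on the same
#'   loci
#' @return AFD in [0, 1]
#' @export
afd <- function(freqA, freqB) {
    ok <- !is.na(freqA) & !is.na(freqB)
    if (!any(ok)) stop("afd: no shared non-missing loci")
    mean(abs(freqA[ok] - freqB[ok]))
}

#' Per-accession agreement between two frequency tables
#'
#' For each accession present in both tables, counts shared loci, private
#' alleles on each side, fixed differences, and the AFD, all restricted to
#' loci non-missing in both tables for that accession.
#'
#' @param tableA,tableB \linkS4class{AccessionFrequencyTable}s with a common
#'   accession space
#' @return data.frame with one row per accession
#' @export
poolAgreement <- function(tableA, tableB) {
    accs <- intersect(accessionIds(tableA), accessionIds(tableB))
    if (!length(accs)) stop("no common accessions between tables")
    loci <- intersect(rownames(freqMat(tableA)), rownames(freqMat(tableB)))
    fa <- freqMat(tableA)[loci, accs, drop = FALSE]
    fb <- freqMat(tableB)[loci, accs, drop = FALSE]
    rows <- lapply(accs, function(a) {
        pf <- privateAndFixed(fa[, a], fb[, a])
        data.frame(accession = a, shared_loci = pf$shared_loci,
                   private_a = pf$private_a, private_b = pf$private_b,
                   fixed = pf$fixed,
                   afd = if (pf$shared_loci > 0) afd(fa[, a], fb[, a])
                         else NA_real_,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Quasi-Poisson one-factor model with analysis-of-deviance F test
#'
#' Fits counts ~ group with a log link and quasi-Poisson variance
#' (dispersion = Pearson chi-squared / residual df), then tests the group
#' effect with an analysis-of-deviance F test. Back-transformed group means
#' equal the arithmetic group means (the closed-form MLE of the saturated
#' one-factor log-linear model).
#'
#' @param counts non-negative integer vector (e.g. private-allele counts)
#' @param groups factor or character vector of the same length with >= 2
#'   levels and >= 2 observations per level
#' @return list of class \code{"quasiPoissonFit"}: \code{means} (response
#'   scale, per group), \code{dispersion}, \code{fStatistic}, \code{df} (the
#'   numerator/denominator degrees of freedom), \code{pValue} and the
#'   underlying \code{fit}
#' @export
quasipoissonAnodev <- function(counts, groups) {
    groups <- factor(groups)
    if (nlevels(groups) < 2) stop("need at least two groups")
    if (any(table(groups) < 2)) stop("each group needs >= 2 observations")
    if (any(counts < 0)) stop("counts must be non-negative")
    gm <- tapply(counts, groups, mean)
    if (any(gm == 0))
        stop("group(s) with all-zero counts: log-link mean 0 is not ",
             "representable")
    fit <- glm(counts ~ groups, family = quasipoisson(),
               control = list(epsilon = 1e-12, maxit = 50))
    disp <- summary(fit)$dispersion
    an <- car::Anova(fit, test.statistic = "F")
    fCol <- grep("^F", colnames(an), value = TRUE)[1]
    pCol <- grep("^Pr", colnames(an), value = TRUE)[1]
    nd <- data.frame(groups = factor(levels(groups), levels(groups)))
    means <- setNames(as.numeric(predict(fit, nd, type = "response")),
                      levels(groups))
    structure(list(means = means, dispersion = disp,
                   fStatistic = an[[fCol]][1],
                   df = c(an[["Df"]][1], fit$df.residual),
                   pValue = an[[pCol]][1], fit = fit),
              class = "quasiPoissonFit")
}

#' @export
print.quasiPoissonFit <- function(x, ...) {
    cat("Quasi-Poisson one-factor fit\n")
    cat("  group means:",
        paste(names(x$means), round(x$means, 3), sep = "=",
              collapse = ", "), "\n")
    cat(sprintf("  dispersion = %.3f, F(%d, %d) = %.3f, p = %.3g\n",
                x$dispersion, x$df[1], x$df[2], x$fStatistic, x$pValue))
    invisible(x)
}

#' Replicate concordance of pooled frequencies by read depth
#'
#' For each technical replicate pair, the per-locus discrepancy is the
#' absolute difference of the two naive frequency estimates; the locus is
#' assigned to a depth bin by the average total depth across the pair.
#' Summaries pool loci across all replicate pairs.
#'
#' @param counts a \linkS4class{ReadCountTable}
#' @param sheet a sample sheet with \code{replicate_group} set for pools
#' @param binEdges depth bin edges (default \code{c(0, 20, Inf)}, the
#'   below/above-20-reads split)
#' @return data.frame with one row per depth bin: locus count, mean, median
#'   and 90th percentile of |q1 - q2|, and the mean depth
#' @export
replicateConcordanceByDepth <- function(counts, sheet,
                                        binEdges = c(0, 20, Inf)) {
    groups <- linkReplicates(sheet)
    groups <- groups[vapply(groups, length, integer(1)) >= 2]
    groups <- lapply(groups, intersect, colnames(counts))
    groups <- groups[vapply(groups, length, integer(1)) >= 2]
    if (!length(groups)) stop("no replicate groups with >= 2 pool samples")
    ref <- refReads(counts); alt <- altReads(counts)
    tot <- ref + alt
    q <- alt / tot; q[tot == 0] <- NA_real_
    depth <- numeric(0); disc <- numeric(0)
    for (g in groups) {
        d <- (tot[, g[1]] + tot[, g[2]]) / 2
        dd <- abs(q[, g[1]] - q[, g[2]])
        ok <- !is.na(dd)
        depth <- c(depth, d[ok]); disc <- c(disc, dd[ok])
    }
    bin <- cut(depth, binEdges, include.lowest = TRUE, right = FALSE)
    out <- do.call(rbind, lapply(levels(bin), function(b) {
        sel <- which(bin == b)
        data.frame(bin = b, n_loci = length(sel),
                   mean_depth = if (length(sel)) mean(depth[sel])
                                else NA_real_,
                   mean_abs_diff = if (length(sel)) mean(disc[sel])
                                   else NA_real_,
                   median_abs_diff = if (length(sel))
                       unname(median(disc[sel])) else NA_real_,
                   q90_abs_diff = if (length(sel))
                       unname(quantile(disc[sel], 0.9)) else NA_real_,
                   stringsAsFactors = FALSE, row.names = NULL)
    }))
    rownames(out) <- NULL
    out
}
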