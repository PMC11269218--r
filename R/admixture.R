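## Admixture estimation by binomial cross-entropy NMF. Observed genotypes
## scaled to [0, 1] (calls / 2) are modelled as Q %*% G with Q rows on the
## probability simplex (per-sample ancestry proportions) and G in [0, 1]
## (ancestral allele frequencies). Fitting is alternating projected gradient
## with backtracking, so the objective is non-increasing by construction. K
## is selected by masked (held-out) cross-entropy, averaged over repetitions;
## this keeps the cross-entropy model-selection contract of sparse-NMF
## admixture tools without re-implementing any of them.

.EPS <- 1e-6

.projectSimplexRows <- function(Q) {
    ## Euclidean projection of each row onto the probability simplex
    K <- ncol(Q)
    if (K == 1) return(matrix(1, nrow(Q), 1))
    t(apply(Q, 1, function(v) {
        u <- sort(v, decreasing = TRUE)
        css <- cumsum(u)
        rho <- max(which(u + (1 - css) / seq_len(K) > 0))
        theta <- (1 - css[rho]) / rho
        pmax(v + theta, 0)
    }))
}

.crossEntropy <- function(X, P, W) {
    ## mean negative binomial log-likelihood per observed entry
    P <- pmin(pmax(P, .EPS), 1 - .EPS)
    -sum((X * log(P) + (1 - X) * log(1 - P))[W], na.rm = TRUE) / sum(W)
}

.nmfFit <- function(X, W, K, maxIter = 200, tol = 1e-7, seed = 1,
                    gMin = 1e-3) {
    ## gMin bounds ancestral frequencies away from 0/1 (pseudo-count
    ## regularisation), so a held-out genotype can never incur unbounded
    ## cross-entropy
    n <- nrow(X); L <- ncol(X)
    X0 <- X; X0[!W] <- 0                         # masked entries contribute 0
    withr::with_seed(seed, {
        Q <- .projectSimplexRows(matrix(runif(n * K, 0.2, 0.8), n, K))
        G <- matrix(runif(L * K, 0.2, 0.8), K, L)
    })
    obj <- .crossEntropy(X0, Q %*% G, W)
    trace <- obj
    stepQ <- 1; stepG <- 1
    gradP <- function(P) {
        P <- pmin(pmax(P, .EPS), 1 - .EPS)
        D <- -(X0 / P - (1 - X0) / (1 - P))
        D[!W] <- 0
        D / sum(W)
    }
    for (it in seq_len(maxIter)) {
        ## Q update
        D <- gradP(Q %*% G)
        gQ <- D %*% t(G)
        stepQ <- stepQ * 2
        repeat {
            Qn <- .projectSimplexRows(Q - stepQ * gQ)
            objN <- .crossEntropy(X0, Qn %*% G, W)
            if (objN <= obj || stepQ < 1e-12) break
            stepQ <- stepQ / 2
        }
        if (objN <= obj) { Q <- Qn; obj <- objN }
        ## G update
        D <- gradP(Q %*% G)
        gG <- t(Q) %*% D
        stepG <- stepG * 2
        repeat {
            Gn <- pmin(pmax(G - stepG * gG, gMin), 1 - gMin)
            objN <- .crossEntropy(X0, Q %*% Gn, W)
            if (objN <= obj || stepG < 1e-12) break
            stepG <- stepG / 2
        }
        if (objN <= obj) { G <- Gn; obj <- objN }
        trace <- c(trace, obj)
        nT <- length(trace)
        if (nT > 5 && trace[nT - 1] - trace[nT] < tol * max(1, trace[nT]))
            break
    }
    list(Q = Q, G = G, objective = obj, trace = trace)
}

#' Admixture coefficients by masked cross-entropy NMF
#'
#' Factorises scaled genotypes (calls / 2, values in [0, 1], NA = missing)
#' as Q \%*\% G under a binomial cross-entropy loss, with per-sample ancestry
#' rows of Q on the probability simplex and ancestral frequencies G in
#' [0, 1]. For each K a \code{maskedFraction} of the observed entries is
#' held out and the fitted model scored by cross-entropy on the held-out
#' entries, averaged over \code{repetitions}; the selected K is the argmin
#' (ties go to the smallest K). A plateau K (first K whose improvement over
#' K-1 falls below 1\% of the entropy range) is reported alongside.
#'
#' @param x samples x loci matrix with values in [0, 1] (scale genotype
#'   calls by 1/2), NA allowed
#' @param K integer vector of candidate numbers of ancestral populations
#' @param maskedFraction fraction of observed entries held out per
#'   repetition (default 0.05)
#' @param repetitions masked repetitions per K (default 5)
#' @param maxIter projected-gradient iterations per fit (default 200)
#' @param seed integer seed
#' @return list of class \code{"admixtureResult"}: \code{Q}
#'   (samples x selectedK), \code{G} (selectedK x loci),
#'   \code{crossEntropy} (repetitions x K matrix of masked cross-entropies),
#'   \code{selectedK}, \code{plateauK}, \code{objectiveTrace} of the final
#'   fit
#' @export
admixtureNMF <- function(x, K = 1:5, maskedFraction = 0.05, repetitions = 5,
                         maxIter = 200, seed = 1) {
    x <- as.matrix(x)
    if (!length(K)) stop("K range is empty")
    K <- sort(unique(as.integer(K)))
    if (any(x < 0 | x > 1, na.rm = TRUE))
        stop("x must be scaled to [0, 1] (genotype calls / 2)")
    allMiss <- colSums(!is.na(x)) == 0
    if (any(allMiss)) {
        warning(sum(allMiss), " all-missing loci dropped")
        x <- x[, !allMiss, drop = FALSE]
    }
    obs <- !is.na(x)
    obsIdx <- which(obs)
    gMin <- 1 / (2 * nrow(x) + 2)       # pseudo-count frequency floor
    ce <- matrix(NA_real_, repetitions, length(K),
                 dimnames = list(NULL, paste0("K", K)))
    nMask <- max(1L, round(maskedFraction * length(obsIdx)))
    for (r in seq_len(repetitions)) {
        masked <- withr::with_seed(seed + 1000L * r,
                                   sample(obsIdx, nMask))
        Wtrain <- obs; Wtrain[masked] <- FALSE
        Wtest <- matrix(FALSE, nrow(x), ncol(x)); Wtest[masked] <- TRUE
        for (j in seq_along(K)) {
            fit <- .nmfFit(ifelse(obs, x, 0), Wtrain, K[j],
                           maxIter = maxIter, seed = seed + 17L * r + K[j],
                           gMin = gMin)
            ce[r, j] <- .crossEntropy(ifelse(obs, x, 0),
                                      fit$Q %*% fit$G, Wtest)
        }
    }
    meanCe <- colMeans(ce)
    selectedK <- K[which.min(meanCe)]
    plateauK <- K[1]
    if (length(K) > 1) {
        drops <- -diff(meanCe)
        rng <- max(meanCe) - min(meanCe)
        below <- which(drops < 0.01 * max(rng, .EPS))
        plateauK <- if (length(below)) K[min(below)] else K[length(K)]
    }
    final <- .nmfFit(ifelse(obs, x, 0), obs, selectedK,
                     maxIter = maxIter, seed = seed, gMin = gMin)
    rownames(final$Q) <- rownames(x)
    colnames(final$G) <- colnames(x)
    structure(list(Q = final$Q, G = final$G, crossEntropy = ce,
                   selectedK = selectedK, plateauK = plateauK,
                   objectiveTrace = final$trace),
              class = "admixtureResult")
}

#' @export
print.admixtureResult <- function(x, ...) {
    cat("Admixture (cross-entropy NMF): selected K =", x$selectedK,
        "(plateau at K =", x$plateauK, ")\n")
    cat("  mean masked cross-entropy:",
        paste(colnames(x$crossEntropy),
              round(colMeans(x$crossEntropy), 4), sep = "=",
              collapse = ", "), "\n")
    invisible(x)
}

#' Ancestry assignment accuracy against a known grouping
#'
#' Hard-assigns each sample to its majority ancestry component and scores
#' agreement with the true grouping, maximised over component relabellings.
#'
#' @param Q samples x K admixture matrix
#' @param truth vector of true group labels, length nrow(Q)
#' @return fraction of correctly assigned samples in [0, 1]
#' @export
ancestryAccuracy <- function(Q, truth) {
    truth <- as.integer(factor(truth))
    hard <- max.col(Q, ties.method = "first")
    K <- ncol(Q)
    perms <- .permutations(seq_len(K))
    best <- 0
    for (p in perms)
        best <- max(best, mean(p[hard] == truth))
    best
}

.permutations <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
        for (rest in .permutations(v[-i]))
            out[[length(out) + 1L]] <- c(v[i], rest)
    out
}
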