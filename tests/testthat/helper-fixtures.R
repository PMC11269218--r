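# Shared fixture builders. All fixtures are built in code; nothing is read
# from disk except files the tests themselves write to tempdir().

# small genotype matrix with dimnames
gmat <- function(values, nLoci, nSamples,
                 loci = sprintf("L%03d", seq_len(nLoci)),
                 samples = sprintf("S%02d", seq_len(nSamples))) {
    matrix(values, nLoci, nSamples, dimnames = list(loci, samples))
}

# a small panel used across tests (cached per session)
smallPanel <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- simulatePanel(syntheticConfig(
                nAccessions = 8, nLoci = 400, nReplicatePools = 3, seed = 42))
        cache
    }
})

# fixture: each enabled filter removes exactly two of ten loci
tenLocusFixture <- function() {
    m <- gmat(NA_real_, 10, 4)
    m[3:10, ] <- rep(c(0, 1, 0, 1), each = 8)      # polymorphic, all called
    m[7, 3:4] <- NA; m[8, 3:4] <- NA               # call rate 0.5
    m[9, ] <- 0; m[10, ] <- 2                      # monomorphic
    lm <- data.frame(rep_avg = c(1, 1, 0.99, 0.98, 1, 1, 1, 1, 1, 1),
                     avg_depth = c(50, 50, 50, 50, 3, 150, 50, 50, 50, 50))
    GenotypeDataset(m, locusMeta = lm)
}

# independent quasi-Poisson oracle: IRLS for the one-factor log-link model,
# Pearson dispersion, analysis-of-deviance F test
qpOracle <- function(counts, groups) {
    groups <- factor(groups)
    X <- stats::model.matrix(~groups)
    beta <- rep(0, ncol(X))
    beta[1] <- log(mean(counts))
    for (it in 1:100) {
        eta <- as.vector(X %*% beta)
        mu <- exp(eta)
        z <- eta + (counts - mu) / mu
        w <- mu
        betaNew <- solve(t(X) %*% (w * X), t(X) %*% (w * z))
        if (max(abs(betaNew - beta)) < 1e-12) { beta <- betaNew; break }
        beta <- betaNew
    }
    mu <- exp(as.vector(X %*% beta))
    dfResid <- length(counts) - ncol(X)
    disp <- sum((counts - mu)^2 / mu) / dfResid
    devFull <- 2 * sum(ifelse(counts > 0, counts * log(counts / mu), 0) -
                       (counts - mu))
    mu0 <- mean(counts)
    dev0 <- 2 * sum(ifelse(counts > 0, counts * log(counts / mu0), 0) -
                    (counts - mu0))
    df1 <- nlevels(groups) - 1
    fStat <- ((dev0 - devFull) / df1) / disp
    means <- exp(tapply(as.vector(X %*% beta), groups, mean))
    list(means = as.vector(tapply(mu, groups, mean)), dispersion = disp,
         fStatistic = fStat, pValue = stats::pf(fStat, df1, dfResid,
                                                lower.tail = FALSE))
}

# brute-force complete linkage: O(n^3) agglomeration on a distance matrix,
# returning merge heights and the leaf partition at every step
clOracle <- function(D) {
    labs <- rownames(D)
    clusters <- as.list(labs)
    heights <- numeric(0)
    merges <- list()
    while (length(clusters) > 1) {
        best <- c(NA, NA); bestD <- Inf
        for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
            d <- max(D[clusters[[i]], clusters[[j]]])
            if (d < bestD) { bestD <- d; best <- c(j, i) }
        }
        merges[[length(merges) + 1]] <-
            sort(c(clusters[[best[1]]], clusters[[best[2]]]))
        heights <- c(heights, bestD)
        clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
        clusters[[best[2]]] <- NULL
    }
    list(heights = heights, merges = merges)
}

# clusters of an hclust at each merge, as sorted label sets
hclustMerges <- function(hc) {
    n <- length(hc$labels)
    members <- vector("list", nrow(hc$merge))
    out <- vector("list", nrow(hc$merge))
    for (k in seq_len(nrow(hc$merge))) {
        get <- function(i) if (i < 0) hc$labels[-i] else members[[i]]
        members[[k]] <- c(get(hc$merge[k, 1]), get(hc$merge[k, 2]))
        out[[k]] <- sort(members[[k]])
    }
    out
}

# Procrustes distance after optimal rotation/reflection/translation/scale
procrustesError <- function(A, B) {
    A <- scale(A, scale = FALSE); B <- scale(B, scale = FALSE)
    s <- svd(t(B) %*% A)
    R <- s$u %*% t(s$v)          # orthogonal map B -> A
    sc <- sum(s$d) / sum(B^2)
    sqrt(sum((A - sc * B %*% R)^2) / nrow(A))
}
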