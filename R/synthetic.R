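## Synthetic DArTseq-style data generator. Emulates a genebank panel drawn
## from two divergent gene pools: accessions are mixtures of a few inbred
## lines, individuals are selfed progeny (occasionally F1 outcrosses between
## lines), pooled-tissue sequencing yields per-locus read counts, and
## individual genotyping yields calls with dropout. A truth ledger (pool
## assignments, line genotypes, true accession frequencies) makes parameter
## recovery testable.

.checkRate <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
        stop(name, " must be a single value in [0, 1]")
}

.rdirichlet <- function(n, alpha) {
    g <- rgamma(n, shape = alpha, rate = 1)
    g / sum(g)
}

#' Configuration of the synthetic panel generator
#'
#' Defaults emulate the study conditions: 44 accessions drawn from 2
#' divergent gene pools, 22-25 mostly inbred plants per accession, half the
#' accessions homogeneous (one inbred line) and half 3-line seed mixtures,
#' negative-binomial locus read depth around 50x, and 8 technically
#' replicated pools (so 52 pool samples for 44 accessions).
#'
#' @param nPools number of ancestral gene pools (default 2)
#' @param fst divergence between gene pools, in (0, 1); the Balding-Nichols
#'   F parameter (default 0.4)
#' @param nAccessions number of accessions (default 44)
#' @param plantsPerAccession integer range c(min, max) of plants grown per
#'   accession (default 22-25)
#' @param nLoci number of biallelic SNP loci (default 5000)
#' @param linesPerAccession integer vector (recycled over accessions) of
#'   inbred lines mixed in each seed lot; 1 = homogeneous. Default
#'   \code{c(1, 3)}: alternating homogeneous / 3-line mixtures.
#' @param residualHetRate per-locus probability that a line is heterozygous
#'   (residual heterozygosity of an inbred; default 0.005)
#' @param outcrossRate per-individual probability of being an F1 between two
#'   lines of the accession (default 0.02; common bean is mostly selfing)
#' @param depthMean,depthDispersion negative-binomial per-locus read depth:
#'   mean and size (dispersion) parameters (defaults 50 and 5)
#' @param missingRate per-call dropout probability for individual genotyping
#'   (default 0.05)
#' @param allelicDropoutRate probability a heterozygous call is miscalled as
#'   a homozygote (default 0)
#' @param dirichletAlpha concentration of per-plant DNA contributions to a
#'   pool; large = even contributions (default 10, moderately uneven)
#' @param nReplicatePools number of accessions whose pool is sequenced twice
#'   (default 8)
#' @param ancestralRange range of the uniform ancestral allele frequency
#'   (default c(0.1, 0.9), symmetric about 0.5)
#' @param seed integer seed for the whole panel
#' @return a validated list of class \code{"syntheticConfig"}
#' @export
syntheticConfig <- function(nPools = 2, fst = 0.4, nAccessions = 44,
                            plantsPerAccession = c(22, 25), nLoci = 5000,
                            linesPerAccession = c(1, 3),
                            residualHetRate = 0.005, outcrossRate = 0.02,
                            depthMean = 50, depthDispersion = 5,
                            missingRate = 0.05, allelicDropoutRate = 0,
                            dirichletAlpha = 10, nReplicatePools = 8,
                            ancestralRange = c(0.1, 0.9), seed = 1) {
    stopifnot(nPools >= 1, nAccessions >= 1, nLoci >= 1,
              all(linesPerAccession >= 1),
              length(plantsPerAccession) %in% c(1, 2),
              depthMean > 0, depthDispersion > 0, dirichletAlpha > 0,
              nReplicatePools >= 0, nReplicatePools <= nAccessions,
              length(ancestralRange) == 2,
              ancestralRange[1] > 0, ancestralRange[2] < 1,
              ancestralRange[1] < ancestralRange[2])
    if (!is.numeric(fst) || fst <= 0 || fst >= 1)
        stop("fst must lie in (0, 1)")
    .checkRate(residualHetRate, "residualHetRate")
    .checkRate(outcrossRate, "outcrossRate")
    .checkRate(missingRate, "missingRate")
    .checkRate(allelicDropoutRate, "allelicDropoutRate")
    if (length(plantsPerAccession) == 1)
        plantsPerAccession <- rep(plantsPerAccession, 2)
    cfg <- list(nPools = nPools, fst = fst, nAccessions = nAccessions,
                plantsPerAccession = plantsPerAccession, nLoci = nLoci,
                linesPerAccession = linesPerAccession,
                residualHetRate = residualHetRate,
                outcrossRate = outcrossRate, depthMean = depthMean,
                depthDispersion = depthDispersion,
                missingRate = missingRate,
                allelicDropoutRate = allelicDropoutRate,
                dirichletAlpha = dirichletAlpha,
                nReplicatePools = nReplicatePools,
                ancestralRange = ancestralRange, seed = as.integer(seed))
    class(cfg) <- "syntheticConfig"
    cfg
}

#' Draw gene-pool allele frequencies (Balding-Nichols model)
#'
#' Per locus, an ancestral frequency p is drawn uniformly on
#' \code{ancestralRange}; each pool's frequency is then drawn from
#' Beta(p(1-F)/F, (1-p)(1-F)/F), so pools have mean p and variance
#' p(1-p)F around it.
#'
#' @param config a \code{\link{syntheticConfig}}
#' @param seed integer seed (defaults to \code{config$seed})
#' @return list with \code{ancestral} (length-nLoci vector) and \code{pools}
#'   (nLoci x nPools matrix)
#' @export
drawPoolFrequencies <- function(config, seed = config$seed) {
    withr::with_seed(seed, {
        p <- runif(config$nLoci, config$ancestralRange[1],
                   config$ancestralRange[2])
        f <- config$fst
        pools <- vapply(seq_len(config$nPools), function(k)
            rbeta(config$nLoci, p * (1 - f) / f, (1 - p) * (1 - f) / f),
            numeric(config$nLoci))
        ## guard against numerically exact 0/1 which would make loci trivially
        ## monomorphic everywhere
        pools <- pmin(pmax(pools, 1e-9), 1 - 1e-9)
        list(ancestral = p, pools = pools)
    })
}

.gamete <- function(g) {
    ## one gamete per locus from a diploid genotype vector in {0,1,2}
    out <- g / 2
    het <- which(g == 1)
    if (length(het)) out[het] <- rbinom(length(het), 1, 0.5)
    out
}

#' Generate one accession: inbred lines and individual plants
#'
#' Lines are homozygous draws from the accession's gene-pool frequencies,
#' heterozygous at a locus with probability \code{residualHetRate}.
#' Individuals are selfed progeny of a uniformly chosen line (heterozygous
#' line loci segregate 1:2:1) or, with probability \code{outcrossRate}, F1s
#' between two distinct lines.
#'
#' @param config a \code{\link{syntheticConfig}}
#' @param poolFreqs length-nLoci vector of the accession's gene-pool
#'   alternate-allele frequencies
#' @param nLines number of lines mixed in the seed lot
#' @param nPlants number of plants grown
#' @param seed integer seed
#' @return list with \code{lines} (nLoci x nLines), \code{genotypes}
#'   (nLoci x nPlants, values in \{0, 1, 2\}), \code{trueFreq} (the
#'   alternate-allele frequency realised in the generated individuals) and
#'   \code{lineOfPlant}
#' @export
generateAccession <- function(config, poolFreqs, nLines, nPlants, seed) {
    if (nLines > nPlants)
        stop("linesPerAccession (", nLines, ") exceeds plants (", nPlants, ")")
    nL <- length(poolFreqs)
    withr::with_seed(seed, {
        lines <- matrix(2 * rbinom(nL * nLines, 1, poolFreqs), nL, nLines)
        het <- matrix(rbinom(nL * nLines, 1, config$residualHetRate) == 1,
                      nL, nLines)
        lines[het] <- 1
        lineOf <- sample.int(nLines, nPlants, replace = TRUE)
        outcross <- nLines > 1 & rbinom(nPlants, 1, config$outcrossRate) == 1
        genotypes <- matrix(0, nL, nPlants)
        for (i in seq_len(nPlants)) {
            if (outcross[i]) {
                par <- sample.int(nLines, 2, replace = FALSE)
                genotypes[, i] <- .gamete(lines[, par[1]]) +
                    .gamete(lines[, par[2]])
            } else {
                g <- lines[, lineOf[i]]
                gi <- g
                hetIdx <- which(g == 1)
                if (length(hetIdx))
                    gi[hetIdx] <- rbinom(length(hetIdx), 2, 0.5)
                genotypes[, i] <- gi
            }
        }
        list(lines = lines, genotypes = genotypes,
             trueFreq = rowMeans(genotypes) / 2,
             lineOfPlant = lineOf)
    })
}

#' Sequence a tissue pool: per-locus read counts with technical replicates
#'
#' Plant DNA contributions are Dirichlet-weighted (one draw per pool; large
#' \code{dirichletAlpha} = even contributions). Per locus, the pool's
#' alternate-read probability is the contribution-weighted mean of the
#' plants' allele doses. Locus depth is gamma-Poisson: a per-locus
#' representation factor (gamma with shape and rate
#' \code{depthDispersion}, a property of the restriction fragment shared by
#' every sample and replicate of a panel) multiplies \code{depthMean}, and
#' realised depth is Poisson around it, so depth is marginally
#' negative-binomial. Alternate reads are binomial given depth. Technical
#' replicates share the DNA pool (same weights) and the locus factors and
#' differ only in the sequencing draws. Loci with zero depth are missing.
#'
#' @param genotypes nLoci x nPlants matrix in \{0, 1, 2\}
#' @param config a \code{\link{syntheticConfig}}
#' @param seed integer seed
#' @param nReplicates number of technical replicates to sequence (default 1)
#' @param depthFactor optional length-nLoci vector of per-locus
#'   representation factors (drawn internally when NULL)
#' @return list with matrices \code{ref} and \code{alt}
#'   (nLoci x nReplicates), the weighted true frequency \code{qw} and the
#'   \code{depthFactor} used
#' @export
sequencePool <- function(genotypes, config, seed, nReplicates = 1,
                         depthFactor = NULL) {
    stopifnot(ncol(genotypes) >= 1, nReplicates >= 1)
    nL <- nrow(genotypes)
    withr::with_seed(seed, {
        if (is.null(depthFactor))
            depthFactor <- rgamma(nL, shape = config$depthDispersion,
                                  rate = config$depthDispersion)
        w <- .rdirichlet(ncol(genotypes), config$dirichletAlpha)
        qw <- pmin(pmax(as.vector(genotypes %*% w) / 2, 0), 1)
        alt <- ref <- matrix(0, nL, nReplicates)
        for (r in seq_len(nReplicates)) {
            depth <- stats::rpois(nL, config$depthMean * depthFactor)
            a <- rbinom(nL, depth, qw)
            alt[, r] <- a
            ref[, r] <- depth - a
        }
        list(ref = ref, alt = alt, qw = qw, depthFactor = depthFactor)
    })
}

#' Genotype individual plants: calls with dropout and locus metadata
#'
#' Applies per-call dropout at \code{missingRate}; optionally miscalls
#' heterozygotes as a random homozygote at \code{allelicDropoutRate}
#' (allelic dropout at low depth). Locus metadata are filled: \code{rep_avg}
#' is 1 for most loci with a tail above 0.95, \code{avg_depth} is
#' \code{depthMean} times the per-locus representation factor (the
#' marker-level average depth a provider would report), and \code{callrate}
#' is computed from the realised calls.
#'
#' @param genotypes nLoci x nPlants truth matrix in \{0, 1, 2\}
#' @param config a \code{\link{syntheticConfig}}
#' @param seed integer seed
#' @param sampleIds,alleleIds dimension names for the resulting dataset
#' @param depthFactor optional length-nLoci vector of per-locus
#'   representation factors (drawn internally when NULL)
#' @return a \linkS4class{GenotypeDataset}
#' @export
genotypeIndividuals <- function(genotypes, config, seed,
                                sampleIds = NULL, alleleIds = NULL,
                                depthFactor = NULL) {
    nL <- nrow(genotypes); nS <- ncol(genotypes)
    if (is.null(alleleIds)) alleleIds <- sprintf("L%05d", seq_len(nL))
    if (is.null(sampleIds)) sampleIds <- sprintf("S%04d", seq_len(nS))
    withr::with_seed(seed, {
        callsM <- genotypes
        if (config$allelicDropoutRate > 0) {
            hetIdx <- which(callsM == 1)
            drop <- hetIdx[rbinom(length(hetIdx), 1,
                                  config$allelicDropoutRate) == 1]
            if (length(drop))
                callsM[drop] <- 2 * rbinom(length(drop), 1, 0.5)
        }
        if (config$missingRate > 0) {
            miss <- matrix(rbinom(nL * nS, 1, config$missingRate) == 1,
                           nL, nS)
            callsM[miss] <- NA_real_
        }
        dimnames(callsM) <- list(alleleIds, sampleIds)
        repAvg <- ifelse(runif(nL) < 0.9, 1, runif(nL, 0.95, 1))
        if (is.null(depthFactor))
            depthFactor <- rgamma(nL, shape = config$depthDispersion,
                                  rate = config$depthDispersion)
        avgDepth <- config$depthMean * depthFactor
        GenotypeDataset(callsM,
                        locusMeta = data.frame(rep_avg = repAvg,
                                               avg_depth = avgDepth))
    })
}

#' Call pool genotypes from read counts
#'
#' Reference-free calling as a marker pipeline would report a pooled sample:
#' only reference reads = homozygous reference (0), only alternate reads =
#' homozygous alternate (2), both alleles seen = heterozygous (1), zero
#' depth = missing.
#'
#' @param ct a \linkS4class{ReadCountTable}
#' @return loci x samples calls matrix in \{0, 1, 2, NA\}
#' @export
callsFromCounts <- function(ct) {
    ref <- refReads(ct); alt <- altReads(ct)
    m <- matrix(NA_real_, nrow(ref), ncol(ref), dimnames = dimnames(ref))
    m[ref > 0 & alt == 0] <- 0
    m[ref == 0 & alt > 0] <- 2
    m[ref > 0 & alt > 0] <- 1
    m
}

#' Generate a full synthetic panel with its truth ledger
#'
#' Accessions are assigned in equal halves to the gene pools; lines, plants,
#' pooled read counts (with technical replicates for the first
#' \code{nReplicatePools} accessions), individual genotype calls and pool
#' genotype calls are generated per the configuration. With a fixed seed the
#' panel is bit-reproducible.
#'
#' @param config a \code{\link{syntheticConfig}}
#' @return list with \code{individuals} (\linkS4class{GenotypeDataset}),
#'   \code{poolCounts} (\linkS4class{ReadCountTable}), \code{poolCalls}
#'   (\linkS4class{GenotypeDataset} of the pool samples), \code{sheet}
#'   (sample sheet for all samples) and \code{truth} (pool assignment, true
#'   accession frequency matrix, line genotypes, pool-weighted frequencies)
#' @export
simulatePanel <- function(config) {
    pf <- drawPoolFrequencies(config, config$seed)
    nAcc <- config$nAccessions
    accIds <- sprintf("ACC%03d", seq_len(nAcc))
    alleleIds <- sprintf("L%05d", seq_len(config$nLoci))
    poolOf <- rep(seq_len(config$nPools), length.out = nAcc)
    poolOf <- sort(poolOf)                      # first half pool 1, etc.
    nLines <- rep(config$linesPerAccession, length.out = nAcc)
    withr::with_seed(config$seed + 1L, {
        nPlants <- sample(config$plantsPerAccession[1]:
                          config$plantsPerAccession[2], nAcc, replace = TRUE)
        depthFactor <- rgamma(config$nLoci,
                              shape = config$depthDispersion,
                              rate = config$depthDispersion)
    })
    replicated <- seq_len(config$nReplicatePools)

    genoList <- vector("list", nAcc)
    trueFreq <- matrix(NA_real_, config$nLoci, nAcc,
                       dimnames = list(alleleIds, accIds))
    qwMat <- trueFreq
    lineGenotypes <- vector("list", nAcc); names(lineGenotypes) <- accIds
    refL <- list(); altL <- list(); poolSampleIds <- character()
    poolAcc <- character(); poolRepGrp <- character()

    for (a in seq_len(nAcc)) {
        acc <- generateAccession(config, pf$pools[, poolOf[a]],
                                 nLines[a], nPlants[a],
                                 seed = config$seed + 100L + a)
        genoList[[a]] <- acc$genotypes
        trueFreq[, a] <- acc$trueFreq
        lineGenotypes[[a]] <- acc$lines
        nRep <- if (a %in% replicated) 2L else 1L
        sq <- sequencePool(acc$genotypes, config,
                           seed = config$seed + 5000L + a,
                           nReplicates = nRep, depthFactor = depthFactor)
        qwMat[, a] <- sq$qw
        for (r in seq_len(nRep)) {
            refL[[length(refL) + 1L]] <- sq$ref[, r]
            altL[[length(altL) + 1L]] <- sq$alt[, r]
            poolSampleIds <- c(poolSampleIds,
                               paste0(accIds[a], "_pool",
                                      if (r > 1) paste0("R", r) else ""))
            poolAcc <- c(poolAcc, accIds[a])
            poolRepGrp <- c(poolRepGrp, accIds[a])
        }
    }

    allGeno <- do.call(cbind, genoList)
    indivIds <- unlist(lapply(seq_len(nAcc), function(a)
        sprintf("%s_P%02d", accIds[a], seq_len(nPlants[a]))))
    indivAcc <- rep(accIds, nPlants)
    dimnames(allGeno) <- list(alleleIds, indivIds)
    individuals <- genotypeIndividuals(allGeno, config,
                                       seed = config$seed + 2L,
                                       sampleIds = indivIds,
                                       alleleIds = alleleIds,
                                       depthFactor = depthFactor)
    colData(individuals)$accession_id <- indivAcc
    colData(individuals)$sample_type <- "individual"

    ref <- do.call(cbind, refL); alt <- do.call(cbind, altL)
    dimnames(ref) <- dimnames(alt) <- list(alleleIds, poolSampleIds)
    poolCounts <- ReadCountTable(ref, alt)

    poolCallsM <- callsFromCounts(poolCounts)
    poolCalls <- GenotypeDataset(
        poolCallsM,
        locusMeta = data.frame(
            rep_avg = rowData(individuals)$rep_avg,
            avg_depth = config$depthMean * depthFactor),
        sampleMeta = data.frame(accession_id = poolAcc,
                                sample_type = "seq_pool",
                                replicate_group = poolRepGrp))

    sheet <- data.frame(
        sample_id = c(indivIds, poolSampleIds),
        accession_id = c(indivAcc, poolAcc),
        sample_type = c(rep("individual", length(indivIds)),
                        rep("seq_pool", length(poolSampleIds))),
        replicate_group = c(rep(NA_character_, length(indivIds)), poolRepGrp),
        origin_region = NA_character_,
        stringsAsFactors = FALSE)

    truth <- list(poolAssignment = setNames(poolOf, accIds),
                  trueFreq = trueFreq, qw = qwMat,
                  lineGenotypes = lineGenotypes,
                  truthGenotypes = allGeno,
                  nPlants = setNames(nPlants, accIds),
                  nLines = setNames(nLines, accIds),
                  poolFreqs = pf)
    list(individuals = individuals, poolCounts = poolCounts,
         poolCalls = poolCalls, sheet = sheet, truth = truth,
         config = config)
}

#' Write the truth ledger of a synthetic panel
#'
#' Emits the pool assignment / line composition table and the true accession
#' allele-frequency matrix as CSV, plus a JSON echo of the configuration.
#'
#' @param panel result of \code{\link{simulatePanel}}
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writeTruthLedger <- function(panel, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    tr <- panel$truth
    acc <- data.frame(accession_id = names(tr$poolAssignment),
                      gene_pool = as.integer(tr$poolAssignment),
                      n_plants = as.integer(tr$nPlants),
                      n_lines = as.integer(tr$nLines))
    p1 <- file.path(dir, "truth_accessions.csv")
    write.csv(acc, p1, row.names = FALSE)
    p2 <- file.path(dir, "truth_frequencies.csv")
    write.csv(data.frame(allele_id = rownames(tr$trueFreq), tr$trueFreq,
                         check.names = FALSE), p2, row.names = FALSE)
    p3 <- file.path(dir, "config.json")
    jsonlite::write_json(unclass(panel$config), p3, auto_unbox = TRUE,
                         digits = NA)
    invisible(c(p1, p2, p3))
}
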