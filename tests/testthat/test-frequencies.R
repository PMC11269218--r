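poolSheet <- function(ids, accs, repGrp = NA) {
    data.frame(sample_id = ids, accession_id = accs,
               sample_type = "seq_pool", replicate_group = repGrp,
               stringsAsFactors = FALSE)
}

test_that("the naive pooled estimator is the read ratio with missing at 0x", {
    ref <- gmat(c(30, 0, 10), 3, 1, samples = "P1")
    alt <- gmat(c(10, 0, 0), 3, 1, samples = "P1")
    ct <- ReadCountTable(ref, alt)
    ft <- pooledFreqFromReads(ct, poolSheet("P1", "A"))
    expect_equal(unname(freqMat(ft)[, "A"]), c(0.25, NA, 0))
    expect_equal(unname(supportMat(ft)[, "A"]), c(40, 0, 10))
    expect_equal(provenance(ft), "pooled_reads")

    # replicate handling: first by default, averaging on request
    ct2 <- ReadCountTable(gmat(c(10, 20), 1, 2, samples = c("P1", "P2")),
                          gmat(c(10, 60), 1, 2, samples = c("P1", "P2")))
    sh <- poolSheet(c("P1", "P2"), "A", "A")
    expect_equal(unname(freqMat(pooledFreqFromReads(ct2, sh))[1, 1]), 0.5)
    expect_equal(unname(freqMat(pooledFreqFromReads(
        ct2, sh, collapse = "average"))[1, 1]), (0.5 + 0.75) / 2)
    expect_equal(ncol(freqMat(pooledFreqFromReads(ct2, sh,
                                                  collapse = "none"))), 2)
})

test_that("genotype-based frequencies equal f(AA) + f(AB)/2 and the
           algebraic oracle", {
    # 10 AA (ref hom), 5 AB, 10 BB: p = 0.4 + 0.1 = 0.5
    m <- gmat(rep(c(0, 1, 2), c(10, 5, 10)), 1, 25)
    ds <- GenotypeDataset(m, sampleMeta = data.frame(
        accession_id = "A", sample_type = "individual"))
    ft <- genotypeFreq(ds)
    expect_equal(unname(freqMat(ft)[1, "A"]), 0.5)
    expect_equal(unname(supportMat(ft)[1, "A"]), 25)

    # all AA: p = 1, q = 0
    dsA <- GenotypeDataset(gmat(0, 1, 4), sampleMeta = data.frame(
        accession_id = "A", sample_type = "individual"))
    expect_equal(unname(freqMat(genotypeFreq(dsA))[1, 1]), 0)

    # random fixtures: q equals mean(calls)/2 over non-missing;
    # p equals mean(2 - calls)/2
    set.seed(1)
    for (i in 1:5) {
        m <- gmat(sample(c(0, 1, 2, NA), 80, replace = TRUE), 20, 4)
        ds <- GenotypeDataset(m, sampleMeta = data.frame(
            accession_id = "X", sample_type = "individual"))
        q <- freqMat(genotypeFreq(ds))[, "X"]
        oracle <- apply(m, 1, function(r) mean(r, na.rm = TRUE) / 2)
        oracle[is.nan(oracle)] <- NA
        expect_equal(unname(q), unname(oracle), tolerance = 1e-12)
    }
})

test_that("both estimators agree on an error-free homozygous fixture", {
    # every individual homozygous, pool reads drawn with zero noise
    m <- gmat(rep(c(0, 2, 2, 0, 0, 0), times = 4), 6, 4)
    ds <- GenotypeDataset(m, sampleMeta = data.frame(
        accession_id = "A", sample_type = "individual"))
    q <- freqMat(genotypeFreq(ds))[, "A"]
    depth <- 40
    alt <- gmat(q * depth, 6, 1, samples = "A_pool")
    ref <- gmat((1 - q) * depth, 6, 1, samples = "A_pool")
    ft <- pooledFreqFromReads(ReadCountTable(ref, alt),
                              poolSheet("A_pool", "A"))
    expect_equal(unname(freqMat(ft)[, "A"]), unname(q))
})

test_that("shared loci are the intersection of present loci", {
    fa <- AccessionFrequencyTable(gmat(c(0.5, NA, 0.2, NA), 4, 1,
                                       loci = paste0("L", 1:4)),
                                  gmat(c(10, NA, 10, NA), 4, 1,
                                       loci = paste0("L", 1:4)),
                                  "pooled_reads")
    fb <- AccessionFrequencyTable(gmat(c(0.1, 0.3, NA, NA), 4, 1,
                                       loci = paste0("L", 1:4)),
                                  gmat(c(5, 5, NA, NA), 4, 1,
                                       loci = paste0("L", 1:4)),
                                  "genotype_based")
    expect_equal(sharedLoci(fa, fb), "L1")
    expect_equal(sharedLoci(fa, fa), c("L1", "L3"))
    # disjoint locus keys share nothing
    fc <- AccessionFrequencyTable(gmat(0.5, 4, 1, loci = paste0("M", 1:4)),
                                  gmat(5, 4, 1, loci = paste0("M", 1:4)),
                                  "genotype_based")
    expect_length(sharedLoci(fa, fc), 0)
})

test_that("private and fixed alleles follow the exclusive-allele rule", {
    # A segregates for an allele absent in B: private to A
    expect_equal(privateAndFixed(0.6, 0)$private_a, 1)
    expect_equal(privateAndFixed(0.6, 0)$private_b, 0)
    # opposite fixation: a fixed difference, not a private allele
    pf <- privateAndFixed(1, 0)
    expect_equal(pf$fixed, 1)
    expect_equal(pf$private_a + pf$private_b, 0)
    # identical frequencies: nothing
    q <- c(0, 0.5, 1)
    expect_equal(unlist(privateAndFixed(q, q)[1:3]),
                 c(private_a = 0, private_b = 0, fixed = 0))
    # the reference allele can be private too (q = 1 on the other side)
    expect_equal(privateAndFixed(0.4, 1)$private_a, 1)
    # swap symmetry
    set.seed(2)
    qa <- round(runif(50), 2); qb <- round(runif(50), 2)
    qa[sample(50, 10)] <- 0; qb[sample(50, 10)] <- 1
    ab <- privateAndFixed(qa, qb); ba <- privateAndFixed(qb, qa)
    expect_equal(ab$private_a, ba$private_b)
    expect_equal(ab$private_b, ba$private_a)
    expect_equal(ab$fixed, ba$fixed)
})

test_that("AFD matches hand computations and its invariants", {
    expect_equal(afd(c(0.5, 0.1), c(0.5, 0.1)), 0)
    expect_equal(afd(c(1, 0), c(0, 1)), 1)
    expect_equal(afd(c(0.2, 0.6), c(0.4, 0.8)), 0.2)
    # symmetry, bounds, missing handling
    set.seed(3)
    qa <- runif(100); qb <- runif(100)
    qa[1:10] <- NA
    expect_equal(afd(qa, qb), afd(qb, qa))
    expect_gte(afd(qa, qb), 0); expect_lte(afd(qa, qb), 1)
    expect_error(afd(c(NA, NA), c(0.5, NA)), "no shared")
})

test_that("the quasi-Poisson analysis of deviance matches its oracle", {
    # closed-form group means
    fit <- quasipoissonAnodev(c(2, 4, 6, 10, 20, 30),
                              rep(c("a", "b"), each = 3))
    expect_equal(unname(fit$means), c(4, 20), tolerance = 1e-10)
    # identical groups: no effect
    fit0 <- quasipoissonAnodev(c(5, 7, 9, 5, 7, 9),
                               rep(c("a", "b"), each = 3))
    expect_lt(fit0$fStatistic, 1e-10)
    expect_gt(fit0$pValue, 0.999)
    # all-zero group is a hard error
    expect_error(quasipoissonAnodev(c(0, 0, 3, 4),
                                    rep(c("a", "b"), each = 2)),
                 "all-zero")
    # independent IRLS oracle on random counts, to 1e-8
    set.seed(4)
    for (i in 1:5) {
        counts <- rpois(24, rep(c(8, 25, 13), each = 8))
        groups <- rep(c("x", "y", "z"), each = 8)
        got <- quasipoissonAnodev(counts, groups)
        want <- qpOracle(counts, groups)
        expect_equal(unname(got$means), want$means, tolerance = 1e-8)
        expect_equal(got$dispersion, want$dispersion, tolerance = 1e-6)
        expect_equal(got$fStatistic, want$fStatistic, tolerance = 1e-8)
        expect_equal(got$pValue, want$pValue, tolerance = 1e-8)
    }
})

test_that("replicate concordance is zero for identical replicates and
           binned by depth", {
    ref <- gmat(c(10, 0, 30), 3, 2, samples = c("P1", "P2"))
    alt <- gmat(c(10, 40, 0), 3, 2, samples = c("P1", "P2"))
    ct <- ReadCountTable(ref, alt)
    out <- replicateConcordanceByDepth(ct, poolSheet(c("P1", "P2"),
                                                     "A", "A"))
    expect_true(all(out$mean_abs_diff[out$n_loci > 0] == 0))
    expect_equal(sum(out$n_loci), 3)
    # no replicate groups: error
    expect_error(replicateConcordanceByDepth(
        ct, poolSheet(c("P1", "P2"), c("A", "B"))), "replicate")
})

test_that("pool agreement summarises per accession", {
    panel <- smallPanel()
    filt <- applyFilters(panel$individuals)
    gf <- genotypeFreq(filt$dataset)
    pf <- pooledFreqFromReads(panel$poolCounts, panel$sheet)
    ag <- poolAgreement(gf, pf)
    expect_equal(nrow(ag), panel$config$nAccessions)
    expect_true(all(ag$afd >= 0 & ag$afd <= 1))
    expect_true(all(ag$shared_loci > 0))
    # AFD of a table against itself is zero
    agSelf <- poolAgreement(gf, gf)
    expect_true(all(agSelf$afd == 0))
    expect_true(all(agSelf$private_a == 0 & agSelf$fixed == 0))
})
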