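test_that("expected heterozygosity separates H and H-prime correctly", {
    # single locus at q = 0.5
    expect_equal(expectedHet(0.5)$value, 0.5)
    # all fixed: H' = 0; H has no polymorphic loci, reported 0 with n = 0
    fixed <- c(0, 0, 1, 1)
    expect_equal(expectedHet(fixed, includeMonomorphic = TRUE)$value, 0)
    h <- expectedHet(fixed)
    expect_equal(h$value, 0); expect_equal(h$nLoci, 0L)
    # 9 fixed + 1 locus at q = 0.5: H' = 0.05, H = 0.5
    q <- c(rep(0, 9), 0.5)
    expect_equal(expectedHet(q, includeMonomorphic = TRUE)$value, 0.05)
    expect_equal(expectedHet(q)$value, 0.5)
    expect_equal(expectedHet(q)$nLoci, 1L)
    expect_error(expectedHet(NA_real_), "zero loci")

    # property: H' <= H whenever both defined, equality iff no monomorphic
    set.seed(5)
    for (i in 1:20) {
        q <- runif(50)
        q[sample(50, sample(0:40, 1))] <- sample(c(0, 1), 40,
                                                 replace = TRUE)[1]
        hp <- expectedHet(q, includeMonomorphic = TRUE)
        h <- expectedHet(q)
        if (h$nLoci > 0) {
            expect_lte(hp$value, h$value + 1e-12)
            expect_equal(hp$value, h$value * h$nLoci / hp$nLoci)
        }
    }
})

test_that("polymorphic sites count both-allele loci for pools and plants", {
    # a fully homozygous single plant: calls/2 in {0, 1}, none polymorphic
    expect_equal(polymorphicSites(c(0, 1, 0, 1))$count, 0)
    # 5 heterozygous calls out of 8
    plant <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0, 1, 0)
    expect_equal(polymorphicSites(plant)$count, 5)
    expect_equal(polymorphicSites(plant)$fraction, 5 / 8)
    expect_equal(polymorphicSites(c(NA, 0.2))$count, 1)

    # in-silico and seq-pool polymorphic counts agree on an error-free
    # fixture (pool reads proportional to genotype frequencies)
    q <- c(0, 0.25, 0.5, 1, 0)
    alt <- q * 20; ref <- (1 - q) * 20
    expect_equal(polymorphicSites(alt / (alt + ref))$count,
                 polymorphicSites(q)$count)
})

test_that("the homogeneity classifier uses a strict 92% threshold", {
    expect_equal(classifyHomogeneity(c(rep(0, 95), runif(5, 0.2, 0.8))),
                 "homogeneous")
    # exactly at the threshold: heterogeneous (strict >)
    q <- c(rep(0, 92), rep(0.5, 8))
    expect_equal(classifyHomogeneity(q), "heterogeneous")
    # single-line accessions classify homogeneous nearly always
    hits <- vapply(1:10, function(s) {
        cfg <- syntheticConfig(nLoci = 400, seed = 300 + s)
        pq <- drawPoolFrequencies(cfg)$pools[, 1]
        acc <- generateAccession(cfg, pq, nLines = 1, nPlants = 20,
                                 seed = 400 + s)
        classifyHomogeneity(acc$trueFreq) == "homogeneous"
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})

test_that("diversity tables respect the no-missing subset and invariants", {
    panel <- smallPanel()
    filt <- applyFilters(panel$individuals)
    tab <- diversityTable(filt$dataset, "in_silico")
    expect_equal(nrow(tab), panel$config$nAccessions)
    expect_true(all(tab$H_prime <= tab$H + 1e-12))
    expect_true(all(tab$H >= 0 & tab$H <= 0.5 + 1e-12))
    expect_true(all(tab$n_polymorphic <= tab$n_loci_all))
    expect_equal(tab$H_prime,
                 tab$H * tab$n_polymorphic / tab$n_loci_all)
    # heterogeneous (3-line) accessions come out heterogeneous more often
    nl <- panel$truth$nLines[tab$accession]
    expect_gt(mean(tab$homogeneity_class[nl == 3] == "heterogeneous"),
              mean(tab$homogeneity_class[nl == 1] == "heterogeneous"))
})

test_that("MRD matches hand computations and the brute-force oracle", {
    expect_equal(mrd(c(0.3, 0.7), c(0.3, 0.7)), 0)
    expect_equal(mrd(c(1, 0, 1), c(0, 1, 0)), 1)  # all fixed-opposite
    expect_equal(mrd(0.5, 1.0), 0.5)              # single-locus hand case
    expect_error(mrd(NA_real_, 0.5), "no pairwise-complete")

    # 5 accessions x 20 loci with missing cells vs a double loop
    set.seed(6)
    f <- gmat(runif(100), 20, 5)
    f[sample(100, 15)] <- NA
    ft <- AccessionFrequencyTable(f, gmat(10, 20, 5), "genotype_based")
    got <- mrdMatrix(ft)
    m <- as.matrix(got)
    for (i in 1:5) for (j in 1:5) {
        if (i == j) next
        ok <- !is.na(f[, i]) & !is.na(f[, j])
        expect_equal(m[i, j], sqrt(mean((f[ok, i] - f[ok, j])^2)),
                     tolerance = 1e-12)
        expect_equal(unname(nLociUsed(got)[i, j]), sum(ok))
    }
    # invariants
    expect_true(isSymmetric(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0 & m <= 1))

    # identical accessions are at distance zero
    f2 <- cbind(A = f[, 1], B = f[, 1])
    expect_equal(unname(as.matrix(mrdMatrix(f2))[1, 2]), 0)
})

test_that("cross-strategy MRD pairs accessions over common loci", {
    set.seed(7)
    fa <- gmat(runif(30), 10, 3, loci = paste0("L", 1:10),
               samples = c("A", "B", "C"))
    fb <- fa + gmat(rnorm(30, 0, 0.05), 10, 3, loci = paste0("L", 1:10),
                    samples = c("A", "B", "C"))
    fb <- pmin(pmax(fb, 0), 1)
    cross <- mrdCross(fa, fb)
    expect_equal(cross$accession, c("A", "B", "C"))
    for (k in 1:3)
        expect_equal(cross$mrd[k], mrd(fa[, k], fb[, k]))
    expect_error(mrdCross(fa, gmat(0.5, 2, 2, loci = c("X1", "X2"))),
                 "no common")
})

test_that("removing rare private loci raises the mean pairwise MRD", {
    # loci fixed at 0 in most accessions dilute distances through the
    # denominator; restricting to the shared polymorphic set removes them
    panel <- smallPanel()
    gf <- genotypeFreq(buildInSilicoPool(
        panel$individuals,
        panel$sheet[panel$sheet$sample_type == "individual", ]))
    f <- freqMat(gf)
    rare <- rowSums(f > 0, na.rm = TRUE) <= 1 &
        rowSums(!is.na(f)) == ncol(f)
    keep <- !rare
    mAll <- as.matrix(mrdMatrix(f))
    mShared <- as.matrix(mrdMatrix(f[keep, ]))
    expect_gt(mean(mShared[upper.tri(mShared)]),
              mean(mAll[upper.tri(mAll)]))
})
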