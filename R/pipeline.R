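## One-command orchestration of the full comparison: generate or read the
## panel, filter each dataset, split into the three strategies, estimate
## frequencies and agreement, diversity, distances, structure; write every
## table, figures, a Markdown report and a seed manifest.

#' Configuration of a full pipeline run
#'
#' Exactly one of \code{synthetic} or \code{inputs} must be set. The
#' defaults reproduce the study design on synthetic data: 10 single-plant
#' resampling runs, 1000 bootstrap replicates, K from 1 to 5.
#'
#' @param synthetic a \code{\link{syntheticConfig}}, or NULL when reading
#'   files
#' @param inputs NULL, or a list with paths \code{genotypes} (one-row SNP
#'   report), \code{counts} (read-count report), \code{sheet} (sample
#'   sheet) and optional \code{dialect}
#' @param filters a \code{\link{filterConfig}}
#' @param nSinglePlantRuns single-plant resampling runs (default 10)
#' @param bootstrapB bootstrap replicates for node support (default 1000)
#' @param kRange candidate K values for admixture (default 1:5)
#' @param seed integer seed for sampling, bootstrap and admixture
#' @param outDir output directory
#' @return a validated list of class \code{"runConfig"}
#' @export
runConfig <- function(synthetic = syntheticConfig(), inputs = NULL,
                      filters = filterConfig(), nSinglePlantRuns = 10,
                      bootstrapB = 1000, kRange = 1:5, seed = 1,
                      outDir = "poolstrat_run") {
    if (is.null(synthetic) == is.null(inputs))
        stop("exactly one of 'synthetic' or 'inputs' must be set")
    if (!is.null(inputs)) {
        need <- c("genotypes", "counts", "sheet")
        if (!all(need %in% names(inputs)))
            stop("inputs must name paths: ", paste(need, collapse = ", "))
        for (f in need)
            if (!file.exists(inputs[[f]]))
                stop("input path does not exist: ", inputs[[f]])
    }
    stopifnot(nSinglePlantRuns >= 1, bootstrapB >= 1, length(kRange) >= 1)
    structure(list(synthetic = synthetic, inputs = inputs, filters = filters,
                   nSinglePlantRuns = nSinglePlantRuns,
                   bootstrapB = bootstrapB, kRange = kRange,
                   seed = as.integer(seed), outDir = outDir),
              class = "runConfig")
}

.stage <- function(name, expr) {
    message("[poolstrat] stage: ", name)
    tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

.writeTable <- function(df, dir, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    write.csv(df, path, row.names = FALSE)
    path
}

.writeMatrix <- function(m, dir, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    write.csv(data.frame(id = rownames(m), m, check.names = FALSE),
              path, row.names = FALSE)
    path
}

#' Run the full strategy comparison
#'
#' Executes generate/read, per-dataset filtering, the three-way split,
#' frequency estimation and pool agreement (private/fixed alleles with the
#' quasi-Poisson analysis of deviance, AFD), replicate concordance by
#' depth, diversity tables, MRD matrices (within and across strategies),
#' PCoA, complete-linkage clustering with bootstrap support, and admixture
#' with cross-entropy K selection. All tables are written as CSV, figures
#' as PDF, plus \code{report.md} and a \code{manifest.json} of seeds and
#' versions. Rerunning with the same configuration reproduces the tables
#' byte for byte.
#'
#' @param cfg a \code{\link{runConfig}}
#' @return invisibly, a list with every intermediate result
#' @export
runAll <- function(cfg = runConfig()) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    res <- list(config = cfg)

    panel <- .stage("input", {
        if (!is.null(cfg$synthetic)) {
            p <- simulatePanel(cfg$synthetic)
            writeTruthLedger(p, file.path(cfg$outDir, "truth"))
            p
        } else {
            ds <- readDartOneRow(cfg$inputs$genotypes,
                                 dialect = cfg$inputs$dialect %||%
                                     "dart_onerow")
            sheet <- readSampleSheet(cfg$inputs$sheet)
            counts <- readDartCounts(cfg$inputs$counts)
            indiv <- sheet$sample_id[sheet$sample_type == "individual"]
            poolIds <- sheet$sample_id[sheet$sample_type == "seq_pool"]
            list(individuals = buildInSilicoPool(
                     ds[, intersect(colnames(ds), indiv)], sheet),
                 poolCounts = counts[, intersect(colnames(counts), poolIds)],
                 poolCalls = if (length(intersect(colnames(ds), poolIds)))
                     buildInSilicoPool(
                         ds[, intersect(colnames(ds), poolIds)], sheet)
                     else NULL,
                 sheet = sheet, truth = NULL)
        }
    })
    res$panel <- panel

    filt <- .stage("filter", {
        insilico <- applyFilters(panel$individuals, cfg$filters)
        seqpool <- if (!is.null(panel$poolCalls))
            applyFilters(panel$poolCalls, cfg$filters) else NULL
        runs <- resampleRuns(panel$individuals, nRuns = cfg$nSinglePlantRuns,
                             baseSeed = cfg$seed)
        singleRuns <- lapply(runs, applyFilters, cfg = cfg$filters)
        rep <- rbind(cbind(dataset = "in_silico", insilico$report),
                     if (!is.null(seqpool))
                         cbind(dataset = "seq_pool", seqpool$report),
                     cbind(dataset = "single_plant_run1",
                           singleRuns[[1]]$report))
        .writeTable(rep, cfg$outDir, "filter_report")
        list(insilico = insilico, seqpool = seqpool,
             singleRuns = singleRuns, report = rep)
    })
    res$filters <- filt

    freqs <- .stage("frequencies", {
        gf <- genotypeFreq(filt$insilico$dataset)
        pf <- pooledFreqFromReads(panel$poolCounts, panel$sheet)
        ## restrict the pooled table to the loci surviving the seq-pool
        ## genotype filter when pool calls exist
        if (!is.null(filt$seqpool)) {
            keep <- intersect(rownames(freqMat(pf)),
                              rownames(filt$seqpool$dataset))
            pf <- pf[match(keep, rownames(freqMat(pf))), ]
        }
        sf <- lapply(filt$singleRuns, function(r)
            genotypeFreq(r$dataset))
        list(insilico = gf, seqpool = pf, singleRuns = sf)
    })
    res$frequencies <- freqs

    agree <- .stage("agreement", {
        ag <- poolAgreement(freqs$insilico, freqs$seqpool)
        names(ag)[names(ag) == "private_a"] <- "private_insilico"
        names(ag)[names(ag) == "private_b"] <- "private_seqpool"
        .writeTable(ag, cfg$outDir, "pool_agreement")
        counts <- c(ag$private_insilico, ag$private_seqpool)
        groups <- rep(c("in_silico", "seq_pool"), each = nrow(ag))
        fit <- if (all(tapply(counts, groups, mean) > 0))
            quasipoissonAnodev(counts, groups) else NULL
        if (!is.null(fit))
            jsonlite::write_json(
                list(means = as.list(fit$means), dispersion = fit$dispersion,
                     F = fit$fStatistic, df = fit$df, p_value = fit$pValue),
                file.path(cfg$outDir, "private_allele_glm.json"),
                auto_unbox = TRUE, digits = NA)
        list(table = ag, glm = fit)
    })
    res$agreement <- agree

    conc <- .stage("replicate_concordance", {
        out <- tryCatch(
            replicateConcordanceByDepth(panel$poolCounts, panel$sheet),
            error = function(e) NULL)
        if (!is.null(out)) .writeTable(out, cfg$outDir,
                                       "replicate_concordance")
        out
    })
    res$concordance <- conc

    divs <- .stage("diversity", {
        tabs <- rbind(
            diversityTable(filt$insilico$dataset, "in_silico"),
            diversityTable(freqs$seqpool, "seq_pool"))
        .writeTable(tabs, cfg$outDir, "diversity")
        tabs
    })
    res$diversity <- divs

    dists <- .stage("distances", {
        mIns <- mrdMatrix(freqs$insilico)
        mSeq <- mrdMatrix(freqs$seqpool)
        single1 <- freqs$singleRuns[[1]]
        mSgl <- mrdMatrix(single1)
        .writeMatrix(as.matrix(mIns), cfg$outDir, "mrd_in_silico")
        .writeMatrix(as.matrix(mSeq), cfg$outDir, "mrd_seq_pool")
        .writeMatrix(as.matrix(mSgl), cfg$outDir, "mrd_single_plant")
        cross <- rbind(
            cbind(comparison = "in_silico_vs_seq_pool",
                  mrdCross(freqs$insilico, freqs$seqpool)),
            cbind(comparison = "in_silico_vs_single",
                  mrdCross(freqs$insilico, single1)),
            cbind(comparison = "seq_pool_vs_single",
                  mrdCross(freqs$seqpool, single1)))
        .writeTable(cross, cfg$outDir, "mrd_cross_strategy")
        list(insilico = mIns, seqpool = mSeq, single = mSgl, cross = cross)
    })
    res$distances <- dists

    struct <- .stage("structure", {
        pc <- lapply(list(in_silico = dists$insilico,
                          seq_pool = dists$seqpool,
                          single_plant = dists$single), pcoa, k = 3)
        for (nm in names(pc))
            .writeMatrix(pc[[nm]]$coordinates, cfg$outDir,
                         paste0("pcoa_", nm))
        boot <- bootstrapSupport(freqs$insilico, B = cfg$bootstrapB,
                                 seed = cfg$seed)
        tre <- boot$phylo
        tre$node.label <- round(boot$support, 1)
        ape::write.tree(tre, file.path(cfg$outDir,
                                       "dendrogram_in_silico.nwk"))
        spCalls <- calls(filt$singleRuns[[1]]$dataset)
        adm <- admixtureNMF(t(spCalls) / 2, K = cfg$kRange,
                            seed = cfg$seed)
        .writeMatrix(adm$Q, cfg$outDir, "admixture_Q_single_plant")
        .writeTable(data.frame(K = sub("K", "", colnames(adm$crossEntropy)),
                               mean_cross_entropy =
                                   colMeans(adm$crossEntropy)),
                    cfg$outDir, "admixture_cross_entropy")
        list(pcoa = pc, bootstrap = boot, admixture = adm)
    })
    res$structure <- struct

    .stage("report", {
        .runFigures(res, cfg$outDir)
        .runReport(res, cfg$outDir)
        manifest <- list(
            package_version = as.character(packageVersion("poolstrat")),
            r_version = as.character(getRversion()),
            seed = cfg$seed,
            single_plant_run_seeds = cfg$seed + seq_len(cfg$nSinglePlantRuns),
            synthetic_seed = if (!is.null(cfg$synthetic))
                cfg$synthetic$seed else NULL,
            bootstrap_B = cfg$bootstrapB,
            k_range = cfg$kRange)
        jsonlite::write_json(manifest,
                             file.path(cfg$outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA)
    })
    invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.runFigures <- function(res, outDir) {
    grDevices::pdf(file.path(outDir, "figures.pdf"), width = 8, height = 6)
    on.exit(grDevices::dev.off())
    ## sample call rate by dataset
    cr <- list(in_silico = sampleCallrate(res$filters$insilico$dataset),
               single_plant =
                   sampleCallrate(res$filters$singleRuns[[1]]$dataset))
    if (!is.null(res$filters$seqpool))
        cr$seq_pool <- sampleCallrate(res$filters$seqpool$dataset)
    graphics::boxplot(cr, main = "Sample call rate after filtering",
                      ylab = "call rate")
    ## frequency agreement scatter
    loci <- intersect(rownames(freqMat(res$frequencies$insilico)),
                      rownames(freqMat(res$frequencies$seqpool)))
    accs <- intersect(accessionIds(res$frequencies$insilico),
                      accessionIds(res$frequencies$seqpool))
    x <- freqMat(res$frequencies$insilico)[loci, accs]
    y <- freqMat(res$frequencies$seqpool)[loci, accs]
    graphics::plot(as.vector(x), as.vector(y), pch = ".",
                   xlab = "in-silico pool q", ylab = "seq-pool q",
                   main = "Allele frequency agreement between pools")
    graphics::abline(0, 1, col = "red")
    ## MRD distributions
    dl <- list(in_silico = as.matrix(res$distances$insilico),
               seq_pool = as.matrix(res$distances$seqpool),
               single_plant = as.matrix(res$distances$single))
    graphics::boxplot(lapply(dl, function(m) m[upper.tri(m)]),
                      main = "Pairwise MRD between accessions",
                      ylab = "MRD")
    ## PCoA
    for (nm in names(res$structure$pcoa)) {
        p <- res$structure$pcoa[[nm]]
        graphics::plot(p$coordinates[, 1], p$coordinates[, 2],
                       xlab = sprintf("Axis 1 (%.1f%%)",
                                      100 * p$explained[1]),
                       ylab = sprintf("Axis 2 (%.1f%%)",
                                      100 * p$explained[2]),
                       main = paste("PCoA:", nm))
    }
    ## dendrogram + admixture entropy
    graphics::plot(res$structure$bootstrap$hclust,
                   main = "Complete-linkage clustering (in-silico MRD)",
                   xlab = "", sub = "")
    ce <- colMeans(res$structure$admixture$crossEntropy)
    graphics::plot(as.integer(sub("K", "", names(ce))), ce, type = "b",
                   xlab = "K", ylab = "masked cross-entropy",
                   main = "Admixture model selection")
}

.runReport <- function(res, outDir) {
    ag <- res$agreement$table
    lines <- c(
        "# poolstrat run report", "",
        paste0("Generated: poolstrat ",
               as.character(packageVersion("poolstrat"))), "",
        "## Datasets", "",
        paste0("- in-silico pool: ", ncol(res$filters$insilico$dataset),
               " individuals, ", nrow(res$filters$insilico$dataset),
               " loci after filtering"),
        if (!is.null(res$filters$seqpool))
            paste0("- seq-pool: ", ncol(res$filters$seqpool$dataset),
                   " pool samples, ", nrow(res$filters$seqpool$dataset),
                   " loci after filtering"),
        paste0("- single plant (run 1 of ",
               length(res$filters$singleRuns), "): ",
               nrow(res$filters$singleRuns[[1]]$dataset),
               " loci after filtering"), "",
        "## Pool agreement", "",
        paste0("- mean AFD between in-silico and seq-pools: ",
               signif(mean(ag$afd, na.rm = TRUE), 3)),
        paste0("- mean private alleles: in-silico ",
               signif(mean(ag$private_insilico), 4), ", seq-pool ",
               signif(mean(ag$private_seqpool), 4)),
        if (!is.null(res$agreement$glm))
            paste0("- quasi-Poisson F(", res$agreement$glm$df[1], ", ",
                   res$agreement$glm$df[2], ") = ",
                   signif(res$agreement$glm$fStatistic, 4), ", p = ",
                   signif(res$agreement$glm$pValue, 3)), "",
        "## Structure", "",
        paste0("- PCoA axis 1 explains ",
               sprintf("%.1f%%",
                       100 * res$structure$pcoa$in_silico$explained[1]),
               " of the variance (in-silico)"),
        paste0("- admixture selected K = ",
               res$structure$admixture$selectedK), "",
        "See figures.pdf and the CSV tables in this directory.")
    writeLines(lines[!vapply(lines, is.null, logical(1))],
               file.path(outDir, "report.md"))
}
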