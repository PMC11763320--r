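#' Configuration for the full synthetic pipeline
#'
#' Bundles every stage's parameters with a single master seed from
#' which all stage seeds are derived.
#'
#' @param seed master integer seed.
#' @param panel arguments for \code{\link{generatePanel}}.
#' @param cohort arguments for \code{\link{cohortSpec}} (seed is
#'   derived).
#' @param reads arguments for \code{\link{readSimParams}}.
#' @param qpcr arguments for \code{\link{qpcrSimParams}}.
#' @param minCoverage site filter threshold
#'   (\code{\link{filterSites}}).
#' @param alpha per-gene significance level.
#' @param nSplits,trainFraction hold-out benchmark scheme.
#' @param families model families to benchmark.
#' @param enetTune elastic-net tuning settings (see
#'   \code{\link{repeatedHoldout}}).
#' @param rfTrees random-forest size.
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(seed = 1,
                           panel = list(),
                           cohort = list(),
                           reads = list(readsPerAmplicon = 300),
                           qpcr = list(),
                           minCoverage = 8,
                           alpha = 0.05,
                           nSplits = 5000,
                           trainFraction = 0.7,
                           families = "enet",
                           enetTune = list(alphaGrid = c(0, 0.5, 1),
                                           lambdaGrid = NULL, k = 5),
                           rfTrees = 500) {
    structure(list(seed = as.integer(seed), panel = panel,
                   cohort = cohort, reads = reads, qpcr = qpcr,
                   minCoverage = minCoverage, alpha = alpha,
                   nSplits = nSplits, trainFraction = trainFraction,
                   families = families, enetTune = enetTune,
                   rfTrees = rfTrees),
              class = "PipelineConfig")
}

#' Run the complete synthetic diagnostic pipeline
#'
#' Executes every stage end to end on synthetic data with known truth:
#' panel generation, cohort simulation, bisulfite read simulation,
#' qPCR simulation, standard-curve quantification and group ANOVA,
#' read merging/assignment/counting, site filtering and library
#' normalization, per-gene chi-square tests, feature assembly, the
#' repeated hold-out benchmark with averaged ROC, and the final INDEX
#' model. Fully reproducible from the config seed.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir optional directory; when given, TSV/JSON reports are
#'   written there (quantification, site counts, gene percentages, gene
#'   tests, benchmark metrics, averaged ROC, INDEX model, full report).
#' @return list of class \code{PipelineReport}: \code{panel},
#'   \code{cohort}, \code{curve}, \code{quant}, \code{groupSummary},
#'   \code{counts}, \code{qc}, \code{genePct}, \code{geneTests},
#'   \code{features}, \code{benchmark}, \code{tuned}, \code{model}.
#' @export
runFullPipeline <- function(config = pipelineConfig(), outDir = NULL) {
    stopifnot(inherits(config, "PipelineConfig"))
    sd <- function(k) .deriveSeed(config$seed, k)

    panel <- do.call(generatePanel,
                     c(config$panel[setdiff(names(config$panel), "seed")],
                       list(seed = sd(1))))
    spec <- do.call(cohortSpec,
                    c(config$cohort[setdiff(names(config$cohort), "seed")],
                      list(seed = sd(2))))
    cohort <- simulateCohort(spec)

    readsDir <- if (is.null(outDir)) file.path(tempfile("reads"))
                else file.path(outDir, "reads")
    rp <- do.call(readSimParams,
                  c(config$reads[setdiff(names(config$reads), "seed")],
                    list(seed = sd(3))))
    files <- simulateBisulfiteReads(panel, cohort, rp, readsDir)

    qp <- do.call(qpcrSimParams,
                  c(config$qpcr[setdiff(names(config$qpcr), "seed")],
                    list(seed = sd(4))))
    qpcr <- simulateQpcr(cohort, qp)
    curve <- fitStandardCurve(qpcr$standards)
    quant <- quantifySamples(qpcr$samples, curve)
    groupSummary <- summarizeGroups(quant$copies_per_reaction,
                                    cohort$group)

    called <- callMethylation(files, panel)
    counts <- filterSites(called$counts, minCoverage = config$minCoverage)
    counts <- normalizeLibraries(counts)
    genePct <- geneMethylation(counts)
    geneTests <- testDifferentialMethylation(counts, cohort$group,
                                             alpha = config$alpha)

    features <- buildFeatureTable(genePct, quant$copies_per_reaction,
                                  cohort$group)
    scheme <- splitScheme(nSplits = config$nSplits,
                          trainFraction = config$trainFraction,
                          seed = sd(5))
    benchmark <- repeatedHoldout(features, scheme,
                                 families = config$families,
                                 enetTune = config$enetTune,
                                 rfTrees = config$rfTrees)
    tuned <- tuneHyperparameters(features,
                                 alphaGrid = config$enetTune$alphaGrid,
                                 lambdaGrid = config$enetTune$lambdaGrid,
                                 k = config$enetTune$k, seed = sd(6))
    model <- finalizeIndexModel(features, alpha = tuned$alpha,
                                lambda = tuned$lambda)

    report <- structure(
        list(config = config, panel = panel, cohort = cohort,
             curve = curve, quant = quant, groupSummary = groupSummary,
             counts = counts, qc = called$qc, genePct = genePct,
             geneTests = geneTests, features = features,
             benchmark = benchmark,
             tuned = tuned[c("alpha", "lambda", "cv_auc")],
             model = model),
        class = "PipelineReport")
    if (!is.null(outDir)) .writePipelineReport(report, outDir)
    report
}

.writePipelineReport <- function(report, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    tsv <- function(d, f) write.table(d, file.path(outDir, f),
                                      sep = "\t", quote = FALSE,
                                      row.names = FALSE)
    writePanel(report$panel, file.path(outDir, "panel.fasta"),
               file.path(outDir, "panel_cpg.bed"))
    tsv(report$cohort, "cohort_truth.tsv")
    tsv(report$quant, "quantification.tsv")
    tsv(report$geneTests, "gene_tests.tsv")
    gp <- data.frame(sample_id = rownames(report$genePct),
                     report$genePct, check.names = FALSE)
    tsv(gp, "gene_methylation_percent.tsv")
    x <- report$counts
    cnt <- data.frame(
        site = rep(rownames(x), ncol(x)),
        gene = rep(SummarizedExperiment::rowData(x)$gene, ncol(x)),
        position = rep(GenomicRanges::start(
            SummarizedExperiment::rowRanges(x)), ncol(x)),
        sample_id = rep(colnames(x), each = nrow(x)),
        c = as.vector(SummarizedExperiment::assay(x, "c")),
        t = as.vector(SummarizedExperiment::assay(x, "t")),
        other = as.vector(SummarizedExperiment::assay(x, "other")),
        retained = rep(retainedSites(x), ncol(x)))
    cnt$rate <- ifelse(cnt$c + cnt$t > 0, cnt$c / (cnt$c + cnt$t), NA)
    tsv(cnt, "site_counts.tsv")
    for (f in names(report$benchmark)) {
        b <- report$benchmark[[f]]
        tsv(b@metrics, sprintf("benchmark_%s_metrics.tsv", f))
        tsv(b@roc, sprintf("benchmark_%s_roc.tsv", f))
    }
    writeIndexModel(report$model, file.path(outDir, "index_model.json"))
    jsonlite::write_json(.reportSummary(report),
                         file.path(outDir, "report.json"),
                         digits = NA, auto_unbox = TRUE)
    invisible(outDir)
}

# Flat, JSON-serializable summary of a pipeline run
.reportSummary <- function(report) {
    gs <- report$groupSummary
    bm <- lapply(report$benchmark, function(b)
        c(as.list(b@summary), list(auc_of_averaged_roc = b@aucAveraged)))
    list(group_summary = list(
             groups = as.data.frame(gs$groups),
             difference_of_means = gs$difference_of_means,
             difference_of_medians = gs$difference_of_medians,
             factor_means = gs$factor_means,
             factor_medians = gs$factor_medians,
             anova_f = gs$anova_f, anova_p = gs$anova_p),
         standard_curve = list(slope = curveSlope(report$curve),
                               intercept = curveIntercept(report$curve),
                               r_squared = curveR2(report$curve),
                               efficiency = curveEfficiency(report$curve)),
         conversion_rate = unname(median(conversionRate(report$counts),
                                         na.rm = TRUE)),
         gene_tests = report$geneTests,
         n_significant = attr(report$geneTests, "significant_count"),
         benchmark = bm,
         tuned = report$tuned,
         index_model = list(
             features = report$model@featureNames,
             raw_intercept = report$model@rawIntercept,
             raw_betas = report$model@rawBetas))
}

#' @export
print.PipelineReport <- function(x, ...) {
    cat("Pipeline report\n===============\n")
    print(x$groupSummary)
    cat("\nGene tests:\n")
    print(x$geneTests[, c("gene", "case_rate", "control_rate",
                          "chi2", "p_value", "direction",
                          "significant")], digits = 3)
    cat("\nBenchmark:\n")
    for (f in names(x$benchmark)) show(x$benchmark[[f]])
    cat("\n")
    show(x$model)
    invisible(x)
}
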