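test_that("cohort simulation matches its specification and is deterministic", {
    spec <- cohortSpec(seed = 11)
    truth <- simulateCohort(spec)
    expect_equal(nrow(truth), 78)
    expect_equal(sum(truth$group == "case"), 38)
    expect_equal(sum(truth$group == "control"), 40)
    expect_true(all(vapply(rownames(defaultMethLevels()), function(g)
        all(truth[[g]] >= 0 & truth[[g]] <= 1), logical(1))))
    expect_identical(truth, simulateCohort(spec))
    expect_false(identical(truth, simulateCohort(cohortSpec(seed = 12))))
})

test_that("log-copy moments and the median separation recover spec parameters", {
    spec <- cohortSpec(nCases = 2000, nControls = 2000, seed = 5)
    truth <- simulateCohort(spec)
    for (g in c("case", "control")) {
        lc <- log(truth$true_copies[truth$group == g])
        n <- length(lc)
        mu <- spec$copyMeanlog[[g]]; sdl <- spec$copySdlog[[g]]
        expect_lt(abs(mean(lc) - mu), 3 * sdl / sqrt(n))
        expect_lt(abs(sd(lc) - sdl), 3 * sdl / sqrt(2 * (n - 1)))
    }
    ratio <- median(truth$true_copies[truth$group == "case"]) /
        median(truth$true_copies[truth$group == "control"])
    expect_lt(abs(ratio - 3.9) / 3.9, 0.10)
})

test_that("identical group parameters give exchangeable groups", {
    lv <- defaultMethLevels(hypoDelta = 0)
    nonsig <- vapply(1:40, function(s) {
        spec <- cohortSpec(nCases = 20, nControls = 20,
                           copyMeanlog = c(case = 8, control = 8),
                           copySdlog = c(case = 0.9, control = 0.9),
                           geneMethLevels = lv, seed = 1000 + s)
        truth <- simulateCohort(spec)
        t.test(log(true_copies) ~ group, data = truth)$p.value > 0.05
    }, logical(1))
    # 5% type-I error per seed: allow a few rejections in 40 draws
    expect_gte(sum(nonsig), 34)
})

test_that("bisulfite read simulation honours its limiting cases", {
    panel <- tinyPanel()
    cohort <- data.frame(sample_id = "S1", group = "case",
                         true_copies = 1000, geneA = 1, geneB = 1,
                         stringsAsFactors = FALSE)
    d <- withr::local_tempdir()
    files <- simulateBisulfiteReads(
        panel, cohort,
        readSimParams(readsPerAmplicon = 40, conversionEfficiency = 1,
                      methylatedProtection = 1, errorRate = 0, seed = 3),
        file.path(d, "full"))
    asn <- assignToAmplicon(
        mergeReadPairs(readFastq(files$r1)$sequence,
                       readFastq(files$r1)$qualities,
                       readFastq(files$r2)$sequence,
                       readFastq(files$r2)$qualities)$sequence, panel)
    x <- countCpgSites(asn, rep("S1", nrow(asn)), panel)
    cc <- SummarizedExperiment::assay(x, "c")
    tt <- SummarizedExperiment::assay(x, "t")
    # fully methylated, perfect protection: every CpG reads C
    expect_true(all(tt == 0) && all(cc > 0))
    # perfect conversion: no C at non-CpG cytosines
    expect_equal(unname(conversionRate(x)), 1)

    cohort0 <- transform(cohort, geneA = 0, geneB = 0)
    files0 <- simulateBisulfiteReads(
        panel, cohort0,
        readSimParams(readsPerAmplicon = 40, conversionEfficiency = 1,
                      errorRate = 0, seed = 3),
        file.path(d, "none"))
    asn0 <- assignToAmplicon(
        mergeReadPairs(readFastq(files0$r1)$sequence,
                       readFastq(files0$r1)$qualities,
                       readFastq(files0$r2)$sequence,
                       readFastq(files0$r2)$qualities)$sequence, panel)
    x0 <- countCpgSites(asn0, rep("S1", nrow(asn0)), panel)
    expect_true(all(SummarizedExperiment::assay(x0, "c") == 0))
})

test_that("planted methylation is recovered within binomial error", {
    panel <- tinyPanel()
    cohort <- data.frame(sample_id = "S1", group = "case",
                         true_copies = 1000, geneA = 0.5, geneB = 0.5,
                         stringsAsFactors = FALSE)
    d <- withr::local_tempdir()
    files <- simulateBisulfiteReads(
        panel, cohort,
        readSimParams(readsPerAmplicon = 1000, conversionEfficiency = 1,
                      methylatedProtection = 1, errorRate = 0, seed = 7),
        d)
    r1 <- readFastq(files$r1); r2 <- readFastq(files$r2)
    merged <- mergeReadPairs(r1$sequence, r1$qualities,
                             r2$sequence, r2$qualities)
    asn <- assignToAmplicon(merged$sequence, panel)
    x <- countCpgSites(asn, rep("S1", nrow(asn)), panel)
    cc <- SummarizedExperiment::assay(x, "c")[, 1]
    tt <- SummarizedExperiment::assay(x, "t")[, 1]
    rate <- cc / (cc + tt)
    expect_true(all(abs(rate - 0.5) <= 3 * sqrt(0.25 / (cc + tt))))
})

test_that("read simulation is byte-identical under a fixed seed", {
    panel <- tinyPanel()
    cohort <- data.frame(sample_id = "S1", group = "case",
                         true_copies = 10, geneA = 0.4, geneB = 0.6,
                         stringsAsFactors = FALSE)
    d <- withr::local_tempdir()
    p <- readSimParams(readsPerAmplicon = 25, seed = 99)
    f1 <- simulateBisulfiteReads(panel, cohort, p, file.path(d, "a"))
    f2 <- simulateBisulfiteReads(panel, cohort, p, file.path(d, "b"))
    expect_identical(readFastq(f1$r1), readFastq(f2$r1))
    expect_identical(readFastq(f1$r2), readFastq(f2$r2))
})

test_that("qPCR simulation follows the calibration line exactly at zero noise", {
    cohort <- data.frame(sample_id = c("A", "B"),
                         true_copies = c(1, 200000))
    qp <- simulateQpcr(cohort, qpcrSimParams(cqNoiseSd = 0, seed = 1))
    cq <- as.matrix(qp$samples[, c("cq1", "cq2", "cq3")])
    expect_equal(unname(cq[1, ]), rep(40, 3))
    expect_equal(unname(cq[2, ]),
                 rep(40 - 3.3219 * log10(2e5), 3))
    # ten-fold dilution: successive standard Cq differences = -slope
    std <- qp$standards[qp$standards$replicate == 1, ]
    expect_equal(diff(std$cq), rep(3.3219, 4), tolerance = 1e-12)
    expect_error(simulateQpcr(data.frame(sample_id = "A",
                                         true_copies = 0),
                              qpcrSimParams()), "positive")
    expect_error(qpcrSimParams(standardCopies = c(100, 200, 400)),
                 "decades")
})
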