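test_that("per-site rates follow directly from C/T tallies", {
    panel <- AmpliconPanel(c(g = "AACGTTACGA"))  # CpGs at 3 and 8
    # ten reads: k methylated at site 3, half at site 8
    reads <- c(rep("AACGTTATGA", 4), rep("AATGTTACGA", 3),
               rep("AACGTTACGA", 3))
    asn <- assignToAmplicon(reads, panel, minLength = 10)
    expect_true(all(asn$gene == "g"))
    x <- countCpgSites(asn, rep("S1", 10), panel)
    cc <- SummarizedExperiment::assay(x, "c")[, 1]
    tt <- SummarizedExperiment::assay(x, "t")[, 1]
    expect_equal(unname(cc), c(7, 6))
    expect_equal(unname(tt), c(3, 4))
    expect_equal(unname(cc / (cc + tt)), c(0.7, 0.6))
})

test_that("site filters apply the coverage and constancy rules", {
    # 3 sites x 2 samples; site 1 undercovered in sample 2,
    # site 2 constant (all methylated), site 3 mixed and covered
    cC <- rbind(c(10, 5), c(8, 9), c(6, 7))
    tC <- rbind(c(5, 2), c(0, 0), c(2, 1))
    x <- makeScm(cC, tC, gene = rep("g", 3), position = c(3L, 10L, 20L),
                 samples = c("S1", "S2"))
    x <- filterSites(x, minCoverage = 8)
    expect_identical(unname(retainedSites(x)), c(FALSE, FALSE, TRUE))

    # boundary: coverage exactly 8 everywhere with mixed rates retains
    x2 <- makeScm(rbind(c(4, 4)), rbind(c(4, 4)), gene = "g",
                  position = 3L, samples = c("S1", "S2"))
    expect_true(all(retainedSites(filterSites(x2, 8))))

    # raising the threshold never grows the retained set
    set.seed(13)
    cC3 <- matrix(rpois(40, 6), 10)
    tC3 <- matrix(rpois(40, 6), 10)
    x3 <- makeScm(cC3, tC3, gene = rep("g", 10), position = 1:10 * 5L,
                  samples = paste0("S", 1:4))
    prev <- rep(TRUE, 10)
    for (mc in c(2, 5, 8, 12)) {
        cur <- retainedSites(filterSites(x3, mc))
        expect_true(all(prev | !cur))  # cur subset of prev
        prev <- cur
    }
})

test_that("library normalization uses the average total read count", {
    x <- makeScm(rbind(c(40, 120)), rbind(c(60, 180)), gene = "g",
                 position = 3L, samples = c("S1", "S2"))
    x$total_assigned <- c(100L, 300L)
    x <- normalizeLibraries(x)
    expect_equal(unname(normFactors(x)), c(2, 2 / 3))
    # normalized totals all equal the mean, conserving the mean
    expect_equal(mean(c(100, 300) * normFactors(x)), mean(c(100, 300)))

    xe <- makeScm(rbind(c(50, 50)), rbind(c(50, 50)), gene = "g",
                  position = 3L, samples = c("S1", "S2"))
    xe$total_assigned <- c(80L, 80L)
    expect_equal(unname(normFactors(normalizeLibraries(xe))), c(1, 1))

    x0 <- makeScm(rbind(c(10, 0)), rbind(c(10, 0)), gene = "g",
                  position = 3L, samples = c("S1", "S2"))
    x0$total_assigned <- c(20L, 0L)
    expect_warning(x0 <- normalizeLibraries(x0), "zero assigned")
    expect_true(is.na(normFactors(x0)[2]))
})

test_that("gene percentages pool counts over retained sites", {
    # one retained site 5C/5T -> 50%
    x <- makeScm(rbind(5), rbind(5), gene = "g", position = 3L,
                 samples = "S1")
    x <- filterSites(x, minCoverage = 8)
    expect_equal(unname(geneMethylation(x)[, "g"]), 50)

    # pooled vs per-site mean at uneven coverage:
    # site1 10C/2T (cov 12), site2 2C/28T (cov 30)
    x2 <- makeScm(rbind(10, 2), rbind(2, 28), gene = rep("g", 2),
                  position = c(3L, 9L), samples = "S1")
    x2 <- filterSites(x2, minCoverage = 8)
    expect_equal(unname(geneMethylation(x2)[, "g"]),
                 100 * 12 / 42)           # (10+2)/(12+30)
    expect_equal(unname(geneMethylation(x2, type = "mean")[, "g"]),
                 100 * (10 / 12 + 2 / 30) / 2)

    # genes with no retained site come back NA and flagged
    x3 <- makeScm(rbind(10, 3), rbind(0, 9),
                  gene = c("gA", "gB"), position = c(3L, 5L),
                  samples = "S1")
    x3 <- filterSites(x3, minCoverage = 8)   # gA constant -> dropped
    gp <- geneMethylation(x3)
    expect_true(is.na(gp[, "gA"]))
    expect_identical(attr(gp, "flagged_genes"), "gA")

    # everything filtered is an explicit error
    x4 <- makeScm(rbind(2), rbind(2), gene = "g", position = 3L,
                  samples = "S1")
    x4 <- filterSites(x4, minCoverage = 8)
    expect_error(geneMethylation(x4), "empty panel")
    expect_error(geneMethylation(makeScm(rbind(5), rbind(5),
                                         gene = "g", position = 3L,
                                         samples = "S1")),
                 "filterSites")
})

test_that("conversion QC recovers the simulator's conversion efficiency", {
    panel <- tinyPanel()
    cohort <- data.frame(sample_id = "S1", group = "case",
                         true_copies = 10, geneA = 0.5, geneB = 0.5,
                         stringsAsFactors = FALSE)
    d <- withr::local_tempdir()
    files <- simulateBisulfiteReads(
        panel, cohort,
        readSimParams(readsPerAmplicon = 800,
                      conversionEfficiency = 0.99, errorRate = 0,
                      seed = 17), d)
    called <- callMethylation(files, panel)
    expect_lt(abs(conversionRate(called$counts)[["S1"]] - 0.99), 0.005)
})
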