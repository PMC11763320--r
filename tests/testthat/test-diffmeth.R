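test_that("count pooling assembles the group-by-base table", {
    # one site, one sample per group: direct assembly
    x <- makeScm(rbind(c(3, 6)), rbind(c(7, 4)), gene = "g",
                 position = 3L, samples = c("S1", "S2"))
    x <- filterSites(x, minCoverage = 1)
    tab <- poolCounts(x, c("case", "control"), "g")
    expect_equal(unname(tab), rbind(c(3, 7), c(6, 4)))

    # additivity over samples within a group
    x2 <- makeScm(rbind(c(1, 1, 5)), rbind(c(1, 1, 5)), gene = "g",
                  position = 3L, samples = c("S1", "S2", "S3"))
    x2 <- filterSites(x2, minCoverage = 1)
    tab2 <- poolCounts(x2, c("case", "case", "control"), "g")
    expect_equal(unname(tab2["case", ]), c(2, 2))

    # pooling respects the retained-site mask
    x3 <- makeScm(rbind(c(50, 50), c(9, 9)), rbind(c(50, 50), c(1, 1)),
                  gene = rep("g", 2), position = c(3L, 9L),
                  samples = c("S1", "S2"))
    x3 <- filterSites(x3, minCoverage = 11)
    tab3 <- poolCounts(x3, c("case", "control"), "g")
    expect_equal(unname(tab3["case", ]), c(50, 50))
    expect_error(poolCounts(x3, c("case", "case"), "g"), "both groups")
})

test_that("chi-square homogeneity matches hand-computed and z-squared oracles", {
    ht <- chiSquareHomogeneity(rbind(c(30, 70), c(50, 50)))
    # margins give expected counts 40/60 per row: X2 = 2*(100/40+100/60)
    expect_equal(ht$chi2, 25 / 3, tolerance = 1e-12)
    expect_equal(ht$df, 1)
    expect_equal(ht$p_value, pchisq(25 / 3, 1, lower.tail = FALSE),
                 tolerance = 1e-12)

    same <- chiSquareHomogeneity(rbind(c(12, 30), c(12, 30)))
    expect_equal(same$chi2, 0, tolerance = 1e-12)
    expect_equal(same$p_value, 1)

    swapped <- chiSquareHomogeneity(rbind(c(50, 50), c(30, 70)))
    expect_equal(swapped$chi2, ht$chi2, tolerance = 1e-12)

    # equivalence with the two-proportion z statistic
    set.seed(2)
    for (i in 1:20) {
        n1 <- sample(50:500, 1); n2 <- sample(50:500, 1)
        c1 <- rbinom(1, n1, 0.4); c2 <- rbinom(1, n2, 0.6)
        tab <- rbind(c(c1, n1 - c1), c(c2, n2 - c2))
        if (any(colSums(tab) == 0)) next
        p1 <- c1 / n1; p2 <- c2 / n2; pp <- (c1 + c2) / (n1 + n2)
        z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
        expect_equal(chiSquareHomogeneity(tab)$chi2, z^2,
                     tolerance = 1e-10)
    }

    und <- chiSquareHomogeneity(rbind(c(0, 10), c(0, 20)))
    expect_false(und$testable)
})

test_that("direction and significance calls follow the pooled rates", {
    x <- makeScm(rbind(c(20, 50)), rbind(c(80, 50)), gene = "g",
                 position = 3L, samples = c("S1", "S2"))
    x <- filterSites(x, minCoverage = 1)
    res <- testDifferentialMethylation(x, c("case", "control"))
    expect_identical(res$direction, "hypo")
    expect_true(res$significant)
    expect_equal(attr(res, "significant_count"), 1L)

    # swapping group labels flips the direction, not the statistic
    res2 <- testDifferentialMethylation(x, c("control", "case"))
    expect_identical(res2$direction, "hyper")
    expect_equal(res2$chi2, res$chi2, tolerance = 1e-12)

    # BH adjustment is available but off by default
    resBH <- classifyGenes(data.frame(
        gene = c("a", "b"), p_value = c(0.03, 0.04),
        case_rate = c(0.2, 0.2), control_rate = c(0.4, 0.4)),
        alpha = 0.05, adjust = "BH")
    expect_equal(resBH$p_adjusted, c(0.04, 0.04))
})

test_that("null chi-square p-values are uniform and power grows with effect", {
    set.seed(31)
    nulls <- replicate(2000, {
        c1 <- rbinom(1, 600, 0.5); c2 <- rbinom(1, 600, 0.5)
        chiSquareHomogeneity(rbind(c(c1, 600 - c1),
                                   c(c2, 600 - c2)))$p_value
    })
    ks <- suppressWarnings(ks.test(nulls, "punif"))
    expect_lt(unname(ks$statistic), 0.05)

    rejRate <- vapply(c(0, 0.03, 0.06), function(d) {
        rej <- replicate(500, {
            c1 <- rbinom(1, 400, 0.5 - d); c2 <- rbinom(1, 400, 0.5)
            chiSquareHomogeneity(rbind(c(c1, 400 - c1),
                                       c(c2, 400 - c2)))$p_value < 0.05
        })
        mean(rej)
    }, numeric(1))
    expect_true(all(diff(rejRate) >= 0))
})

test_that("simulated group difference is detected in the right direction", {
    # planted case 0.2 vs control 0.5 at the count level
    set.seed(41)
    nS <- 6
    cov <- matrix(500L, 2, nS)
    m <- c(rep(0.2, 3), rep(0.5, 3))
    cC <- rbind(rbinom(nS, 500, m), rbinom(nS, 500, m))
    x <- makeScm(cC, cov - cC, gene = rep("g", 2),
                 position = c(3L, 9L), samples = paste0("S", 1:nS))
    x <- filterSites(x, 8)
    labels <- c(rep("case", 3), rep("control", 3))
    res <- testDifferentialMethylation(x, labels)
    expect_lt(res$case_rate, res$control_rate)
    expect_identical(res$direction, "hypo")
    expect_true(res$significant)
})
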