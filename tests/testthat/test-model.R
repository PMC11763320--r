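suppressGlmnetSmallClass <- function(expr) suppressWarnings(expr)

gaussianTable <- function(n, p = 10, shift = 0, nSignal = 0, seed = 1) {
    set.seed(seed)
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("S%04d", 1:n),
                                sprintf("f%02d", 1:p)))
    lab <- factor(rep(c("control", "case"), length.out = n),
                  levels = c("control", "case"))
    if (nSignal > 0)
        x[lab == "case", seq_len(nSignal)] <-
            x[lab == "case", seq_len(nSignal)] + shift
    d <- as.data.frame(x)
    d$label <- lab
    d
}

test_that("feature table has the expected shape, transform and rules", {
    set.seed(3)
    gp <- matrix(runif(78 * 9, 20, 80), 78, 9,
                 dimnames = list(sprintf("S%03d", 1:78),
                                 rownames(defaultMethLevels())))
    copies <- rlnorm(78, 8, 1)
    labels <- rep(c("case", "control"), c(38, 40))
    ft <- buildFeatureTable(gp, copies, labels)
    expect_equal(dim(ft), c(78, 11))   # 9 genes + copies + label
    expect_identical(attr(ft, "copy_feature"), "log10_copies")
    expect_equal(ft$log10_copies, log10(copies))
    expect_equal(sum(ft$label == "case"), 38)

    ft2 <- buildFeatureTable(matrix(50, 1, 9,
                                    dimnames = list("S1", colnames(gp))),
                             1000, "case")
    expect_equal(ft2$log10_copies, 3)

    # a sample missing most features is excluded; isolated NAs imputed
    gp[1, ] <- NA
    gp[2, 3] <- NA
    expect_warning(ft3 <- buildFeatureTable(gp, copies, labels),
                   "excluding 1 sample")
    expect_equal(nrow(ft3), 77)
    expect_false(anyNA(ft3[[3]]))
    expect_identical(attr(ft3, "imputed")[[colnames(gp)[3]]], "S002")
})

test_that("elastic net at lambda 0 matches unpenalized logistic regression", {
    d <- gaussianTable(200, p = 10, shift = 1, nSignal = 3, seed = 5)
    fit <- fitElasticNet(d, alpha = 0.5, lambda = 0)
    xs <- scale(as.matrix(d[, 1:10]))
    g <- glm(d$label ~ xs, family = binomial())
    expect_lt(max(abs(unname(fit$betas) - unname(coef(g)[-1]))), 1e-4)
    expect_lt(abs(fit$intercept - unname(coef(g)[1])), 1e-4)
})

test_that("total shrinkage leaves only the class-balance intercept", {
    d <- gaussianTable(120, p = 6, shift = 2, nSignal = 2, seed = 6)
    d$label <- factor(rep(c("control", "control", "case"), 40),
                      levels = c("control", "case"))
    fit <- fitElasticNet(d, alpha = 1, lambda = 50)
    expect_true(all(fit$betas == 0))
    expect_equal(fit$intercept, qlogis(mean(d$label == "case")),
                 tolerance = 1e-6)
})

test_that("the lasso zeroes noise features when only two carry signal", {
    nz <- vapply(1:20, function(s) {
        d <- gaussianTable(150, p = 10, shift = 2, nSignal = 2,
                           seed = 100 + s)
        fit <- fitElasticNet(d, alpha = 1, lambda = 0.08)
        sum(fit$betas[3:10] == 0)
    }, numeric(1))
    expect_true(all(nz >= 6))
})

test_that("hyperparameter tuning selects sensibly and honours ties", {
    d <- gaussianTable(80, p = 4, shift = 2, nSignal = 2, seed = 7)
    one <- suppressGlmnetSmallClass(
        tuneHyperparameters(d, alphaGrid = 0.3, lambdaGrid = 0.02,
                            k = 4, seed = 2))
    expect_equal(one$alpha, 0.3)
    expect_equal(one$lambda, 0.02)

    # pure noise: cross-validated AUC hovers near chance
    aucs <- vapply(1:20, function(s) {
        dn <- gaussianTable(60, p = 5, seed = 200 + s)
        suppressGlmnetSmallClass(
            tuneHyperparameters(dn, alphaGrid = c(0, 1), k = 3,
                                seed = s)$cv_auc)
    }, numeric(1))
    expect_gt(mean(aucs), 0.35)
    expect_lt(mean(aucs), 0.65)

    # strong planted signal approaches the Gaussian Bayes AUC
    ds <- gaussianTable(400, p = 5, shift = 2, nSignal = 1, seed = 8)
    tuned <- suppressGlmnetSmallClass(
        tuneHyperparameters(ds, alphaGrid = c(0, 0.5, 1), k = 5,
                            seed = 3))
    expect_lt(abs(tuned$cv_auc - pnorm(2 / sqrt(2))), 0.05)
})

test_that("AUC is rank-based and agrees with an independent implementation", {
    skip_if_not_installed("pROC")
    set.seed(10)
    for (i in 1:5) {
        sc <- rnorm(60)
        lab <- factor(sample(rep(c("control", "case"), 30)),
                      levels = c("control", "case"))
        ref <- as.numeric(suppressMessages(
            pROC::auc(pROC::roc(lab, sc, levels = c("control", "case"),
                                direction = "<"))))
        expect_equal(aucRank(sc, lab), ref, tolerance = 1e-12)
        # invariance under strictly monotone transforms; negation flips
        expect_equal(aucRank(exp(sc), lab), aucRank(sc, lab))
        expect_equal(aucRank(-sc, lab), 1 - aucRank(sc, lab))
    }
})

test_that("confusion metrics are internally consistent", {
    set.seed(12)
    prob <- runif(200)
    lab <- factor(sample(rep(c("control", "case"), c(120, 80))),
                  levels = c("control", "case"))
    m <- classificationMetrics(prob, lab)
    prev <- mean(lab == "case")
    expect_equal(m[["accuracy"]],
                 prev * m[["sensitivity"]] +
                     (1 - prev) * m[["specificity"]],
                 tolerance = 1e-12)
})

test_that("test-fold features never leak into training standardization", {
    d <- gaussianTable(60, p = 4, shift = 1, nSignal = 1, seed = 13)
    fit <- fitElasticNet(d, alpha = 0.5, lambda = 0.05)
    expect_equal(unname(fit$center),
                 unname(colMeans(as.matrix(d[, 1:4]))))
    # an extreme test-only outlier cannot move the training transform
    outlier <- d[1, ]
    outlier[1, 1:4] <- 1e6
    p1 <- cfMethDx:::.predictEnetProb(fit, as.matrix(d[2:10, 1:4]))
    fit2 <- fitElasticNet(d, alpha = 0.5, lambda = 0.05)
    p2 <- cfMethDx:::.predictEnetProb(fit2, as.matrix(
        rbind(outlier[, 1:4], d[2:10, 1:4])))
    expect_equal(unname(p2[-1]), unname(p1), tolerance = 1e-12)
})

test_that("repeated hold-out is seed-deterministic and order-invariant", {
    d <- gaussianTable(60, p = 5, shift = 1.5, nSignal = 2, seed = 14)
    sch <- splitScheme(nSplits = 25, seed = 9)
    tune <- list(alphaGrid = 0.5, lambdaGrid = 0.05, k = 3)
    b1 <- suppressGlmnetSmallClass(
        repeatedHoldout(d, sch, families = "enet", enetTune = tune))
    b2 <- suppressGlmnetSmallClass(
        repeatedHoldout(d, sch, families = "enet", enetTune = tune))
    expect_identical(b1$enet@metrics, b2$enet@metrics)

    # shuffling rows leaves the id-keyed splits (hence metrics) intact
    set.seed(1)
    d3 <- d[sample(nrow(d)), ]
    b3 <- suppressGlmnetSmallClass(
        repeatedHoldout(d3, sch, families = "enet", enetTune = tune))
    expect_equal(b1$enet@summary, b3$enet@summary, tolerance = 1e-12)

    # a perfectly separating feature gives a perfect benchmark
    dsep <- gaussianTable(40, p = 3, seed = 15)
    dsep$f01 <- ifelse(dsep$label == "case", 10, -10)
    bs <- suppressGlmnetSmallClass(
        repeatedHoldout(dsep, splitScheme(nSplits = 10, seed = 2),
                        families = "enet", enetTune = tune))
    expect_equal(unname(bs$enet@summary["mean_auc"]), 1)
    expect_gte(unname(bs$enet@summary["mean_accuracy"]), 0.98)
})

test_that("the INDEX model predicts, serializes and reloads exactly", {
    d <- gaussianTable(100, p = 3, shift = 1, nSignal = 1, seed = 16)
    model <- finalizeIndexModel(d, alpha = 0.5, lambda = 0.02)
    expect_s4_class(model, "IndexModel")

    # hand-computed dot product on the standardized scale
    z <- (as.matrix(d[1, 1:3]) - model@center) / model@scale
    idx <- model@intercept + sum(z * model@betas)
    pr <- predictIndex(model, d[1, ])
    expect_equal(pr$index, unname(idx), tolerance = 1e-12)
    # raw-scale coefficients agree with the standardized ones
    idxRaw <- model@rawIntercept +
        sum(as.matrix(d[1, 1:3]) * model@rawBetas)
    expect_equal(pr$index, unname(idxRaw), tolerance = 1e-9)
    expect_equal(pr$probability, plogis(pr$index), tolerance = 1e-12)

    # strict-inequality decision boundary: p = 0.5 -> control
    m0 <- model
    m0@betas <- rep(0, 3); m0@intercept <- 0
    p0 <- predictIndex(m0, d[1:5, ])
    expect_true(all(p0$probability == 0.5))
    expect_true(all(p0$status == "control"))

    expect_error(predictIndex(model, d[, c("f02", "f03")]),
                 "f01")

    tmp <- withr::local_tempfile(fileext = ".json")
    writeIndexModel(model, tmp)
    back <- readIndexModel(tmp)
    set.seed(17)
    newx <- matrix(rnorm(300), 100, 3,
                   dimnames = list(NULL, model@featureNames))
    expect_equal(predictIndex(back, newx)$index,
                 predictIndex(model, newx)$index, tolerance = 1e-12)
})

test_that("unpenalized coefficients recover planted effects at large n", {
    set.seed(18)
    n <- 2000
    x <- matrix(rnorm(n * 3), n, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    beta <- c(0.8, -0.5, 0)
    eta <- -0.2 + drop(x %*% beta)
    y <- factor(ifelse(runif(n) < plogis(eta), "case", "control"),
                levels = c("control", "case"))
    d <- as.data.frame(x); d$label <- y
    fit <- fitElasticNet(d, alpha = 0, lambda = 0)
    rawBetas <- fit$betas / fit$scale
    g <- glm(y ~ x, family = binomial())
    se <- sqrt(diag(vcov(g)))[-1]
    expect_true(all(abs(rawBetas - beta) < 3 * se))
})

test_that("all five model families return valid, bounded metrics", {
    d <- gaussianTable(60, p = 5, shift = 2, nSignal = 2, seed = 19)
    bm <- suppressWarnings(repeatedHoldout(
        d, splitScheme(nSplits = 10, seed = 4),
        families = c("cart", "logistic", "svm", "rf", "enet"),
        enetTune = list(alphaGrid = 0.5, lambdaGrid = 0.05, k = 3),
        rfTrees = 200))
    for (f in names(bm)) {
        m <- as.matrix(bm[[f]]@metrics[, c("auc", "sensitivity",
                                           "specificity", "accuracy",
                                           "sensitivity_youden",
                                           "specificity_youden",
                                           "accuracy_youden")])
        expect_true(all(m >= 0 & m <= 1), info = f)
        roc <- bm[[f]]@roc
        expect_true(all(diff(roc$mean_tpr) >= -1e-12), info = f)
    }
    # the discriminative families separate a 2-SD shift easily
    expect_gt(bm$enet@summary[["mean_auc"]], 0.8)
    expect_gt(bm$rf@summary[["mean_auc"]], 0.8)
})
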