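#' Assemble the diagnostic feature table
#'
#' One row per sample: the nine gene-level methylation percentages plus
#' one cf-DNA copy-number feature (log10-transformed by default; Table
#' copy numbers span about three decades), and a case/control label.
#' Samples missing more than a third of their features are excluded
#' with a warning; remaining missing percentages are imputed by the
#' per-feature median (the imputation is recorded in the
#' \code{"imputed"} attribute).
#'
#' @param genePct numeric matrix samples x genes (percent, 0-100), as
#'   from \code{\link{geneMethylation}}.
#' @param copies per-sample copy numbers (> 0), aligned with
#'   \code{genePct} rows.
#' @param labels per-sample \code{case}/\code{control} labels.
#' @param log10Copies log10-transform the copy feature (default TRUE).
#' @return data.frame with feature columns, a \code{label} factor
#'   (levels control, case), row names = sample ids; attributes
#'   \code{"copy_feature"}, \code{"imputed"}, \code{"excluded"}.
#' @export
buildFeatureTable <- function(genePct, copies, labels,
                              log10Copies = TRUE) {
    stopifnot(nrow(genePct) == length(copies),
              nrow(genePct) == length(labels))
    labels <- as.character(labels)
    stopifnot(all(labels %in% c("case", "control")))
    if (any(copies <= 0)) stop("all samples need copies > 0")

    copyName <- if (log10Copies) "log10_copies" else "copies"
    feat <- cbind(as.data.frame(genePct),
                  setNames(data.frame(if (log10Copies) log10(copies)
                                      else copies), copyName))
    missFrac <- rowMeans(is.na(feat))
    excluded <- rownames(feat)[missFrac > 1 / 3]
    if (length(excluded)) {
        warning("excluding ", length(excluded),
                " sample(s) missing > 1/3 of features: ",
                paste(excluded, collapse = ", "))
        keep <- missFrac <= 1 / 3
        feat <- feat[keep, , drop = FALSE]
        labels <- labels[keep]
    }
    imputed <- list()
    for (j in colnames(feat)) {
        na <- is.na(feat[[j]])
        if (any(na)) {
            feat[[j]][na] <- median(feat[[j]], na.rm = TRUE)
            imputed[[j]] <- rownames(feat)[na]
        }
    }
    feat$label <- factor(labels, levels = c("control", "case"))
    attr(feat, "copy_feature") <- copyName
    attr(feat, "imputed") <- imputed
    attr(feat, "excluded") <- excluded
    feat
}

.featureMatrix <- function(table) {
    stopifnot("label" %in% colnames(table))
    x <- as.matrix(table[, setdiff(colnames(table), "label"),
                         drop = FALSE])
    y <- table$label
    list(x = x, y = y)
}

# z-score columns by training statistics only; constant columns get
# scale 1 so they standardize to 0 rather than NaN
.trainStats <- function(x) {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, sd)
    scl[!is.finite(scl) | scl < 1e-12] <- 1
    list(center = ctr, scale = scl)
}

.applyStats <- function(x, stats) {
    scale(x, center = stats$center, scale = stats$scale)
}

# glmnet requires >= 2 predictor columns; pad with an all-zero dummy
# (its coefficient is identically zero and is dropped on extraction)
.padForGlmnet <- function(x) {
    if (ncol(x) >= 2L) return(x)
    cbind(x, `.dummy.` = 0)
}

#' Rank-based AUC
#'
#' Probability that a random positive (case) scores above a random
#' negative, ties counted half (Mann-Whitney form; equals the
#' trapezoidal area under the empirical ROC curve).
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels; \code{case}/second factor level is
#'   positive.
#' @return AUC in [0, 1].
#' @export
aucRank <- function(scores, labels) {
    pos <- .isCase(labels)
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(scores)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.isCase <- function(labels) {
    if (is.factor(labels)) labels == levels(labels)[nlevels(labels)]
    else labels == "case" | labels == 1
}

#' Confusion-based classification metrics
#'
#' @param prob predicted case probabilities.
#' @param labels true labels (case = positive).
#' @param threshold probability cut-off; predicted case iff prob >
#'   threshold (strict).
#' @return named numeric: \code{auc}, \code{sensitivity},
#'   \code{specificity}, \code{accuracy}.
#' @export
classificationMetrics <- function(prob, labels, threshold = 0.5) {
    pos <- .isCase(labels)
    pred <- prob > threshold
    tp <- sum(pred & pos); fn <- sum(!pred & pos)
    tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
    c(auc = aucRank(prob, labels),
      sensitivity = tp / (tp + fn),
      specificity = tn / (tn + fp),
      accuracy = (tp + tn) / length(pos))
}

#' Fit an elastic-net logistic model
#'
#' Penalized logistic regression minimizing the average binomial
#' deviance plus lambda * [alpha * sum|beta| + (1 - alpha)/2 *
#' sum beta^2] over the slope coefficients (intercept unpenalized).
#' Features are z-scored with statistics computed from the supplied
#' (training) data only; the statistics are stored with the fit so
#' prediction applies the same transform.
#'
#' @param features feature table from \code{\link{buildFeatureTable}} (or
#'   any data.frame with numeric features and a \code{label} column).
#' @param alpha elastic-net mixing weight in [0, 1] (1 = lasso,
#'   0 = ridge).
#' @param lambda penalty strength (>= 0).
#' @return list of class \code{ElasticNetFit}: \code{intercept},
#'   \code{betas} (standardized scale), \code{center}, \code{scale},
#'   \code{alpha}, \code{lambda}.
#' @export
fitElasticNet <- function(features, alpha, lambda) {
    fm <- .featureMatrix(features)
    if (min(table(fm$y)) < 2)
        stop("degenerate training fold: need >= 2 samples per class")
    st <- .trainStats(fm$x)
    xs <- .padForGlmnet(.applyStats(fm$x, st))
    # glmnet converges most reliably along a decreasing lambda path
    lamSeq <- if (lambda > 0)
        sort(unique(c(lambda, lambda * c(100, 10, 2))),
             decreasing = TRUE)
    else c(0.1, 0.01, 0.001, 0)
    fit <- glmnet::glmnet(xs, fm$y, family = "binomial", alpha = alpha,
                          lambda = lamSeq, standardize = FALSE,
                          thresh = 1e-12, maxit = 1e6)
    cf <- as.numeric(coef(fit, s = lambda,
                          exact = FALSE))[seq_len(ncol(fm$x) + 1L)]
    structure(list(intercept = cf[1],
                   betas = setNames(cf[-1], colnames(fm$x)),
                   center = st$center, scale = st$scale,
                   alpha = alpha, lambda = lambda),
              class = "ElasticNetFit")
}

.predictEnetProb <- function(fit, x) {
    xs <- .applyStats(as.matrix(x), list(center = fit$center,
                                         scale = fit$scale))
    plogis(fit$intercept + drop(xs %*% fit$betas))
}

# glmnet-style lambda path: lambda_max (smallest lambda with all slopes
# zero) down `decades` decades on a log grid
.lambdaPath <- function(x, y, alpha, nLambda = 50, decades = 4) {
    xs <- .applyStats(x, .trainStats(x))
    yy <- .isCase(y) - mean(.isCase(y))
    lamMax <- max(abs(crossprod(xs, yy))) / (nrow(x) * max(alpha, 0.001))
    10^seq(log10(lamMax), log10(lamMax) - decades, length.out = nLambda)
}

.stratifiedFolds <- function(y, k) {
    pos <- which(.isCase(y)); neg <- which(!.isCase(y))
    f <- integer(length(y))
    f[pos] <- sample(rep_len(seq_len(k), length(pos)))
    f[neg] <- sample(rep_len(seq_len(k), length(neg)))
    f
}

#' Tune elastic-net hyperparameters by stratified cross-validation
#'
#' Grid search over the mixing weight alpha and penalty lambda by
#' stratified k-fold cross-validation inside the training set,
#' maximizing mean CV AUC. Ties prefer the larger lambda, then the
#' larger alpha (the more parsimonious model). If a class has fewer
#' members than k, k is reduced with a warning.
#'
#' @param features training feature table (with \code{label}).
#' @param alphaGrid candidate mixing weights (default 0, 0.1, ..., 1).
#' @param lambdaGrid candidate penalties; \code{NULL} (default) builds a
#'   50-point log grid per alpha from lambda_max down 4 decades.
#' @param k folds (>= 2, default 5).
#' @param seed integer seed for the fold assignment.
#' @return list: \code{alpha}, \code{lambda}, \code{cv_auc}, and the
#'   full \code{grid} of mean CV AUCs.
#' @export
tuneHyperparameters <- function(features,
                                alphaGrid = seq(0, 1, by = 0.1),
                                lambdaGrid = NULL, k = 5, seed = 1) {
    stopifnot(k >= 2, length(alphaGrid) >= 1)
    fm <- .featureMatrix(features)
    minClass <- min(table(fm$y))
    if (minClass < k) {
        warning("reducing k from ", k, " to ", minClass,
                " (smallest class size)")
        k <- max(2L, minClass)
    }
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old))
    set.seed(seed)
    folds <- .stratifiedFolds(fm$y, k)

    best <- NULL
    grid <- list()
    for (a in sort(alphaGrid)) {
        lams <- if (is.null(lambdaGrid))
            .lambdaPath(fm$x, fm$y, a) else sort(lambdaGrid,
                                                 decreasing = TRUE)
        aucs <- matrix(NA_real_, k, length(lams))
        for (f in seq_len(k)) {
            tr <- folds != f; te <- !tr
            if (min(table(fm$y[tr])) < 2 ||
                length(unique(fm$y[te])) < 2) next
            st <- .trainStats(fm$x[tr, , drop = FALSE])
            xs <- .padForGlmnet(.applyStats(fm$x[tr, , drop = FALSE],
                                            st))
            fit <- glmnet::glmnet(xs, fm$y[tr], family = "binomial",
                                  alpha = a, lambda = lams,
                                  standardize = FALSE)
            pr <- predict(fit,
                          .padForGlmnet(.applyStats(
                              fm$x[te, , drop = FALSE], st)),
                          s = lams, type = "response")
            aucs[f, ] <- apply(pr, 2L, aucRank, labels = fm$y[te])
        }
        mean_auc <- colMeans(aucs, na.rm = TRUE)
        grid[[length(grid) + 1L]] <-
            data.frame(alpha = a, lambda = lams, cv_auc = mean_auc)
        for (j in seq_along(lams)) {
            cand <- list(alpha = a, lambda = lams[j],
                         cv_auc = mean_auc[j])
            if (!is.finite(cand$cv_auc)) next
            if (is.null(best) ||
                cand$cv_auc > best$cv_auc + 1e-12 ||
                (abs(cand$cv_auc - best$cv_auc) <= 1e-12 &&
                 (cand$lambda > best$lambda + 1e-12 ||
                  (abs(cand$lambda - best$lambda) <= 1e-12 &&
                   cand$alpha > best$alpha))))
                best <- cand
        }
    }
    if (is.null(best))
        stop("training set too small for cross-validated tuning")
    c(best, list(grid = do.call(rbind, grid)))
}

#' Hold-out split scheme
#'
#' @param nSplits number of randomized train/test splits (default
#'   5000).
#' @param trainFraction fraction of each class used for training
#'   (default 0.7).
#' @param stratified stratify the partition by class (default TRUE).
#' @param seed integer seed; (table, seed) fully determines all
#'   partitions.
#' @return a validated list of class \code{SplitScheme}.
#' @export
splitScheme <- function(nSplits = 5000, trainFraction = 0.7,
                        stratified = TRUE, seed = 1) {
    stopifnot(nSplits >= 1, trainFraction > 0, trainFraction < 1)
    structure(list(nSplits = as.integer(nSplits),
                   trainFraction = trainFraction,
                   stratified = stratified, seed = as.integer(seed)),
              class = "SplitScheme")
}

# Sample ids keyed by sorted id so row order cannot change the splits
.drawSplit <- function(ids, isCase, trainFraction, stratified) {
    ord <- order(ids)
    ids <- ids[ord]; isCase <- isCase[ord]
    pick <- function(v) {
        k <- max(2L, round(trainFraction * length(v)))
        k <- min(k, length(v) - 1L)
        sample(v, k)
    }
    train <- if (stratified) c(pick(ids[isCase]), pick(ids[!isCase]))
             else pick(ids)
    list(train = train, test = setdiff(ids, train))
}

.FAMILIES <- c("cart", "logistic", "svm", "rf", "enet")

# Fit one model family on standardized-or-raw features, return a
# case-probability prediction function
.fitFamily <- function(family, xTrain, yTrain, enetTune, rfTrees) {
    switch(family,
        cart = {
            d <- data.frame(xTrain, y = yTrain, check.names = FALSE)
            fit <- rpart::rpart(y ~ ., data = d, method = "class")
            function(xTest)
                predict(fit, data.frame(xTest, check.names = FALSE),
                        type = "prob")[, "case"]
        },
        logistic = {
            st <- .trainStats(xTrain)
            d <- data.frame(.applyStats(xTrain, st), y = yTrain,
                            check.names = FALSE)
            fit <- suppressWarnings(
                stats::glm(y ~ ., data = d, family = stats::binomial()))
            function(xTest)
                suppressWarnings(predict(
                    fit, data.frame(.applyStats(xTest, st),
                                    check.names = FALSE),
                    type = "response"))
        },
        svm = {
            st <- .trainStats(xTrain)
            fit <- e1071::svm(.applyStats(xTrain, st), yTrain,
                              kernel = "radial", probability = TRUE,
                              scale = FALSE)
            function(xTest) {
                pr <- predict(fit, .applyStats(xTest, st),
                              probability = TRUE)
                attr(pr, "probabilities")[, "case"]
            }
        },
        rf = {
            fit <- randomForest::randomForest(xTrain, yTrain,
                                              ntree = rfTrees)
            function(xTest)
                predict(fit, xTest, type = "prob")[, "case"]
        },
        enet = {
            d <- data.frame(xTrain, check.names = FALSE)
            d$label <- yTrain
            tuned <- tuneHyperparameters(
                d, alphaGrid = enetTune$alphaGrid,
                lambdaGrid = enetTune$lambdaGrid, k = enetTune$k,
                seed = sample.int(2^31 - 2, 1))
            fit <- fitElasticNet(d, alpha = tuned$alpha,
                                 lambda = tuned$lambda)
            function(xTest) .predictEnetProb(fit, xTest)
        },
        stop("unknown model family: ", family))
}

#' BenchmarkResult: repeated hold-out metrics for one model family
#'
#' @slot family model family name.
#' @slot metrics data.frame of per-split AUC, sensitivity, specificity,
#'   accuracy.
#' @slot summary named numeric of means and SDs across splits.
#' @slot roc data.frame \code{fpr}, \code{mean_tpr}: the vertically
#'   averaged ROC curve.
#' @slot aucAveraged area under the averaged ROC curve.
#' @slot nRedraws number of degenerate splits redrawn.
#' @exportClass BenchmarkResult
setClass("BenchmarkResult",
         slots = c(family = "character", metrics = "data.frame",
                   summary = "numeric", roc = "data.frame",
                   aucAveraged = "numeric", nRedraws = "integer"))

setMethod("show", "BenchmarkResult", function(object) {
    s <- object@summary
    cat(sprintf("BenchmarkResult [%s]: %d splits\n", object@family,
                nrow(object@metrics)))
    cat(sprintf(paste0("  mean AUC %.3f (sd %.3f), sens %.3f,",
                       " spec %.3f, acc %.3f\n"),
                s["mean_auc"], s["sd_auc"], s["mean_sensitivity"],
                s["mean_specificity"], s["mean_accuracy"]))
    cat(sprintf("  AUC of averaged ROC %.3f\n", object@aucAveraged))
})

#' Benchmark model families over repeated stratified hold-out splits
#'
#' For each randomized split the data are partitioned (stratified by
#' class, 70/30 by default), each requested family is fitted on the
#' training part (elastic net with inner cross-validated tuning; the
#' comparator families with fixed documented defaults), and test-set
#' AUC, sensitivity, specificity and accuracy (probability threshold
#' 0.5, case = positive) are recorded. All randomness derives from the
#' scheme seed, so re-running reproduces every partition and metric.
#' Alongside the fixed-threshold confusion metrics, each split also
#' records the Youden-optimal threshold estimated on its training
#' fold and the test metrics at that threshold; these are reported
#' for reference and never replace the fixed-threshold headline
#' numbers.
#'
#' @param features feature table with \code{label}.
#' @param scheme a \code{\link{splitScheme}}.
#' @param families subset of \code{cart}, \code{logistic}, \code{svm},
#'   \code{rf}, \code{enet}.
#' @param enetTune list of tuning settings for the elastic net:
#'   \code{alphaGrid}, \code{lambdaGrid} (NULL = automatic path),
#'   \code{k}.
#' @param rfTrees random-forest size (default 500).
#' @param threshold probability threshold for the confusion metrics.
#' @return named list of \link{BenchmarkResult-class}, one per family.
#' @export
repeatedHoldout <- function(features, scheme = splitScheme(),
                            families = .FAMILIES,
                            enetTune = list(alphaGrid = c(0, 0.5, 1),
                                            lambdaGrid = NULL, k = 5),
                            rfTrees = 500, threshold = 0.5) {
    stopifnot(inherits(scheme, "SplitScheme"),
              all(families %in% .FAMILIES))
    fm <- .featureMatrix(features)
    ids <- rownames(features)
    if (is.null(ids)) ids <- sprintf("row%05d", seq_len(nrow(table)))
    isCase <- .isCase(fm$y)
    if (sum(isCase) < 3 || sum(!isCase) < 3)
        stop("need >= 3 samples per class for a 70/30 split scheme")

    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old))
    set.seed(scheme$seed)
    splitSeeds <- sample.int(2^31 - 2, scheme$nSplits)

    metrics <- lapply(families, function(f)
        matrix(NA_real_, scheme$nSplits, 8,
               dimnames = list(NULL, c("auc", "sensitivity",
                                       "specificity", "accuracy",
                                       "youden_threshold",
                                       "sensitivity_youden",
                                       "specificity_youden",
                                       "accuracy_youden"))))
    names(metrics) <- families
    scores <- lapply(families, function(f) vector("list", scheme$nSplits))
    names(scores) <- families
    testLabels <- vector("list", scheme$nSplits)
    nRedraws <- 0L

    for (s in seq_len(scheme$nSplits)) {
        set.seed(splitSeeds[s])
        repeat {
            sp <- .drawSplit(ids, isCase, scheme$trainFraction,
                             scheme$stratified)
            trIdx <- match(sp$train, ids); teIdx <- match(sp$test, ids)
            okTr <- min(table(fm$y[trIdx])) >= 2
            okTe <- min(table(fm$y[teIdx])) >= 1
            if (okTr && okTe) break
            nRedraws <- nRedraws + 1L
        }
        testLabels[[s]] <- fm$y[teIdx]
        for (f in families) {
            set.seed(.deriveSeed(splitSeeds[s], match(f, .FAMILIES)))
            pred <- .fitFamily(f, fm$x[trIdx, , drop = FALSE],
                               fm$y[trIdx], enetTune, rfTrees)
            prob <- pred(fm$x[teIdx, , drop = FALSE])
            # Youden-optimal threshold, chosen on the training fold;
            # reported alongside, never used for the headline metrics
            ty <- .youdenThreshold(pred(fm$x[trIdx, , drop = FALSE]),
                                   fm$y[trIdx])
            my <- classificationMetrics(prob, fm$y[teIdx],
                                        threshold = ty)
            metrics[[f]][s, ] <- c(classificationMetrics(
                prob, fm$y[teIdx], threshold = threshold),
                ty, my[["sensitivity"]], my[["specificity"]],
                my[["accuracy"]])
            scores[[f]][[s]] <- prob
        }
    }

    out <- lapply(families, function(f) {
        m <- as.data.frame(metrics[[f]])
        roc <- averageRoc(scores[[f]], testLabels)
        new("BenchmarkResult", family = f, metrics = m,
            summary = c(mean_auc = mean(m$auc), sd_auc = sd(m$auc),
                        mean_sensitivity = mean(m$sensitivity),
                        mean_specificity = mean(m$specificity),
                        mean_accuracy = mean(m$accuracy),
                        mean_sensitivity_youden =
                            mean(m$sensitivity_youden),
                        mean_specificity_youden =
                            mean(m$specificity_youden),
                        mean_accuracy_youden = mean(m$accuracy_youden)),
            roc = roc, aucAveraged = attr(roc, "auc"),
            nRedraws = nRedraws)
    })
    names(out) <- families
    out
}

#' Vertically averaged ROC curve
#'
#' Per split, the empirical ROC curve is evaluated (TPR as a function
#' of FPR, interpolating linearly between ROC vertices, so tied scores
#' contribute sloped segments) on a fixed grid of 101 FPR points, then
#' averaged across splits. The area under the averaged
#' curve (trapezoidal) is attached as the \code{"auc"} attribute.
#'
#' @param scoreList list of per-split score vectors.
#' @param labelList list of per-split label vectors (case = positive).
#' @param grid FPR grid (default 101 points on [0, 1]).
#' @return data.frame \code{fpr}, \code{mean_tpr} with attribute
#'   \code{"auc"}.
#' @export
averageRoc <- function(scoreList, labelList,
                       grid = seq(0, 1, length.out = 101)) {
    stopifnot(length(scoreList) == length(labelList),
              length(scoreList) >= 1)
    tprs <- vapply(seq_along(scoreList), function(i)
        .tprAtFpr(scoreList[[i]], labelList[[i]], grid),
        numeric(length(grid)))
    out <- data.frame(fpr = grid, mean_tpr = rowMeans(tprs))
    attr(out, "auc") <- sum(diff(grid) *
                            (head(out$mean_tpr, -1) +
                             out$mean_tpr[-1]) / 2)
    out
}

# Threshold maximizing Youden's J = sensitivity + specificity - 1,
# evaluated at midpoints between adjacent observed probabilities
.youdenThreshold <- function(prob, labels) {
    pos <- .isCase(labels)
    cand <- sort(unique(prob))
    th <- if (length(cand) > 1)
        c(-Inf, (cand[-1] + cand[-length(cand)]) / 2) else -Inf
    j <- vapply(th, function(t) {
        pred <- prob > t
        sum(pred & pos) / sum(pos) + sum(!pred & !pos) / sum(!pos) - 1
    }, numeric(1))
    th[which.max(j)]
}

.tprAtFpr <- function(scores, labels, grid) {
    pos <- .isCase(labels)
    n1 <- sum(pos); n0 <- sum(!pos)
    ord <- order(scores, decreasing = TRUE)
    tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
    # collapse tied scores to the last point of each tie group
    keep <- c(diff(scores[ord]) != 0, TRUE)
    fpr <- c(0, fp[keep] / n0); tpr <- c(0, tp[keep] / n1)
    stats::approx(fpr, tpr, xout = grid, ties = max, rule = 2)$y
}
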