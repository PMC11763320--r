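#' IndexModel: the final linear diagnostic INDEX
#'
#' The diagnostic score is a linear combination of the feature values
#' and their fitted beta coefficients:
#' INDEX(x) = intercept + sum_j beta_j x_j, with predicted case
#' probability 1 / (1 + exp(-INDEX)) and predicted status case iff the
#' probability strictly exceeds the decision threshold. Betas are
#' stored on the standardized scale together with the training
#' center/scale, plus the equivalent raw-scale coefficients.
#'
#' @slot featureNames feature column names, in fixed order.
#' @slot center,scale training-set standardization statistics.
#' @slot intercept,betas coefficients on the standardized scale.
#' @slot rawIntercept,rawBetas equivalent coefficients on the raw
#'   feature scale.
#' @slot alpha,lambda elastic-net hyperparameters used for the fit.
#' @slot threshold decision threshold on the predicted probability.
#' @exportClass IndexModel
setClass("IndexModel",
         slots = c(featureNames = "character", center = "numeric",
                   scale = "numeric", intercept = "numeric",
                   betas = "numeric", rawIntercept = "numeric",
                   rawBetas = "numeric", alpha = "numeric",
                   lambda = "numeric", threshold = "numeric"))

setValidity("IndexModel", function(object) {
    n <- length(object@featureNames)
    if (length(object@betas) != n || length(object@rawBetas) != n ||
        length(object@center) != n || length(object@scale) != n)
        return("coefficient/statistic lengths must match featureNames")
    if (object@alpha < 0 || object@alpha > 1)
        return("alpha must lie in [0, 1]")
    if (object@lambda < 0) return("lambda must be >= 0")
    TRUE
})

setMethod("show", "IndexModel", function(object) {
    cat(sprintf(paste0("IndexModel: %d features, alpha = %.2f, ",
                       "lambda = %.4g, threshold = %.2f\n"),
                length(object@featureNames), object@alpha,
                object@lambda, object@threshold))
    nz <- sum(object@betas != 0)
    cat(sprintf("  non-zero betas: %d of %d\n", nz,
                length(object@betas)))
})

#' @describeIn finalizeIndexModel standardized-scale coefficients
#'   (intercept first).
#' @param object an \code{IndexModel}.
#' @export
setMethod("coef", "IndexModel", function(object, ...) {
    c("(Intercept)" = object@intercept,
      setNames(object@betas, object@featureNames))
})

#' Fit the final INDEX model on the full feature table
#'
#' Elastic-net logistic fit at the tuned hyperparameters on the whole
#' cohort, packaged as a serializable \link{IndexModel-class}.
#'
#' @param features feature table with \code{label}
#'   (\code{\link{buildFeatureTable}}).
#' @param alpha,lambda tuned elastic-net hyperparameters.
#' @param threshold decision threshold on the predicted probability
#'   (default 0.5).
#' @return an \link{IndexModel-class}.
#' @export
finalizeIndexModel <- function(features, alpha, lambda,
                               threshold = 0.5) {
    fit <- fitElasticNet(features, alpha = alpha, lambda = lambda)
    rawBetas <- fit$betas / fit$scale
    rawIntercept <- fit$intercept - sum(fit$betas * fit$center /
                                        fit$scale)
    new("IndexModel", featureNames = names(fit$betas),
        center = unname(fit$center), scale = unname(fit$scale),
        intercept = fit$intercept, betas = unname(fit$betas),
        rawIntercept = rawIntercept, rawBetas = unname(rawBetas),
        alpha = alpha, lambda = lambda, threshold = threshold)
}

#' Predict the INDEX score and status for new samples
#'
#' index = intercept + sum(beta * z), with z the features standardized
#' by the model's stored training statistics; probability =
#' 1/(1 + exp(-index)); status = case iff probability > threshold
#' (strict, so probability exactly at the threshold gives control).
#'
#' @param model an \link{IndexModel-class}.
#' @param features data.frame or matrix containing every model feature
#'   column (extra columns, e.g. \code{label}, are ignored).
#' @return data.frame: \code{index}, \code{probability}, \code{status}.
#' @export
predictIndex <- function(model, features) {
    stopifnot(is(model, "IndexModel"))
    features <- as.data.frame(features)
    miss <- setdiff(model@featureNames, colnames(features))
    if (length(miss))
        stop("missing feature column(s): ", paste(miss, collapse = ", "))
    x <- as.matrix(features[, model@featureNames, drop = FALSE])
    z <- scale(x, center = model@center, scale = model@scale)
    idx <- model@intercept + drop(z %*% model@betas)
    prob <- plogis(idx)
    data.frame(index = idx, probability = prob,
               status = ifelse(prob > model@threshold, "case",
                               "control"),
               row.names = rownames(features))
}

#' Serialize / restore an INDEX model as JSON
#'
#' The JSON stores every slot at full double precision, so
#' save-then-load reproduces predictions bit-for-bit.
#'
#' @param model an \link{IndexModel-class}.
#' @param path JSON file path.
#' @return \code{writeIndexModel} invisibly returns \code{path};
#'   \code{readIndexModel} returns the restored
#'   \link{IndexModel-class}.
#' @export
writeIndexModel <- function(model, path) {
    stopifnot(is(model, "IndexModel"))
    obj <- list(featureNames = model@featureNames,
                center = model@center, scale = model@scale,
                intercept = model@intercept, betas = model@betas,
                rawIntercept = model@rawIntercept,
                rawBetas = model@rawBetas, alpha = model@alpha,
                lambda = model@lambda, threshold = model@threshold)
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeIndexModel
#' @export
readIndexModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("IndexModel", featureNames = obj$featureNames,
        center = as.numeric(obj$center), scale = as.numeric(obj$scale),
        intercept = as.numeric(obj$intercept),
        betas = as.numeric(obj$betas),
        rawIntercept = as.numeric(obj$rawIntercept),
        rawBetas = as.numeric(obj$rawBetas),
        alpha = as.numeric(obj$alpha), lambda = as.numeric(obj$lambda),
        threshold = as.numeric(obj$threshold))
}
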