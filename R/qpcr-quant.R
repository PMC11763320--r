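#' StandardCurve: fitted Cq vs log10(copies) calibration line
#'
#' Ordinary least-squares fit of Cq on log10 input copies, with the
#' derived amplification efficiency E = 10^(-1/slope) - 1 (E = 1 means
#' perfect doubling per cycle).
#'
#' @slot slope Cq per log10 copies (negative for a valid curve).
#' @slot intercept Cq at 1 copy.
#' @slot rSquared coefficient of determination of the fit.
#' @slot efficiency amplification efficiency.
#' @slot nStandards number of standard points used.
#' @slot positiveSlope TRUE if the fitted slope was non-negative (the
#'   curve is flagged rather than rejected).
#'
#' @param x a \code{StandardCurve}.
#' @aliases curveSlope curveIntercept curveEfficiency curveR2
#' @exportClass StandardCurve
setClass("StandardCurve",
         slots = c(slope = "numeric", intercept = "numeric",
                   rSquared = "numeric", efficiency = "numeric",
                   nStandards = "integer", positiveSlope = "logical"))

setValidity("StandardCurve", function(object) {
    if (object@rSquared < -1e-9 || object@rSquared > 1 + 1e-9)
        return("rSquared must lie in [0, 1]")
    if (!object@positiveSlope && object@efficiency <= -1)
        return("efficiency must be > -1")
    TRUE
})

#' @rdname StandardCurve-class
#' @export
setMethod("curveSlope", "StandardCurve", function(x) x@slope)
#' @rdname StandardCurve-class
#' @export
setMethod("curveIntercept", "StandardCurve", function(x) x@intercept)
#' @rdname StandardCurve-class
#' @export
setMethod("curveEfficiency", "StandardCurve", function(x) x@efficiency)
#' @rdname StandardCurve-class
#' @export
setMethod("curveR2", "StandardCurve", function(x) x@rSquared)

setMethod("show", "StandardCurve", function(object) {
    cat(sprintf(paste0("StandardCurve: Cq = %.4f %+.4f * log10(copies)\n",
                       "  R^2 = %.4f, efficiency = %.3f (n = %d)\n"),
                object@intercept, object@slope, object@rSquared,
                object@efficiency, object@nStandards))
    if (object@positiveSlope)
        cat("  WARNING: non-negative slope; curve is not usable\n")
})

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(copies) over a standard
#' dilution series.
#'
#' @param standards data.frame with columns \code{copies} (> 0) and
#'   \code{cq}; at least 3 distinct concentrations.
#' @return a \link{StandardCurve-class} object.
#' @examples
#' std <- data.frame(copies = 10^(1:5), cq = 40 - 3.3219 * (1:5))
#' fitStandardCurve(std)
#' @export
fitStandardCurve <- function(standards) {
    stopifnot(all(c("copies", "cq") %in% colnames(standards)))
    if (any(standards$copies <= 0))
        stop("all standard copy numbers must be positive")
    if (length(unique(standards$copies)) < 3)
        stop("insufficient standards: need >= 3 distinct concentrations")
    x <- log10(standards$copies)
    fit <- lm(cq ~ x, data = data.frame(cq = standards$cq, x = x))
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    r2 <- suppressWarnings(summary(fit)$r.squared)
    pos <- slope >= 0
    if (pos)
        warning("fitted standard-curve slope is non-negative")
    eff <- if (pos) NA_real_ else 10^(-1 / slope) - 1
    new("StandardCurve", slope = slope, intercept = intercept,
        rSquared = r2, efficiency = eff,
        nStandards = nrow(standards), positiveSlope = pos)
}

#' Absolute quantification of one sample from Cq replicates
#'
#' Each replicate is back-transformed through the standard curve,
#' Q_r = 10^((Cq_r - intercept)/slope), and the reported concentration
#' is the mean of the replicate copies. Copies per mL serum scale the
#' per-reaction value by (eluate volume / reaction input volume) /
#' serum volume (defaults 50 uL / 5 uL / 1 mL, i.e. x10).
#'
#' @param cqValues numeric vector of replicate Cq values (typically 3).
#' @param curve a fitted \link{StandardCurve-class}.
#' @param volumes named numeric: \code{serumMl}, \code{eluateUl},
#'   \code{inputUl}.
#' @param cvThreshold replicate coefficient-of-variation above which the
#'   result is QC-flagged (never rejected).
#' @return list of class \code{QuantResult}: \code{cq_values},
#'   \code{copies_per_reaction}, \code{copies_per_ml_serum}, \code{cv},
#'   \code{qc_flag}.
#' @examples
#' curve <- fitStandardCurve(
#'     data.frame(copies = 10^(1:5), cq = 40 - 3.3219 * (1:5)))
#' quantifySample(c(30.1, 30.0, 30.2), curve)
#' @export
quantifySample <- function(cqValues, curve,
                           volumes = c(serumMl = 1, eluateUl = 50,
                                       inputUl = 5),
                           cvThreshold = 0.3) {
    stopifnot(is(curve, "StandardCurve"))
    if (length(cqValues) == 0)
        stop("empty Cq list")
    if (any(!is.finite(cqValues)))
        stop("all Cq values must be finite")
    if (curve@positiveSlope)
        stop("cannot quantify against a curve with non-negative slope")
    q <- 10^((cqValues - curve@intercept) / curve@slope)
    copies <- mean(q)
    cv <- if (length(q) > 1 && copies > 0) sd(q) / copies else NA_real_
    scaling <- (volumes[["eluateUl"]] / volumes[["inputUl"]]) /
        volumes[["serumMl"]]
    structure(list(cq_values = cqValues,
                   copies_per_reaction = copies,
                   copies_per_ml_serum = copies * scaling,
                   cv = cv,
                   qc_flag = isTRUE(cv > cvThreshold)),
              class = "QuantResult")
}

#' Quantify a whole sample sheet
#'
#' @param samples data.frame with \code{sample_id} and Cq replicate
#'   columns \code{cq1}, \code{cq2}, ... (as written by
#'   \code{\link{simulateQpcr}}).
#' @inheritParams quantifySample
#' @return data.frame: \code{sample_id}, \code{copies_per_reaction},
#'   \code{copies_per_ml_serum}, \code{cv}, \code{qc_flag}.
#' @export
quantifySamples <- function(samples, curve,
                            volumes = c(serumMl = 1, eluateUl = 50,
                                        inputUl = 5),
                            cvThreshold = 0.3) {
    cqCols <- grep("^cq[0-9]+$", colnames(samples), value = TRUE)
    if (!length(cqCols))
        stop("no cq replicate columns (cq1, cq2, ...) found")
    res <- lapply(seq_len(nrow(samples)), function(i)
        quantifySample(as.numeric(samples[i, cqCols]), curve,
                       volumes = volumes, cvThreshold = cvThreshold))
    data.frame(sample_id = samples$sample_id,
               copies_per_reaction =
                   vapply(res, `[[`, numeric(1), "copies_per_reaction"),
               copies_per_ml_serum =
                   vapply(res, `[[`, numeric(1), "copies_per_ml_serum"),
               cv = vapply(res, `[[`, numeric(1), "cv"),
               qc_flag = vapply(res, `[[`, logical(1), "qc_flag"),
               stringsAsFactors = FALSE)
}

#' Compare case/control copy-number summaries
#'
#' Arithmetic layer shared by \code{\link{summarizeGroups}}: differences
#' and ratios of group means and medians, with printed factors rounded
#' half-up to one decimal at report time.
#'
#' @param caseStats,controlStats named numeric with at least \code{mean}
#'   and \code{median} (optionally \code{max}, \code{min}).
#' @return list with \code{difference_of_means},
#'   \code{difference_of_medians}, \code{factor_means},
#'   \code{factor_medians} (1-decimal) and the unrounded
#'   \code{factor_means_raw}, \code{factor_medians_raw}.
#' @examples
#' compareGroupSummaries(c(mean = 14762, median = 8602),
#'                       c(mean = 3166, median = 2224))
#' @export
compareGroupSummaries <- function(caseStats, controlStats) {
    stopifnot(all(c("mean", "median") %in% names(caseStats)),
              all(c("mean", "median") %in% names(controlStats)))
    fm <- caseStats[["mean"]] / controlStats[["mean"]]
    fd <- caseStats[["median"]] / controlStats[["median"]]
    list(difference_of_means = caseStats[["mean"]] - controlStats[["mean"]],
         difference_of_medians =
             caseStats[["median"]] - controlStats[["median"]],
         factor_means = roundHalfUp(fm, 1),
         factor_medians = roundHalfUp(fd, 1),
         factor_means_raw = fm,
         factor_medians_raw = fd)
}

#' Group-level copy-number summary and one-way ANOVA
#'
#' Per-group mean/median/max/min copy numbers, case-control differences
#' and 1-decimal factors, and a one-way ANOVA F-test (df 1, n - 2) on
#' the raw copy numbers (use \code{logScale = TRUE} for a log10-scale
#' test).
#'
#' @param copies numeric vector of copy numbers (one per sample).
#' @param labels factor/character of group labels, \code{"case"} /
#'   \code{"control"}.
#' @param logScale test log10(copies) instead of raw copies.
#' @return list of class \code{CohortComparison}: \code{groups} (summary
#'   matrix), the difference/factor fields of
#'   \code{\link{compareGroupSummaries}}, \code{anova_f}, \code{anova_p},
#'   \code{anova_df}, \code{anova_flag}.
#' @export
summarizeGroups <- function(copies, labels, logScale = FALSE) {
    labels <- as.character(labels)
    stopifnot(length(copies) == length(labels),
              all(labels %in% c("case", "control")))
    if (!any(labels == "case") || !any(labels == "control"))
        stop("both groups must be nonempty")
    stat <- function(x) c(mean = mean(x), median = median(x),
                          max = max(x), min = min(x))
    caseStats <- stat(copies[labels == "case"])
    controlStats <- stat(copies[labels == "control"])
    cmp <- compareGroupSummaries(caseStats, controlStats)

    nCase <- sum(labels == "case"); nControl <- sum(labels == "control")
    if (nCase < 2 || nControl < 2) {
        an <- list(anova_f = NA_real_, anova_p = NA_real_,
                   anova_df = c(NA_real_, NA_real_),
                   anova_flag = "omitted: a group has < 2 samples")
    } else {
        y <- if (logScale) log10(copies) else copies
        ft <- oneway.test(y ~ g,
                          data = data.frame(y = y, g = factor(labels)),
                          var.equal = TRUE)
        an <- list(anova_f = unname(ft$statistic),
                   anova_p = unname(ft$p.value),
                   anova_df = unname(ft$parameter),
                   anova_flag = "ok")
    }
    structure(c(list(groups = rbind(case = caseStats,
                                    control = controlStats),
                     n = c(case = nCase, control = nControl)),
                cmp, an),
              class = "CohortComparison")
}

#' @export
print.CohortComparison <- function(x, ...) {
    cat("Cohort copy-number comparison\n")
    print(round(x$groups, 1))
    cat(sprintf("  difference of means   %.0f\n", x$difference_of_means))
    cat(sprintf("  difference of medians %.0f\n", x$difference_of_medians))
    cat(sprintf("  factor (means)        %.1f\n", x$factor_means))
    cat(sprintf("  factor (medians)      %.1f\n", x$factor_medians))
    if (identical(x$anova_flag, "ok"))
        cat(sprintf("  ANOVA F(%d, %d) = %.3f, p = %.3g\n",
                    x$anova_df[1], x$anova_df[2], x$anova_f, x$anova_p))
    else cat("  ANOVA ", x$anova_flag, "\n")
    invisible(x)
}
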