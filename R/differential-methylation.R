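#' Pool C/T counts into a group-by-base table for one gene
#'
#' Sums raw C and T counts over the gene's retained CpG sites and over
#' the samples of each group. With \code{perSite = TRUE} the counts are
#' kept per site, giving a 2 x k table (k = retained sites, columns
#' named \code{gene_pos:C/T} interleaved as a two-row count matrix per
#' base is not needed there; see Details).
#'
#' @details The default 2 x 2 table has rows \code{case}, \code{control}
#' and columns \code{C}, \code{T}. The per-site variant returns a
#' 2 x (2k) matrix only internally; for the homogeneity test the
#' per-site option compares the distribution of methylated counts over
#' sites between groups (2 x k table of C counts), df = k - 1.
#'
#' @param x a \link{SiteCountMatrix-class} after
#'   \code{\link{filterSites}}.
#' @param labels group label per sample (\code{case} / \code{control}).
#' @param gene gene symbol.
#' @param perSite return the 2 x k per-site C-count table instead of
#'   the pooled 2 x 2 C/T table.
#' @return integer matrix (2 x 2 or 2 x k).
#' @export
poolCounts <- function(x, labels, gene, perSite = FALSE) {
    stopifnot(is(x, "SiteCountMatrix"))
    labels <- as.character(labels)
    stopifnot(length(labels) == ncol(x),
              all(labels %in% c("case", "control")))
    ret <- retainedSites(x)
    if (all(is.na(ret)))
        stop("run filterSites() before poolCounts()")
    rows <- which(ret & SummarizedExperiment::rowData(x)$gene == gene)
    if (!length(rows))
        stop("skipped gene: no retained CpG sites for ", gene)
    cc <- SummarizedExperiment::assay(x, "c")[rows, , drop = FALSE]
    tt <- SummarizedExperiment::assay(x, "t")[rows, , drop = FALSE]
    case <- labels == "case"
    if (!any(case) || all(case)) stop("both groups must be present")
    if (perSite) {
        tab <- rbind(case = rowSums(cc[, case, drop = FALSE]),
                     control = rowSums(cc[, !case, drop = FALSE]))
        colnames(tab) <- rownames(x)[rows]
    } else {
        tab <- rbind(case = c(C = sum(cc[, case]), T = sum(tt[, case])),
                     control = c(C = sum(cc[, !case]),
                                 T = sum(tt[, !case])))
    }
    tab
}

#' Pearson chi-square test of homogeneity
#'
#' Plain Pearson X^2 = sum (O - E)^2 / E with expected counts from the
#' row/column margins, df = (rows - 1)(cols - 1), no continuity
#' correction; the p-value is the upper chi-square tail. A zero row or
#' column margin makes the test undefined (returned as not testable).
#'
#' @param table a 2 x 2 (or 2 x k) matrix of non-negative counts.
#' @return list: \code{chi2}, \code{df}, \code{p_value},
#'   \code{testable}.
#' @examples
#' chiSquareHomogeneity(rbind(c(30, 70), c(50, 50)))
#' @export
chiSquareHomogeneity <- function(table) {
    table <- as.matrix(table)
    stopifnot(all(table >= 0))
    if (any(rowSums(table) == 0) || any(colSums(table) == 0))
        return(list(chi2 = NA_real_, df = NA_integer_,
                    p_value = NA_real_, testable = FALSE))
    ht <- suppressWarnings(chisq.test(table, correct = FALSE))
    list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
         p_value = unname(ht$p.value), testable = TRUE)
}

#' Per-gene differential methylation tests
#'
#' For every gene with at least one retained CpG site, pools raw C/T
#' counts by group and applies the chi-square test of homogeneity
#' (one pooled 2 x 2 test per amplicon by default; \code{perSite = TRUE}
#' compares per-site methylated counts, df = k - 1). Direction and
#' significance calls are added by \code{\link{classifyGenes}}.
#'
#' @inheritParams poolCounts
#' @param alpha per-gene significance level (default 0.05).
#' @param adjust \code{"none"} (default) or \code{"BH"} for
#'   Benjamini-Hochberg adjusted significance calls.
#' @param perSite use the 2 x k per-site test instead of pooled 2 x 2.
#' @return data.frame, one row per gene: pooled counts, rates, chi2,
#'   df, p_value, direction, significant; skipped genes appear with NA
#'   statistics and \code{skipped = TRUE}.
#' @export
testDifferentialMethylation <- function(x, labels, alpha = 0.05,
                                        adjust = c("none", "BH"),
                                        perSite = FALSE) {
    adjust <- match.arg(adjust)
    genes <- unique(SummarizedExperiment::rowData(x)$gene)
    rows <- lapply(genes, function(g) {
        pooled <- tryCatch(poolCounts(x, labels, g),
                           error = function(e) NULL)
        if (is.null(pooled))
            return(data.frame(gene = g, case_c = NA_real_,
                              case_t = NA_real_, control_c = NA_real_,
                              control_t = NA_real_, case_rate = NA_real_,
                              control_rate = NA_real_, chi2 = NA_real_,
                              df = NA_integer_, p_value = NA_real_,
                              skipped = TRUE, stringsAsFactors = FALSE))
        tab <- if (perSite) poolCounts(x, labels, g, perSite = TRUE)
               else pooled
        ht <- chiSquareHomogeneity(tab)
        data.frame(gene = g,
                   case_c = pooled["case", "C"],
                   case_t = pooled["case", "T"],
                   control_c = pooled["control", "C"],
                   control_t = pooled["control", "T"],
                   case_rate = pooled["case", "C"] /
                       sum(pooled["case", ]),
                   control_rate = pooled["control", "C"] /
                       sum(pooled["control", ]),
                   chi2 = ht$chi2, df = ht$df, p_value = ht$p_value,
                   skipped = FALSE, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    classifyGenes(res, alpha = alpha, adjust = adjust)
}

#' Direction and significance calls for gene test results
#'
#' direction = \code{hypo} when the case pooled methylation rate is
#' below the control rate, \code{hyper} otherwise; significant when
#' p < alpha (optionally after Benjamini-Hochberg adjustment; off by
#' default).
#'
#' @param results data.frame with columns \code{gene}, \code{p_value},
#'   \code{case_rate}, \code{control_rate}.
#' @param alpha significance level.
#' @param adjust \code{"none"} or \code{"BH"}.
#' @return the results with \code{direction}, \code{p_adjusted} (if
#'   BH), \code{significant} columns and attribute
#'   \code{"significant_count"}.
#' @export
classifyGenes <- function(results, alpha = 0.05,
                          adjust = c("none", "BH")) {
    adjust <- match.arg(adjust)
    stopifnot(all(c("gene", "p_value", "case_rate", "control_rate")
                  %in% colnames(results)))
    results$direction <- ifelse(
        is.na(results$case_rate) | is.na(results$control_rate), NA,
        ifelse(results$case_rate < results$control_rate, "hypo", "hyper"))
    p <- results$p_value
    if (adjust == "BH") {
        results$p_adjusted <- stats::p.adjust(p, method = "BH")
        p <- results$p_adjusted
    }
    results$significant <- !is.na(p) & p < alpha
    attr(results, "significant_count") <- sum(results$significant)
    results
}
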