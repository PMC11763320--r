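#' Merge paired-end reads by best ungapped overlap
#'
#' R2 is reverse-complemented internally; the best overlap (lowest
#' mismatch fraction, ties to the longer overlap) of at least
#' \code{minOverlap} nt and mismatch fraction at most
#' \code{maxMismatchFrac} is accepted. Disagreeing bases in the overlap
#' resolve to the higher-Phred call (quality tie goes to R1); the merged
#' quality is the per-base maximum.
#'
#' @param r1Seq,r2Seq character vectors of read sequences (R2 in
#'   sequencing orientation).
#' @param r1Qual,r2Qual Phred+33 quality strings (same lengths).
#' @param minOverlap minimum acceptable overlap, nt.
#' @param maxMismatchFrac maximum mismatch fraction in the overlap.
#' @return data.frame: \code{sequence}, \code{qualities}, \code{status}
#'   (\code{merged} / \code{no_overlap} / \code{too_short}),
#'   \code{overlap}, \code{mismatches}.
#' @examples
#' amp <- strrep("ACGT", 50)                       # 200 nt
#' r1 <- substr(amp, 1, 150)
#' r2 <- as.character(Biostrings::reverseComplement(
#'     Biostrings::DNAString(substr(amp, 51, 200))))
#' mergeReadPairs(r1, strrep("I", 150), r2, strrep("I", 150))$overlap
#' @export
mergeReadPairs <- function(r1Seq, r1Qual, r2Seq, r2Qual,
                           minOverlap = 20, maxMismatchFrac = 0.1) {
    stopifnot(length(r1Seq) == length(r2Seq),
              length(r1Seq) == length(r1Qual),
              length(r2Seq) == length(r2Qual))
    if (any(nchar(r1Seq) == 0L) || any(nchar(r2Seq) == 0L))
        stop("reads must be non-empty")
    out <- .merge_pairs_cpp(r1Seq, r1Qual, r2Seq, r2Qual,
                            as.integer(minOverlap), maxMismatchFrac)
    data.frame(sequence = out$sequence, qualities = out$qualities,
               status = out$status, overlap = out$overlap,
               mismatches = out$mismatches, stringsAsFactors = FALSE)
}

#' Merge one read pair
#'
#' @inheritParams mergeReadPairs
#' @param r1,r2 single read sequences.
#' @param q1,q2 single quality strings.
#' @return list with \code{sequence}, \code{qualities}, \code{status},
#'   \code{overlap}, \code{mismatches}.
#' @export
mergeReadPair <- function(r1, q1, r2, q2, minOverlap = 20,
                          maxMismatchFrac = 0.1) {
    as.list(mergeReadPairs(r1, q1, r2, q2, minOverlap = minOverlap,
                           maxMismatchFrac = maxMismatchFrac)[1, ])
}

# Bisulfite-expected reference patterns: non-CpG C -> T, plus a logical
# mask marking CpG Cs (where C and T both count as a match).
.convertedPatterns <- function(panel) {
    seqs <- as.character(ampliconSeqs(panel))
    sites <- cpgSites(panel)
    conv <- character(length(seqs)); masks <- vector("list", length(seqs))
    for (i in seq_along(seqs)) {
        ch <- strsplit(seqs[[i]], "")[[1]]
        mask <- logical(length(ch))
        mask[sites[[i]]] <- TRUE
        ch[ch == "C" & !mask] <- "T"
        conv[i] <- paste(ch, collapse = "")
        masks[[i]] <- mask
    }
    list(conv = conv, masks = masks, genes = names(seqs))
}

#' Assign merged reads to panel amplicons
#'
#' Each read is compared, in both orientations, against every
#' bisulfite-expected reference (non-CpG C expected as T; CpG C accepts
#' C or T; everything else exact) at every ungapped offset with full
#' containment of the shorter sequence. The score is the mismatch
#' fraction over the aligned length; a read is assigned to the unique
#' gene with minimal score at most \code{maxMismatchFrac}. Ties between
#' genes, no qualifying gene, or reads shorter than \code{minLength}
#' stay unassigned (reason \code{ambiguous} / \code{no_match} /
#' \code{too_short}).
#'
#' @param sequences character vector of merged read sequences (NA
#'   allowed for unmerged pairs).
#' @param panel an \link{AmpliconPanel}.
#' @param maxMismatchFrac maximum acceptable mismatch fraction.
#' @param minLength minimum assignable read / aligned length, nt.
#' @return data.frame: \code{gene} (symbol or NA), \code{score},
#'   \code{ref_start}, \code{aln_len}, \code{strand}, \code{oriented}
#'   (read re-oriented to the top strand), \code{reason}.
#' @export
assignToAmplicon <- function(sequences, panel, maxMismatchFrac = 0.1,
                             minLength = 40) {
    stopifnot(is(panel, "AmpliconPanel"), length(panel) >= 1)
    pat <- .convertedPatterns(panel)
    out <- .assign_reads_cpp(sequences, as.list(pat$conv), pat$masks,
                             maxMismatchFrac, as.integer(minLength))
    data.frame(gene = ifelse(is.na(out$gene), NA_character_,
                             pat$genes[out$gene]),
               score = out$score, ref_start = out$ref_start,
               aln_len = out$aln_len, strand = out$strand,
               oriented = out$oriented, reason = out$reason,
               stringsAsFactors = FALSE)
}

#' SiteCountMatrix: per-CpG methylation counts across samples
#'
#' A \link[SummarizedExperiment]{RangedSummarizedExperiment} with one
#' row per panel CpG site (seqnames = gene symbol, position = 1-based
#' offset of the C) and one column per sample, carrying integer assays
#' \code{c} (reads calling C, i.e. methylated), \code{t} (reads calling
#' T, unmethylated) and \code{other} (A/G/N calls). Row metadata holds
#' the retained-site filter mask; column metadata holds per-sample
#' totals, library normalization factors and bisulfite-conversion QC
#' counts.
#'
#' @param x a \code{SiteCountMatrix}.
#' @return \code{retainedSites()} the logical filter mask (NA before
#'   \code{\link{filterSites}}); \code{normFactors()} the per-sample
#'   factors (NA before \code{\link{normalizeLibraries}});
#'   \code{conversionRate()} the per-sample estimated bisulfite
#'   conversion rate (T fraction at non-CpG C positions).
#' @aliases retainedSites normFactors conversionRate
#' @exportClass SiteCountMatrix
setClass("SiteCountMatrix", contains = "RangedSummarizedExperiment")

setValidity("SiteCountMatrix", function(object) {
    a <- SummarizedExperiment::assayNames(object)
    if (!all(c("c", "t", "other") %in% a))
        return("assays 'c', 't' and 'other' are required")
    for (nm in c("c", "t", "other")) {
        m <- SummarizedExperiment::assay(object, nm)
        if (any(m < 0)) return(sprintf("assay '%s' has negative counts", nm))
    }
    nf <- object$norm_factor
    if (!is.null(nf) && any(!is.na(nf) & nf <= 0))
        return("normalization factors must be strictly positive")
    TRUE
})

#' @rdname SiteCountMatrix-class
#' @export
setMethod("retainedSites", "SiteCountMatrix", function(x)
    SummarizedExperiment::rowData(x)$retained)

#' @rdname SiteCountMatrix-class
#' @export
setMethod("normFactors", "SiteCountMatrix", function(x) {
    nf <- x$norm_factor
    if (is.null(nf)) nf <- rep(NA_real_, ncol(x))
    setNames(nf, colnames(x))
})

#' @rdname SiteCountMatrix-class
#' @export
setMethod("conversionRate", "SiteCountMatrix", function(x) {
    ct <- x$conv_t; cc <- x$conv_c
    if (is.null(ct)) return(setNames(rep(NA_real_, ncol(x)), colnames(x)))
    setNames(ct / (ct + cc), colnames(x))
})

#' Build a SiteCountMatrix from per-site counts
#'
#' Low-level constructor used by \code{\link{countCpgSites}} and handy
#' for constructing count matrices directly (e.g. in simulations that
#' skip the read level).
#'
#' @param cCounts,tCounts,otherCounts integer matrices, sites x samples.
#' @param gene character vector of gene symbols, one per row.
#' @param position integer vector of CpG positions (1-based), one per row.
#' @param sampleData optional \code{DataFrame}/data.frame of column
#'   metadata (per-sample totals, conversion QC counts, group labels).
#' @return a \link{SiteCountMatrix-class}.
#' @export
SiteCountMatrix <- function(cCounts, tCounts,
                            otherCounts = 0 * cCounts,
                            gene, position,
                            sampleData = NULL) {
    stopifnot(all(dim(cCounts) == dim(tCounts)),
              all(dim(cCounts) == dim(otherCounts)),
              length(gene) == nrow(cCounts),
              length(position) == nrow(cCounts))
    rr <- GenomicRanges::GRanges(
        seqnames = gene,
        ranges = IRanges::IRanges(start = as.integer(position), width = 1L))
    S4Vectors::mcols(rr)$gene <- gene
    S4Vectors::mcols(rr)$retained <- rep(NA, length(gene))
    cd <- if (is.null(sampleData))
        S4Vectors::DataFrame(row.names = colnames(cCounts))
    else S4Vectors::DataFrame(sampleData)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(c = cCounts, t = tCounts, other = otherCounts),
        rowRanges = rr, colData = cd)
    rownames(se) <- paste0(gene, "_", position)
    new("SiteCountMatrix", se)
}

setMethod("show", "SiteCountMatrix", function(object) {
    ret <- retainedSites(object)
    cat(sprintf("SiteCountMatrix: %d CpG sites x %d samples\n",
                nrow(object), ncol(object)))
    if (!all(is.na(ret)))
        cat(sprintf("  retained sites: %d of %d\n", sum(ret), length(ret)))
    nf <- normFactors(object)
    if (!all(is.na(nf)))
        cat(sprintf("  norm factors: %.3f-%.3f\n", min(nf), max(nf)))
    cv <- conversionRate(object)
    if (!all(is.na(cv)))
        cat(sprintf("  conversion rate: median %.4f\n",
                    median(cv, na.rm = TRUE)))
})

#' Count C/T calls at every panel CpG site
#'
#' Tabulates, per sample and CpG site, the number of assigned reads
#' calling C (methylated), T (unmethylated) or anything else. Also
#' accumulates per-sample totals and the C/T tallies at non-CpG
#' cytosine positions used for bisulfite conversion QC.
#'
#' @param assignments data.frame from \code{\link{assignToAmplicon}}
#'   (columns \code{gene}, \code{ref_start}, \code{oriented}).
#' @param sampleIds character vector, one sample id per read.
#' @param panel an \link{AmpliconPanel}.
#' @param sampleLevels optional character vector fixing the sample set
#'   and order (samples with zero reads get zero columns).
#' @return a \link{SiteCountMatrix-class}.
#' @export
countCpgSites <- function(assignments, sampleIds, panel,
                          sampleLevels = unique(sampleIds)) {
    stopifnot(nrow(assignments) == length(sampleIds))
    genes <- geneNames(panel)
    sites <- cpgSites(panel)
    seqs <- as.character(ampliconSeqs(panel))
    samp <- factor(sampleIds, levels = sampleLevels)
    ns <- length(sampleLevels)

    geneOf <- rep(genes, lengths(sites))
    posOf <- unlist(sites, use.names = FALSE)
    nSite <- length(posOf)
    cM <- matrix(0L, nSite, ns); tM <- matrix(0L, nSite, ns)
    oM <- matrix(0L, nSite, ns)
    colnames(cM) <- colnames(tM) <- colnames(oM) <- sampleLevels
    convC <- convT <- rep(0, ns)

    assigned <- !is.na(assignments$gene)
    row0 <- 0L
    for (g in genes) {
        idx <- which(assigned & assignments$gene == g)
        cp <- sites[[g]]
        base <- strsplit(seqs[[g]], "")[[1]]
        nonCpgC <- setdiff(which(base == "C"), cp)
        if (length(idx)) {
            sq <- assignments$oriented[idx]
            rs <- assignments$ref_start[idx]
            sg <- samp[idx]
            len <- nchar(sq)
            for (j in seq_along(cp)) {
                off <- cp[j] - rs + 1L
                cov <- off >= 1L & off <= len
                if (!any(cov)) next
                b <- substring(sq[cov], off[cov], off[cov])
                sj <- as.integer(sg[cov])
                cM[row0 + j, ] <- cM[row0 + j, ] +
                    tabulate(sj[b == "C"], nbins = ns)
                tM[row0 + j, ] <- tM[row0 + j, ] +
                    tabulate(sj[b == "T"], nbins = ns)
                oM[row0 + j, ] <- oM[row0 + j, ] +
                    tabulate(sj[b != "C" & b != "T"], nbins = ns)
            }
            for (p in nonCpgC) {
                off <- p - rs + 1L
                cov <- off >= 1L & off <= len
                if (!any(cov)) next
                b <- substring(sq[cov], off[cov], off[cov])
                sj <- as.integer(sg[cov])
                convC <- convC + tabulate(sj[b == "C"], nbins = ns)
                convT <- convT + tabulate(sj[b == "T"], nbins = ns)
            }
        }
        row0 <- row0 + length(cp)
    }
    totals <- tabulate(samp[assigned], nbins = ns)
    cd <- S4Vectors::DataFrame(sample_id = sampleLevels,
                               total_assigned = totals,
                               conv_c = convC, conv_t = convT,
                               row.names = sampleLevels)
    SiteCountMatrix(cM, tM, oM, gene = geneOf, position = posOf,
                    sampleData = cd)
}

#' Filter CpG sites by coverage and constant methylation
#'
#' A site is dropped if any sample covers it with fewer than
#' \code{minCoverage} reads (coverage = C + T calls), or if its pooled
#' methylation rate across all samples is exactly 0 or exactly 1.
#' Counts are never deleted; the mask is stored in the row metadata.
#'
#' @param x a \link{SiteCountMatrix-class}.
#' @param minCoverage minimum per-sample coverage (default 8 reads).
#' @return the object with \code{retainedSites(x)} filled in.
#' @export
filterSites <- function(x, minCoverage = 8) {
    stopifnot(is(x, "SiteCountMatrix"))
    cc <- SummarizedExperiment::assay(x, "c")
    tt <- SummarizedExperiment::assay(x, "t")
    cov <- cc + tt
    enough <- apply(cov, 1L, function(v) all(v >= minCoverage))
    pooled <- rowSums(cc) / pmax(rowSums(cov), 1L)
    variable <- rowSums(cov) > 0 & pooled > 0 & pooled < 1
    SummarizedExperiment::rowData(x)$retained <- enough & variable
    x
}

#' Library-size normalization by the average total read count
#'
#' factor_i = mean_j(total_j) / total_i, so that every sample's
#' normalized total equals the cohort mean. Raw integer counts are kept
#' untouched (the chi-square stage needs them); factors feed reporting
#' and the feature table. Samples with zero assigned reads are excluded
#' (factor NA) with a warning.
#'
#' @param x a \link{SiteCountMatrix-class} (after
#'   \code{\link{countCpgSites}}).
#' @return the object with \code{normFactors(x)} filled in.
#' @export
normalizeLibraries <- function(x) {
    stopifnot(is(x, "SiteCountMatrix"))
    totals <- x$total_assigned
    if (is.null(totals))
        totals <- colSums(SummarizedExperiment::assay(x, "c") +
                          SummarizedExperiment::assay(x, "t") +
                          SummarizedExperiment::assay(x, "other"))
    ok <- totals > 0
    if (!all(ok))
        warning(sum(!ok), " sample(s) with zero assigned reads excluded ",
                "from normalization")
    nf <- rep(NA_real_, length(totals))
    nf[ok] <- mean(totals[ok]) / totals[ok]
    x$norm_factor <- nf
    x
}

#' Gene-level methylation percentages
#'
#' Per sample and gene, pools raw C/T counts over the gene's retained
#' CpG sites: percent = 100 * sum(C) / sum(C + T)
#' (coverage-weighted pooling, the default), or the unweighted mean of
#' per-site rates (\code{type = "mean"}). Genes with no retained sites
#' give NA and are flagged in the \code{"flagged_genes"} attribute.
#'
#' @param x a \link{SiteCountMatrix-class} after
#'   \code{\link{filterSites}}.
#' @param type \code{"pooled"} (count-weighted) or \code{"mean"}.
#' @param percent return percentages in [0, 100] (default) rather than
#'   fractions.
#' @return numeric matrix samples x genes.
#' @export
setMethod("geneMethylation", "SiteCountMatrix",
          function(x, type = c("pooled", "mean"), percent = TRUE) {
    type <- match.arg(type)
    ret <- retainedSites(x)
    if (all(is.na(ret)))
        stop("run filterSites() before geneMethylation()")
    if (!any(ret))
        stop("empty panel: all CpG sites were filtered out")
    gene <- SummarizedExperiment::rowData(x)$gene
    genes <- unique(gene)
    cc <- SummarizedExperiment::assay(x, "c")
    tt <- SummarizedExperiment::assay(x, "t")
    out <- matrix(NA_real_, ncol(x), length(genes),
                  dimnames = list(colnames(x), genes))
    for (g in genes) {
        rows <- which(ret & gene == g)
        if (!length(rows)) next
        if (type == "pooled") {
            num <- colSums(cc[rows, , drop = FALSE])
            den <- colSums(cc[rows, , drop = FALSE] +
                           tt[rows, , drop = FALSE])
            out[, g] <- ifelse(den > 0, num / den, NA_real_)
        } else {
            r <- cc[rows, , drop = FALSE] /
                (cc[rows, , drop = FALSE] + tt[rows, , drop = FALSE])
            out[, g] <- colMeans(r)
        }
    }
    flagged <- genes[vapply(genes, function(g)
        !any(ret & gene == g), logical(1))]
    if (percent) out <- 100 * out
    attr(out, "flagged_genes") <- flagged
    out
})

#' Call methylation from FASTQ pairs
#'
#' Convenience driver: reads each sample's FASTQ pair, merges the
#' pairs, assigns merged reads to panel amplicons, and tabulates per-CpG
#' C/T counts, returning the count matrix plus per-sample QC (merge
#' rate, assignment rate, conversion-rate estimate).
#'
#' @param files data.frame with \code{sample_id}, \code{r1}, \code{r2}
#'   paths (as returned by \code{\link{simulateBisulfiteReads}}).
#' @param panel an \link{AmpliconPanel}.
#' @param minOverlap,maxMismatchFrac merging / assignment parameters
#'   (see \code{\link{mergeReadPairs}}, \code{\link{assignToAmplicon}}).
#' @param minLength minimum assignable merged-read length.
#' @return list: \code{counts} (a \link{SiteCountMatrix-class}) and
#'   \code{qc} (data.frame: sample, read pairs, merge rate, assignment
#'   rate).
#' @export
callMethylation <- function(files, panel, minOverlap = 20,
                            maxMismatchFrac = 0.1, minLength = 40) {
    stopifnot(all(c("sample_id", "r1", "r2") %in% colnames(files)))
    allAssign <- vector("list", nrow(files))
    qc <- data.frame(sample_id = files$sample_id, n_pairs = 0L,
                     merge_rate = NA_real_, assign_rate = NA_real_,
                     stringsAsFactors = FALSE)
    for (i in seq_len(nrow(files))) {
        f1 <- readFastq(files$r1[i]); f2 <- readFastq(files$r2[i])
        merged <- mergeReadPairs(f1$sequence, f1$qualities,
                                 f2$sequence, f2$qualities,
                                 minOverlap = minOverlap,
                                 maxMismatchFrac = maxMismatchFrac)
        asn <- assignToAmplicon(merged$sequence, panel,
                                maxMismatchFrac = maxMismatchFrac,
                                minLength = minLength)
        asn$sample_id <- files$sample_id[i]
        allAssign[[i]] <- asn
        qc$n_pairs[i] <- nrow(f1)
        qc$merge_rate[i] <- mean(merged$status == "merged")
        qc$assign_rate[i] <- mean(!is.na(asn$gene))
    }
    asn <- do.call(rbind, allAssign)
    counts <- countCpgSites(asn, asn$sample_id, panel,
                            sampleLevels = files$sample_id)
    list(counts = counts, qc = qc)
}
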