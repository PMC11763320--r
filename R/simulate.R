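#' Default per-gene methylation levels for the synthetic study conditions
#'
#' Control-group methylation fractions for the nine panel genes, with
#' four genes (DIP2C, DNMT1, RRP1, USP1) hypomethylated in cases by
#' \code{hypoDelta} (default 0.15, i.e. -15 percentage points).
#'
#' @param hypoDelta drop in methylation fraction for the hypomethylated
#'   genes in the case group.
#' @return matrix (genes x groups \code{control}, \code{case}) of true
#'   methylation fractions.
#' @examples
#' defaultMethLevels()
#' @export
defaultMethLevels <- function(hypoDelta = 0.15) {
    control <- c(CALD1 = 0.45, RRP1 = 0.55, FN1 = 0.30, DIP2C = 0.60,
                 RMI2 = 0.35, TDRD5 = 0.50, USP1 = 0.65, HDAC1 = 0.40,
                 DNMT1 = 0.55)
    case <- control
    case[.HYPO_GENES] <- case[.HYPO_GENES] - hypoDelta
    cbind(control = control, case = case)
}

#' Cohort specification for the synthetic study
#'
#' Bundles the study conditions: group sizes, a per-group log-normal
#' copy-number model, and per-gene true methylation fractions. The
#' defaults reproduce the reference cohort: 38 cases / 40 controls,
#' log-normal copies with medians 8602 (cases) and 2224 (controls)
#' (a 3.9x median separation with a heavy right tail), and four genes
#' hypomethylated in cases by 15 percentage points.
#'
#' @param nCases,nControls group sizes (>= 2).
#' @param copyMeanlog,copySdlog named numeric (\code{case},
#'   \code{control}): log-scale location/scale of the copy-number
#'   log-normal per group.
#' @param geneMethLevels matrix (genes x \code{control}/\code{case}) of
#'   true methylation fractions in [0, 1]; see
#'   \code{\link{defaultMethLevels}}.
#' @param methConcentration beta concentration for inter-individual
#'   variation around the group mean (larger = tighter).
#' @param seed integer seed.
#' @return a validated list of class \code{CohortSpec}.
#' @examples
#' spec <- cohortSpec(seed = 1)
#' @export
cohortSpec <- function(nCases = 38, nControls = 40,
                       copyMeanlog = c(case = log(8602),
                                       control = log(2224)),
                       copySdlog = c(case = 1.04, control = 0.84),
                       geneMethLevels = defaultMethLevels(),
                       methConcentration = 60,
                       seed = 1) {
    stopifnot(nCases >= 2, nControls >= 2,
              all(c("case", "control") %in% names(copyMeanlog)),
              all(c("case", "control") %in% names(copySdlog)),
              all(copySdlog >= 0),
              is.matrix(geneMethLevels),
              all(c("control", "case") %in% colnames(geneMethLevels)),
              all(geneMethLevels >= 0 & geneMethLevels <= 1),
              methConcentration > 0)
    structure(list(nCases = nCases, nControls = nControls,
                   copyMeanlog = copyMeanlog, copySdlog = copySdlog,
                   geneMethLevels = geneMethLevels,
                   methConcentration = methConcentration,
                   seed = as.integer(seed)),
              class = "CohortSpec")
}

#' Simulate a cohort truth table
#'
#' Draws, per sample, a true cf-DNA copy number (i.i.d. log-normal per
#' group) and a true methylation fraction per panel gene
#' (beta-distributed around the group mean with concentration
#' \code{methConcentration}).
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @return data.frame with columns \code{sample_id}, \code{group}
#'   (factor control/case), \code{true_copies}, and one column per gene
#'   holding the sample's true methylation fraction.
#' @examples
#' truth <- simulateCohort(cohortSpec(seed = 1))
#' table(truth$group)
#' @export
simulateCohort <- function(spec = cohortSpec()) {
    stopifnot(inherits(spec, "CohortSpec"))
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old))
    set.seed(spec$seed)

    n <- spec$nCases + spec$nControls
    group <- factor(rep(c("case", "control"),
                        c(spec$nCases, spec$nControls)),
                    levels = c("control", "case"))
    ids <- sprintf("S%03d", seq_len(n))
    copies <- numeric(n)
    for (g in c("case", "control")) {
        idx <- group == g
        copies[idx] <- rlnorm(sum(idx), meanlog = spec$copyMeanlog[[g]],
                              sdlog = spec$copySdlog[[g]])
    }
    out <- data.frame(sample_id = ids, group = group,
                      true_copies = copies,
                      stringsAsFactors = FALSE)
    kappa <- spec$methConcentration
    for (gene in rownames(spec$geneMethLevels)) {
        m <- spec$geneMethLevels[gene, as.character(group)]
        frac <- ifelse(m <= 0, 0,
                ifelse(m >= 1, 1,
                       rbeta(n, shape1 = m * kappa,
                             shape2 = (1 - m) * kappa)))
        out[[gene]] <- pmin(pmax(frac, 0), 1)
    }
    out
}

#' Read-simulation parameters
#'
#' @param readLength read length in nt (paired-end 2 x 150 bp default).
#' @param readsPerAmplicon read pairs simulated per sample per amplicon.
#' @param conversionEfficiency probability an unmethylated C is read as
#'   T after bisulfite conversion.
#' @param methylatedProtection probability a methylated C survives
#'   conversion and is read as C.
#' @param errorRate per-base substitution probability.
#' @param qualityChar Phred+33 quality character used for every base
#'   (default \code{"?"} = Q30).
#' @param seed integer seed.
#' @return a validated list of class \code{ReadSimParams}.
#' @export
readSimParams <- function(readLength = 150, readsPerAmplicon = 1000,
                          conversionEfficiency = 0.99,
                          methylatedProtection = 0.995,
                          errorRate = 0.001, qualityChar = "?",
                          seed = 1) {
    stopifnot(readLength >= 30, readsPerAmplicon >= 1,
              conversionEfficiency >= 0, conversionEfficiency <= 1,
              methylatedProtection >= 0, methylatedProtection <= 1,
              errorRate >= 0, errorRate <= 1,
              nchar(qualityChar) == 1)
    structure(list(readLength = as.integer(readLength),
                   readsPerAmplicon = as.integer(readsPerAmplicon),
                   conversionEfficiency = conversionEfficiency,
                   methylatedProtection = methylatedProtection,
                   errorRate = errorRate, qualityChar = qualityChar,
                   seed = as.integer(seed)),
              class = "ReadSimParams")
}

#' Simulate paired-end bisulfite amplicon reads
#'
#' For every sample and amplicon, simulates bisulfite-converted
#' molecules from the top strand: each CpG C is methylated with the
#' sample's gene-level probability; a methylated C is emitted as C with
#' probability \code{methylatedProtection}; an unmethylated C (CpG or
#' not) is emitted as T with probability \code{conversionEfficiency};
#' uniform substitution errors are then applied. R1 is the 5' read, R2
#' the reverse complement of the 3' end; reads overlap whenever the
#' amplicon is shorter than twice the read length. Output is one gzip
#' FASTQ pair per sample (\code{{sample}_R1.fastq.gz} /
#' \code{{sample}_R2.fastq.gz}, Phred+33).
#'
#' @param panel an \link{AmpliconPanel}.
#' @param cohort cohort truth table from \code{\link{simulateCohort}}
#'   (needs \code{sample_id} plus one methylation column per gene).
#' @param params a \code{\link{readSimParams}}.
#' @param outDir output directory (created if missing).
#' @return invisibly, a data.frame with \code{sample_id}, \code{r1},
#'   \code{r2} file paths.
#' @export
simulateBisulfiteReads <- function(panel, cohort,
                                   params = readSimParams(),
                                   outDir) {
    stopifnot(is(panel, "AmpliconPanel"), inherits(params, "ReadSimParams"))
    genes <- geneNames(panel)
    miss <- setdiff(genes, colnames(cohort))
    if (length(miss))
        stop("cohort lacks methylation columns for: ",
             paste(miss, collapse = ", "))
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", outDir)

    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old))
    set.seed(params$seed)

    seqs <- as.character(ampliconSeqs(panel))
    sites <- cpgSites(panel)
    files <- data.frame(sample_id = cohort$sample_id,
                        r1 = file.path(outDir, paste0(cohort$sample_id,
                                                      "_R1.fastq.gz")),
                        r2 = file.path(outDir, paste0(cohort$sample_id,
                                                      "_R2.fastq.gz")),
                        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(cohort))) {
        r1 <- character(0); r2 <- character(0); ids <- character(0)
        for (g in genes) {
            sim <- .simulateMolecules(seqs[[g]], sites[[g]],
                                      m = cohort[[g]][i], params)
            rl <- params$readLength
            L <- nchar(seqs[[g]])
            k <- min(rl, L)
            r1 <- c(r1, substring(sim, 1L, k))
            r2 <- c(r2, .revcomp(substring(sim, L - k + 1L, L)))
            ids <- c(ids, sprintf("%s:%s:%04d", cohort$sample_id[i], g,
                                  seq_along(sim)))
        }
        .writeFastq(ids, r1, files$r1[i], params$qualityChar)
        .writeFastq(ids, r2, files$r2[i], params$qualityChar)
    }
    invisible(files)
}

# Bisulfite-converted molecules for one sample x amplicon, as strings
.simulateMolecules <- function(seq, cpg, m, params) {
    n <- params$readsPerAmplicon
    L <- nchar(seq)
    base <- strsplit(seq, "")[[1]]
    mat <- matrix(rep(base, each = n), nrow = n)
    isC <- which(base == "C")
    nonCpgC <- setdiff(isC, cpg)
    # CpG cytosines: methylated with prob m, then readout model
    if (length(cpg)) {
        meth <- matrix(runif(n * length(cpg)) < m, nrow = n)
        keepC <- matrix(runif(n * length(cpg)), nrow = n)
        emitted <- ifelse(meth,
                          ifelse(keepC < params$methylatedProtection,
                                 "C", "T"),
                          ifelse(keepC < 1 - params$conversionEfficiency,
                                 "C", "T"))
        mat[, cpg] <- emitted
    }
    # non-CpG cytosines are unmethylated
    if (length(nonCpgC)) {
        conv <- matrix(runif(n * length(nonCpgC)) <
                           params$conversionEfficiency, nrow = n)
        mat[, nonCpgC] <- ifelse(conv, "T", "C")
    }
    if (params$errorRate > 0) {
        err <- which(matrix(runif(n * L) < params$errorRate, nrow = n))
        if (length(err)) {
            alt <- c("A", "C", "G", "T")
            cur <- mat[err]
            pick <- vapply(cur, function(b)
                sample(setdiff(alt, b), 1L), character(1))
            mat[err] <- pick
        }
    }
    do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

.writeFastq <- function(ids, seqs, path, qualityChar) {
    qual <- strrep(qualityChar, nchar(seqs))
    con <- gzfile(path, "wb")
    on.exit(close(con))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con)
}

#' Read a FASTQ file (plain or gzip, Phred+33)
#'
#' @param path FASTQ path.
#' @return data.frame with \code{id}, \code{sequence}, \code{qualities}
#'   (quality strings, Phred+33).
#' @export
readFastq <- function(path) {
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L)
        stop("malformed FASTQ: ", path)
    idx <- seq(1L, length(lines), by = 4L)
    data.frame(id = sub("^@", "", sub("\\s.*$", "", lines[idx])),
               sequence = lines[idx + 1L],
               qualities = lines[idx + 3L],
               stringsAsFactors = FALSE)
}

#' qPCR simulation parameters
#'
#' @param trueSlope Cq change per log10 copies (< 0; default -3.3219,
#'   i.e. perfect doubling).
#' @param trueIntercept Cq at 1 copy.
#' @param cqNoiseSd replicate noise SD in cycles.
#' @param standardCopies known copy numbers of the standard series; the
#'   default is a ten-fold dilution of a positive control calibrated at
#'   200,000 copies/uL. Must span >= 3 log10 decades.
#' @param nReplicates replicates per measurement (default 3).
#' @param seed integer seed.
#' @return a validated list of class \code{QpcrSimParams}.
#' @export
qpcrSimParams <- function(trueSlope = -3.3219, trueIntercept = 40,
                          cqNoiseSd = 0.15,
                          standardCopies = 200000 / 10^(0:4),
                          nReplicates = 3, seed = 1) {
    stopifnot(trueSlope < 0, cqNoiseSd >= 0, nReplicates >= 1,
              all(standardCopies > 0))
    if (diff(range(log10(standardCopies))) < 3)
        stop("standard series must span >= 3 log10 decades")
    structure(list(trueSlope = trueSlope, trueIntercept = trueIntercept,
                   cqNoiseSd = cqNoiseSd, standardCopies = standardCopies,
                   nReplicates = as.integer(nReplicates),
                   seed = as.integer(seed)),
              class = "QpcrSimParams")
}

#' Simulate qPCR standards and per-sample Cq triplicates
#'
#' Cq = intercept + slope * log10(copies) + Normal(0, cqNoiseSd), for a
#' known standard dilution series and for every cohort sample.
#'
#' @param cohort cohort truth table (\code{sample_id},
#'   \code{true_copies} > 0).
#' @param params a \code{\link{qpcrSimParams}}.
#' @return list with \code{standards} (data.frame \code{copies},
#'   \code{replicate}, \code{cq}) and \code{samples} (data.frame
#'   \code{sample_id}, \code{cq1..cqK}).
#' @export
simulateQpcr <- function(cohort, params = qpcrSimParams()) {
    stopifnot(inherits(params, "QpcrSimParams"))
    if (any(cohort$true_copies <= 0))
        stop("all true copy numbers must be positive")
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old))
    set.seed(params$seed)

    cqOf <- function(copies, k) {
        params$trueIntercept + params$trueSlope * log10(copies) +
            rnorm(length(copies) * k, sd = params$cqNoiseSd)
    }
    k <- params$nReplicates
    standards <- data.frame(
        copies = rep(params$standardCopies, each = k),
        replicate = rep(seq_len(k), length(params$standardCopies)))
    standards$cq <- cqOf(rep(params$standardCopies, each = k), 1L)

    cqs <- matrix(cqOf(rep(cohort$true_copies, each = k), 1L),
                  ncol = k, byrow = TRUE)
    colnames(cqs) <- paste0("cq", seq_len(k))
    samples <- data.frame(sample_id = cohort$sample_id, cqs,
                          stringsAsFactors = FALSE)
    list(standards = standards, samples = samples)
}
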