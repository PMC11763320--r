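# Shared fixtures, all built in code.

# Two hand-written amplicons with known CpG positions.
# geneA: 200 nt with CpGs at 11, 61, 151 (1-based, position of the C).
.fixedAmplicon <- function(len, cpgAt, seed) {
    set.seed(seed)
    s <- sample(c("A", "G", "T"), len, replace = TRUE)
    s[cpgAt] <- "C"
    s[cpgAt + 1L] <- "G"
    # add non-CpG cytosines (needed for conversion QC) where they
    # cannot create a stray CpG
    ok <- setdiff(which(s[-len] != "G") , c(cpgAt, cpgAt + 1L, len))
    ok <- ok[s[ok + 1L] != "G"]
    s[sample(ok, 15)] <- "C"
    seq <- paste(s, collapse = "")
    stopifnot(identical(cfMethDx:::.findCpg(seq), as.integer(cpgAt)))
    seq
}

tinyPanel <- function() {
    AmpliconPanel(c(
        geneA = .fixedAmplicon(200, c(11L, 61L, 151L), seed = 101),
        geneB = .fixedAmplicon(160, c(21L, 81L), seed = 202)))
}

# SiteCountMatrix straight from count matrices (sites x samples)
makeScm <- function(cC, tC, gene, position, samples = colnames(cC),
                    group = NULL) {
    colnames(cC) <- colnames(tC) <- samples
    sd <- S4Vectors::DataFrame(sample_id = samples, row.names = samples)
    if (!is.null(group)) sd$group <- group
    SiteCountMatrix(cC, tC, gene = gene, position = position,
                    sampleData = sd)
}

# Perfectly converted bisulfite read for a panel gene: non-CpG C -> T,
# CpG C kept as C (fully methylated) or converted (unmethylated)
convertedRead <- function(panel, gene, methylated = TRUE) {
    s <- strsplit(as.character(ampliconSeqs(panel)[[gene]]), "")[[1]]
    cpg <- cpgSites(panel)[[gene]]
    isC <- s == "C"
    mask <- logical(length(s)); mask[cpg] <- TRUE
    s[isC & !mask] <- "T"
    if (!methylated) s[mask] <- "T"
    paste(s, collapse = "")
}

# The nine published per-gene p-values used for significance-call checks
reportedGeneP <- function() {
    data.frame(
        gene = c("CALD1", "RRP1", "FN1", "DIP2C", "RMI2", "TDRD5",
                 "USP1", "HDAC1", "DNMT1"),
        p_value = c(0.4009, 2.83e-3, 0.9328, 2.22e-5, 0.11, 0.846,
                    2.15e-15, 0.2761, 1.05e-4),
        stringsAsFactors = FALSE)
}
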