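#' AmpliconPanel: bisulfite amplicon references with CpG annotation
#'
#' Holds the reference sequence of each amplicon in a targeted bisulfite
#' panel together with the (1-based) position of the C of every CpG
#' dinucleotide. Amplicons represent the bisulfite PCR top strand; all
#' methylation calls are made in these coordinates.
#'
#' @slot sequences a \link[Biostrings]{DNAStringSet}, one entry per
#'   amplicon, named by gene symbol.
#' @slot cpgSites a named list of strictly increasing integer vectors:
#'   1-based offsets of the C of each CpG within the amplicon.
#'
#' @param x an \code{AmpliconPanel}.
#' @param sequences named character vector or \code{DNAStringSet} of
#'   amplicon sequences (upper-case A/C/G/T).
#'
#' @return \code{AmpliconPanel()} returns a validated object.
#'   \code{cpgSites()} returns the list of CpG positions,
#'   \code{ampliconSeqs()} the \code{DNAStringSet}, \code{geneNames()}
#'   the gene symbols.
#'
#' @examples
#' panel <- AmpliconPanel(c(GENE1 = "ACGTTACGGA"))
#' cpgSites(panel)
#'
#' @aliases cpgSites ampliconSeqs geneNames
#' @export AmpliconPanel
#' @exportClass AmpliconPanel
setClass("AmpliconPanel",
         slots = c(sequences = "DNAStringSet", cpgSites = "list"))

setValidity("AmpliconPanel", function(object) {
    seqs <- object@sequences
    sites <- object@cpgSites
    if (length(seqs) == 0L) return("panel must contain >= 1 amplicon")
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
        return("amplicons must have unique gene names")
    if (!identical(names(seqs), names(sites)))
        return("cpgSites names must match sequence names")
    chars <- as.character(seqs)
    for (g in names(seqs)) {
        s <- chars[[g]]
        if (grepl("[^ACGT]", s))
            return(sprintf("%s: sequence must be upper-case A/C/G/T", g))
        p <- sites[[g]]
        if (length(p) < 1L)
            return(sprintf("%s: every amplicon needs >= 1 CpG", g))
        if (is.unsorted(p, strictly = TRUE))
            return(sprintf("%s: CpG positions must be strictly increasing", g))
        if (any(p < 1L) || any(p + 1L > nchar(s)))
            return(sprintf("%s: CpG position out of range", g))
        dint <- substring(s, p, p + 1L)
        if (any(dint != "CG"))
            return(sprintf("%s: annotated position is not a CpG", g))
    }
    TRUE
})

#' @rdname AmpliconPanel-class
AmpliconPanel <- function(sequences) {
    if (!is(sequences, "DNAStringSet"))
        sequences <- Biostrings::DNAStringSet(sequences)
    sites <- lapply(as.character(sequences), .findCpg)
    new("AmpliconPanel", sequences = sequences, cpgSites = sites)
}

.findCpg <- function(seq) {
    hits <- gregexpr("CG", seq, fixed = TRUE)[[1]]
    if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' @rdname AmpliconPanel-class
#' @export
setMethod("cpgSites", "AmpliconPanel", function(x) x@cpgSites)

#' @rdname AmpliconPanel-class
#' @export
setMethod("ampliconSeqs", "AmpliconPanel", function(x) x@sequences)

#' @rdname AmpliconPanel-class
#' @export
setMethod("geneNames", "AmpliconPanel", function(x) names(x@sequences))

#' @rdname AmpliconPanel-class
#' @export
setMethod("length", "AmpliconPanel", function(x) length(x@sequences))

setMethod("show", "AmpliconPanel", function(object) {
    w <- Biostrings::width(object@sequences)
    cat(sprintf("AmpliconPanel with %d amplicons, %d CpG sites\n",
                length(object), sum(lengths(object@cpgSites))))
    cat(sprintf("  lengths %d-%d nt; genes: %s\n", min(w), max(w),
                paste(head(geneNames(object), 9), collapse = ", ")))
})

#' Generate a synthetic amplicon panel
#'
#' Draws random amplicon reference sequences with a guaranteed minimum
#' number of CpG dinucleotides each. For \code{nGenes = 9} and no
#' explicit \code{genes} argument, the default gene symbols are the
#' nine-gene serum panel (CALD1, RRP1, FN1, DIP2C, RMI2, TDRD5, USP1,
#' HDAC1, DNMT1).
#'
#' @param nGenes number of amplicons (>= 1).
#' @param lengthRange two integers within [80, 400]: min and max
#'   amplicon length in nt.
#' @param minCpg minimum number of CpG sites per amplicon (>= 1).
#' @param seed integer seed; identical seeds give identical panels.
#' @param genes optional character vector of gene symbols.
#' @return an \link{AmpliconPanel}.
#' @examples
#' panel <- generatePanel(nGenes = 9, seed = 1)
#' geneNames(panel)
#' @export
generatePanel <- function(nGenes = 9, lengthRange = c(120, 280),
                          minCpg = 3, seed = 1, genes = NULL) {
    stopifnot(nGenes >= 1)
    if (minCpg < 1)
        stop("minCpg must be >= 1: every amplicon needs a CpG site")
    lengthRange <- as.integer(lengthRange)
    if (length(lengthRange) != 2L || lengthRange[1] > lengthRange[2] ||
        lengthRange[1] < 80L || lengthRange[2] > 400L)
        stop("lengthRange must be an increasing pair within [80, 400]")
    if (lengthRange[1] < 3L * minCpg)
        stop("impossible CpG placement: amplicon too short for minCpg")
    if (is.null(genes)) {
        genes <- if (nGenes == 9) .PANEL_GENES
                 else sprintf("GENE%02d", seq_len(nGenes))
    }
    stopifnot(length(genes) == nGenes)

    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old))
    set.seed(seed)

    seqs <- character(nGenes)
    for (i in seq_len(nGenes)) {
        L <- sample(lengthRange[1]:lengthRange[2], 1L)
        s <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                    prob = c(0.3, 0.2, 0.2, 0.3))
        # plant minCpg CpGs on a grid with spacing >= 3 so none collide
        slots <- seq(2L, L - 1L, by = 3L)
        at <- sort(sample(slots, minCpg))
        s[at] <- "C"
        s[at + 1L] <- "G"
        seqs[i] <- paste(s, collapse = "")
    }
    names(seqs) <- genes
    AmpliconPanel(seqs)
}

.Random.seed.save <- function() {
    if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed.restore <- function(old) {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write / read an amplicon panel as FASTA + BED
#'
#' The FASTA holds one record per amplicon (header = gene symbol); the
#' BED (0-based, half-open) holds one record per CpG, covering the C.
#'
#' @param panel an \link{AmpliconPanel}.
#' @param fastaPath,bedPath file paths.
#' @return \code{writePanel} invisibly returns the two paths;
#'   \code{readPanel} returns an \link{AmpliconPanel}.
#' @export
writePanel <- function(panel, fastaPath, bedPath) {
    Biostrings::writeXStringSet(ampliconSeqs(panel), fastaPath)
    sites <- cpgSites(panel)
    gr <- GenomicRanges::GRanges(
        seqnames = rep(names(sites), lengths(sites)),
        ranges = IRanges::IRanges(start = unlist(sites, use.names = FALSE),
                                  width = 1L),
        name = unlist(lapply(sites, function(p)
            sprintf("CpG_%d", seq_along(p))), use.names = FALSE))
    rtracklayer::export(gr, bedPath, format = "BED")
    invisible(c(fasta = fastaPath, bed = bedPath))
}

#' @rdname writePanel
#' @export
readPanel <- function(fastaPath, bedPath) {
    seqs <- Biostrings::readDNAStringSet(fastaPath)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    panel <- AmpliconPanel(seqs)
    gr <- rtracklayer::import(bedPath, format = "BED")
    sites <- split(GenomicRanges::start(gr),
                   as.character(GenomicRanges::seqnames(gr)))
    sites <- lapply(sites, function(p) sort(as.integer(p)))
    got <- sites[names(seqs)]
    names(got) <- names(seqs)
    if (!identical(got, panel@cpgSites))
        stop("BED CpG annotation disagrees with CpGs found in the FASTA")
    panel
}
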