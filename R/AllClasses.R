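#' TagSet: collapsed small-RNA tags with per-library counts
#'
#' A \code{TagSet} is the central container of the pipeline: one row per
#' distinct small-RNA sequence ("tag") and one column per organ library,
#' holding the integer read count of that tag in that library.  It extends
#' \linkS4class{SummarizedExperiment}; the tag sequence is kept in
#' \code{rowData(x)$sequence} (RNA alphabet, 5'->3').
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @name TagSet-class
#' @aliases TagSet-class
#' @exportClass TagSet
setClass("TagSet", contains = "SummarizedExperiment")

setValidity("TagSet", function(object) {
    msg <- NULL
    if (!"counts" %in% names(assays(object)))
        msg <- c(msg, "assay 'counts' is required")
    if (!"sequence" %in% names(rowData(object)))
        msg <- c(msg, "rowData column 'sequence' is required")
    else {
        sq <- rowData(object)$sequence
        if (anyDuplicated(sq))
            msg <- c(msg, "tag sequences must be unique")
        if (length(sq) && !all(grepl("^[ACGU]+$", sq)))
            msg <- c(msg, "tag sequences must be over the RNA alphabet {A,C,G,U}")
    }
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "library names must be present and unique")
    k <- assay(object, "counts")
    if (length(k) && (any(k < 0) || any(k != round(k))))
        msg <- c(msg, "counts must be non-negative integers")
    if (is.null(msg)) TRUE else msg
})

#' Construct a TagSet
#'
#' @param sequences character vector of distinct tag sequences (RNA or DNA
#'   alphabet; normalised to RNA).
#' @param counts integer matrix, one row per tag, one column per library.
#' @param libraries library (organ) names; defaults to
#'   \code{colnames(counts)}.
#' @return A \linkS4class{TagSet}.
#' @examples
#' ts <- TagSet(c("UGACAGAAGAGAGUGAGCAC"), matrix(5, 1, 1,
#'   dimnames = list(NULL, "LL")))
#' tagTotals(ts)
#' @export
TagSet <- function(sequences, counts, libraries = colnames(counts)) {
    counts <- as.matrix(counts)
    if (length(sequences) != nrow(counts))
        stop("length(sequences) must equal nrow(counts)")
    if (is.null(libraries))
        stop("library names are required")
    colnames(counts) <- libraries
    sequences <- normalizeRNA(sequences)
    storage.mode(counts) <- "integer"
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(sequence = sequences))
    new("TagSet", se)
}

#' @describeIn TagSet tag sequences (RNA alphabet)
#' @param x a TagSet
#' @export
tagSequences <- function(x) rowData(x)$sequence

#' @describeIn TagSet per-library count matrix
#' @export
tagCounts <- function(x) assay(x, "counts")

#' @describeIn TagSet library (organ) names
#' @export
libNames <- function(x) colnames(x)

#' @describeIn TagSet total reads per tag across libraries
#' @export
tagTotals <- function(x) as.integer(rowSums(assay(x, "counts")))

#' @describeIn TagSet number of libraries in which each tag was detected
#' @export
librariesDetected <- function(x) as.integer(rowSums(assay(x, "counts") > 0L))

setMethod("show", "TagSet", function(object) {
    cat(sprintf("TagSet with %d tags over %d libraries (%s)\n",
                nrow(object), ncol(object),
                paste(colnames(object), collapse = ", ")))
    cat(sprintf("  total reads: %s\n",
                format(sum(assay(object, "counts")), big.mark = ",")))
})

#' SecondaryStructure: a folded RNA secondary structure
#'
#' Holds a sequence, its minimum-free-energy structure in dot-bracket
#' (Vienna) notation, and the free energy in kcal/mol under the packaged
#' nearest-neighbour model.
#'
#' @slot sequence RNA sequence (5'->3').
#' @slot dotbracket dot-bracket pairing string, same length as sequence.
#' @slot mfe minimum free energy, kcal/mol.
#' @exportClass SecondaryStructure
setClass("SecondaryStructure",
    representation(sequence = "character", dotbracket = "character",
                   mfe = "numeric"))

setValidity("SecondaryStructure", function(object) {
    if (nchar(object@sequence) != nchar(object@dotbracket))
        return("dot-bracket length must equal sequence length")
    db <- strsplit(object@dotbracket, "")[[1]]
    depth <- cumsum((db == "(") - (db == ")"))
    if (any(depth < 0) || (length(depth) && depth[length(depth)] != 0))
        return("unbalanced dot-bracket string")
    TRUE
})

setMethod("show", "SecondaryStructure", function(object) {
    cat(object@sequence, "\n", object@dotbracket,
        sprintf(" (%.2f kcal/mol)\n", object@mfe), sep = "")
})

#' @describeIn SecondaryStructure 1-based pairing vector (0 = unpaired)
#' @param x a SecondaryStructure
#' @export
pairingVector <- function(x) dotbracketToPairs(x@dotbracket)

#' @describeIn SecondaryStructure the free energy in kcal/mol
#' @export
structureMFE <- function(x) x@mfe

#' @describeIn SecondaryStructure the dot-bracket string
#' @export
dotBracket <- function(x) x@dotbracket

#' DuplexHybrid: an intermolecular miRNA:target hybrid
#'
#' The result of [duplexMFE()]: the energetically best antiparallel hybrid
#' between a miRNA and a target window, with a per-column pairing diagram
#' using \code{|} for Watson-Crick pairs, \code{x} for G:U wobbles,
#' \code{*} for mismatches and \code{-} for bulged positions.
#'
#' @slot mirna miRNA sequence (5'->3').
#' @slot targetId identifier of the target sequence.
#' @slot siteStart,siteEnd 1-based site coordinates on the target.
#' @slot mfe hybrid free energy, kcal/mol.
#' @slot diagram per-column pairing symbols.
#' @exportClass DuplexHybrid
setClass("DuplexHybrid",
    representation(mirna = "character", targetId = "character",
                   siteStart = "integer", siteEnd = "integer",
                   mfe = "numeric", diagram = "character"))

setMethod("show", "DuplexHybrid", function(object) {
    cat(sprintf("DuplexHybrid %s @ %s:%d-%d  %.2f kcal/mol\n  %s\n",
                object@mirna, object@targetId, object@siteStart,
                object@siteEnd, object@mfe, object@diagram))
})
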