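## Readers/writers for the standard formats the pipeline touches and the
## collapsed-tag data model.  Internal alphabet is RNA (U); DNA input is
## accepted and converted.  Coordinates are 1-based inclusive in all emitted
## reports.

#' Normalise sequences to the RNA alphabet
#'
#' Upper-cases and converts T to U.  Any residual non-ACGU symbol is an
#' error.
#'
#' @param x character vector of sequences.
#' @param allow_n also admit the ambiguity symbol N (used for masking).
#' @return character vector over \{A,C,G,U\} (plus N when allowed).
#' @examples
#' normalizeRNA("tgacagaagagagtgagcac")
#' @export
normalizeRNA <- function(x, allow_n = FALSE) {
    x <- chartr("acgut", "ACGUU", x)
    x <- chartr("Tn", "UN", x)
    bad <- if (allow_n) grepl("[^ACGUN]", x) else grepl("[^ACGU]", x)
    if (any(bad))
        stop("non-ACGU symbols in sequence(s): ",
             paste(head(which(bad), 3L), collapse = ", "))
    x
}

#' Reverse complement of an RNA sequence
#'
#' @param x character vector (RNA or DNA alphabet).
#' @return reverse complement, RNA alphabet.
#' @export
revComplement <- function(x) {
    x <- normalizeRNA(x)
    vapply(x, function(s) {
        chartr("ACGU", "UGCA",
               paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    }, character(1), USE.NAMES = FALSE)
}

#' Read sequence records from FASTA or FASTQ
#'
#' Sequences are normalised to the RNA alphabet (T -> U, upper case);
#' record order is preserved.  An empty file yields a zero-row result.
#'
#' @param path input file.
#' @param format \code{"fasta"} or \code{"fastq"} (default: guessed from
#'   the file extension, falling back to fasta).
#' @return a data.frame with columns \code{id}, \code{sequence} and, for
#'   FASTQ, \code{quality} (numeric mean Phred per read in column
#'   \code{meanQ} plus the raw quality string).
#' @export
readSequences <- function(path, format = c("auto", "fasta", "fastq")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE))
            "fastq" else "fasta"
    if (file.info(path)$size == 0)
        return(data.frame(id = character(), sequence = character(),
                          stringsAsFactors = FALSE))
    if (format == "fasta") {
        ss <- tryCatch(readBStringSet(path, format = "fasta"),
                       error = function(e)
                           stop("malformed FASTA in ", path, ": ",
                                conditionMessage(e)))
        data.frame(id = names(ss), sequence = normalizeRNA(as.character(ss)),
                   stringsAsFactors = FALSE)
    } else {
        ss <- tryCatch(
            readQualityScaledDNAStringSet(path),
            error = function(e)
                stop("malformed FASTQ in ", path, ": ", conditionMessage(e)))
        q <- as(quality(ss), "IntegerList")
        data.frame(id = names(ss), sequence = normalizeRNA(as.character(ss)),
                   quality = as.character(quality(ss)),
                   meanQ = vapply(q, function(v) mean(as.numeric(v)),
                                  numeric(1)),
                   stringsAsFactors = FALSE)
    }
}

#' Write sequence records to FASTA
#'
#' @param records data.frame with \code{id} and \code{sequence}.
#' @param path output file.
#' @param alphabet \code{"RNA"} (default) or \code{"DNA"} (prints T).
#' @return \code{path}, invisibly.
#' @export
writeSequences <- function(records, path, alphabet = c("RNA", "DNA")) {
    alphabet <- match.arg(alphabet)
    sq <- normalizeRNA(records$sequence)
    if (alphabet == "DNA") sq <- chartr("U", "T", sq)
    writeLines(paste0(">", records$id, "\n", sq), path)
    invisible(path)
}

#' Collapse preprocessed reads into a TagSet
#'
#' Groups identical sequences into unique tags with per-library
#' frequencies.  Per-library read counts are conserved exactly:
#' \code{sum(tagCounts(x)[, lib])} equals the number of input reads of
#' \code{lib}.
#'
#' @param reads named list (one element per library) of character vectors
#'   of read sequences, or data.frames with a \code{sequence} column.
#' @param libraries library names; defaults to \code{names(reads)}.
#' @return a [TagSet], rows sorted by decreasing total count then
#'   lexicographically by sequence.
#' @export
collapseToTags <- function(reads, libraries = names(reads)) {
    if (is.null(libraries) || any(!nzchar(libraries)))
        stop("every read list element must carry a library name")
    seqs <- lapply(reads, function(r)
        normalizeRNA(if (is.data.frame(r)) r$sequence else r))
    all_tags <- sort(unique(unlist(seqs, use.names = FALSE)))
    counts <- vapply(seqs, function(s)
        as.integer(table(factor(s, levels = all_tags))),
        integer(length(all_tags)))
    if (length(all_tags) == 1L)
        counts <- matrix(counts, nrow = 1L,
                         dimnames = list(NULL, libraries))
    colnames(counts) <- libraries
    ts <- TagSet(all_tags, counts, libraries)
    sortTags(ts)
}

#' Deterministic tag ordering: decreasing total, then sequence
#' @param x a TagSet
#' @return the reordered TagSet
#' @export
sortTags <- function(x) {
    o <- order(-tagTotals(x), tagSequences(x))
    x[o, ]
}

#' Write a report table as TSV
#'
#' Tab-separated, header row, UTF-8.  Sequences are printed in the RNA
#' alphabet unless \code{alphabet = "DNA"}, which converts any
#' \code{sequence}-like column to T.
#'
#' @param rows a data.frame.
#' @param path output file.
#' @param alphabet \code{"RNA"} or \code{"DNA"}.
#' @return \code{path}, invisibly.
#' @export
writeTable <- function(rows, path, alphabet = c("RNA", "DNA")) {
    alphabet <- match.arg(alphabet)
    if (alphabet == "DNA")
        for (cn in intersect(c("sequence", "variant", "mature", "star"),
                             names(rows)))
            rows[[cn]] <- chartr("U", "T", rows[[cn]])
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read back a TSV written by [writeTable()]
#' @param path file path.
#' @return data.frame.
#' @export
readTable <- function(path)
    read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)

#' Export / import a TagSet in the collapsed-tag FASTA dialect
#'
#' Headers are \code{>tagN_xCOUNT} with COUNT the total read count; the
#' per-library breakdown is written to a sidecar TSV with the same stem.
#'
#' @param x a [TagSet].
#' @param path FASTA path (the sidecar is \code{<path>.counts.tsv}).
#' @return \code{path}, invisibly.
#' @export
writeCollapsedFasta <- function(x, path) {
    tot <- tagTotals(x)
    ids <- sprintf("tag%d_x%d", seq_along(tot), tot)
    writeLines(paste0(">", ids, "\n", tagSequences(x)), path)
    tab <- data.frame(id = ids, sequence = tagSequences(x),
                      tagCounts(x), check.names = FALSE)
    writeTable(tab, paste0(path, ".counts.tsv"))
    invisible(path)
}

#' @rdname writeCollapsedFasta
#' @export
readCollapsedFasta <- function(path) {
    tab <- readTable(paste0(path, ".counts.tsv"))
    libs <- setdiff(names(tab), c("id", "sequence"))
    sortTags(TagSet(tab$sequence,
                    as.matrix(tab[, libs, drop = FALSE]), libs))
}

#' Read a mature miRNA reference set
#'
#' Accepts either a FASTA file in the \code{"ID FAMILY"} header dialect
#' (family is the second whitespace token; a trailing \code{*} or
#' \code{-5p}/\code{-3p} star marker in the ID flags a mature-star entry)
#' or a data.frame with columns \code{name}, \code{sequence} and optional
#' \code{family}, \code{is_star}.  Duplicate reference sequences are an
#' error: the set must be canonicalised to one name per distinct sequence.
#'
#' @param x FASTA path or data.frame.
#' @return data.frame with columns \code{name}, \code{family},
#'   \code{sequence}, \code{is_star}.
#' @export
readMatureRefs <- function(x) {
    if (is.character(x)) {
        ss <- readBStringSet(x, format = "fasta")
        name <- sub("\\s.*$", "", names(ss))
        family <- ifelse(grepl("\\s", names(ss)),
                         sub("^\\S+\\s+(\\S+).*$", "\\1", names(ss)),
                         mirFamily(name))
        x <- data.frame(name = name, family = family,
                        sequence = normalizeRNA(as.character(ss)),
                        stringsAsFactors = FALSE)
    }
    if (is.null(x$family)) x$family <- mirFamily(x$name)
    if (is.null(x$is_star)) x$is_star <- isStarName(x$name)
    x$sequence <- normalizeRNA(x$sequence)
    if (anyDuplicated(x$sequence))
        stop("duplicate reference sequences; canonicalise to one name per sequence")
    if (any(!nzchar(x$family)))
        stop("empty family label in reference set")
    x[, c("name", "family", "sequence", "is_star")]
}

#' Extract the family label from a miRNA name
#'
#' \code{"gma-miR1510a-3p"} -> \code{"1510"}; \code{"aly-MIR171a*"} ->
#' \code{"171"}.  Names without a miR number are returned unchanged.
#'
#' @param name character vector of miRNA names.
#' @return character vector of family labels.
#' @export
mirFamily <- function(name) {
    has <- grepl("mir_?[0-9]+", name, ignore.case = TRUE, perl = TRUE)
    res <- name
    res[has] <- sub(".*?mir_?([0-9]+).*", "\\1", name[has],
                    ignore.case = TRUE, perl = TRUE)
    res
}

isStarName <- function(name)
    grepl("\\*$", name) | grepl("-(5p|3p)$", name)

#' Read the packaged conserved-miRNA fixture tables
#'
#' The package ships TSV transcriptions of a published four-organ common
#' bean (Phaseolus vulgaris) small RNA study: the conserved mature and
#' mature-star annotation tables, the per-family predicted loci table, and
#' the isomiR table.  Column order of the count columns is LL, FL, RL, SL
#' (leaves, flowers, roots, seedlings).
#'
#' @param which one of \code{"mature"}, \code{"star"}, \code{"loci"},
#'   \code{"isomir"}.
#' @return data.frame.
#' @export
mirbeanFixture <- function(which = c("mature", "star", "loci", "isomir")) {
    which <- match.arg(which)
    f <- c(mature = "conserved_mature.tsv", star = "conserved_star.tsv",
           loci = "family_loci.tsv", isomir = "isomir_table.tsv")[[which]]
    tab <- readTable(system.file("extdata", f, package = "mirbean",
                                 mustWork = TRUE))
    if ("sequence" %in% names(tab)) tab$sequence <- normalizeRNA(tab$sequence)
    tab
}

#' Build an annotated-hit table from a fixture table
#'
#' Converts a fixture annotation table (family/name/sequence/counts) into
#' the AnnotationHit layout produced by [annotateExact()], so the
#' downstream filters can be applied to the published tables directly.
#'
#' @param tab a fixture data.frame from [mirbeanFixture()].
#' @param is_star logical flag applied to all rows.
#' @return data.frame of hits.
#' @export
fixtureHits <- function(tab, is_star = FALSE) {
    libs <- c("LL", "FL", "RL", "SL")
    data.frame(name = tab$name, family = as.character(tab$family),
               sequence = tab$sequence, is_star = is_star,
               tab[, libs], total = rowSums(tab[, libs]),
               stringsAsFactors = FALSE)
}
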