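## Conserved-miRNA annotation: ncRNA removal, exact matching against the
## mature reference set, the two-library / 15-read conservation filter,
## per-family loci prediction and cross-species loci correlation.

#' Remove tags matching non-miRNA ncRNAs
#'
#' A tag is removed iff its sequence is identical to an ncRNA entry or is
#' contained as a full-length substring of one ("only perfect matches"):
#' tags are fragments of full-length ncRNAs.  The ncRNA set must share no
#' sequence with the mature miRNA reference set.
#'
#' @param x a [TagSet].
#' @param ncrna character vector of ncRNA sequences (or data.frame with a
#'   \code{sequence} column), with miRNA entries already removed.
#' @param refs optional mature reference set ([readMatureRefs()]); if
#'   given, an ncRNA entry equal to a reference sequence is a
#'   configuration error.
#' @return list with \code{tags} (filtered TagSet) and \code{removed}
#'   (integer count of removed tags).
#' @export
filterNcrna <- function(x, ncrna, refs = NULL) {
    if (is.data.frame(ncrna)) ncrna <- ncrna$sequence
    ncrna <- normalizeRNA(ncrna)
    if (!is.null(refs) && any(refs$sequence %in% ncrna))
        stop("ncRNA set shares sequences with the mature reference set")
    sq <- tagSequences(x)
    hit <- sq %in% ncrna
    ## full-tag substring of a longer ncRNA entry
    todo <- which(!hit)
    if (length(todo) && length(ncrna)) {
        subj <- paste(ncrna, collapse = "\n")
        hit[todo] <- vapply(sq[todo], function(s)
            grepl(s, subj, fixed = TRUE), logical(1))
    }
    list(tags = x[!hit, ], removed = sum(hit))
}

#' Annotate tags exactly matching mature reference miRNAs
#'
#' A tag annotates iff its sequence equals a reference sequence (same
#' size and nucleotide composition); each tag maps to at most one
#' reference because the reference set is deduplicated.  Annotated tags
#' are removed from the residual pool passed downstream.
#'
#' @param x a [TagSet].
#' @param refs reference set from [readMatureRefs()].
#' @return list with \code{hits} (data.frame: name, family, sequence,
#'   is_star, per-library counts, total) and \code{residual} (TagSet of
#'   unannotated tags).
#' @export
annotateExact <- function(x, refs) {
    refs <- readMatureRefs(refs)
    idx <- match(tagSequences(x), refs$sequence)
    ann <- !is.na(idx)
    k <- tagCounts(x)[ann, , drop = FALSE]
    hits <- data.frame(name = refs$name[idx[ann]],
                       family = refs$family[idx[ann]],
                       sequence = tagSequences(x)[ann],
                       is_star = refs$is_star[idx[ann]],
                       k, total = as.integer(rowSums(k)),
                       stringsAsFactors = FALSE, check.names = FALSE)
    list(hits = hits[order(-hits$total, hits$name), , drop = FALSE],
         residual = x[!ann, ])
}

#' Conservation filter: detected in >= 2 libraries and >= 15 total reads
#'
#' A pure function of the count columns; idempotent.  Discarded hits are
#' kept in a side table (they may later be rescued by precursor
#' evidence).
#'
#' @param hits data.frame from [annotateExact()] (or [fixtureHits()]).
#' @param min_total minimum total reads (inclusive; default 15).
#' @param min_libraries minimum libraries detected (inclusive; default 2).
#' @param libraries count column names; defaults to all integer columns
#'   except \code{total}.
#' @return list with \code{kept} and \code{discarded} data.frames.
#' @export
conservationFilter <- function(hits, min_total = 15L, min_libraries = 2L,
                               libraries = NULL) {
    if (is.null(libraries))
        libraries <- setdiff(names(hits)[vapply(hits, is.numeric,
                                                logical(1))],
                             c("total", "length"))
    k <- as.matrix(hits[, libraries, drop = FALSE])
    keep <- rowSums(k) >= min_total & rowSums(k > 0) >= min_libraries
    list(kept = hits[keep, , drop = FALSE],
         discarded = hits[!keep, , drop = FALSE])
}

#' Predict the number of loci per miRNA family
#'
#' Two mature sequences are "reconcilable" (can derive from one locus)
#' when one is an extension/truncation/shift of the other: a
#' zero-substitution ungapped alignment with terminal offsets of at most
#' \code{max_offset} nt per end.  The predicted loci count of a family is
#' the number of equivalence classes of its distinct mature sequences
#' under the transitive closure of that relation.
#'
#' @param sequences character vector of mature sequences (one family).
#' @param max_offset maximum terminal offset per end (default 2 nt).
#' @return integer loci count.
#' @export
predictLoci <- function(sequences, max_offset = 2L) {
    sq <- unique(normalizeRNA(sequences))
    n <- length(sq)
    if (n == 0L) return(0L)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        if (reconcilable(sq[i], sq[j], max_offset)) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[rj] <- ri
        }
    }
    length(unique(vapply(seq_len(n), find, integer(1))))
}

## zero-substitution ungapped offset alignment with per-end offsets <= mx
reconcilable <- function(a, b, mx = 2L) {
    la <- nchar(a); lb <- nchar(b)
    for (k in -mx:mx) {            # a[i] aligns b[i + k]
        off5 <- -k
        off3 <- (la + k) - lb
        if (abs(off5) > mx || abs(off3) > mx) next
        i1 <- max(1L, 1L - k); i2 <- min(la, lb - k)
        if (i2 < i1) next
        if (substr(a, i1, i2) == substr(b, i1 + k, i2 + k)) return(TRUE)
    }
    FALSE
}

#' Predicted loci per family for a whole reference table
#'
#' @param hits data.frame with \code{family} and \code{sequence}.
#' @param max_offset see [predictLoci()].
#' @return data.frame \code{family}, \code{loci} (families with >= 1
#'   sequence only).
#' @export
lociTable <- function(hits, max_offset = 2L) {
    fam <- split(hits$sequence, as.character(hits$family))
    out <- data.frame(family = names(fam),
                      loci = vapply(fam, predictLoci, integer(1),
                                    max_offset = max_offset),
                      row.names = NULL, stringsAsFactors = FALSE)
    out[order(suppressWarnings(as.numeric(out$family)), out$family), ]
}

#' Pearson correlation between two per-family loci vectors
#'
#' @param a,b numeric loci counts over the same families, length >= 3.
#' @return list with \code{r} (full precision) and \code{r2} (rounded to
#'   2 decimals).
#' @export
pearsonLoci <- function(a, b) {
    if (length(a) != length(b) || length(a) < 3L)
        stop("need two equal-length vectors of length >= 3")
    if (sd(a) == 0 || sd(b) == 0)
        stop("zero variance: correlation undefined")
    r <- cor(a, b)
    list(r = r, r2 = round(r, 2))
}
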