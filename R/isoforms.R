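## isomiR detection: bounded ungapped fuzzy matching of residual tags
## against the mature reference set, the 50%-over-reference abundance
## filter, three-way classification, and promotion of new families.

#' Prefilter residual tags by total abundance
#'
#' Keeps tags whose summed count across libraries is strictly greater
#' than \code{min_total} (default 10): low-abundance residual tags are
#' dominated by degradation products and sequencing error.
#'
#' @param x a [TagSet] (residual pool after exact annotation).
#' @param min_total strict lower bound on the total (default 10).
#' @return list with \code{pass} and \code{fail} TagSets.
#' @export
prefilterTags <- function(x, min_total = 10L) {
    keep <- tagTotals(x) > min_total
    list(pass = x[keep, ], fail = x[!keep, ])
}

#' All bounded ungapped alignments of a tag against a reference set
#'
#' Considers every reference and every ungapped alignment with terminal
#' offsets of at most \code{max_offset} nt per end and a length
#' difference of at most \code{max_offset} nt, and returns those with at
#' most \code{max_subs} substitutions in the aligned overlap.  Terminal
#' overhangs are offsets, never mismatches.  Offsets are signed with
#' positive = the variant extends beyond the reference at that end.
#'
#' @param tag variant sequence (RNA alphabet).
#' @param refs reference set ([readMatureRefs()]).
#' @param max_subs maximum substitutions (default 2).
#' @param max_offset maximum terminal offset per end (default 2).
#' @return data.frame with one row per qualifying (reference, alignment):
#'   \code{name}, \code{family}, \code{is_star}, \code{n_subs},
#'   \code{offset5}, \code{offset3}.
#' @export
fuzzyMatchAll <- function(tag, refs, max_subs = 2L, max_offset = 2L) {
    tag <- normalizeRNA(tag)
    lt <- nchar(tag)
    out <- vector("list", nrow(refs) * (2L * max_offset + 1L))
    nrow_out <- 0L
    for (r in seq_len(nrow(refs))) {
        rs <- refs$sequence[r]; lr <- nchar(rs)
        if (abs(lt - lr) > max_offset) next
        best <- NULL
        for (k in -max_offset:max_offset) {  # tag[i] aligns ref[i + k]
            off5 <- -k
            off3 <- (lt + k) - lr
            if (abs(off5) > max_offset || abs(off3) > max_offset) next
            i1 <- max(1L, 1L - k); i2 <- min(lt, lr - k)
            if (i2 < i1) next
            a <- strsplit(substr(tag, i1, i2), "")[[1]]
            b <- strsplit(substr(rs, i1 + k, i2 + k), "")[[1]]
            ns <- sum(a != b)
            if (ns > max_subs) next
            cand <- c(ns, abs(off5) + abs(off3), off5, off3)
            if (is.null(best) || cand[1] < best[1] ||
                (cand[1] == best[1] && cand[2] < best[2]))
                best <- cand
        }
        if (!is.null(best)) {
            nrow_out <- nrow_out + 1L
            out[[nrow_out]] <- data.frame(
                name = refs$name[r], family = refs$family[r],
                is_star = refs$is_star[r], n_subs = best[1],
                offset5 = best[3], offset3 = best[4],
                stringsAsFactors = FALSE)
        }
    }
    if (nrow_out == 0L)
        return(data.frame(name = character(), family = character(),
                          is_star = logical(), n_subs = integer(),
                          offset5 = integer(), offset3 = integer()))
    do.call(rbind, out[seq_len(nrow_out)])
}

#' Best fuzzy match of a tag against a reference set
#'
#' Over all qualifying alignments ([fuzzyMatchAll()]), chooses the one
#' minimising the substitution count, breaking ties by smaller
#' \code{|offset5| + |offset3|}, then by the reference with the larger
#' total observed reads (\code{ref_totals}), then by lexicographic
#' reference name.  Returns \code{NULL} when no alignment qualifies.
#'
#' @inheritParams fuzzyMatchAll
#' @param ref_totals named numeric vector of observed reference totals
#'   (0 for references absent from the libraries).
#' @return one-row data.frame (a VariantCall skeleton) or \code{NULL}.
#' @export
fuzzyMatch <- function(tag, refs, ref_totals = NULL, max_subs = 2L,
                       max_offset = 2L) {
    cand <- fuzzyMatchAll(tag, refs, max_subs, max_offset)
    if (nrow(cand) == 0L) return(NULL)
    tot <- if (is.null(ref_totals)) rep(0, nrow(cand)) else
        ifelse(is.na(ref_totals[cand$name]), 0, ref_totals[cand$name])
    o <- order(cand$n_subs, abs(cand$offset5) + abs(cand$offset3),
               -tot, cand$name)
    cbind(variant = normalizeRNA(tag), cand[o[1L], , drop = FALSE],
          stringsAsFactors = FALSE)
}

#' Abundance filter for variants grouped by reference
#'
#' When the reference was observed (\code{ref_total > 0}) a variant is
#' retained iff its total is at least 1.5x the reference total
#' (inclusive).  When the reference was never observed, only the single
#' highest-total variant of that reference is retained.
#'
#' @param calls data.frame of variant calls with columns \code{name}
#'   (reference), \code{total} (variant total reads).
#' @param ref_totals named numeric vector of reference totals.
#' @param ratio abundance ratio (default 1.5).
#' @return \code{calls} with a logical column \code{retained}.
#' @export
abundanceFilter <- function(calls, ref_totals, ratio = 1.5) {
    rt <- ifelse(is.na(ref_totals[calls$name]), 0, ref_totals[calls$name])
    retained <- logical(nrow(calls))
    for (ref in unique(calls$name)) {
        i <- which(calls$name == ref)
        if (rt[i[1L]] > 0) {
            retained[i] <- calls$total[i] >= ratio * rt[i[1L]]
        } else {
            retained[i[which.max(calls$total[i])]] <- TRUE
        }
    }
    calls$retained <- retained
    calls
}

#' Classify retained variants into the three isomiR groups
#'
#' \code{length}: zero substitutions (pure terminal heterogeneity);
#' \code{conserved}: >= 1 substitution and the reference family is in the
#' conserved set; \code{non_conserved}: >= 1 substitution, family not
#' conserved.  The three classes partition the retained calls.
#'
#' @param calls data.frame with \code{n_subs} and \code{family}.
#' @param conserved_families character vector of conserved family labels.
#' @return \code{calls} with a \code{var_class} column.
#' @export
classifyVariants <- function(calls, conserved_families) {
    calls$var_class <- ifelse(calls$n_subs == 0L, "length",
        ifelse(as.character(calls$family) %in%
                   as.character(conserved_families),
               "conserved", "non_conserved"))
    calls
}

#' Promote abundant new families to the conserved set
#'
#' Families absent from the conserved set whose retained variants sum to
#' at least \code{min_total} reads across libraries are promoted and join
#' the conserved family list used by the expression stage.
#'
#' @param calls classified calls (retained rows are used).
#' @param conserved_families current conserved family labels.
#' @param min_total promotion threshold (default 1000 reads).
#' @return character vector of promoted family labels.
#' @export
promoteFamilies <- function(calls, conserved_families, min_total = 1000) {
    r <- if ("retained" %in% names(calls))
        calls[calls$retained, , drop = FALSE] else calls
    r <- r[!as.character(r$family) %in% as.character(conserved_families), ,
           drop = FALSE]
    if (nrow(r) == 0L) return(character())
    s <- tapply(r$total, as.character(r$family), sum)
    sort(names(s)[s >= min_total])
}

#' Run the full isomiR chain on a set of variant tags
#'
#' For each tag: best fuzzy match against the reference set; then the
#' abundance filter per reference; then classification.  Variant calls
#' carry per-library counts.
#'
#' @param x a [TagSet] of candidate variant tags (prefiltered residuals).
#' @param refs reference set ([readMatureRefs()]).
#' @param ref_totals named numeric vector of observed reference totals.
#' @param conserved_families conserved family labels.
#' @param ratio,min_promote see [abundanceFilter()], [promoteFamilies()].
#' @return list with \code{calls} (all matched calls, with
#'   \code{retained} and \code{var_class}) and \code{promoted}.
#' @export
isomirChain <- function(x, refs, ref_totals, conserved_families,
                        ratio = 1.5, min_promote = 1000) {
    refs <- readMatureRefs(refs)
    k <- tagCounts(x)
    calls <- vector("list", nrow(x))
    for (i in seq_len(nrow(x))) {
        m <- fuzzyMatch(tagSequences(x)[i], refs, ref_totals)
        if (is.null(m)) next
        calls[[i]] <- cbind(m, as.data.frame(t(k[i, ])),
                            total = sum(k[i, ]))
    }
    calls <- do.call(rbind, calls[!vapply(calls, is.null, logical(1))])
    if (is.null(calls) || nrow(calls) == 0L)
        return(list(calls = NULL, promoted = character()))
    calls <- abundanceFilter(calls, ref_totals, ratio)
    calls <- classifyVariants(calls, conserved_families)
    calls$var_class[!calls$retained] <- NA_character_
    promoted <- promoteFamilies(calls[calls$retained, , drop = FALSE],
                                conserved_families, min_promote)
    rownames(calls) <- NULL
    list(calls = calls, promoted = promoted)
}
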