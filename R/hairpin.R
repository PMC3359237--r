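## Stem-loop precursor identification: fold candidate EST/GSS windows by
## free-energy minimisation, validate hairpin geometry, and score novel
## miRNA candidates from the read signature over the precursor.

#' Fold an RNA sequence by free-energy minimisation
#'
#' Returns the minimum-energy non-crossing structure under the packaged
#' nearest-neighbour model restricted to multiloop-free structures
#' (nested stems with bulges and interior loops, one terminal hairpin per
#' stem; the exterior loop may hold several stems).  Only the lowest
#' energy structure is returned.
#'
#' @param seq RNA (or DNA; T is aliased to U) sequence, <= 1000 nt.
#' @param params [foldParams()].
#' @return a [SecondaryStructure-class] object.
#' @examples
#' foldMinEnergy("GGGGAAAACCCC")
#' @export
foldMinEnergy <- function(seq, params = foldParams()) {
    seq <- normalizeRNA(seq)
    if (nchar(seq) > 1000L) stop("sequence longer than 1000 nt")
    b <- encodeBases(seq)
    res <- c_fold(b, params$stack, params$hairpin_pen, params$bulge_pen,
                  params$internal_pen, params$max_loop, params$min_loop)
    new("SecondaryStructure", sequence = seq,
        dotbracket = pairsToDotbracket(res$pairs),
        mfe = res$mfe)
}

#' Locate candidate precursor windows for a mature miRNA in an EST set
#'
#' Every exact full-length occurrence of the mature sequence (both
#' strands; reverse-complement occurrences are reported on the minus
#' strand of the EST) yields up to three windows -- mature-proximal to
#' the 5' end, centred, and mature-proximal to the 3' end -- each
#' clipped at the sequence ends.  Occurrences with any mismatch yield no
#' candidate (100% coverage and identity).
#'
#' @param mature mature miRNA sequence, 16-30 nt.
#' @param est_db data.frame with \code{id}, \code{sequence} (e.g. from
#'   [readSequences()]).
#' @param flank window flank size in nt (default 200).
#' @return data.frame of unfolded windows: \code{source_id},
#'   \code{strand}, \code{win_start}, \code{win_end} (1-based on the
#'   plus strand), \code{mat_start}, \code{mat_end} (within the window,
#'   1-based, in window orientation), \code{window_seq}.
#' @export
findPrecursorCandidates <- function(mature, est_db, flank = 200L) {
    mature <- normalizeRNA(mature)
    L <- nchar(mature)
    if (L < 16L || L > 30L) stop("mature length must be 16-30 nt")
    out <- list()
    for (r in seq_len(nrow(est_db))) {
        s <- normalizeRNA(est_db$sequence[r])
        for (strand in c("+", "-")) {
            subj <- if (strand == "+") s else revComplement(s)
            starts <- allOccurrences(mature, subj)
            for (st in starts) {
                en <- st + L - 1L
                n <- nchar(subj)
                ## mature near the window 5' end, centred, near the 3' end
                short <- max(10L, flank %/% 6L)
                lefts <- unique(c(short, flank, 2L * flank - short))
                for (lf in lefts) {
                    w1 <- max(1L, st - lf)
                    w2 <- min(n, en + (2L * flank - lf))
                    out[[length(out) + 1L]] <- data.frame(
                        source_id = est_db$id[r], strand = strand,
                        win_start = w1, win_end = w2,
                        mat_start = st - w1 + 1L, mat_end = en - w1 + 1L,
                        window_seq = substr(subj, w1, w2),
                        stringsAsFactors = FALSE)
                }
            }
        }
    }
    if (length(out) == 0L)
        return(data.frame(source_id = character(), strand = character(),
                          win_start = integer(), win_end = integer(),
                          mat_start = integer(), mat_end = integer(),
                          window_seq = character()))
    unique(do.call(rbind, out))
}

allOccurrences <- function(pattern, subject) {
    hits <- integer(0)
    from <- 1L
    repeat {
        p <- regexpr(pattern, substr(subject, from, nchar(subject)),
                     fixed = TRUE)
        if (p < 0L) break
        hits <- c(hits, from + p - 1L)
        from <- from + p
    }
    hits
}

#' Validate a folded precursor window as a miRNA hairpin
#'
#' Criteria (flags in the result): (a) the mature lies entirely on one
#' arm of a single stem-loop and does not overlap its terminal loop;
#' (b) at least \code{min_paired_frac} of mature bases are paired;
#' (c) at most \code{max_bulges} asymmetric bulges of at most
#' \code{max_bulge_size} nt within the mature/star duplex region;
#' (d) normalised folding energy <= \code{max_norm_mfe} kcal/mol/nt over
#' the window.  The star interval is predicted as the pairing partner of
#' the mature shifted to leave a 2-nt 3' overhang.
#'
#' @param structure a [SecondaryStructure-class] from [foldMinEnergy()].
#' @param mat_start,mat_end 1-based mature interval within the window.
#' @param min_paired_frac default 0.6.
#' @param max_bulges default 2.
#' @param max_bulge_size default 3 nt.
#' @param max_norm_mfe default -0.25 kcal/mol/nt.
#' @return list with \code{verdict}, \code{flags} (named logical),
#'   \code{arm} ("5p"/"3p"), \code{star_start}, \code{star_end},
#'   \code{norm_mfe}.
#' @export
validateHairpin <- function(structure, mat_start, mat_end,
                            min_paired_frac = 0.6, max_bulges = 2L,
                            max_bulge_size = 3L, max_norm_mfe = -0.25) {
    n <- nchar(structure@sequence)
    if (mat_start < 1L || mat_end > n || mat_start > mat_end)
        stop("mature interval outside the window")
    pairs <- pairingVector(structure)
    mat <- mat_start:mat_end
    L <- length(mat)
    partners <- pairs[mat]
    paired <- partners != 0L

    flags <- c(one_arm = FALSE, paired_frac = FALSE, bulges = FALSE,
               stability = FALSE)
    ## (b) paired fraction
    flags["paired_frac"] <- mean(paired) >= min_paired_frac
    ## (a) all partners outside the mature and on one side; no overlap
    ##     with the terminal loop of its stem
    arm <- NA_character_
    star_start <- star_end <- NA_integer_
    if (any(paired)) {
        pp <- partners[paired]
        self_pair <- any(pp >= mat_start & pp <= mat_end)
        one_side <- all(pp > mat_end) || all(pp < mat_start)
        loop_free <- TRUE
        loop_slop <- 4L   # tolerated loop-proximal unpaired mature bases
        if (!self_pair && one_side) {
            arm <- if (all(pp > mat_end)) "5p" else "3p"
            ## open region between the mature's deepest pair and its
            ## partner holds the terminal loop of the mature's stem
            lo <- if (arm == "5p") max(mat[paired]) else max(pp)
            hi <- if (arm == "5p") min(pp) else min(mat[paired])
            loop_free <- sum(mat > lo & mat < hi) <= loop_slop
            ## predicted star: partner of the first paired mature base,
            ## plus the 2-nt 3' overhang
            m1p <- partners[which(paired)[1L]]
            star_end <- min(n, m1p + 2L)
            star_start <- max(1L, star_end - L + 1L)
        }
        flags["one_arm"] <- !self_pair && one_side && loop_free
    }
    ## (c) asymmetric bulges within the duplex region
    if (flags["one_arm"]) {
        mp <- mat[paired]
        ok <- TRUE
        nb <- 0L
        if (length(mp) > 1L) {
            for (t in seq_len(length(mp) - 1L)) {
                g1 <- mp[t + 1L] - mp[t] - 1L
                g2 <- abs(pairs[mp[t]] - pairs[mp[t + 1L]]) - 1L
                if (g1 != g2) {
                    nb <- nb + 1L
                    if (max(g1, g2) > max_bulge_size) ok <- FALSE
                }
            }
        }
        flags["bulges"] <- ok && nb <= max_bulges
    }
    ## (d) stability
    norm <- structure@mfe / n
    flags["stability"] <- norm <= max_norm_mfe
    list(verdict = all(flags), flags = flags, arm = arm,
         star_start = star_start, star_end = star_end, norm_mfe = norm)
}

#' Score a validated precursor candidate from the read signature
#'
#' Residual tags are mapped into the window by exact substring match and
#' partitioned into mature / star / loop / inconsistent bins (a read is
#' consistent when at least 90% of its positions fall inside one bin,
#' each bin widened by \code{slop} nt).  The score is
#' \code{log(1 + mature_reads) + star_bonus * [star_reads > 0] -
#' inconsistency_penalty * inconsistent_reads / total}; candidates with
#' star evidence therefore rank strictly above otherwise identical
#' candidates without it.  Candidates with no mapped reads are dropped
#' (score \code{NA}).
#'
#' @param window_seq window sequence (window orientation).
#' @param mat_start,mat_end,star_start,star_end 1-based bins.
#' @param tags a [TagSet] of residual tags.
#' @param star_bonus,inconsistency_penalty,slop scoring constants
#'   (defaults 2, 4, 3).
#' @return list with read-bin counts and \code{score}.
#' @export
scoreNovel <- function(window_seq, mat_start, mat_end, star_start,
                       star_end, tags, star_bonus = 2,
                       inconsistency_penalty = 4, slop = 3L) {
    window_seq <- normalizeRNA(window_seq)
    sq <- tagSequences(tags)
    tot <- tagTotals(tags)
    bins <- c(mature = 0, star = 0, loop = 0, inconsistent = 0)
    loop_lo <- min(mat_end, star_end) + 1L
    loop_hi <- max(mat_start, star_start) - 1L
    inBin <- function(s, e, lo, hi) {
        ov <- max(0L, min(e, hi) - max(s, lo) + 1L)
        ov / (e - s + 1L) >= 0.9
    }
    for (t in seq_along(sq)) {
        p <- regexpr(sq[t], window_seq, fixed = TRUE)
        if (p < 0L) next
        s <- as.integer(p); e <- s + nchar(sq[t]) - 1L
        if (inBin(s, e, mat_start - slop, mat_end + slop))
            bins["mature"] <- bins["mature"] + tot[t]
        else if (!is.na(star_start) &&
                 inBin(s, e, star_start - slop, star_end + slop))
            bins["star"] <- bins["star"] + tot[t]
        else if (loop_hi >= loop_lo && inBin(s, e, loop_lo, loop_hi))
            bins["loop"] <- bins["loop"] + tot[t]
        else
            bins["inconsistent"] <- bins["inconsistent"] + tot[t]
    }
    total <- sum(bins)
    score <- if (total == 0) NA_real_ else
        log1p(bins[["mature"]]) +
        star_bonus * (bins[["star"]] > 0) -
        inconsistency_penalty * bins[["inconsistent"]] / total
    c(as.list(bins), list(total = total, score = score))
}

#' Discover and score novel miRNA candidates from residual tags
#'
#' Takes abundant residual tags as candidate matures, locates exact
#' occurrences in the EST set, folds and validates the windows, and
#' scores validated candidates by their read signature.
#'
#' @param tags residual [TagSet].
#' @param est_db EST data.frame (\code{id}, \code{sequence}).
#' @param min_total minimum candidate-mature total reads (default 20).
#' @param flank window flank (default 60 nt; plant precursor scale).
#' @param keep_threshold minimum score (default 1).
#' @param params [foldParams()].
#' @return data.frame of scored candidates sorted by decreasing score.
#' @export
discoverNovel <- function(tags, est_db, min_total = 20L, flank = 60L,
                          keep_threshold = 1, params = foldParams()) {
    cand_tags <- tags[tagTotals(tags) >= min_total &
                      nchar(tagSequences(tags)) >= 18L &
                      nchar(tagSequences(tags)) <= 25L, ]
    rows <- list()
    for (i in seq_len(nrow(cand_tags))) {
        mat <- tagSequences(cand_tags)[i]
        wins <- findPrecursorCandidates(mat, est_db, flank)
        best <- NULL
        for (w in seq_len(nrow(wins))) {
            st <- foldMinEnergy(wins$window_seq[w], params)
            v <- validateHairpin(st, wins$mat_start[w], wins$mat_end[w])
            if (!v$verdict) next
            sc <- scoreNovel(wins$window_seq[w], wins$mat_start[w],
                             wins$mat_end[w], v$star_start, v$star_end,
                             tags)
            if (is.na(sc$score) || sc$score < keep_threshold) next
            row <- data.frame(mature = mat, source_id = wins$source_id[w],
                              strand = wins$strand[w],
                              win_start = wins$win_start[w],
                              win_end = wins$win_end[w],
                              mfe = structureMFE(st),
                              mature_reads = sc$mature,
                              star_reads = sc$star,
                              loop_reads = sc$loop,
                              inconsistent_reads = sc$inconsistent,
                              score = sc$score, stringsAsFactors = FALSE)
            if (is.null(best) || row$score > best$score) best <- row
        }
        if (!is.null(best)) rows[[length(rows) + 1L]] <- best
    }
    if (length(rows) == 0L) return(NULL)
    out <- do.call(rbind, rows)
    out[order(-out$score), , drop = FALSE]
}
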