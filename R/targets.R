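## Target prediction: intermolecular miRNA:mRNA duplex free-energy
## minimisation over EST sequences, with the |/x/* pairing-diagram
## notation (| = Watson-Crick pair, x = G:U wobble, * = mismatch,
## - = bulged position) and the dual-site TAS3-like scan.

#' Minimum-energy intermolecular hybrid of a miRNA and a target window
#'
#' No intramolecular pairing is considered.  The hybrid minimises the sum
#' of stacking energies over Watson-Crick and G:U pairs, with per-column
#' mismatch penalties, bulge penalties (<= \code{max_bulge} nt per
#' bulge), and dangling-end costs for unpaired miRNA termini.  G:U
#' wobbles are pairs, never mismatches.
#'
#' @param mirna miRNA sequence (5'->3').
#' @param target target window sequence (5'->3'), length <= 40 nt for a
#'   single-site call.
#' @param target_id identifier for reporting.
#' @param params [duplexParams()].
#' @return a [DuplexHybrid-class]; site coordinates are 1-based on the
#'   target as given.
#' @export
duplexMFE <- function(mirna, target, target_id = "target",
                      params = duplexParams()) {
    mirna <- normalizeRNA(mirna)
    target <- normalizeRNA(target, allow_n = TRUE)
    if (!nzchar(mirna) || !nzchar(target)) stop("empty input sequence")
    m <- encodeBases(mirna)
    r <- rev(encodeBases(target))
    res <- c_duplex(m, r, params$stack, params$mismatch,
                    params$bulge_open, params$bulge_ext, params$dangle,
                    params$max_bulge, params$max_mismatch_run)
    if (!is.finite(res$mfe))
        return(new("DuplexHybrid", mirna = mirna, targetId = target_id,
                   siteStart = NA_integer_, siteEnd = NA_integer_,
                   mfe = Inf, diagram = ""))
    N <- length(r)
    new("DuplexHybrid", mirna = mirna, targetId = target_id,
        siteStart = as.integer(N - res$rev_last + 1L),
        siteEnd = as.integer(N - res$rev_first + 1L),
        mfe = res$mfe, diagram = res$diagram)
}

#' Energy of a miRNA against its exact reverse complement
#'
#' The reference ("perfect") duplex energy used to normalise hybrid
#' energies into a length/GC-independent ratio.
#'
#' @inheritParams duplexMFE
#' @return kcal/mol (negative).
#' @export
perfectDuplexMFE <- function(mirna, params = duplexParams())
    duplexMFE(mirna, revComplement(mirna), "perfect", params)@mfe

#' Scan an EST set for miRNA target sites
#'
#' For each miRNA x EST the best-site hybrid is computed over the whole
#' EST; calls with \code{mfe <= threshold_ratio * perfect_mfe} (both
#' negative) are reported, sorted by energy.
#'
#' @param mirnas named character vector of miRNA sequences (names used
#'   in the report) or data.frame with \code{name}, \code{sequence}.
#' @param est_db data.frame with \code{id}, \code{sequence}.
#' @param threshold_ratio energy ratio to the perfect duplex required to
#'   call a target (default 0.7).
#' @param params [duplexParams()].
#' @return data.frame: \code{mirna}, \code{target_id}, \code{site_start},
#'   \code{site_end}, \code{mfe}, \code{perfect_mfe}, \code{ratio},
#'   \code{diagram}, \code{passed}.
#' @export
scanTargets <- function(mirnas, est_db, threshold_ratio = 0.7,
                        params = duplexParams()) {
    if (is.data.frame(mirnas))
        mirnas <- setNames(mirnas$sequence, mirnas$name)
    if (is.null(names(mirnas)))
        names(mirnas) <- paste0("mir", seq_along(mirnas))
    rows <- list()
    for (mn in names(mirnas)) {
        m <- normalizeRNA(mirnas[[mn]])
        pmfe <- perfectDuplexMFE(m, params)
        for (r in seq_len(nrow(est_db))) {
            hy <- duplexMFE(m, est_db$sequence[r], est_db$id[r], params)
            if (!is.finite(hy@mfe)) next
            rows[[length(rows) + 1L]] <- data.frame(
                mirna = mn, target_id = hy@targetId,
                site_start = hy@siteStart, site_end = hy@siteEnd,
                mfe = hy@mfe, perfect_mfe = pmfe,
                ratio = hy@mfe / pmfe, diagram = hy@diagram,
                passed = hy@mfe <= threshold_ratio * pmfe,
                stringsAsFactors = FALSE)
        }
    }
    if (length(rows) == 0L) return(NULL)
    out <- do.call(rbind, rows)
    out <- out[out$passed, , drop = FALSE]
    out[order(out$mfe, out$mirna, out$target_id), , drop = FALSE]
}

#' Scan for TAS3-like transcripts carrying two miR390 sites
#'
#' Reports ESTs with at least two non-overlapping miR390 hybrid sites at
#' a relaxed energy ratio, with both site coordinates and the inter-site
#' spacing (distance between the inner site ends).  Overlapping hits are
#' collapsed to the best non-overlapping pair.
#'
#' @param mir390 the miR390 sequence.
#' @param est_db data.frame with \code{id}, \code{sequence}.
#' @param threshold_ratio relaxed ratio (default 0.55).
#' @param params [duplexParams()].
#' @return data.frame with one row per dual-site EST, or \code{NULL}.
#' @export
scanTAS3 <- function(mir390, est_db, threshold_ratio = 0.55,
                     params = duplexParams()) {
    mir390 <- normalizeRNA(mir390)
    pmfe <- perfectDuplexMFE(mir390, params)
    rows <- list()
    for (r in seq_len(nrow(est_db))) {
        s <- normalizeRNA(est_db$sequence[r])
        h1 <- duplexMFE(mir390, s, est_db$id[r], params)
        if (!is.finite(h1@mfe) || h1@mfe > threshold_ratio * pmfe) next
        ## mask the first site and rescan for a non-overlapping second
        masked <- s
        substr(masked, h1@siteStart, h1@siteEnd) <-
            paste(rep("N", h1@siteEnd - h1@siteStart + 1L), collapse = "")
        h2 <- duplexMFE(mir390, masked, est_db$id[r], params)
        if (!is.finite(h2@mfe) || h2@mfe > threshold_ratio * pmfe) next
        sites <- list(h1, h2)[order(c(h1@siteStart, h2@siteStart))]
        rows[[length(rows) + 1L]] <- data.frame(
            target_id = est_db$id[r],
            site1_start = sites[[1]]@siteStart,
            site1_end = sites[[1]]@siteEnd,
            site2_start = sites[[2]]@siteStart,
            site2_end = sites[[2]]@siteEnd,
            spacing = sites[[2]]@siteStart - sites[[1]]@siteEnd,
            mfe1 = sites[[1]]@mfe, mfe2 = sites[[2]]@mfe,
            stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L) return(NULL)
    do.call(rbind, rows)
}
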