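## Read cleaning: 3' adapter trimming, quality/length filtering, and the
## length-distribution summary of collapsed libraries.

#' Preprocessing parameters
#'
#' @param adapter 3' adapter sequence (RNA or DNA alphabet).  Reads are
#'   expected to read through into the adapter (short-insert small RNA
#'   sequencing), so reads with no adapter match are discarded.
#' @param min_len,max_len retained insert length range, inclusive
#'   (defaults 16 and 30 nt).
#' @param min_mean_quality minimum mean Phred score (applied only when
#'   qualities are present).
#' @param adapter_min_prefix minimum matched adapter prefix length
#'   (>= 6; default 8).
#' @return a list of class \code{PreprocessParams}.
#' @export
preprocessParams <- function(adapter = "UCGUAUGCCGUCUUCUGCUUG",
                             min_len = 16L, max_len = 30L,
                             min_mean_quality = 20,
                             adapter_min_prefix = 8L) {
    if (!nzchar(adapter)) stop("empty adapter sequence")
    if (adapter_min_prefix < 6L) stop("adapter_min_prefix must be >= 6")
    if (min_len <= 0L || min_len > max_len)
        stop("need 0 < min_len <= max_len")
    structure(list(adapter = normalizeRNA(adapter),
                   min_len = as.integer(min_len),
                   max_len = as.integer(max_len),
                   min_mean_quality = min_mean_quality,
                   adapter_min_prefix = as.integer(adapter_min_prefix)),
              class = "PreprocessParams")
}

#' Trim the 3' adapter from reads
#'
#' The insert is everything before the leftmost exact match of the first
#' \code{adapter_min_prefix} bases of the adapter.  Reads without a match
#' are returned as \code{NA} (to be discarded): with read lengths well
#' above the insert size range, every genuine small-RNA read reads through
#' into the adapter.
#'
#' @param sequences character vector of read sequences.
#' @param params a [preprocessParams()] object.
#' @return character vector of inserts (\code{NA} where no adapter match).
#' @export
trimAdapter <- function(sequences, params = preprocessParams()) {
    sequences <- normalizeRNA(sequences)
    probe <- substr(params$adapter, 1L, params$adapter_min_prefix)
    pos <- regexpr(probe, sequences, fixed = TRUE)
    ifelse(pos > 0L, substr(sequences, 1L, pos - 1L), NA_character_)
}

#' Quality- and length-filter adapter-trimmed reads
#'
#' A read is kept iff \code{min_len <= length <= max_len} and (when
#' qualities are present) its mean Phred score is at least
#' \code{min_mean_quality}.  The discard tally partitions the input:
#' \code{kept + no_adapter + short + long + low_quality == n}.
#'
#' @param inserts character vector from [trimAdapter()] (\code{NA} = no
#'   adapter found).  Zero-length inserts count as short.
#' @param meanQ optional numeric vector of per-read mean Phred scores.
#' @param params a [preprocessParams()] object.
#' @return list with \code{kept} (character vector) and \code{tally}
#'   (named integer vector).
#' @export
filterReads <- function(inserts, meanQ = NULL, params = preprocessParams()) {
    n <- length(inserts)
    no_adapter <- is.na(inserts)
    len <- ifelse(no_adapter, NA_integer_, nchar(inserts))
    short <- !no_adapter & len < params$min_len
    long  <- !no_adapter & len > params$max_len
    lowq  <- rep(FALSE, n)
    if (!is.null(meanQ))
        lowq <- !no_adapter & !short & !long &
            meanQ < params$min_mean_quality
    keep <- !no_adapter & !short & !long & !lowq
    list(kept = inserts[keep],
         tally = c(kept = sum(keep), no_adapter = sum(no_adapter),
                   short = sum(short), long = sum(long),
                   low_quality = sum(lowq)))
}

#' Per-library length distribution of unique and redundant sequences
#'
#' For each library, the percentage of unique tags (distinct sequences)
#' and of redundant reads (counts) in each length bin from
#' \code{min_len} to \code{max_len}.  Each percentage vector sums to 100.
#'
#' @param x a [TagSet].
#' @param min_len,max_len bin range (default 16-30 nt).
#' @return list with matrices \code{unique_pct} and \code{redundant_pct}
#'   (rows = lengths, columns = libraries).
#' @export
lengthDistribution <- function(x, min_len = 16L, max_len = 30L) {
    len <- nchar(tagSequences(x))
    if (any(len < min_len | len > max_len))
        stop("tags outside the ", min_len, "-", max_len, " nt range")
    bins <- factor(len, levels = min_len:max_len)
    k <- tagCounts(x)
    upct <- vapply(seq_len(ncol(k)), function(j) {
        det <- k[, j] > 0
        tab <- table(bins[det])
        100 * as.numeric(tab) / max(1L, sum(det))
    }, numeric(max_len - min_len + 1L))
    rpct <- vapply(seq_len(ncol(k)), function(j) {
        tot <- tapply(k[, j], bins, sum, default = 0L)
        100 * as.numeric(tot) / max(1L, sum(k[, j]))
    }, numeric(max_len - min_len + 1L))
    dimnames(upct) <- dimnames(rpct) <-
        list(min_len:max_len, libNames(x))
    list(unique_pct = upct, redundant_pct = rpct)
}
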