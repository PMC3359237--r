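## The simplified nearest-neighbour energy model shared by the folding and
## duplex engines: Watson-Crick and G:U stacking energies (kcal/mol) from a
## versioned packaged table, plus logarithmic loop penalties.

PAIR_LEVELS <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Folding parameters: stacking table and loop penalties
#'
#' Loads the packaged, versioned stacking-energy table (symmetric under
#' strand reversal, all entries negative) and builds the loop penalty
#' vectors.  Penalties are logarithmic in loop size:
#' hairpin(n) = 5.4 + 1.08 log(n/3) for n >= 3 unpaired bases,
#' bulge(n) = 3.8 + 1.08 log(n), internal(n) = 1.7 + 1.08 log(n/2) with n
#' the total unpaired bases.  Interior loops are capped at
#' \code{max_loop} unpaired bases per side; the minimum hairpin loop is 3.
#'
#' @param max_loop maximum unpaired bases per interior-loop side
#'   (default 10).
#' @param min_loop minimum hairpin loop size (default 3).
#' @param max_hairpin largest representable loop (penalty vector length).
#' @return list of class \code{FoldParams}.
#' @export
foldParams <- function(max_loop = 10L, min_loop = 3L, max_hairpin = 400L) {
    key <- paste(max_loop, min_loop, max_hairpin)
    hit <- .fold_params_cache[[key]]
    if (!is.null(hit)) return(hit)
    tab <- readTable(system.file("extdata", "stack_energies_v1.tsv",
                                 package = "mirbean", mustWork = TRUE))
    S <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_LEVELS, PAIR_LEVELS))
    S[cbind(tab$pair1, tab$pair2)] <- tab$dG
    stopifnot(!anyNA(S), all(S < 0))
    n <- seq_len(max_hairpin)
    .fold_params_cache[[key]] <- structure(list(
        stack = S,
        hairpin_pen = ifelse(n < min_loop, Inf, 5.4 + 1.08 * log(n / 3)),
        bulge_pen = 3.8 + 1.08 * log(n),
        internal_pen = ifelse(n < 2, Inf, 1.7 + 1.08 * log(n / 2)),
        max_loop = as.integer(max_loop),
        min_loop = as.integer(min_loop)), class = "FoldParams")
    .fold_params_cache[[key]]
}

.fold_params_cache <- new.env(parent = emptyenv())

#' Duplex (hybridisation) parameters
#'
#' Intermolecular hybrids use the same stacking table; mismatched columns
#' cost \code{mismatch} kcal/mol each, bulges of b nt cost
#' \code{bulge_open + bulge_ext * b} (b <= \code{max_bulge}), and
#' unpaired miRNA bases dangling outside the duplex cost \code{dangle}
#' per nt.
#'
#' @param mismatch,bulge_open,bulge_ext,dangle energy penalties
#'   (kcal/mol, positive).
#' @param max_bulge largest bulge (nt) allowed in a hybrid (default 3).
#' @param max_mismatch_run longest run of consecutive mismatched columns.
#' @return list of class \code{DuplexParams}.
#' @export
duplexParams <- function(mismatch = 1.1, bulge_open = 2.6, bulge_ext = 0.4,
                         dangle = 0.3, max_bulge = 3L,
                         max_mismatch_run = 3L) {
    fp <- foldParams()
    structure(list(stack = fp$stack, mismatch = mismatch,
                   bulge_open = bulge_open, bulge_ext = bulge_ext,
                   dangle = dangle, max_bulge = as.integer(max_bulge),
                   max_mismatch_run = as.integer(max_mismatch_run)),
              class = "DuplexParams")
}

## base encoding A=1 C=2 G=3 U=4 (0 = non-pairable placeholder, e.g. N)
encodeBases <- function(seq) {
    v <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "U"))
    v[is.na(v)] <- 0L
    as.integer(v)
}

## pair code in PAIR_LEVELS order; 0 if not a legal pair
pairCode <- function(a, b) {
    lut <- matrix(0L, 4, 4)
    lut[1, 4] <- 1L; lut[4, 1] <- 2L; lut[3, 2] <- 3L
    lut[2, 3] <- 4L; lut[3, 4] <- 5L; lut[4, 3] <- 6L
    code <- integer(length(a))
    ok <- a >= 1 & a <= 4 & b >= 1 & b <= 4
    code[ok] <- lut[cbind(a, b)[ok, , drop = FALSE]]
    code
}

#' Convert a dot-bracket string to a pairing vector
#'
#' @param db dot-bracket string.
#' @return integer vector: partner index per position (0 = unpaired).
#' @export
dotbracketToPairs <- function(db) {
    v <- strsplit(db, "")[[1]]
    pairs <- integer(length(v))
    stack <- integer(0)
    for (i in seq_along(v)) {
        if (v[i] == "(") stack <- c(stack, i)
        else if (v[i] == ")") {
            j <- stack[length(stack)]
            stack <- stack[-length(stack)]
            pairs[i] <- j; pairs[j] <- i
        }
    }
    pairs
}

pairsToDotbracket <- function(pairs) {
    v <- rep(".", length(pairs))
    v[pairs > seq_along(pairs)] <- "("
    v[pairs != 0 & pairs < seq_along(pairs)] <- ")"
    paste(v, collapse = "")
}

#' Recompute the free energy of an explicit structure
#'
#' Independent scorer used to verify folded structures and as the basis
#' of the enumeration oracle: walks the pair list, checks legality
#' (non-crossing, legal pairs, hairpin loops >= min_loop, no multiloops,
#' interior loops within \code{max_loop} per side) and sums stacking
#' energies and loop penalties.
#'
#' @param seq RNA sequence.
#' @param pairs pairing vector (partner index, 0 = unpaired) or
#'   dot-bracket string.
#' @param params [foldParams()].
#' @return energy in kcal/mol; \code{Inf} for an illegal structure.
#' @export
energyOfStructure <- function(seq, pairs, params = foldParams()) {
    seq <- normalizeRNA(seq)
    if (is.character(pairs)) pairs <- dotbracketToPairs(pairs)
    b <- encodeBases(seq)
    n <- length(b)
    opens <- which(pairs > seq_len(n))
    if (length(opens) == 0L) return(0)
    ## legality: pair types
    for (i in opens)
        if (pairCode(b[i], b[pairs[i]]) == 0L) return(Inf)
    ## non-crossing
    for (i in opens) for (j in opens)
        if (i < j && j < pairs[i] && pairs[j] > pairs[i]) return(Inf)
    ## parent of each open pair = innermost enclosing open pair (0 = exterior)
    parent <- vapply(opens, function(k) {
        enc <- opens[opens < k & pairs[opens] > pairs[k]]
        if (length(enc)) max(enc) else 0L
    }, integer(1))
    e <- 0
    for (i in opens) {
        j <- pairs[i]
        direct <- opens[parent == i]
        if (length(direct) == 0L) {           # hairpin
            h <- j - i - 1L
            if (h < params$min_loop) return(Inf)
            e <- e + params$hairpin_pen[h]
        } else if (length(direct) == 1L) {    # stack / bulge / interior
            k <- direct; l <- pairs[k]
            n1 <- k - i - 1L; n2 <- j - l - 1L
            if (n1 == 0L && n2 == 0L) {
                e <- e + params$stack[pairCode(b[i], b[j]),
                                      pairCode(b[k], b[l])]
            } else if (n1 == 0L || n2 == 0L) {
                if (max(n1, n2) > params$max_loop) return(Inf)
                e <- e + params$bulge_pen[n1 + n2]
            } else {
                if (max(n1, n2) > params$max_loop) return(Inf)
                e <- e + params$internal_pen[n1 + n2]
            }
        } else {
            return(Inf)                       # multiloop: outside the model
        }
    }
    e
}
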