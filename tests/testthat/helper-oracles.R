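# Independent brute-force oracles for the folding and duplex engines.
# Both enumerate explicitly and score with energyOfStructure / a
# column-cost sum, never reusing the DP recursions.

# all legal closed structures (pair lists) with (i, j) paired, under the
# multiloop-free model; pair list = integer vector c(i1,j1, i2,j2, ...)
oracle_closed <- function(b, i, j, fp, counter) {
  if (mirbean:::pairCode(b[i], b[j]) == 0L) return(list())
  out <- list()
  if (j - i - 1L >= fp$min_loop) out[[1L]] <- c(i, j)
  if (j - i < 2L) return(out)
  for (k in (i + 1L):min(j - 1L, i + 1L + fp$max_loop)) {
    for (l in (j - 1L):max(k + 1L, j - 1L - fp$max_loop)) {
      if (l <= k) next
      if (mirbean:::pairCode(b[k], b[l]) == 0L) next
      for (sub in oracle_closed(b, k, l, fp, counter)) {
        out[[length(out) + 1L]] <- c(i, j, sub)
        counter$n <- counter$n + 1L
        if (counter$n > counter$cap) stop("oracle_cap")
      }
    }
  }
  out
}

# all structures over region [i, n]: empty or a closed stem + rest
oracle_exterior <- function(b, i, n, fp, counter) {
  if (i > n - fp$min_loop - 1L) return(list(integer(0)))
  out <- list(integer(0))
  for (a in i:(n - fp$min_loop - 1L)) {
    for (e in (a + fp$min_loop + 1L):n) {
      for (cs in oracle_closed(b, a, e, fp, counter)) {
        for (rest in oracle_exterior(b, e + 1L, n, fp, counter)) {
          out[[length(out) + 1L]] <- c(cs, rest)
          counter$n <- counter$n + 1L
          if (counter$n > counter$cap) stop("oracle_cap")
        }
      }
    }
  }
  out
}

# brute-force MFE: enumerate every legal structure, score each with the
# independent energy recomputation, take the minimum (0 = open chain)
oracle_fold_mfe <- function(seq, fp = foldParams(), cap = 50000L) {
  b <- mirbean:::encodeBases(normalizeRNA(seq))
  n <- length(b)
  counter <- new.env(); counter$n <- 0L; counter$cap <- cap
  structs <- oracle_exterior(b, 1L, n, fp, counter)
  best <- 0
  for (s in structs) {
    if (length(s) == 0L) next
    pairs <- integer(n)
    ii <- s[seq(1L, length(s), 2L)]
    jj <- s[seq(2L, length(s), 2L)]
    pairs[ii] <- jj; pairs[jj] <- ii
    e <- energyOfStructure(seq, pairs, fp)
    if (e < best) best <- e
  }
  best
}

# duplex oracle: exhaustive top-down search over alignments (miRNA i,
# reversed-target j), memoised; costs mirror duplexParams directly
oracle_duplex_mfe <- function(mirna, target, dp = duplexParams()) {
  m <- mirbean:::encodeBases(normalizeRNA(mirna))
  r <- rev(mirbean:::encodeBases(normalizeRNA(target)))
  M <- length(m); N <- length(r)
  stack <- dp$stack
  memo <- new.env()
  # best energy from pair (i, j) onwards, including right dangle
  from <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- dp$dangle * (M - i)           # stop here
    if (i < M && j < N) for (p in (i + 1L):M) {
      gm <- p - i - 1L
      for (q in (j + 1L):N) {
        gw <- q - j - 1L
        if (min(gm, gw) > dp$max_mismatch_run) next
        if (abs(gm - gw) > dp$max_bulge) next
        if (mirbean:::pairCode(m[p], r[q]) == 0L) next
        cost <- dp$mismatch * min(gm, gw)
        if (gm != gw) cost <- cost + dp$bulge_open +
            dp$bulge_ext * abs(gm - gw)
        if (gm == 0L && gw == 0L)
          cost <- cost + stack[mirbean:::pairCode(m[i], r[j]),
                               mirbean:::pairCode(m[p], r[q])]
        e <- cost + from(p, q)
        if (e < best) best <- e
      }
    }
    memo[[key]] <- best
    best
  }
  best <- Inf
  for (i in seq_len(M)) for (j in seq_len(N)) {
    if (mirbean:::pairCode(m[i], r[j]) == 0L) next
    e <- dp$dangle * (i - 1L) + from(i, j)
    if (e < best) best <- e
  }
  best
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")
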