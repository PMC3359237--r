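# helper: dinucleotide shuffle (permutes dinucleotide units)
dinuc_shuffle <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v) - length(v) %% 2
  units <- vapply(seq(1, n, 2), function(i) paste0(v[i], v[i + 1]), "")
  paste0(paste(sample(units), collapse = ""),
         if (n < length(v)) v[length(v)] else "")
}

# helper: one synthetic precursor window with known geometry
planted_window <- function(seed = 1) {
  cfg <- simConfig(n_genes = 1L, n_contam = 0L, contamination_frac = 0,
                   seed = seed)
  sim <- simulateReferenceSets(cfg)
  g <- sim$truth$genes[1, ]
  list(seq = sim$est$sequence[sim$est$id == g$est_id], gene = g)
}

test_that("folding handles trivial and closed-form cases", {
  s <- foldMinEnergy("AAAAAAAAAA")
  expect_equal(structureMFE(s), 0)
  expect_equal(dotBracket(s), "..........")
  ## 4-stack GC stem with a tetraloop: 3 GC/GC stacks + hairpin(4)
  fp <- foldParams()
  s2 <- foldMinEnergy("GGGGAAAACCCC", fp)
  expect_equal(dotBracket(s2), "((((....))))")
  expect_equal(structureMFE(s2),
               3 * fp$stack["GC", "GC"] + fp$hairpin_pen[4],
               tolerance = 1e-9)
})

test_that("reported energies recompute from the returned structure", {
  set.seed(21)
  fp <- foldParams()
  for (i in 1:25) {
    s <- random_rna(sample(15:60, 1))
    st <- foldMinEnergy(s, fp)
    expect_equal(energyOfStructure(s, dotBracket(st), fp),
                 structureMFE(st), tolerance = 1e-6)
    expect_true(structureMFE(st) <= 0)
  }
})

test_that("folding is invariant under T/U input aliasing", {
  set.seed(22)
  for (i in 1:5) {
    s <- random_rna(30)
    expect_equal(structureMFE(foldMinEnergy(chartr("U", "T", s))),
                 structureMFE(foldMinEnergy(s)))
  }
})

test_that("folding DP agrees with the enumeration oracle (spot check)", {
  set.seed(23)
  fp <- foldParams()
  for (i in 1:25) {
    s <- random_rna(sample(8:15, 1))
    o <- tryCatch(oracle_fold_mfe(s, fp), error = function(e) NA)
    if (is.na(o)) next
    expect_equal(structureMFE(foldMinEnergy(s, fp)), o, tolerance = 1e-6,
                 label = paste("mfe of", s))
  }
})

test_that("precursor windows require exact full-length occurrences", {
  pw <- planted_window(31)
  g <- pw$gene
  est <- data.frame(id = g$est_id, sequence = pw$seq)
  wins <- findPrecursorCandidates(g$mature, est, flank = 60L)
  expect_gt(nrow(wins), 0)
  cover <- wins$win_start <= g$mat_start & wins$win_end >= g$mat_end
  expect_true(any(cover))
  ## a single mismatch kills the occurrence
  mm <- g$mature
  substr(mm, 10, 10) <- setdiff(c("A", "C", "G", "U"),
                                substr(mm, 10, 10))[1]
  expect_equal(nrow(findPrecursorCandidates(mm, est, 60L)), 0L)
  ## reverse-complement occurrences surface on the minus strand (the
  ## near-complementary star arm can additionally hit the plus strand)
  est_rc <- data.frame(id = "rc", sequence = revComplement(pw$seq))
  wins_rc <- findPrecursorCandidates(g$mature, est_rc, 60L)
  expect_gt(nrow(wins_rc), 0)
  expect_true(any(wins_rc$strand == "-"))
})

test_that("planted precursors validate; corrupted geometries do not", {
  for (seed in c(41, 42, 43)) {
    pw <- planted_window(seed)
    g <- pw$gene
    st <- foldMinEnergy(pw$seq)
    v <- validateHairpin(st, g$mat_start, g$mat_end)
    expect_true(v$verdict, label = paste("seed", seed))
    expect_equal(v$arm, "5p")
    ## predicted star overlaps the planted star window
    expect_lte(abs(v$star_start - g$star_start), 3)
    ## an interval straddling the terminal loop fails flag (a)
    lo <- g$mat_end - 5L
    vb <- validateHairpin(st, lo, lo + nchar(g$mature) - 1L)
    expect_false(vb$flags[["one_arm"]])
    expect_false(vb$verdict)
  }
  pw <- planted_window(44)
  expect_error(validateHairpin(foldMinEnergy(pw$seq), 5, 5000), "outside")
})

test_that("dinucleotide-shuffled windows fail the stability criterion", {
  set.seed(51)
  pw <- planted_window(52)
  g <- pw$gene
  fails <- 0L
  n_shuf <- 40L
  for (i in seq_len(n_shuf)) {
    sh <- dinuc_shuffle(pw$seq)
    st <- foldMinEnergy(sh)
    v <- validateHairpin(st, g$mat_start, g$mat_end)
    if (!v$verdict) fails <- fails + 1L
  }
  expect_gte(fails / n_shuf, 0.95)
})

test_that("star evidence ranks candidates strictly higher", {
  pw <- planted_window(61)
  g <- pw$gene
  st <- foldMinEnergy(pw$seq)
  v <- validateHairpin(st, g$mat_start, g$mat_end)
  mk <- function(seqs, counts) TagSet(seqs,
      matrix(as.integer(counts), length(seqs), 1,
             dimnames = list(NULL, "LL")))
  with_star <- scoreNovel(pw$seq, g$mat_start, g$mat_end,
                          v$star_start, v$star_end,
                          mk(c(g$mature, g$star), c(50, 5)))
  without <- scoreNovel(pw$seq, g$mat_start, g$mat_end,
                        v$star_start, v$star_end,
                        mk(g$mature, 50))
  expect_gt(with_star$score, without$score)
  expect_equal(with_star$mature, 50)
  expect_equal(with_star$star, 5)
  ## reads scattered over the window drag the score below threshold
  set.seed(62)
  frag <- vapply(seq(1, nchar(pw$seq) - 20, by = 11),
                 function(i) substr(pw$seq, i, i + 19), "")
  uniform <- scoreNovel(pw$seq, g$mat_start, g$mat_end,
                        v$star_start, v$star_end,
                        mk(frag, rep(10, length(frag))))
  expect_lt(uniform$score, without$score)
  ## no mapped reads: score undefined
  none <- scoreNovel(pw$seq, g$mat_start, g$mat_end, v$star_start,
                     v$star_end, mk("GCGCGCAUAUGCGCAUAU", 4))
  expect_true(is.na(none$score))
})
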