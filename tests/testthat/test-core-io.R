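test_that("FASTA records are read, normalised and round-tripped", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">pvu-miR159a.1 159", "UUUGGAUUGAAGGGAGCUCUA",
               ">x1 foo", "tgacagaagagagtgagcac"), f)
  rec <- readSequences(f)
  expect_equal(nrow(rec), 2L)
  expect_equal(nchar(rec$sequence[1]), 21L)
  expect_equal(rec$sequence[2], "UGACAGAAGAGAGUGAGCAC")
  ## round trip
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeSequences(rec, f2)
  expect_equal(readSequences(f2)$sequence, rec$sequence)
  ## DNA alphabet writer option
  writeSequences(rec, f2, alphabet = "DNA")
  expect_true(grepl("T", readLines(f2)[2]))
})

test_that("empty and malformed inputs behave as specified", {
  f <- withr::local_tempfile(fileext = ".fasta")
  file.create(f)
  expect_equal(nrow(readSequences(f)), 0L)
  writeLines(c("no header", "ACGT>"), f)
  expect_error(readSequences(f), "malformed")
  expect_error(normalizeRNA("ACGX"), "non-ACGU")
})

test_that("collapseToTags counts, conserves and orders deterministically", {
  reads <- list(LL = c(rep("UGACAGAAGAGAGUGAGCAC", 3), "AAAACCCCGGGGUUUU"),
                RL = "UGACAGAAGAGAGUGAGCAC")
  ts <- collapseToTags(reads)
  expect_s4_class(ts, "TagSet")
  i <- match("UGACAGAAGAGAGUGAGCAC", tagSequences(ts))
  expect_equal(unname(tagCounts(ts)[i, ]), c(3L, 1L))
  ## per-library conservation
  expect_equal(unname(colSums(tagCounts(ts))), c(4L, 1L))
  ## disjoint read sets: tag count is the sum of distinct counts
  ts2 <- collapseToTags(list(A = c("ACGUACGUACGUACGUA"),
                             B = c("GGGGCCCCAAAAUUUUG", "CCCCGGGGAAAAUUUUC")))
  expect_equal(nrow(ts2), 3L)
  ## deterministic order: descending total then lexicographic
  tot <- tagTotals(ts)
  expect_true(all(diff(tot) <= 0))
  expect_error(collapseToTags(list(c("ACGU"))), "library name")
})

test_that("random collapse conserves per-library totals", {
  set.seed(11)
  pool <- vapply(1:30, function(i) random_rna(sample(16:30, 1)), "")
  reads <- list(LL = sample(pool, 200, TRUE), RL = sample(pool, 120, TRUE),
                SL = sample(pool, 57, TRUE))
  ts <- collapseToTags(reads)
  expect_equal(unname(colSums(tagCounts(ts))), c(200L, 120L, 57L))
  expect_equal(sum(tagTotals(ts)), 377L)
})

test_that("TagSet validity rejects duplicates and bad counts", {
  expect_error(TagSet(c("ACGUACGUACGUACGUA", "ACGUACGUACGUACGUA"),
                      matrix(1L, 2, 1, dimnames = list(NULL, "LL"))),
               "unique")
  expect_error(TagSet("ACGUACGUACGUACGUA",
                      matrix(-1L, 1, 1, dimnames = list(NULL, "LL"))))
})

test_that("report tables round-trip bit-exactly", {
  rows <- data.frame(variant = c("UGAAGCUGCCAGCAUGAUCUA", "ACGUACGU"),
                     class = c("length", "conserved"),
                     LL = c(10L, 0L), FL = c(2L, 5L), total = c(12L, 5L),
                     stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeTable(rows, f)
  expect_identical(readTable(f), rows)
  ## DNA alphabet option converts sequence-like columns
  writeTable(rows, f, alphabet = "DNA")
  expect_equal(readTable(f)$variant[1], "TGAAGCTGCCAGCATGATCTA")
  ## empty row set -> header-only file
  writeTable(rows[0, ], f)
  expect_equal(length(readLines(f)), 1L)
})

test_that("collapsed-tag FASTA dialect round-trips a TagSet", {
  set.seed(3)
  ts <- collapseToTags(list(LL = replicate(20, random_rna(20)),
                            FL = replicate(10, random_rna(21))))
  f <- withr::local_tempfile(fileext = ".fasta")
  writeCollapsedFasta(ts, f)
  expect_true(grepl("^>tag1_x", readLines(f)[1]))
  back <- readCollapsedFasta(f)
  expect_equal(tagSequences(back), tagSequences(ts))
  expect_equal(tagCounts(back), tagCounts(ts))
})

test_that("mature reference sets parse the ID FAMILY dialect", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ath-miR156a 156", "UGACAGAAGAGAGUGAGCAC",
               ">pvu-miR482* 482", "GGAAUGGGCUGAUUGGGAAGCA",
               ">gma-miR166a-5p 166", "GGAAUGUUGUCUGGCUCGAGG"), f)
  refs <- readMatureRefs(f)
  expect_equal(refs$family, c("156", "482", "166"))
  expect_equal(refs$is_star, c(FALSE, TRUE, TRUE))
  ## duplicate sequences force canonicalisation
  writeLines(c(">a 1", "ACGUACGUACGUACGUA", ">b 2", "ACGUACGUACGUACGUA"), f)
  expect_error(readMatureRefs(f), "duplicate")
})

test_that("family labels are extracted from miRNA names", {
  expect_equal(mirFamily(c("gma-miR1510a-3p", "aly-MIR171a*",
                           "pvu-miR159a.1", "ath-miR858")),
               c("1510", "171", "159", "858"))
})
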