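iso_refs <- function() {
  readMatureRefs(data.frame(
    name = c("gma-miR1511", "mtr-miR2199", "mtr-miR171b", "ptc-miR396f"),
    family = c("1511", "2199", "171", "396"),
    sequence = c("AACCAGGCUCUGAUACCAUG", "UGAUACACUAGCACGGAUCAC",
                 "UGAUUGAGCCGCGUCAAUAUC", "UUCCACGGCUUUCUUGAACUG"),
    is_star = FALSE))
}

test_that("abundance prefilter is a strict >10 partition", {
  ts <- TagSet(c("ACGUACGUACGUACGUA", "GGCCGGCCGGCCGGCCA",
                 "AAUUAAUUAAUUAAUUA"),
               matrix(c(6L, 5L, 0L, 5L, 5L, 3L), 3, 2,
                      dimnames = list(NULL, c("LL", "FL"))))
  pf <- prefilterTags(ts)
  expect_equal(tagTotals(pf$pass), 11L)       # 11 passes
  expect_equal(sort(tagTotals(pf$fail)), c(3L, 10L))  # 10 fails (strict)
  expect_equal(nrow(pf$pass) + nrow(pf$fail), nrow(ts))
  empty <- prefilterTags(ts[0, ])
  expect_equal(nrow(empty$pass), 0L)
})

test_that("fuzzy matching reproduces published alignment geometries", {
  refs <- iso_refs()
  ## 1-nt 3' extension: 0 subs, offset3 = +1
  m <- fuzzyMatch("AACCAGGCUCUGAUACCAUGA", refs)
  expect_equal(m$name, "gma-miR1511")
  expect_equal(m$n_subs, 0)
  expect_equal(c(m$offset5, m$offset3), c(0, 1))
  ## single substitution at position 17 (A -> G)
  m2 <- fuzzyMatch("UGAUACACUAGCACGGGUCAC", refs)
  expect_equal(m2$name, "mtr-miR2199")
  expect_equal(m2$n_subs, 1)
  expect_equal(c(m2$offset5, m2$offset3), c(0, 0))
  v <- strsplit("UGAUACACUAGCACGGGUCAC", "")[[1]]
  r <- strsplit("UGAUACACUAGCACGGAUCAC", "")[[1]]
  expect_equal(which(v != r), 17L)
  ## 2-nt shift at equal length: 0 subs, offsets +2/-2
  m3 <- fuzzyMatch("UCUGAUUGAGCCGCGUCAAUA", refs)
  expect_equal(m3$name, "mtr-miR171b")
  expect_equal(m3$n_subs, 0)
  expect_equal(c(m3$offset5, m3$offset3), c(2, -2))
  ## three substitutions needed -> no call
  expect_null(fuzzyMatch("UUCCACGGCUUUCAAGUACUG", refs))
  ## length difference beyond 2 nt -> no call
  expect_null(fuzzyMatch("AACCAGGCUCUGAUACCAUGAAAA", refs))
})

test_that("fuzzy-match ties prefer fewer subs, smaller offsets, larger refs", {
  refs <- readMatureRefs(data.frame(
    name = c("refA", "refB"), family = c("1", "1"),
    sequence = c("UGACAGAAGAGAGUGAGCAC", "UGACAGAAGAGAGUGAGCACAA"),
    is_star = FALSE))
  ## exact prefix of both: refA needs no offset, refB offset3 = -2
  m <- fuzzyMatch("UGACAGAAGAGAGUGAGCAC", refs)
  expect_equal(m$name, "refA")
  ## equal subs and offsets: larger observed total wins
  refs2 <- readMatureRefs(data.frame(
    name = c("refC", "refD"), family = c("1", "1"),
    sequence = c("UGACAGAAGAGAGUGAGCAA", "UGACAGAAGAGAGUGAGCAG"),
    is_star = FALSE))
  m2 <- fuzzyMatch("UGACAGAAGAGAGUGAGCAU", refs2,
                   ref_totals = c(refC = 5, refD = 500))
  expect_equal(m2$name, "refD")
})

test_that("abundance filter applies the inclusive 1.5x rule", {
  calls <- data.frame(name = c("r1", "r1", "r2", "r2", "r3"),
                      total = c(24, 23, 1622, 40, 53573))
  rt <- c(r1 = 16, r2 = 0, r3 = 3581)
  af <- abundanceFilter(calls, rt)
  expect_equal(af$retained, c(TRUE, FALSE, TRUE, FALSE, TRUE))
})

test_that("classification partitions retained calls into three groups", {
  calls <- data.frame(n_subs = c(0L, 1L, 1L, 2L),
                      family = c("482", "393", "894", "398"))
  cl <- classifyVariants(calls, conserved_families = c("482", "393", "398"))
  expect_equal(cl$var_class,
               c("length", "conserved", "non_conserved", "conserved"))
  expect_false(any(is.na(cl$var_class)))
})

test_that("family promotion follows the retained-total threshold", {
  chain <- fixture_isomir_chain()
  expect_equal(chain$promoted, c("1510", "2199", "4376", "479"))
  retained <- chain$calls[chain$calls$retained, ]
  expect_equal(promoteFamilies(retained, fixture_conserved_families(),
                               min_total = Inf), character())
  ## already-conserved families are never promoted
  expect_false(any(chain$promoted %in% fixture_conserved_families()))
})

test_that("the full chain reproduces the published isomiR table", {
  chain <- fixture_isomir_chain()
  calls <- chain$calls
  expect_equal(nrow(calls), 26L)
  expect_equal(sum(calls$retained), 26L)
  got <- table(calls$var_class[calls$retained])
  expect_equal(unname(got[c("length", "non_conserved", "conserved")]),
               c(7L, 9L, 10L), ignore_attr = TRUE)
  ## printed group membership matches row by row
  expect_equal(calls$var_class, chain$printed_group)
  ## retained variants are disjoint from the reference sequences
  t5 <- mirbeanFixture("isomir")
  expect_length(intersect(calls$variant,
                          t5$sequence[t5$role == "reference"]), 0)
})
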