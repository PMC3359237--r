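test_that("perfect-complement hybrids hit the closed-form energy", {
  dp <- duplexParams()
  m <- "UUCCACAGCUUUCUUGAACUG"
  h <- duplexMFE(m, revComplement(m))
  b <- mirbean:::encodeBases(m)
  rc <- rev(mirbean:::encodeBases(revComplement(m)))
  pc <- mirbean:::pairCode(b, rc)
  expect_equal(h@mfe, sum(dp$stack[cbind(pc[-length(pc)], pc[-1])]),
               tolerance = 1e-9)
  expect_equal(h@diagram, strrep("|", nchar(m)))
  expect_equal(c(h@siteStart, h@siteEnd), c(1L, nchar(m)))
  expect_error(duplexMFE("", "ACGU"), "empty")
})

test_that("a central substitution strictly weakens the hybrid", {
  set.seed(71)
  for (i in 1:10) {
    m <- random_rna(21)
    w <- revComplement(m)
    w2 <- w
    p <- 11L
    ## replacement must neither WC-pair nor wobble-pair the miRNA base
    wob <- c(A = "", C = "", G = "U", U = "G")[substr(m, 11, 11)]
    substr(w2, p, p) <- setdiff(c("A", "C", "G", "U"),
                                c(substr(w, p, p), wob))[1]
    expect_gt(duplexMFE(m, w2)@mfe, duplexMFE(m, w)@mfe)
  }
})

test_that("duplex DP agrees with the exhaustive oracle (spot check)", {
  set.seed(72)
  for (i in 1:30) {
    m <- random_rna(sample(6:12, 1))
    w <- random_rna(sample(6:12, 1))
    o <- oracle_duplex_mfe(m, w)
    d <- duplexMFE(m, w)@mfe
    if (is.infinite(o)) expect_true(is.infinite(d))
    else expect_equal(d, o, tolerance = 1e-6, label = paste(m, w))
  }
})

test_that("the perfect complement is the optimal same-length window", {
  set.seed(73)
  for (i in 1:20) {
    m <- random_rna(sample(18:22, 1))
    perfect <- duplexMFE(m, revComplement(m))@mfe
    expect_lte(perfect, duplexMFE(m, random_rna(nchar(m)))@mfe)
  }
})

test_that("diagram symbols are consistent with the energy decomposition", {
  set.seed(74)
  dp <- duplexParams()
  for (i in 1:15) {
    m <- random_rna(12)
    w <- random_rna(16)
    h <- duplexMFE(m, w)
    if (!is.finite(h@mfe)) next
    sym <- table(factor(strsplit(h@diagram, "")[[1]],
                        levels = c("|", "x", "*", "-")))
    res <- mirbean:::c_duplex(mirbean:::encodeBases(m),
                              rev(mirbean:::encodeBases(w)), dp$stack,
                              dp$mismatch, dp$bulge_open, dp$bulge_ext,
                              dp$dangle, dp$max_bulge, dp$max_mismatch_run)
    expect_equal(unname(sym[["x"]]), res$n_wobble)
    expect_equal(unname(sym[["*"]]), res$n_mismatch)
    expect_equal(unname(sym[["-"]]), res$n_bulge)
    expect_equal(unname(sym[["|"]]) + unname(sym[["x"]]), res$n_pairs)
  }
})

test_that("planted sites are called; wobbled sites show x and still pass", {
  set.seed(75)
  m <- "UGACAGAAGAGAGUGAGCAC"
  site <- revComplement(m)
  ## two G:U wobbles on the target side (C->U opposite G keeps a pair)
  sc <- strsplit(site, "")[[1]]
  cpos <- which(sc == "C")[1:2]
  sc[cpos] <- "U"
  wob_site <- paste(sc, collapse = "")
  est <- data.frame(
    id = c("perfect", "wobbled"),
    sequence = c(paste0(random_rna(40), site, random_rna(40)),
                 paste0(random_rna(40), wob_site, random_rna(40))))
  calls <- scanTargets(c(mir = m), est, threshold_ratio = 0.7)
  expect_setequal(calls$target_id, c("perfect", "wobbled"))
  wrow <- calls[calls$target_id == "wobbled", ]
  expect_true(grepl("x", wrow$diagram))
  expect_equal(calls[calls$target_id == "perfect", "site_start"], 41L)
  expect_equal(calls[calls$target_id == "perfect", "site_end"], 60L)
})

test_that("shuffled ESTs pass the default threshold in under 1% of scans", {
  set.seed(76)
  mirnas <- setNames(vapply(1:3, function(i) random_rna(21), ""),
                     paste0("m", 1:3))
  est <- data.frame(id = paste0("e", 1:40),
                    sequence = vapply(1:40, function(i)
                      random_rna(250), ""))
  calls <- scanTargets(mirnas, est, threshold_ratio = 0.7)
  n_pass <- if (is.null(calls)) 0L else nrow(calls)
  expect_lt(n_pass / (3 * 40), 0.01)
})

test_that("TAS3 scan requires two non-overlapping sites", {
  set.seed(77)
  m390 <- "AAGCUCAGGAGGGAUAGCGCC"
  site <- revComplement(m390)
  dual <- paste0(random_rna(30), site, random_rna(129), site,
                 random_rna(30))
  single <- paste0(random_rna(30), site, random_rna(150))
  est <- data.frame(id = c("dual", "single"),
                    sequence = c(dual, single))
  hits <- scanTAS3(m390, est)
  expect_equal(hits$target_id, "dual")
  expect_equal(hits$site1_start, 31L)
  expect_equal(hits$spacing, 130L)
  ## the two reported sites never overlap
  expect_true(hits$site2_start > hits$site1_end)
})
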