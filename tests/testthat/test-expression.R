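test_that("family pooling sums matures and excludes stars", {
  kept <- conservationFilter(fixture_hits_all())$kept
  k <- poolFamilies(kept, libraries = c("LL", "FL", "RL", "SL"))
  ## miR157: two printed rows, LL = 3114 + 361
  expect_equal(unname(k["157", "LL"]), 3475L)
  ## single-member family equals its member counts
  expect_equal(unname(k["1511", ]), c(978L, 625L, 449L, 1529L))
  ## stars excluded: miR166 row is the sum of the mature rows only
  t2 <- mirbeanFixture("mature")
  expect_equal(unname(k["166", "LL"]),
               sum(t2$LL[t2$family == 166]))
  expect_equal(nrow(k), 29L)
})

test_that("size factors match the hand-computed toy and equivariance", {
  toy <- matrix(c(2, 4, 6, 8, 16, 24), 3, 2,
                dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(medianRatioSizeFactors(toy)), c(0.5, 2))
  ## identical columns -> unit factors
  same <- cbind(a = c(5, 50, 500), b = c(5, 50, 500))
  expect_equal(unname(medianRatioSizeFactors(same)), c(1, 1))
  ## a duplicated-then-doubled column gets exactly twice the factor
  set.seed(81)
  k <- matrix(rpois(40, 50) + 1, 10, 4)
  kd <- cbind(k, 2L * k[, 2])
  sd_ <- medianRatioSizeFactors(kd)
  expect_equal(unname(sd_[5] / sd_[2]), 2, tolerance = 1e-12)
  ## scale equivariance of relative factors (factors are defined up to
  ## the geometric-mean reference): scaling a column by c scales its
  ## factor relative to any other column by c
  for (i in 1:5) {
    k <- matrix(rpois(40, 50) + 1, 10, 4)
    s1 <- medianRatioSizeFactors(k)
    k2 <- k; k2[, 3] <- k2[, 3] * 7
    s2 <- medianRatioSizeFactors(k2)
    expect_equal(unname(s2[3] / s2[1]), unname(7 * s1[3] / s1[1]),
                 tolerance = 1e-12)
  }
  expect_error(medianRatioSizeFactors(matrix(c(0, 1, 1, 0), 2, 2)),
               "size factors undefined")
})

test_that("size factors agree with the DESeq reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(82)
  k <- matrix(rnbinom(200, mu = 100, size = 2) + 1L, 50, 4)
  expect_equal(unname(medianRatioSizeFactors(k)),
               unname(DESeq2::estimateSizeFactorsForMatrix(k)),
               tolerance = 1e-8)
})

test_that("the VST has the stated analytic limits and monotonicity", {
  k <- matrix(c(0, 1, 4, 9, 16, 25), 3, 2,
              dimnames = list(NULL, c("a", "b")))
  v0 <- varianceStabilize(k, sf = c(1, 1), alpha = 0)
  expect_equal(v0$t, 2 * sqrt(k), ignore_attr = TRUE)
  ## strictly increasing in the counts at fixed size factors
  v1 <- varianceStabilize(matrix(0:20, 21, 1,
                                 dimnames = list(NULL, "a")),
                          sf = 1, alpha = 0.3)
  expect_true(all(diff(v1$t[, 1]) > 0))
  ## row relabeling leaves the transform unchanged
  set.seed(83)
  k2 <- matrix(rnbinom(120, mu = 80, size = 4) + 1L, 30, 4,
               dimnames = list(paste0("f", 1:30), paste0("o", 1:4)))
  p <- sample(30)
  va <- varianceStabilize(k2)
  vb <- varianceStabilize(k2[p, ])
  expect_equal(vb$t[rownames(k2), ], va$t, tolerance = 1e-9)
})

test_that("the VST flattens the NB variance-mean relationship", {
  set.seed(84)
  n <- 500
  mu <- exp(runif(n, log(10), log(5000)))
  k <- sapply(1:4, function(j) rnbinom(n, mu = mu, size = 1 / 0.1))
  v <- varianceStabilize(k, sf = rep(1, 4))
  rm_ <- rowMeans(v$t)
  rv <- apply(v$t, 1, var)
  slope <- unname(coef(lm(rv ~ rm_))[2])
  expect_lt(abs(slope), 0.1)
  ## the dispersion estimate recovers the simulated order of magnitude
  expect_gt(v$alpha, 0.05)
  expect_lt(v$alpha, 0.2)
})

test_that("clustering is deterministic and permutation-invariant", {
  set.seed(85)
  t <- matrix(rnorm(80), 20, 4,
              dimnames = list(paste0("f", 1:20), c("LL", "RL", "SL", "FL")))
  cl <- clusterExpression(t)
  ## row permutation: identical organ dendrogram
  p <- sample(20)
  cl2 <- clusterExpression(t[p, ])
  expect_equal(cl2$organ_newick, cl$organ_newick)
  expect_equal(sort(cl2$family_order), sort(cl$family_order))
  ## duplicated organ column merges first at height 0
  t3 <- cbind(t, LL2 = t[, "LL"])
  cl3 <- clusterExpression(t3)
  expect_equal(min(cl3$organ_hclust$height), 0)
  expect_equal(sort(firstMergePartners(cl3$organ_hclust, "LL")), "LL2")
  expect_error(clusterExpression(t[, 1, drop = FALSE]), "at least 2")
})

test_that("organs simulated from shared profiles cluster as sisters", {
  set.seed(86)
  prof1 <- exp(runif(40, log(20), log(2000)))
  prof2 <- exp(runif(40, log(20), log(2000)))
  k <- cbind(A1 = rnbinom(40, mu = prof1, size = 8),
             A2 = rnbinom(40, mu = prof1, size = 8),
             B1 = rnbinom(40, mu = prof2, size = 8),
             B2 = rnbinom(40, mu = prof2, size = 8)) + 1L
  v <- varianceStabilize(k)
  cl <- clusterExpression(v$t)
  expect_setequal(firstMergePartners(cl$organ_hclust, "A1"), "A2")
  expect_setequal(firstMergePartners(cl$organ_hclust, "B1"), "B2")
})
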