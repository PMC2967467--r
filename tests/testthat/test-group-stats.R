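# Group statistics: per-level t tests, the cluster-based permutation
# test, and the regional difference map.

test_that("per-level pooled t statistics match hand and t.test values", {
  out <- levelTstats(matrix(c(1, 2, 3)), matrix(c(4, 5, 6)))
  # pooled SD 1, SE sqrt(2/3): t = -3/0.8165 = -3.674
  expect_equal(out$t, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(out$df, 4)
  set.seed(10)
  g1 <- matrix(rnorm(24), 6)
  g2 <- matrix(rnorm(20, mean = 0.4), 5)
  out <- levelTstats(g1, g2)
  for (l in 1:4) {
    tt <- stats::t.test(g1[, l], g2[, l], var.equal = TRUE)
    expect_equal(out$t[l], unname(tt$statistic), tolerance = 1e-10)
  }
  # identical samples -> t == 0 everywhere
  expect_equal(levelTstats(g1, g1)$t, rep(0, 4))
  # swapping the groups flips every sign
  expect_equal(levelTstats(g2, g1)$t, -out$t)
  # constant data -> zero with a warning
  expect_warning(z <- levelTstats(matrix(1, 3, 1), matrix(1, 3, 1)),
                 "zero")
  expect_equal(z$t, 0)
  # Welch option agrees with t.test(var.equal = FALSE)
  w <- levelTstats(g1, g2, welch = TRUE)
  ttw <- stats::t.test(g1[, 2], g2[, 2])
  expect_equal(w$t[2], unname(ttw$statistic), tolerance = 1e-10)
  expect_equal(w$df[2], unname(ttw$parameter), tolerance = 1e-6)
})

test_that("cluster test flags a strong uniform shift with minimal p", {
  withr::with_seed(2, {
    g1 <- matrix(rnorm(8 * 6), 8)
    g2 <- matrix(rnorm(8 * 6, mean = 3), 8)  # 3 SD shift at every level
  })
  res <- clusterPermutationTest(g1, g2, nPermutations = 500, seed = 1,
                                exact = "never")
  expect_s3_class(res, "slClusterTest")
  expect_equal(nrow(res$clusters), 1L)
  expect_equal(res$clusters$start, 1L)
  expect_equal(res$clusters$end, 6L)
  expect_equal(res$clusters$sign, -1L)
  expect_equal(res$pValue, 1 / 501)
  # p can never undercut the add-one floor
  expect_gte(res$pValue, 1 / (res$nPermutations + 1))
})

test_that("cluster test returns p = 1 when nothing is supra-threshold", {
  withr::with_seed(3, {
    g1 <- matrix(rnorm(6 * 5), 6)
  })
  g2 <- g1[c(4, 6, 2, 1, 5, 3), ]  # same sample: t = 0 at every level
  res <- clusterPermutationTest(g1, g2, nPermutations = 200, seed = 2,
                                exact = "never")
  expect_equal(nrow(res$clusters), 0L)
  expect_equal(res$pValue, 1)
})

test_that("cluster test is deterministic and validates its inputs", {
  withr::with_seed(4, {
    g1 <- matrix(rnorm(5 * 4), 5)
    g2 <- matrix(rnorm(5 * 4, mean = 1), 5)
  })
  a <- clusterPermutationTest(g1, g2, nPermutations = 300, seed = 9,
                              exact = "never")
  b <- clusterPermutationTest(g1, g2, nPermutations = 300, seed = 9,
                              exact = "never")
  expect_identical(a$pValue, b$pValue)
  expect_identical(a$clusters, b$clusters)
  expect_error(clusterPermutationTest(g1[1, , drop = FALSE], g2),
               "at least 2")
  expect_warning(clusterPermutationTest(g1, g2, nPermutations = 50,
                                        seed = 1, exact = "never"),
                 "coarse")
})

test_that("Monte-Carlo permutation p agrees with exhaustive enumeration", {
  withr::with_seed(5, {
    g1 <- matrix(rnorm(4 * 5, mean = 0.9), 4)
    g2 <- matrix(rnorm(4 * 5), 4)
  })
  ex <- clusterPermutationTest(g1, g2, exact = "always")
  expect_true(ex$exhaustive)
  expect_equal(ex$nPermutations, choose(8, 4))
  mc <- clusterPermutationTest(g1, g2, nPermutations = 4000, seed = 31,
                               exact = "never")
  se <- sqrt(ex$pValue * (1 - ex$pValue) / 4000)
  expect_lt(abs(mc$pValue - ex$pValue), 3 * se + 1 / 4001)
  # the identity repartition is part of the exhaustive null, so p > 0
  expect_gte(ex$pValue, 1 / choose(8, 4))
})

test_that("label swap leaves the cluster permutation p invariant", {
  withr::with_seed(6, {
    g1 <- matrix(rnorm(5 * 6, mean = 0.8), 5)
    g2 <- matrix(rnorm(5 * 6), 5)
  })
  a <- clusterPermutationTest(g1, g2, exact = "always")
  b <- clusterPermutationTest(g2, g1, exact = "always")
  expect_equal(a$pValue, b$pValue)
  expect_equal(a$maxStat, b$maxStat)
})

test_that("regional difference map recovers a planted block effect", {
  n <- 16
  shift <- matrix(0, n, n)
  shift[1:5, 1:5] <- 0.08  # planted increase within a block
  g1 <- lapply(1:6, function(s) randomSyncMatrix(n, 700 + s,
                                                 shift = shift))
  g2 <- lapply(1:6, function(s) randomSyncMatrix(n, 800 + s))
  map <- regionalDifferenceMap(g1, g2, alpha = 0.05)
  expect_s3_class(map, "slRegionalMap")
  expect_identical(map$signs, t(map$signs))
  expect_equal(unname(diag(map$signs)), rep(0L, n))
  inBlock <- map$signs[1:5, 1:5][upper.tri(matrix(0, 5, 5))]
  outBlock <- map$signs[6:n, 6:n][upper.tri(matrix(0, n - 5, n - 5))]
  expect_gt(mean(inBlock == 1L), 0.5)
  expect_lt(mean(outBlock != 0L), 0.2)
  # mismatched labels are rejected
  g3 <- randomSyncMatrix(n, 1)
  g3@values <- unname(g3@values)
  dimnames(g3@values) <- list(paste0("X", 1:n), paste0("X", 1:n))
  expect_error(regionalDifferenceMap(g1, c(g2[-1], g3)), "labels")
})

test_that("null regional maps flag about alpha of the pairs", {
  hits <- 0L
  total <- 0L
  for (rep in 1:8) {
    g1 <- lapply(1:6, function(s) randomSyncMatrix(20, 3000 + 10 * rep + s))
    g2 <- lapply(1:6, function(s) randomSyncMatrix(20, 6000 + 10 * rep + s))
    map <- regionalDifferenceMap(g1, g2, alpha = 0.05)
    up <- upper.tri(map$signs)
    hits <- hits + sum(map$signs[up] != 0L)
    total <- total + sum(up)
  }
  frac <- hits / total  # 1520 pair tests in total
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
})

test_that("block summary aggregates signed pairs by lobe blocks", {
  reg <- subsetRegistry(aalRegistry(),
                        c(frontal = 3, "parieto-occipital" = 3))
  mats <- lapply(1:4, function(s) {
    m <- randomSyncMatrix(6, 900 + s)
    syncMatrix(syncValues(m), labels = reg$region)
  })
  map <- regionalDifferenceMap(mats[1:2], mats[3:4], alpha = 0.05)
  # force a known sign pattern
  map$signs[] <- 0L
  map$signs[1, 2] <- map$signs[2, 1] <- 1L   # frontal-frontal
  map$signs[1, 4] <- map$signs[4, 1] <- -1L  # frontal-posterior
  bs <- blockSummary(map, reg)
  ff <- bs[bs$block1 == "frontal" & bs$block2 == "frontal", ]
  fp <- bs[bs$block1 == "frontal" & bs$block2 == "parieto-occipital", ]
  pp <- bs[bs$block1 == "parieto-occipital" &
             bs$block2 == "parieto-occipital", ]
  expect_equal(ff$nPos, 1L)
  expect_equal(ff$nNeg, 0L)
  expect_equal(fp$nNeg, 1L)
  expect_equal(fp$nPairs, 9L)
  expect_equal(pp$nPos + pp$nNeg, 0L)
  # zero map -> zero counts everywhere
  map$signs[] <- 0L
  bs0 <- blockSummary(map, reg)
  expect_true(all(bs0$nPos == 0L & bs0$nNeg == 0L))
  # registry must cover the map
  expect_error(blockSummary(map, reg[-1, ]), "missing")
})
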