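# Graph construction, small-world descriptors, rewired surrogates and
# theoretical references.

test_that("threshold binarization uses strict exceedance", {
  v <- matrix(0.02, 6, 6)
  v[2, 5] <- v[5, 2] <- 0.06
  sm <- syncMatrix(v)
  g <- graphFromThreshold(sm, 0.05)
  expect_equal(numEdges(g), 1L)
  expect_equal(edgeMatrix(g), cbind(2L, 5L), ignore_attr = TRUE)
  # threshold at the maximum -> empty (strict ">")
  expect_equal(numEdges(graphFromThreshold(sm, 0.06)), 0L)
  # just below the minimum -> complete
  expect_equal(numEdges(graphFromThreshold(sm, 0.01)), 15L)
  expect_error(graphFromThreshold(sm, 1.2))
})

test_that("raising the threshold never adds edges", {
  sm <- randomSyncMatrix(20, seed = 4, base = 0.3, sd = 0.15)
  counts <- vapply(seq(0.05, 0.6, by = 0.05),
                   function(T) numEdges(graphFromThreshold(sm, T)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("fixed-K binarization keeps the strongest edges deterministically", {
  sm <- randomSyncMatrix(116, seed = 8, base = 0.4, sd = 0.1)
  g <- suppressWarnings(graphFromDegree(sm, 10))
  expect_equal(numEdges(g), 580L)  # round(116 * 10 / 2)
  # oracle: full sort of the upper triangle
  v <- syncValues(sm)
  ut <- which(upper.tri(v), arr.ind = TRUE)
  keep <- ut[order(-v[ut]), , drop = FALSE][1:580, ]
  keep <- keep[order(keep[, 1], keep[, 2]), ]
  expect_equal(edgeMatrix(g), keep, ignore_attr = TRUE)
  # equal edge counts regardless of mean SL level
  smLow <- syncMatrix(syncValues(sm) * 0.5)
  expect_equal(numEdges(suppressWarnings(graphFromDegree(smLow, 10))),
               580L)
  expect_error(graphFromDegree(sm, 116), "smaller than N")
  expect_warning(graphFromDegree(sm, 3), "ln\\(N\\)")
})

test_that("tied synchronization values break deterministically", {
  v <- matrix(0.5, 8, 8)  # all off-diagonal entries tie
  sm <- syncMatrix(v)
  g1 <- suppressWarnings(graphFromDegree(sm, 4))
  g2 <- suppressWarnings(graphFromDegree(sm, 4))
  expect_identical(edgeMatrix(g1), edgeMatrix(g2))
  expect_equal(numEdges(g1), 16L)
  # lexicographically first pairs win
  expect_equal(g1@edges[1, ], c(1L, 2L), ignore_attr = TRUE)
})

test_that("clustering coefficient matches exhaustive triangle counting", {
  expect_equal(clusteringCoefficient(
    binaryGraph(4, t(combn(4, 2))))$global, 1)  # complete K4
  star <- binaryGraph(6, cbind(1L, 2:6))
  expect_equal(clusteringCoefficient(star)$global, 0)
  # triangle {1,2,3} with pendant 4-1: C = (1/3 + 1 + 1 + 0)/4 = 7/12
  tri <- binaryGraph(4, rbind(c(1, 2), c(1, 3), c(2, 3), c(1, 4)))
  cc <- clusteringCoefficient(tri)
  expect_equal(cc$global, 7 / 12)
  expect_equal(cc$local, c(1 / 3, 1, 1, 0))
  for (s in 1:10) {
    g <- randomGraph(10, sample(6:20, 1), seed = 300 + s)
    expect_equal(clusteringCoefficient(g)$global, bruteClustering(g),
                 tolerance = 1e-12)
  }
})

test_that("harmonic path length matches Floyd-Warshall", {
  expect_equal(harmonicPathLength(binaryGraph(4, t(combn(4, 2)))), 1)
  path3 <- binaryGraph(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(harmonicPathLength(path3), 1.2)  # 3 / (1 + 1 + 1/2)
  # triangle plus isolated vertex: 6 pairs, three at d=1, three
  # disconnected contributing zero
  triIso <- binaryGraph(4, rbind(c(1, 2), c(1, 3), c(2, 3)))
  expect_equal(harmonicPathLength(triIso), 2)
  expect_identical(harmonicPathLength(binaryGraph(5)), Inf)
  for (s in 1:10) {
    g <- randomGraph(11, sample(5:25, 1), seed = 400 + s)
    expect_equal(harmonicPathLength(g), floydHarmonicL(g),
                 tolerance = 1e-12)
  }
})

test_that("rewired surrogates preserve the exact degree sequence", {
  for (s in 1:8) {
    g <- randomGraph(30, 60, seed = 600 + s)
    sg <- rewireSurrogate(g, seed = s)
    expect_identical(degreeSequence(sg), degreeSequence(g))
    expect_identical(numEdges(sg), numEdges(g))
    expect_true(validObject(sg))  # simple graph invariants hold
  }
  # star graph admits no valid swap
  star <- binaryGraph(6, cbind(1L, 2:6))
  expect_identical(edgeMatrix(rewireSurrogate(star, 3)),
                   edgeMatrix(star))
  # seeded reproducibility
  g <- randomGraph(30, 60, seed = 1)
  expect_identical(edgeMatrix(rewireSurrogate(g, 7)),
                   edgeMatrix(rewireSurrogate(g, 7)))
  expect_error(rewireSurrogate(binaryGraph(4, rbind(c(1, 2))), 1),
               "at least 2")
})

test_that("surrogate correction normalizes a random graph to ~1", {
  g <- randomGraph(116, 580, seed = 12)
  cm <- correctedMetrics(g, nSurrogates = 50, seed = 2)
  expect_lt(abs(cm$gamma - 1), 0.25)
  expect_lt(abs(cm$lambda - 1), 0.05)
  expect_equal(cm$gamma, cm$C / cm$C_s)
  expect_equal(cm$lambda, cm$L / cm$L_s)
})

test_that("the ring lattice is strongly small-world ordered", {
  cm <- correctedMetrics(ringLattice(116, 10), nSurrogates = 20, seed = 5)
  expect_gt(cm$gamma, 3)
  expect_gt(cm$lambda, 1.2)
})

test_that("theoretical reference formulas are exact", {
  ref <- theoreticalReferences(116, 10)
  expect_identical(unname(ref["C_ordered"]), 3 / 4)
  expect_identical(unname(ref["L_ordered"]), 116 / 20)
  expect_identical(unname(ref["C_random"]), 10 / 116)
  expect_identical(unname(ref["L_random"]), log(116) / log(10))
  expect_error(theoreticalReferences(116, 1), "exceed 1")
})

test_that("cohortMetrics sweeps levels and reshapes by group", {
  mats <- list(a = randomSyncMatrix(20, 1, base = 0.4, sd = 0.1),
               b = randomSyncMatrix(20, 2, base = 0.4, sd = 0.1),
               c = randomSyncMatrix(20, 3, base = 0.4, sd = 0.1),
               d = randomSyncMatrix(20, 4, base = 0.4, sd = 0.1))
  groups <- c("control", "control", "patient", "patient")
  met <- cohortMetrics(mats, groups, mode = "K", levels = c(4, 6),
                       nSurrogates = 5, seed = 3)
  expect_equal(nrow(met), 8L)
  expect_equal(sort(unique(met$level)), c(4, 6))
  expect_true(all(met$gamma == met$C / met$C_s))
  # identical seeds reproduce the table bit-exactly
  expect_identical(met, cohortMetrics(mats, groups, mode = "K",
                                      levels = c(4, 6), nSurrogates = 5,
                                      seed = 3))
  byLvl <- metricByLevel(met, "lambda")
  expect_named(byLvl, c("control", "patient"))
  expect_equal(dim(byLvl$control), c(2L, 2L))
  expect_equal(byLvl$patient["c", "4"],
               met$lambda[met$subject_id == "c" & met$level == 4])
})
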