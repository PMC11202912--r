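test_that("classical indices reproduce the worked-example cells", {
  expect_equal(scoreCN(toy, "1", "2"), 2)
  expect_equal(scoreCN(toy, "2", "3"), 1)
  expect_equal(scoreJC(toy, "1", "2"), 0.5)
  expect_equal(scoreJC(toy, "4", "7"), 0.4)
  expect_equal(scorePA(toy, "4", "7"), 10)
  expect_equal(scorePA(toy, "1", "2"), 9)
  expect_equal(scoreRA(toy, "1", "2"), 0.7)
  expect_equal(scoreRA(toy, "2", "3"), 0.2)
  expect_equal(scoreAA(toy, "4", "7"), 2 / log(3))
  expect_equal(scoreAA(toy, "2", "6"), 1 / log(5) + 1 / log(4))
})

test_that("degenerate pairs score 0 or 1 as their definitions require", {
  g <- linkGraph(cbind(c("a", "b"), c("c", "c")),
                 nodes = c("a", "b", "c", "i", "j"))
  expect_equal(scoreCN(g, "i", "j"), 0)       # disjoint (empty) neighborhoods
  expect_equal(scoreRA(g, "i", "j"), 0)
  expect_equal(scoreAA(g, "i", "j"), 0)
  expect_equal(scorePA(g, "a", "i"), 0)       # isolated endpoint
  expect_equal(scoreJC(g, "i", "j"), 0)       # empty union, by convention
  expect_equal(scoreJC(g, "a", "b"), 1)       # degree-1 nodes sharing their neighbor
})

test_that("adjacent pairs are rejected unless overridden", {
  expect_error(scoreCN(toy, "1", "4"), "adjacent")
  expect_error(scoreSAC(toy, "1", "4", sacContext(toy, "degree")), "adjacent")
  expect_silent(v <- scoreCN(toy, "1", "4", allowAdjacent = TRUE))
  expect_equal(v, 0)  # neighborhoods of the adjacent pair (1,4) are disjoint
  expect_equal(scoreCN(toy, "4", "5", allowAdjacent = TRUE), 2)  # {2, 6}
  expect_error(scoreCN(toy, "4", "4"), "itself")
})

test_that("CCPA blends CN with N over distance and degrades to CN at alpha 1", {
  expect_equal(scoreCCPA(toy, "1", "2", alpha = 0.8), 2.4)
  expect_equal(scoreCCPA(toy, "2", "6", alpha = 0.8), 2.4)
  gdisc <- linkGraph(cbind(c("a", "c"), c("b", "d")))
  expect_equal(scoreCCPA(gdisc, "a", "c", alpha = 0.8), 0)  # infinite distance
  pairs <- nonAdjacentPairs(toy)
  for (i in seq_len(nrow(pairs)))
    expect_equal(scoreCCPA(toy, pairs$u[i], pairs$v[i], alpha = 1),
                 scoreCN(toy, pairs$u[i], pairs$v[i]))
  expect_error(scoreCCPA(toy, "1", "2", alpha = 1.2), "alpha")
})

test_that("KNLP is the eigenvector sum over the guarded clustering sum", {
  path3 <- linkGraph(cbind(c("a", "b"), c("b", "c")))
  cs <- methods::new("CentralityVector", kind = "eigenvector",
                     scores = c(a = 0.5, b = 0.1, c = 0.5),
                     convention = list())
  cc0 <- methods::new("CentralityVector", kind = "clustering",
                      scores = c(a = 0, b = 0, c = 0), convention = list())
  expect_equal(scoreKNLP(path3, "a", "c", cs, cc0), 1 / 1e-6)
  cc5 <- methods::new("CentralityVector", kind = "clustering",
                      scores = c(a = 0.5, b = 0, c = 0.5), convention = list())
  cs2 <- methods::new("CentralityVector", kind = "eigenvector",
                      scores = c(a = 0.3, b = 0.1, c = 0.2),
                      convention = list())
  expect_equal(scoreKNLP(path3, "a", "c", cs2, cc5), 0.5 / (1 + 1e-6))
  expect_error(scoreKNLP(path3, "a", "c", cc5, cc5), "eigenvector")
  expect_error(scoreKNLP(path3, "a", "c", epsilon = 0), "positive")
})

test_that("SAC counts common neighbors at or above the average centrality", {
  ctxD <- sacContext(toy, "degree")
  expect_equal(scoreSAC(toy, "1", "2", ctxD), 1)
  expect_equal(scoreSAC(toy, "4", "7", ctxD), 2)  # both sit exactly at the mean
  ctxCC <- sacContext(toy, "clustering")
  expect_equal(scoreSAC(toy, "2", "6", ctxCC), 1)
  expect_error(scoreSAC(toy, "1", "2", "degree"), "SACContext")
  # mismatched kind pairing is rejected at construction
  expect_error(methods::new(
    "SACContext", centrality = degreeCentrality(toy),
    average = averageCentrality(clusteringCoefficient(toy))), "kinds differ")
})

test_that("every measure is symmetric in its pair", {
  set.seed(42)
  cases <- 0L
  for (seed in 1:25) {
    g <- random_graph(seed)
    pairs <- nonAdjacentPairs(g)
    if (nrow(pairs) == 0L) next
    take <- pairs[sample(nrow(pairs), min(4L, nrow(pairs))), ]
    cs <- eigenvectorCentrality(g)
    cc <- clusteringCoefficient(g)
    ctxs <- lapply(stats::setNames(nm = c("degree", "betweenness",
                                          "closeness", "clustering")),
                   function(k) sacContext(g, k))
    for (i in seq_len(nrow(take))) {
      u <- take$u[i]; v <- take$v[i]
      for (f in list(scoreCN, scoreJC, scorePA, scoreRA, scoreAA))
        expect_identical(f(g, u, v), f(g, v, u))
      expect_identical(scoreCCPA(g, u, v), scoreCCPA(g, v, u))
      expect_identical(scoreKNLP(g, u, v, cs, cc),
                       scoreKNLP(g, v, u, cs, cc))
      for (ctx in ctxs)
        expect_identical(scoreSAC(g, u, v, ctx), scoreSAC(g, v, u, ctx))
      cases <- cases + 1L
    }
  }
  expect_gte(cases, 90L)
})

test_that("SAC is dominated by CN for every centrality kind", {
  for (seed in 1:100) {
    g <- random_graph(seed)
    pairs <- nonAdjacentPairs(g)
    if (nrow(pairs) == 0L) next
    cn <- rankPairs(g, "cn", pairs = pairs)
    key <- paste(cn$u, cn$v)
    for (ms in c("sac_d", "sac_b", "sac_c", "sac_cc")) {
      sac <- rankPairs(g, ms, pairs = pairs)
      expect_true(all(sac$score >= 0))
      expect_true(all(sac$score <= cn$score[match(paste(sac$u, sac$v), key)]))
    }
  }
})

test_that("SAC with degree reduces to CN on degree-regular graphs", {
  n <- 9
  cyc <- linkGraph(cbind(as.character(1:n), as.character(c(2:n, 1))))
  cn <- rankPairs(cyc, "cn")
  sac <- rankPairs(cyc, "sac_d")
  expect_identical(sac, cn)
})

test_that("SAC_D is bit-identical under degree denominators N and N-1", {
  for (seed in c(1:20, 777)) {
    g <- if (seed == 777) toy else random_graph(seed)
    a <- rankPairs(g, "sac_d", denominator = "N")
    b <- rankPairs(g, "sac_d", denominator = "N-1")
    expect_identical(a, b)
  }
})

test_that("RA and AA respect their CN-derived bounds", {
  for (seed in 1:50) {
    g <- random_graph(seed)
    pairs <- nonAdjacentPairs(g)
    if (nrow(pairs) == 0L) next
    cn <- rankPairs(g, "cn", pairs = pairs)$score
    expect_true(all(rankPairs(g, "ra", pairs = pairs)$score <= cn / 2 + 1e-12))
    maxd <- max(lengths(oracle_adj(g)))
    if (maxd < numNodes(g) && maxd >= 2)
      expect_true(all(rankPairs(g, "aa", pairs = pairs)$score >=
                        cn / log(numNodes(g)) - 1e-12))
  }
})

test_that("bulk scoring agrees with the per-pair scorers", {
  for (seed in 1:20) {
    g <- random_graph(seed)
    pairs <- nonAdjacentPairs(g)
    if (nrow(pairs) == 0L) next
    cs <- eigenvectorCentrality(g)
    cc <- clusteringCoefficient(g)
    ctxs <- lapply(stats::setNames(nm = c("degree", "betweenness",
                                          "closeness", "clustering")),
                   function(k) sacContext(g, k))
    perPair <- function(ms, u, v) switch(ms,
      cn = scoreCN(g, u, v), jc = scoreJC(g, u, v), pa = scorePA(g, u, v),
      ra = scoreRA(g, u, v), aa = scoreAA(g, u, v),
      ccpa = scoreCCPA(g, u, v), knlp = scoreKNLP(g, u, v, cs, cc),
      sac_d = scoreSAC(g, u, v, ctxs$degree),
      sac_b = scoreSAC(g, u, v, ctxs$betweenness),
      sac_c = scoreSAC(g, u, v, ctxs$closeness),
      sac_cc = scoreSAC(g, u, v, ctxs$clustering))
    for (ms in c("cn", "jc", "pa", "ra", "aa", "ccpa", "knlp",
                 "sac_d", "sac_b", "sac_c", "sac_cc")) {
      bulk <- rankPairs(g, ms, pairs = pairs)
      direct <- mapply(function(u, v) perPair(ms, u, v), bulk$u, bulk$v)
      expect_equal(unname(bulk$score), unname(direct), tolerance = 1e-9)
    }
  }
})

test_that("rankPairs sorts by score with deterministic canonical tie-break", {
  r <- rankPairs(toy, "cn")
  expect_equal(nrow(r), 16L)
  expect_true(all(diff(r$score) <= 0))
  topties <- r[r$score == max(r$score), ]
  rank <- function(u, v) as.integer(u) * 10L + as.integer(v)
  expect_true(all(diff(rank(topties$u, topties$v)) > 0))
  expect_equal(r$score[r$u == "1" & r$v == "2"],
               scoreCN(toy, "1", "2"))
  sac <- rankPairs(toy, "sac_d")
  expect_equal(sac$score[sac$u == "1" & sac$v == "2"], 1)
  expect_error(rankPairs(toy, "nope"), "valid measures")
  empty <- rankPairs(toy, "cn", pairs = data.frame(u = character(),
                                                   v = character()))
  expect_equal(nrow(empty), 0L)
  expect_error(rankPairs(toy, "cn", pairs = data.frame(u = "1", v = "4")),
               "adjacent")
})

test_that("the full worked-example table is reproduced cell by cell, errata disagreeing", {
  chk <- checkToyTable()
  expect_equal(nrow(chk), 66L)
  expect_true(all(chk$ok))
  consistent <- chk[chk$status == "consistent", ]
  expect_true(all(mapply(matchesPrinted, consistent$computed,
                         consistent$printed)))
  errata <- chk[chk$status == "erratum", ]
  expect_equal(nrow(errata), 11L)
  expect_false(any(mapply(matchesPrinted, errata$computed, errata$printed)))
})
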