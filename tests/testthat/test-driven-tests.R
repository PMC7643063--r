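test_that("skewness test is zero on symmetric samples and matches moments", {
  x <- seq(-2, 2, length.out = 21)     # exactly mirror-symmetric pool
  x <- c(x, -x)
  st <- skewnessTest(x)
  expect_equal(st$g1, 0, tolerance = 1e-12)
  expect_gt(st$P, 0.9)
  expect_error(skewnessTest(rnorm(7)), "n >= 8")

  set.seed(101)
  for (i in 1:10) {
    v <- rnorm(sample(10:100, 1))
    m <- mean(v)
    g1 <- mean((v - m)^3) / mean((v - m)^2)^1.5
    expect_equal(skewnessTest(v)$g1, g1, tolerance = 1e-12)
  }
})

test_that("skewness z-transform matches frozen external reference values", {
  # frozen from an independent implementation of the D'Agostino transform
  set.seed(42)
  x <- round(rnorm(91), 6)
  st <- skewnessTest(x)
  expect_equal(st$g1, -0.5546033293, tolerance = 1e-8)
  expect_equal(st$z, -2.1887275058, tolerance = 1e-8)
  expect_equal(st$P, 0.0286166515, tolerance = 1e-8)
})

test_that("exponential samples show significant positive skew", {
  hits <- 0L
  for (i in 1:50) {
    set.seed(200 + i)
    st <- skewnessTest(rexp(91))
    if (st$g1 > 0 && st$P < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 45L)
})

test_that("chi-square goodness of fit is symmetric with exact anchors", {
  expect_equal(chiSquareGof(50, 50), 1)
  expect_equal(chiSquareGof(139, 40), chiSquareGof(40, 139))
  expect_error(chiSquareGof(0, 0))
  set.seed(110)
  for (i in 1:10) {
    a <- sample(0:200, 1); b <- sample(1:200, 1)
    expect_equal(chiSquareGof(a, b), chiSquareGof(b, a))
  }
})

make_flat_table <- function(values, xb = 0) {
  # root (id 1) -> basal (id 2) and independent descendants
  n <- length(values)
  data.frame(id = seq_len(n + 2), label = as.character(seq_len(n + 2)),
             value = c(xb + 1, xb, values),
             depth = c(0, 1, rep(1, n)),
             isTip = c(FALSE, FALSE, rep(TRUE, n)),
             parent = c(NA, 1, rep(1, n)))
}

test_that("minimum test partitions, counts and matches the Table-3 style chi-square", {
  set.seed(120)
  vals <- c(rnorm(139, 2, 0.5), rnorm(40, -2, 0.5))
  nv <- make_flat_table(vals)
  mt <- minimumTest(nv, basalNode = 2)
  expect_equal(mt$nHigher, 139L)
  expect_equal(mt$nLower, 40L)
  expect_equal(mt$nHigher + mt$nLower + mt$nTie, nrow(nv) - 2L)
  expect_equal(signif(mt$chisqP, 5), 1.3659e-13)
  expect_lt(mt$tP, 1)           # both groups populated
  expect_error(minimumTest(nv, basalNode = 1), "root")
  expect_error(minimumTest(nv, basalNode = 999), "unknown")
})

test_that("minimum test flags a one-sided extreme when all descendants exceed x_b", {
  set.seed(121)
  nv <- make_flat_table(abs(rnorm(30)) + 0.5)
  mt <- minimumTest(nv, basalNode = 2)
  expect_equal(mt$nLower, 0L)
  expect_lt(mt$chisqP, 1e-6)
  expect_true(is.na(mt$tP))     # no lower group to compare
})

test_that("minimum test counts are unbiased under Brownian nulls", {
  # the above/below-x_b split is unbiased under BM, but its replicate-level
  # variance is far wider than binomial: whole clades cross x_b together
  # because node values are phylogenetically correlated, so the binomial
  # band is not the right per-replicate yardstick
  tr <- yuleTree(48, seed = 122)
  basal <- SeqCompTrends:::.basalNode(tr)
  frac <- vapply(1:40, function(i) {
    s <- simulateBM(tr, seed = 400 + i, internal = TRUE)
    mt <- minimumTest(node_table_from_sim(tr, s), basal)
    mt$nHigher / (mt$nHigher + mt$nLower)
  }, numeric(1))
  expect_gt(mean(frac), 0.35)
  expect_lt(mean(frac), 0.65)
  expect_gt(stats::sd(frac), sqrt(0.25 / 94))   # the overdispersion itself
})

test_that("ancestor-descendant test enumerates hand-built cases", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  # values: root 5, both internals 6,7, tips 8..11 -> every above-mean edge up
  nv <- SeqCompTrends:::.nodeTable(tr, c(8, 9, 10, 11, 5, 6, 7))
  ad <- ancestorDescendantTest(tr, nv, threshold = 5.5)
  expect_equal(ad$nDown, 0L)
  expect_equal(ad$P, 2 * 0.5^ad$nUp)
  expect_error(ancestorDescendantTest(tr, nv, threshold = 100), "no edges")
  adF <- ancestorDescendantTest(tr, nv, threshold = 5.5, test = "fisher")
  expect_true(adF$P >= 0 && adF$P <= 1)
})

test_that("unrestricted ancestor-descendant test is calibrated under pure BM", {
  tr <- yuleTree(64, seed = 11)
  set.seed(130)
  rej <- mean(replicate(100, {
    s <- simulateBM(tr, internal = TRUE)
    ancestorDescendantTest(tr, node_table_from_sim(tr, s),
                           threshold = -Inf)$P < 0.05
  }))
  expect_lte(rej, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 100))
})

test_that("Mood's median test and the sub-clade proofs behave", {
  # self-comparison: same median, P in the 1 region
  expect_gt(moodMedianTest(rnorm(30), rnorm(30))$P, 0, label = "valid P")
  x <- rnorm(40)
  expect_gt(moodMedianTest(x, x)$P, 0.9)

  tr <- yuleTree(24, seed = 140)
  x <- simulateBM(tr, seed = 141)
  root <- ape::Ntip(tr) + 1L
  # whole tree as its own sub-clade: Mood P in the 1 region
  sc <- subcladeTest(tr, x, root, nSim = 100, seed = 1)
  expect_gt(sc$moodP, 0.9)
  # a sub-clade shifted far above the phylum: Mood significant, skew proof
  # becomes applicable
  node <- tr$edge[tr$edge[, 1] == root, 2]
  node <- node[node > ape::Ntip(tr)][1]
  clade_tips <- ape::extract.clade(tr, node)$tip.label
  shifted <- x
  shifted[clade_tips] <- shifted[clade_tips] + 50
  sc2 <- subcladeTest(tr, shifted, node, nSim = 100, seed = 2)
  expect_lt(sc2$moodP, 0.05)
  expect_true(sc2$medianAbove)
  expect_true(sc2$skewApplicable || sc2$nTips < 8)
})

test_that("the applicability rule blocks the skew proof for most Brownian clades", {
  tr <- yuleTree(32, seed = 150)
  root <- ape::Ntip(tr) + 1L
  kids <- tr$edge[tr$edge[, 1] == root, 2]
  node <- kids[kids > ape::Ntip(tr)][1]
  applicable <- logical(20)
  for (i in 1:20) {
    x <- simulateBM(tr, seed = 600 + i)
    applicable[i] <- subcladeTest(tr, x, node, nSim = 100,
                                  seed = i)$skewApplicable
  }
  expect_lte(mean(applicable), 0.5)
})

test_that("Mann-Whitney matches exact enumeration and its extremes", {
  same <- setNames(rep(c(1, 2, 3, 4), 2), paste0("t", 1:8))
  lab <- setNames(rep(c("a", "b"), each = 4), paste0("t", 1:8))
  expect_gt(mannWhitneyGroups(same, lab)$P, 0.5)
  expect_error(mannWhitneyGroups(same, setNames(rep("a", 8), names(same))),
               "two groups")

  # disjoint ranges: minimal attainable two-sided exact p
  x <- setNames(c(1:10, 101:110), paste0("g", 1:20))
  l <- setNames(rep(c("lo", "hi"), each = 10), names(x))
  expect_equal(mannWhitneyGroups(x, l)$P, 2 / choose(20, 10),
               tolerance = 1e-12)

  set.seed(160)
  for (i in 1:8) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    v <- round(rnorm(n1 + n2), 3)        # rounding keeps ties possible out
    while (anyDuplicated(v)) v <- round(rnorm(n1 + n2), 3)
    tv <- setNames(v, paste0("t", seq_along(v)))
    lv <- setNames(rep(c("A", "B"), c(n1, n2)), names(tv))
    expect_equal(mannWhitneyGroups(tv, lv)$P,
                 oracle_mw_exact(v[1:n1], v[(n1 + 1):(n1 + n2)]),
                 tolerance = 1e-9)
  }
})

test_that("the +/-/0 summary grid is a deterministic function of components", {
  signal <- list(K = 0.4, P = 0.001)
  trend <- list(P = 0.01, slope = 2)
  minimum <- list(skewP = 0.2, g1 = 0.3, chisqP = 1e-10, nHigher = 100,
                  nLower = 30, tP = 0.03, meanAbsHigher = 1,
                  meanAbsLower = 2)
  ancDesc <- list(P = 0.2, nUp = 10, nDown = 8)
  sub <- data.frame(trendP = c(0.01, 0.5, 0.01), slope = c(1, 1, -1),
                    trendSkipped = c(FALSE, FALSE, FALSE))
  g <- drivenTrendSummary(signal, trend, minimum, ancDesc, sub)
  expect_equal(g$K, "+")
  expect_equal(g$trend, "+")
  expect_equal(g$skewness, "0")
  expect_equal(g$chisq, "+")
  expect_equal(g$ttest, "-")
  expect_equal(g$ancDesc, "0")
  expect_equal(c(g$sub_plus, g$sub_minus, g$sub_zero), c(1, 1, 1))
  expect_identical(g, drivenTrendSummary(signal, trend, minimum, ancDesc,
                                         sub))
})
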