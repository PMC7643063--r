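test_that("newick reading and root-to-node depths are additive", {
  nwk <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):2,C:3);", nwk)
  tr <- readRootedTree(nwk)
  d <- nodeDepths(tr)
  expect_equal(unname(d[c("A", "B", "C")]), c(3, 3, 3))
  expect_equal(unname(d[as.character(ape::Ntip(tr) + 1L)]), 0)

  noBL <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A,B),C);", noBL)
  expect_error(readRootedTree(noBL), "branch lengths")

  # caterpillar depths equal hand sums
  cat5 <- ape::read.tree(text = "((((A:1,B:2):1,C:3):1,D:4):1,E:5);")
  dc <- nodeDepths(cat5)
  expect_equal(unname(dc[c("A", "B", "C", "D", "E")]), c(4, 5, 5, 5, 5))
})

test_that("phylogenetic VCV matches hand values and the path oracle", {
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(phyloVcv(t2), matrix(c(1, 0, 0, 1), 2,
               dimnames = list(c("A", "B"), c("A", "B"))))
  t3 <- ape::read.tree(text = "((A:1,B:1):2,C:3);")
  C3 <- phyloVcv(t3)
  expect_equal(C3["A", "B"], 2)
  expect_equal(C3["A", "A"], 3)

  set.seed(51)
  for (i in 1:5) {
    tr <- ape::rtree(6)
    C <- phyloVcv(tr)
    expect_equal(C, oracle_vcv(tr)[rownames(C), colnames(C)],
                 tolerance = 1e-12)
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)                      # PSD
    expect_silent(chol(C + diag(1e-10, nrow(C))))
  }
})

test_that("Blomberg's K equals the direct GLS oracle and picante on small trees", {
  tr <- yuleTree(12, seed = 3)
  x <- simulateBM(tr, seed = 4)
  got <- blombergK(tr, x, nPerm = 199, seed = 1)
  expect_equal(got$K, oracle_k_gls(ape::vcv(tr), x[tr$tip.label]),
               tolerance = 1e-9)
  skip_if_not_installed("picante")
  expect_equal(got$K, as.numeric(picante::Kcalc(x[tr$tip.label], tr)),
               tolerance = 1e-9)
})

test_that("K permutation p-value separates structure from noise", {
  tr <- yuleTree(48, seed = 5)
  hits <- 0L
  for (i in 1:20) {
    x <- simulateBM(tr, seed = 300 + i)
    strK <- blombergK(tr, x, nPerm = 199, seed = i)
    perm <- setNames(sample(x), names(x))
    permK <- blombergK(tr, perm, nPerm = 99, seed = i)
    if (permK$K < strK$K) hits <- hits + 1L
    expect_gte(strK$P, 1 / 200)
  }
  expect_gte(hits, 18L)
  expect_error(blombergK(tr, setNames(rep(1, 48), tr$tip.label)),
               "constant")
})

test_that("white-noise traits give a calibrated K permutation test", {
  tr <- yuleTree(32, seed = 6)
  set.seed(61)
  p <- replicate(100, {
    x <- setNames(rnorm(32), tr$tip.label)
    blombergK(tr, x, nPerm = 99)$P
  })
  rej <- mean(p < 0.05)
  expect_lte(rej, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 100))
})

test_that("phylogenetic correlation reduces correctly and is calibrated", {
  st <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  x <- c(A = 1, B = 2, C = 3, D = 6, E = 4)
  y <- c(A = 2, B = 1, C = 5, D = 4, E = 6)
  got <- phyloCorrelation(st, x, y)
  ct <- stats::cor.test(x[st$tip.label], y[st$tip.label])
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-9)
  expect_equal(got$P, ct$p.value, tolerance = 1e-9)
  expect_equal(phyloCorrelation(st, x, x)$r, 1)
  expect_error(phyloCorrelation(st, x, x * 0), "variance")

  tr <- yuleTree(32, seed = 7)
  set.seed(71)
  p <- replicate(100, {
    phyloCorrelation(tr, simulateBM(tr), simulateBM(tr))$P
  })
  expect_lte(mean(p < 0.05), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 100) + 0.02)
})

test_that("correlation matrix applies BH across pairs symmetrically", {
  tr <- yuleTree(16, seed = 8)
  tra <- data.frame(id = tr$tip.label,
                    a = simulateBM(tr, seed = 1)[tr$tip.label],
                    b = simulateBM(tr, seed = 2)[tr$tip.label],
                    c = simulateBM(tr, seed = 3)[tr$tip.label])
  cm <- phyloCorrelationMatrix(tr, tra)
  expect_equal(cm$r, t(cm$r))
  expect_equal(cm$Padj, t(cm$Padj))
  expect_equal(sort(cm$Padj[upper.tri(cm$Padj)]),
               sort(p.adjust(cm$P[upper.tri(cm$P)], "BH")))
})

test_that("ancestral ML/BM states match closed forms and fastAnc", {
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  a2 <- ancestralStates(t2, c(A = 2, B = 4))
  expect_equal(attr(a2, "rootValue"), 3)
  st <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  xs <- c(A = 1, B = 2, C = 3, D = 6)
  expect_equal(attr(ancestralStates(st, xs), "rootValue"), mean(xs))

  tr <- yuleTree(5, seed = 9)
  x <- simulateBM(tr, seed = 10)
  a <- ancestralStates(tr, x)
  skip_if_not_installed("phytools")
  fa <- phytools::fastAnc(tr, x)
  expect_equal(a$value[!a$isTip], as.numeric(fa), tolerance = 1e-6)
})

test_that("ridge reconstruction stays close to ML/BM and respects the root", {
  tr <- fixture_tree_nonultra(24, seed = 12)
  x <- simulateBM(tr, seed = 13)
  ml <- ancestralStates(tr, x, method = "ml_bm")
  rg <- ancestralStates(tr, x, method = "ridge")
  expect_equal(rg$value[rg$isTip], ml$value[ml$isTip], tolerance = 0.35)
  expect_gt(cor(rg$value[!rg$isTip], ml$value[!ml$isTip]), 0.9)
  expect_error(ancestralStates(tr, x, method = "nope"))
})

test_that("edge interpolation is linear and endpoint-faithful", {
  t2 <- ape::read.tree(text = "(A:2,B:2);")
  nv <- ancestralStates(t2, c(A = 0, B = 2))
  ip <- interpolateEdgeStates(t2, nv, nPoints = 2)
  edgeA <- ip[ip$child == 1, ]
  expect_equal(edgeA$value, c(1, 0.5, 0))       # parent 1 -> child 0
  ep <- interpolateEdgeStates(t2, nv, nPoints = 1)
  expect_equal(nrow(ep), 4L)                    # endpoints only
  nvC <- nv; nvC$value <- rep(5, nrow(nvC))
  expect_true(all(interpolateEdgeStates(t2, nvC, 4)$value == 5))
})

test_that("Brownian simulation obeys the variance and drift laws", {
  t2 <- ape::read.tree(text = "(A:2,B:3);")
  expect_equal(unname(simulateBM(t2, sigma2 = 0, z0 = 1.5)),
               c(1.5, 1.5))
  expect_error(simulateBM(t2, sigma2 = -1), "sigma2")
  set.seed(81)
  sims <- replicate(2000, simulateBM(t2, sigma2 = 1.7, z0 = 2, mu = 0))
  expect_equal(var(sims["A", ]), 1.7 * 2, tolerance = 0.1)
  expect_equal(var(sims["B", ]), 1.7 * 3, tolerance = 0.1)
  set.seed(82)
  drift <- replicate(2000, simulateBM(t2, sigma2 = 1, z0 = 1, mu = 1))
  expect_equal(mean(drift["A", ]), 1 + 2, tolerance = 0.1)
  expect_equal(mean(drift["B", ]), 1 + 3, tolerance = 0.1)
})

test_that("trend slope reproduces an independent OLS on the regressed pairs", {
  tr <- fixture_tree_nonultra(32, seed = 14)
  x <- simulateBM(tr, seed = 15)
  res <- searchTrend(tr, x, nSim = 200, seed = 16)
  fit <- lm(value ~ depth, data = res$nodeValues)
  expect_equal(res$slope, unname(coef(fit)[2]), tolerance = 1e-9)
  expect_error(searchTrend(ape::read.tree(text = "(A:1,B:1);"),
                           c(A = 1, B = 2), nSim = 100), "4 tips")
})

test_that("trend null p-values are roughly uniform (sanity, not a hard gate)", {
  tr <- fixture_tree_nonultra(32, seed = 17)
  set.seed(91)
  p <- replicate(100, searchTrend(tr, simulateBM(tr), nSim = 200)$P)
  # simulation p-values are discrete at n_sim = 200, hence the tie warning
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.001)
})
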