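toyTree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

test_that("richness counts positive cells regardless of abundance", {
  cm <- rbind(s1 = c(a = 3, b = 0, c = 7), s2 = c(a = 0, b = 0, c = 0))
  expect_equal(richness(cm), c(s1 = 2, s2 = 0))
  expect_equal(richness(cm > 0), richness(cm))
})

test_that("Faith's PD matches hand sums under the root convention", {
  tr <- toyTree()
  cm <- rbind(s1 = c(A = 1, B = 1, C = 0),
              s2 = c(A = 1, B = 0, C = 0),
              s3 = c(A = 1, B = 1, C = 1),
              s4 = c(A = 0, B = 0, C = 0))
  pd <- faithPd(cm, tr)
  expect_equal(unname(pd), c(3, 2, 5, 0))
  # without the root path, a pair spans only its own subtree and a
  # singleton has no branch surface
  pdNo <- faithPd(cm, tr, includeRoot = FALSE)
  expect_equal(unname(pdNo), c(2, 0, 5, 0))

  expect_error(faithPd(rbind(s1 = c(A = 1, Z = 1)), tr), "Z",
               class = "jumpsieve_input_error")
  unrooted <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_error(faithPd(rbind(s1 = c(A = 1, B = 1)), unrooted),
               "rooted", class = "jumpsieve_input_error")
})

test_that("PD agrees with picante and is monotone under taxon addition", {
  library(picante)
  set.seed(41)
  for (i in 1:15) {
    tr <- ape::rtree(10)
    cm <- randomPA(4, 10)
    colnames(cm) <- tr$tip.label
    mine <- faithPd(cm, tr)
    # picante defines PD for communities of >= 2 taxa with include.root
    rows <- rowSums(cm > 0) >= 2
    if (any(rows)) {
      ref <- picante::pd(cm[rows, , drop = FALSE], tr,
                         include.root = TRUE)
      expect_equal(unname(mine[rows]), ref$PD, tolerance = 1e-10)
    }
    # monotone growth along a nested chain of communities
    ord <- sample(tr$tip.label)
    chain <- t(vapply(seq_along(ord), function(k)
      as.integer(tr$tip.label %in% ord[seq_len(k)]),
      integer(10)))
    dimnames(chain) <- list(sprintf("n%02d", seq_along(ord)),
                            tr$tip.label)
    pds <- faithPd(chain, tr)
    expect_true(all(diff(pds) >= -1e-12))
    expect_equal(unname(pds[length(pds)]), sum(tr$edge.length))
  }
})

test_that("depth residuals satisfy the OLS identities", {
  res <- depthResiduals(c(10, 20, 30), c(1000, 2000, 3000))
  expect_equal(res$raw, rep(0, 3))
  expect_equal(res$scaled, rep(0, 3))

  set.seed(42)
  vals <- rnorm(20, 50, 8)
  depths <- runif(20, 1e3, 1e5)
  r <- depthResiduals(vals, depths)
  expect_lt(abs(sum(r$raw)), 1e-10)
  expect_equal(mean(r$scaled), 0, tolerance = 1e-12)
  expect_equal(var(r$scaled), 1, tolerance = 1e-12)

  # a sample lying above the fitted line gets a positive residual
  above <- depthResiduals(c(10, 20, 30, 45), c(1e3, 2e3, 3e3, 3.5e3))
  expect_gt(above$raw[4], 0)

  expect_error(depthResiduals(1:3, rep(5, 3)),
               class = "jumpsieve_precondition_error")
  centered <- depthResiduals(c(1, 2, 6), rep(5, 3),
                             onConstantDepth = "center")
  expect_equal(sum(centered$raw), 0)
  expect_error(depthResiduals(1:2, 1:2),
               class = "jumpsieve_precondition_error")
})

test_that("pairwise partition reproduces the set-arithmetic cases", {
  pa <- rbind(X = c(a = 1, b = 1, c = 1, d = 0),
              Y = c(a = 0, b = 1, c = 1, d = 1))
  b <- betaPairwise(pa, "X", "Y")
  expect_equal(unname(b), c(1 / 3, 1 / 3, 0))

  nested <- rbind(X = c(a = 1, b = 1, c = 1, d = 1),
                  Y = c(a = 1, b = 1, c = 0, d = 0))
  bn <- betaPairwise(nested, "X", "Y")
  expect_equal(unname(bn), c(1 / 3, 0, 1 / 3))

  same <- rbind(X = c(a = 1, b = 1), Y = c(a = 1, b = 1))
  expect_equal(unname(betaPairwise(same, "X", "Y")), c(0, 0, 0))

  empty <- rbind(X = c(a = 0), Y = c(a = 0))
  expect_error(betaPairwise(empty, "X", "Y"),
               class = "jumpsieve_precondition_error")
})

test_that("multi-site partition matches brute force and vegan", {
  library(vegan)
  # two sites reduce to the pairwise statistic
  pa2 <- rbind(X = c(1, 1, 1, 0), Y = c(0, 1, 1, 1))
  dimnames(pa2) <- list(c("X", "Y"), letters[1:4])
  expect_equal(betaMultisite(pa2), betaPairwise(pa2, "X", "Y"),
               ignore_attr = TRUE)

  identical_ <- matrix(1, 3, 4,
                       dimnames = list(c("r1", "r2", "r3"),
                                       letters[1:4]))
  expect_equal(unname(betaMultisite(identical_)), c(0, 0, 0))

  set.seed(51)
  for (i in 1:50) {
    pa <- randomPA(sample(3:7, 1), sample(5:20, 1))
    mine <- betaMultisite(pa)
    oracle <- bruteMultisite(pa)
    expect_equal(unname(mine), unname(oracle), tolerance = 1e-12)
    ref <- vegan::nestedbetasor(pa)
    expect_equal(unname(mine[c("beta_sim", "beta_sne", "beta_sor")]),
                 unname(ref), tolerance = 1e-10)
  }
})

test_that("partition components are additive and bounded", {
  set.seed(52)
  for (i in 1:200) {
    pa <- randomPA(sample(2:6, 1), sample(3:15, 1), p = runif(1, .2, .8))
    m <- betaMultisite(pa)
    expect_lt(abs(m[["beta_sor"]] - m[["beta_sim"]] - m[["beta_sne"]]),
              1e-12)
    expect_true(all(m >= -1e-12 & m <= 1 + 1e-12))
    nonEmpty <- which(rowSums(pa) > 0)
    if (length(nonEmpty) >= 2) {
      p <- betaPairwise(pa, nonEmpty[1], nonEmpty[2])
      expect_lt(abs(p[["beta_sor"]] - p[["beta_sim"]] - p[["beta_sne"]]),
                1e-12)
    }
  }
})

test_that("group resampling is seeded, warned and degenerate-stable", {
  set.seed(61)
  pa <- randomPA(12, 30)
  groups <- rep(c("g1", "g2"), each = 6)
  d1 <- betaResample(pa, groups, nSites = 6, nIter = 20, seed = 99)
  d2 <- betaResample(pa, groups, nSites = 6, nIter = 20, seed = 99)
  expect_identical(d1, d2)
  # group of exactly nSites: every draw equals the full-group statistic
  full <- betaMultisite(pa[groups == "g1", ])
  expect_true(all(apply(d1$g1, 1, function(r)
    all(abs(r - full) < 1e-12))))
  w <- capture_warnings(
    betaResample(pa, groups, nSites = 10, nIter = 3, seed = 1))
  expect_length(w, 2)          # one per undersized group
  expect_match(w, "resampling at group size", all = TRUE)
  expect_error(betaResample(pa, groups[1:3], nSites = 2, nIter = 2,
                            seed = 1),
               class = "jumpsieve_input_error")
})

test_that("resample means stabilise as iterations grow", {
  set.seed(62)
  pa <- randomPA(10, 40, p = 0.4)
  groups <- rep("g", 10)
  means <- vapply(1:6, function(s) {
    mean(betaResample(pa, groups, nSites = 5, nIter = 400,
                      seed = s)$g$beta_sor)
  }, numeric(1))
  # across independent seeds the Monte-Carlo means agree closely
  expect_lt(diff(range(means)), 0.02)
})

test_that("Venn regions enumerate exclusive and shared OTUs exactly", {
  pa <- rbind(s1 = c(a = 1, b = 1, c = 0, d = 0),
              s2 = c(a = 1, b = 0, c = 1, d = 0),
              s3 = c(a = 0, b = 0, c = 1, d = 1))
  groups <- c("G1", "G2", "G3")
  v <- exclusiveOtus(pa, groups)
  # hand enumeration: a in G1&G2, b in G1, c in G2&G3, d in G3
  expect_equal(v$exclusive, c(G1 = 1L, G2 = 0L, G3 = 1L))
  expect_equal(v$regions[["G1&G2"]], 1L)
  expect_equal(v$regions[["G2&G3"]], 1L)
  expect_equal(sum(v$regions), v$pooledRichness)
  expect_equal(v$pooledRichness, 4L)

  disjoint <- rbind(s1 = c(a = 1, b = 1, c = 0), s2 = c(a = 0, b = 0,
                                                        c = 1))
  vd <- exclusiveOtus(disjoint, c("A", "B"))
  expect_equal(vd$exclusive, c(A = 2L, B = 1L))

  same <- rbind(s1 = c(a = 1, b = 1), s2 = c(a = 1, b = 1))
  vs <- exclusiveOtus(same, c("A", "B"))
  expect_equal(unname(vs$exclusive), c(0L, 0L))
  expect_equal(vs$regions[["A&B"]], 2L)

  many <- matrix(1, 7, 2,
                 dimnames = list(sprintf("s%d", 1:7), c("a", "b")))
  expect_error(exclusiveOtus(many, sprintf("g%d", 1:7)),
               class = "jumpsieve_input_error")
})

test_that("Venn regions sum to pooled richness on random matrices", {
  set.seed(71)
  for (i in 1:25) {
    pa <- randomPA(9, sample(5:25, 1), p = runif(1, .1, .9))
    groups <- sample(c("x", "y", "z"), 9, replace = TRUE)
    if (length(unique(groups)) < 2) next
    v <- exclusiveOtus(pa, groups)
    expect_equal(sum(v$regions), v$pooledRichness)
    # brute per-OTU membership check
    memb <- vapply(unique(groups), function(g)
      colSums(pa[groups == g, , drop = FALSE]) > 0,
      logical(ncol(pa)))
    expect_equal(v$pooledRichness, sum(rowSums(memb) > 0))
  }
})
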