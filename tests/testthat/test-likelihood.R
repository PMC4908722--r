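test_that("pruning reproduces hand-computed small-tree likelihoods", {
  jc <- jukesCantor()
  # root with single leaf child at d = 0: L = f_A = 0.25
  tr0 <- attachAlignment(readNewick("(L:0)R;"), c(L = "A"))
  expect_equal(totalLikelihood(prune(tr0, jc)), 0.25, tolerance = 1e-12)
  # root with two leaf children "A" at d = 0.5: sum_i f_i P_iA(d)^2
  tr2 <- attachAlignment(readNewick("(L1:0.5,L2:0.5)R;"),
                         c(L1 = "A", L2 = "A"))
  pSame <- 0.25 + 0.75 * exp(-2 / 3)
  pDiff <- 0.25 - 0.25 * exp(-2 / 3)
  expect_equal(totalLikelihood(prune(tr2, jc)),
               0.25 * (pSame^2 + 3 * pDiff^2), tolerance = 1e-12)
  # leaf partials are the 1/0 indicators
  tab <- prune(tr2, jc)
  expect_equal(as.numeric(partialLikelihoods(tab, "L1")), c(1, 0, 0, 0))
})

test_that("the four-taxon double sum equals the factorized recursion", {
  jc <- jukesCantor()
  tr <- attachAlignment(fig4Tree(dXY = 1, dXZ = 2, dYR = 1, dYS = 1.5),
                        c(R = "C", S = "C", Z = "A"))
  P <- function(d) transitionMatrix(jc, d)
  manual <- 0
  for (i in 1:4) for (j in 1:4)
    manual <- manual + 0.25 * P(1)[i, j] * P(2)[i, "A"] *
      P(1)[j, "C"] * P(1.5)[j, "C"]
  expect_equal(totalLikelihood(prune(tr, jc)), manual, tolerance = 1e-12)
  expect_equal(bruteForceLikelihood(tr, jc), manual, tolerance = 1e-12)
})

test_that("pruning equals brute-force enumeration on random trees and models", {
  set.seed(181)
  for (k in 1:40) {
    model <- if (k %% 2) jukesCantor() else randomGTR()
    tr <- yuleTree(sample(3:8, 1), seed = 3000 + k)
    tr <- dropAncestral(evolveSequences(tr, model, sample(1:3, 1),
                                        seed = 4000 + k))
    exact <- totalLikelihood(prune(tr, model))
    brute <- bruteForceLikelihood(tr, model)
    expect_equal(exact, brute, tolerance = 1e-10)
  }
})

test_that("fixed ancestral bases restrict the recursion to the 1/0 constants", {
  jc <- jukesCantor()
  topo <- "((R:1,S:1)Y:1,Z:2)X;"
  fixed <- attachAlignment(readNewick(topo),
                           c(R = "C", S = "C", Z = "A", Y = "C", X = "A"))
  P <- function(d) transitionMatrix(jc, d)
  manual <- 0.25 * P(1)["A", "C"] * P(2)["A", "A"] *
    P(1)["C", "C"] * P(1)["C", "C"]
  expect_equal(totalLikelihood(prune(fixed, jc)), manual,
               tolerance = 1e-12)
  expect_equal(bruteForceLikelihood(fixed, jc), manual, tolerance = 1e-12)
})

test_that("site independence: the total factorizes over sites", {
  set.seed(191)
  for (k in 1:10) {
    model <- if (k %% 2) jukesCantor() else randomGTR()
    ns <- sample(2:5, 1)
    tr <- dropAncestral(evolveSequences(yuleTree(sample(3:6, 1),
                                                 seed = 5000 + k),
                                        model, ns, seed = 6000 + k))
    tab <- prune(tr, model)
    perSite <- vapply(seq_len(ns), function(l) {
      trl <- tr
      trl@sequences <- ifelse(is.na(tr@sequences), NA_character_,
                              substr(tr@sequences, l, l))
      names(trl@sequences) <- names(tr@sequences)
      trl@nsites <- 1L
      totalLikelihood(prune(trl, model))
    }, numeric(1))
    expect_equal(totalLikelihood(tab), prod(perSite), tolerance = 1e-10)
    expect_equal(siteLikelihoods(tab), perSite, tolerance = 1e-10)
  }
})

test_that("each partial is computed exactly once (cache contract)", {
  set.seed(201)
  for (k in 1:5) {
    nt <- sample(3:10, 1); ns <- sample(1:4, 1)
    tr <- dropAncestral(evolveSequences(yuleTree(nt, seed = 7000 + k),
                                        jukesCantor(), ns, seed = 7100 + k))
    tab <- prune(tr, jukesCantor())
    expect_identical(tab@evalCount,
                     as.integer(length(nodeIds(tr)) * ns * 4))
  }
})

test_that("likelihood is invariant under child reordering and root sliding", {
  jc <- jukesCantor()
  tr <- attachAlignment(readNewick("((R:1,S:1.5)Y:0.8,Z:2)X;"),
                        c(R = "C", S = "G", Z = "A"))
  sw <- attachAlignment(readNewick("(Z:2,(S:1.5,R:1)Y:0.8)X;"),
                        c(R = "C", S = "G", Z = "A"))
  expect_equal(totalLikelihood(prune(tr, jc)),
               totalLikelihood(prune(sw, jc)), tolerance = 1e-12)
  # pulley: slide the root along the Y--Z axis keeping the sum constant
  set.seed(211)
  m <- randomGTR()
  for (a in c(0.2, 1, 1.9)) {
    slid <- attachAlignment(
      readNewick(sprintf("((R:1,S:1.5)Y:%g,Z:%g)X;", a, 2.8 - a)),
      c(R = "C", S = "G", Z = "A"))
    expect_equal(totalLikelihood(prune(slid, m)),
                 totalLikelihood(prune(tr, m)), tolerance = 1e-9)
  }
})

test_that("long alignments do not underflow thanks to per-site log totals", {
  set.seed(221)
  tr <- dropAncestral(evolveSequences(yuleTree(6, seed = 31), jukesCantor(),
                                      600, seed = 32))
  tab <- prune(tr, jukesCantor())
  expect_true(is.finite(logLikelihood(tab)))
  expect_equal(logLikelihood(tab), sum(tab@siteLogLik), tolerance = 1e-9)
})

test_that("upper-bound variants follow their per-site definitions", {
  jc <- jukesCantor()
  tr <- attachAlignment(fig4Tree(), c(R = "C", S = "C", Z = "A"))
  P <- function(d) transitionMatrix(jc, d)
  DR <- 2; DS <- 2; DZ <- 2
  indep <- max(P(DR)[, "C"]) * max(P(DS)[, "C"]) * max(P(DZ)[, "A"])
  shared <- max(0.25 * P(DR)[, "C"] * P(DS)[, "C"] * P(DZ)[, "A"])
  expect_equal(upperBound(tr, jc, "independent"), indep, tolerance = 1e-12)
  expect_equal(upperBound(tr, jc, "shared-root"), shared, tolerance = 1e-12)
  expect_equal(upperBound(tr, jc, "independent", log = TRUE), log(indep),
               tolerance = 1e-12)
})

test_that("star-tree shared-root bound is one term of the exact sum, hence below it", {
  jc <- jukesCantor()
  star <- attachAlignment(readNewick("(L1:0.3,L2:0.3,L3:0.3)R;"),
                          c(L1 = "A", L2 = "A", L3 = "A"))
  exact <- totalLikelihood(prune(star, jc))
  expect_lte(upperBound(star, jc, "shared-root"), exact + 1e-15)
})

test_that("single-leaf independent bound picks the diagonal at small distances", {
  jc <- jukesCantor()
  tr <- attachAlignment(readNewick("(L:0.1)R;"), c(L = "G"))
  expect_equal(upperBound(tr, jc, "independent"),
               transitionProbability(jc, "G", "G", 0.1), tolerance = 1e-12)
})

test_that("log report exposes per-site logs and flags zero-likelihood sites", {
  jc <- jukesCantor()
  tr <- attachAlignment(readNewick("(L1:0.5,L2:0.5)R;"),
                        c(L1 = "AC", L2 = "AG"))
  rep_ <- logReport(prune(tr, jc))
  expect_equal(nrow(rep_), 2)
  expect_equal(sum(rep_$logLik), attr(rep_, "logTotal"), tolerance = 1e-9)
  expect_equal(exp(sum(rep_$logLik)), attr(rep_, "total"),
               tolerance = 1e-9)
  # an impossible site under a fixed ancestor: zero likelihood reported
  zero <- attachAlignment(readNewick("(L:0)R;"), c(L = "A", R = "C"))
  tabz <- prune(zero, jc)
  expect_warning(rz <- logReport(tabz), "-Inf")
  expect_identical(rz$logLik[1], -Inf)
})

test_that("invalid inputs are rejected with informative errors", {
  jc <- jukesCantor()
  tr <- readNewick("(L1:0.5,L2:0.5)R;")
  expect_error(prune(tr, jc), "alignment")
  big <- yuleTree(20, seed = 9)
  big <- dropAncestral(evolveSequences(big, jc, 1, seed = 10))
  expect_error(bruteForceLikelihood(big, jc), "refused")
})
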