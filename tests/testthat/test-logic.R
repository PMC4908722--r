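twoStateChain <- function(rate = 1) {
  R <- matrix(c(0, rate, 0, 0), 2, 2, byrow = TRUE,
              dimnames = rep(list(c("A", "B")), 2))
  ctmc(R, labels = list(A = "a", B = "b"))
}

test_that("parser produces the documented ASTs", {
  f <- parseFormula("P=?[F<=5 x1=A]")
  expect_equal(f@op, "prob"); expect_equal(f@cmp, "?")
  path <- f@args[[1]]
  expect_equal(path@op, "until")
  expect_equal(path@args[[1]]@op, "true")
  expect_equal(path@args[[2]]@prop, "x1=A")
  expect_equal(path@interval, c(0, 5))
  # P<=0.5[Phi] means the probability lies in [0, 0.5]
  a <- parseFormula("P<=0.5[a U b]")
  expect_equal(a@cmp, "<="); expect_equal(a@lambda, 0.5)
  g <- parseFormula("P>=1[G (p)]")
  expect_equal(g@args[[1]]@op, "globally")
  expect_equal(parseFormula("a => b")@op, "or")   # !a | b
  u <- parseFormula("P>0.3[x1=C U[1,2.5] x1=A]")@args[[1]]
  expect_equal(u@op, "until")
  expect_equal(u@interval, c(1, 2.5))
  expect_error(parseFormula("P>=[F a]"), "number")
  expect_error(parseFormula("P>=1[F a] extra"), "trailing")
  expect_error(parseFormula("@"), "position 1")
  expect_error(cslUntil(cslTrue(), cslTrue(), c(2, 1)), "interval")
  expect_error(cslProb("~", 1, cslNext(cslTrue())), "comparator")
})

test_that("boolean connectives check by set algebra on the labeling", {
  set.seed(131)
  ch <- randomChain(6)
  all6 <- states(ch)
  expect_setequal(satStates(checkFormula(ch, "true")), all6)
  aSet <- all6[vapply(labeling(ch), function(l) "a" %in% l, logical(1))]
  expect_setequal(satStates(checkFormula(ch, "a")), aSet)
  expect_setequal(satStates(checkFormula(ch, "!a")), setdiff(all6, aSet))
  bSet <- satStates(checkFormula(ch, "b"))
  expect_setequal(satStates(checkFormula(ch, "a | b")), union(aSet, bSet))
  expect_setequal(satStates(checkFormula(ch, "a & b")),
                  intersect(aSet, bSet))
})

test_that("next-operator probabilities come from the embedded jump chain", {
  s <- c("A", "B", "C")
  R <- matrix(0, 3, 3, dimnames = list(s, s))
  R["A", "B"] <- 1; R["A", "C"] <- 3
  m <- ctmc(R, labels = list(A = "A", B = "B", C = "C"))
  expect_equal(probNext(m, "A", "C"), 0.75)
  expect_equal(probNext(m, "A", "B"), 0.25)
  # absorbing state: embedded self-loop gives probability 1 to itself
  expect_equal(probNext(m, "B", "B"), 1)
  # unsatisfiable target
  expect_equal(probNext(m, "A", "!true"), 0)
})

test_that("bounded until matches closed forms and the printed boundary cases", {
  m <- twoStateChain()
  # 1 - exp(-t) for reaching B, at t = ln 2 exactly 0.5
  expect_equal(probUntil(m, "A", "true", "b", c(0, log(2))), 0.5,
               tolerance = 1e-10)
  for (t in c(0.2, 1, 2))
    expect_equal(probUntil(m, "A", "true", "b", c(0, t)), 1 - exp(-t),
                 tolerance = 1e-10)
  # boundary: s in Sat(phi) gives 1; s in Sat(!psi & !phi) gives 0; t = 0
  expect_equal(probUntil(m, "B", "true", "b", c(0, 5)), 1)
  expect_equal(probUntil(m, "A", "!true", "b", c(0, 5)), 0)
  expect_equal(probUntil(m, "A", "true", "b", c(0, 0)), 0)
  expect_equal(probUntil(m, "B", "true", "b", c(0, 0)), 1)
  expect_error(probUntil(m, "A", "true", "b", c(2, 1)), "interval")
})

test_that("bounded until is monotone in the bound and respects psi", {
  set.seed(141)
  for (k in 1:10) {
    ch <- randomChain(sample(3:6, 1))
    psi <- setFormula(sample(states(ch), 3))
    phi <- setFormula(sample(states(ch), 2))
    ts <- sort(stats::runif(4, 0, 3))
    p <- vapply(ts, function(t)
      probUntil(ch, states(ch)[1], psi, phi, c(0, t)), numeric(1))
    expect_true(all(diff(p) >= -1e-10))
    expect_true(all(p >= 0 & p <= 1 + 1e-12))
  }
})

test_that("unbounded until agrees with iterative fixed-point evaluation", {
  set.seed(151)
  for (k in 1:10) {
    ch <- randomChain(sample(3:6, 1))
    psi <- setFormula(sample(states(ch), 3))
    phi <- setFormula(sample(states(ch), 2))
    direct <- probUntil(ch, NULL, psi, phi)
    # value iteration on the embedded chain, independent of the solver
    P <- jumpProbs(embed(ch))
    phiSat <- states(ch) %in% satStates(checkFormula(ch, phi))
    psiSat <- states(ch) %in% satStates(checkFormula(ch, psi))
    x <- as.numeric(phiSat)
    for (it in 1:4000) {
      xNew <- as.numeric(phiSat + (!phiSat & psiSat) * (P %*% x))
      if (max(abs(xNew - x)) < 1e-14) break
      x <- xNew
    }
    expect_equal(unname(direct), x, tolerance = 1e-9)
  }
})

test_that("interval until composes a psi-constrained phase with a continuation", {
  m <- twoStateChain()
  # [t,t'] with psi = true: P(hit B by t') counted only if after t? No:
  # hitting before t keeps satisfying at t (B stays B, psi holds), so the
  # value equals the [0,t'] probability here.
  expect_equal(probUntil(m, "A", "true", "b", c(0.5, 1.5)),
               probUntil(m, "A", "true", "b", c(0, 1.5)), tolerance = 1e-9)
  # with psi = "a" the process must still be in A at t: reaching B inside
  # [t, t'] means surviving in A until t, then jumping within t' - t
  t <- 0.4; t2 <- 1.3
  expect_equal(probUntil(m, "A", "a", "b", c(t, t2)),
               exp(-t) * (1 - exp(-(t2 - t))), tolerance = 1e-9)
  # [t, Inf]: survive as A to t, then eventually jump (prob 1)
  expect_equal(probUntil(m, "A", "a", "b", c(0.7, Inf)), exp(-0.7),
               tolerance = 1e-9)
  # degenerate [t,t]
  expect_equal(probUntil(m, "A", "a", "b", c(0.5, 0.5)), 0,
               tolerance = 1e-9)
  expect_equal(probUntil(m, "B", "b", "b", c(0.5, 0.5)), 1,
               tolerance = 1e-9)
})

test_that("until probabilities agree with Monte-Carlo trajectory sampling", {
  set.seed(161)
  nPaths <- 2e4
  for (k in 1:6) {
    ch <- randomChain(sample(3:6, 1))
    psiStates <- sample(states(ch), min(4, length(states(ch))))
    phiStates <- sample(states(ch), 2)
    t <- stats::runif(1, 0.3, 2)
    exact <- probUntil(ch, states(ch)[1], setFormula(psiStates),
                       setFormula(phiStates), c(0, t))
    ts <- samplePaths(ch, states(ch)[1], horizon = t, n = nPaths,
                      seed = 700 + k)
    est <- mcBoundedUntil(ts, psiStates, phiStates, t)
    se <- sqrt(max(exact * (1 - exact), 1e-12) / nPaths)
    expect_lt(abs(est - exact), 3 * se + 1e-9)
  }
})

test_that("the leaf predicate holds at self-loops and identical-children nodes", {
  jc <- jukesCantor()
  full <- attachAlignment(fig4Tree(), c(R = "C", S = "C", Z = "A",
                                        X = "A", Y = "C"))
  sat <- satStates(checkFormula(toPTS(full, jc), leafFormula()))
  # R, S, Z are self-loop leaves; Y's children are sequence-identical to
  # it, so the formula as defined also accepts Y (documented corner)
  expect_setequal(sat, c("R", "S", "Z", "Y"))
  # with a mutated child the internal node is excluded
  full2 <- attachAlignment(fig4Tree(), c(R = "C", S = "G", Z = "A",
                                         X = "A", Y = "C"))
  expect_setequal(satStates(checkFormula(toPTS(full2, jc), leafFormula())),
                  c("R", "S", "Z"))
})

test_that("global pattern: conserved sites satisfy, violations falsify, time bounds matter", {
  jc <- jukesCantor()
  conserved <- attachAlignment(fig4Tree(), c(R = "C", S = "C", Z = "C",
                                             X = "C", Y = "C"))
  pts <- toPTS(conserved, jc)
  root <- "X"
  expect_true(root %in% satStates(checkFormula(pts,
                                               globalPattern(cslAtom("x1=C")))))
  violating <- attachAlignment(fig4Tree(), c(R = "C", S = "C", Z = "A",
                                             X = "C", Y = "C"))
  pts2 <- toPTS(violating, jc)
  expect_false(root %in% satStates(checkFormula(pts2,
                                                globalPattern(cslAtom("x1=C")))))
  # violation two branches deep: under the race semantics traversal times
  # are exponential, so a short time bound only makes the violation
  # unlikely, not impossible — the G-probability decreases with the bound
  # and the untimed G-probability is exactly 0
  late <- attachAlignment(readNewick("((L:1)M:1)X;"),
                          c(X = "C", M = "C", L = "A"))
  pts3 <- toPTS(late, jc)
  pG <- function(iv) 1 - stateProbs(checkFormula(pts3,
    cslProb("?", path = cslF(cslNot(cslAtom("x1=C")), iv))))[["X"]]
  expect_gt(pG(c(0, 0.5)), pG(c(0, 2)))
  expect_equal(pG(c(0, Inf)), 0, tolerance = 1e-9)
  expect_gt(pG(c(0, 0.5)), 0.9)
  # thresholds below 1 separate the timed and untimed patterns
  expect_true("X" %in% satStates(checkFormula(pts3,
    cslProb(">=", 0.9, cslG(cslAtom("x1=C"), c(0, 0.5))))))
  expect_false("X" %in% satStates(checkFormula(pts3,
    cslProb(">=", 0.9, cslG(cslAtom("x1=C"))))))
})

test_that("terminal pattern confines hazardous bases to (near-)leaves", {
  jc <- jukesCantor()
  # pattern A only at leaves
  atLeaves <- attachAlignment(fig4Tree(), c(R = "A", S = "A", Z = "A",
                                            X = "C", Y = "C"))
  expect_true("X" %in% satStates(checkFormula(toPTS(atLeaves, jc),
                                              terminalFormula(cslAtom("x1=A")))))
  # pattern at an internal node (with a non-identical child, so the node
  # is not leaf-like): untimed fails, generous time bound holds
  atY <- attachAlignment(fig4Tree(), c(R = "A", S = "C", Z = "C",
                                       X = "C", Y = "A"))
  ptsY <- toPTS(atY, jc)
  expect_false("X" %in% satStates(checkFormula(ptsY,
    terminalFormula(cslAtom("x1=A")))))
  expect_true("X" %in% satStates(checkFormula(ptsY,
    terminalFormula(cslAtom("x1=A"), t = 50))))
  # vacuous satisfaction when the pattern is absent
  expect_true("X" %in% satStates(checkFormula(toPTS(
    attachAlignment(fig4Tree(), c(R = "C", S = "C", Z = "C",
                                  X = "C", Y = "C")), jc),
    terminalFormula(cslAtom("x1=G")))))
})

test_that("point-mutation formula thresholds on the embedded jump probability", {
  jc <- jukesCantor()
  # single child mutating A -> C
  tr <- attachAlignment(readNewick("(L:1)X;"), c(X = "A", L = "C"))
  pts <- toPTS(tr, jc)
  expect_true("X" %in% satStates(checkFormula(pts,
    pointMutationFormula(1, "A", "C", 1))))
  # leaf keeps its base: self-loop means no mutation in the next state
  expect_false("L" %in% satStates(checkFormula(pts,
    pointMutationFormula(1, "C", "A", 0.1))))
  # two equi-weight children, one mutating: threshold at the jump split
  tr2 <- attachAlignment(readNewick("(L1:1,L2:1)X;"),
                         c(X = "A", L1 = "A", L2 = "C"))
  pts2 <- toPTS(tr2, jc)
  pSplit <- probNext(toPTS(tr2, jc)@ctmc, "X", "x1=C")
  expect_true("X" %in% satStates(checkFormula(pts2,
    pointMutationFormula(1, "A", "C", pSplit - 1e-3))))
  expect_false("X" %in% satStates(checkFormula(pts2,
    pointMutationFormula(1, "A", "C", min(1, pSplit + 1e-3)))))
})

test_that("back-mutation formulas detect planted reversions and nothing else", {
  jc <- jukesCantor()
  # path A -> C -> A: reversion at the root
  rev3 <- attachAlignment(readNewick("((L:1)M:1)X;"),
                          c(X = "A", M = "C", L = "A"))
  expect_true("X" %in% satStates(checkFormula(toPTS(rev3, jc),
                                              hasBMFormula(1))))
  expect_false("X" %in% satStates(checkFormula(toPTS(rev3, jc),
                                               detectBMFormula(1))))
  # A -> C -> C: no reversion
  noRev <- attachAlignment(readNewick("((L:1)M:1)X;"),
                           c(X = "A", M = "C", L = "C"))
  expect_false("X" %in% satStates(checkFormula(toPTS(noRev, jc),
                                               hasBMFormula(1))))
  expect_true("X" %in% satStates(checkFormula(toPTS(noRev, jc),
                                              detectBMFormula(1))))
  # deeper reversion A -> C -> T -> A on a four-node path
  deep <- attachAlignment(readNewick("(((L:1)M2:1)M1:1)X;"),
                          c(X = "A", M1 = "C", M2 = "T", L = "A"))
  expect_true("X" %in% satStates(checkFormula(toPTS(deep, jc),
                                              hasBMFormula(1))))
})

test_that("qualitative P>=1 / P>0 reduce to CTL tree-walking semantics", {
  jc <- jukesCantor()
  set.seed(171)
  for (k in 1:20) {
    tr <- randomLabeledTree(sample(3:8, 1), 2, seed = 2000 + k)
    pts <- toPTS(tr, jc)
    prop <- sprintf("x%d=%s", sample(1:2, 1), sample(c("A","C","G","T"), 1))
    ids <- nodeIds(tr)
    ag <- satStates(checkFormula(pts, sprintf("P>=1[G %s]", prop)))
    af <- satStates(checkFormula(pts, sprintf("P>=1[F %s]", prop)))
    ef <- satStates(checkFormula(pts, sprintf("P>0[F %s]", prop)))
    expect_setequal(ag, ids[treeOracle(tr, "AG", prop)])
    expect_setequal(af, ids[treeOracle(tr, "AF", prop)])
    expect_setequal(ef, ids[treeOracle(tr, "EF", prop)])
  }
})
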