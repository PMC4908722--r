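# Shared fixtures: random chains/models and independent oracles used to
# cross-check the analysis code. The oracles deliberately avoid the code
# paths they validate (direct tree walks, closed forms, power series).

# Random CTMC with every state labeled by its own name plus random extras.
randomChain <- function(nStates, density = 0.6, props = c("a", "b")) {
  s <- paste0("s", seq_len(nStates))
  R <- matrix(stats::rexp(nStates^2), nStates, nStates,
              dimnames = list(s, s))
  diag(R) <- 0
  R[matrix(stats::runif(nStates^2) > density, nStates, nStates)] <- 0
  labels <- lapply(s, function(x)
    c(x, props[stats::runif(length(props)) < 0.5]))
  names(labels) <- s
  ctmc(R, initial = s[1], labels = labels)
}

# Formula satisfied in exactly the given states (each state is labeled
# with its own name by randomChain).
setFormula <- function(stateIds) {
  if (length(stateIds) == 0) return(cslNot(cslTrue()))
  Reduce(cslOr, lapply(stateIds, cslAtom))
}

# Random GTR model with dispersed frequencies and exchangeabilities.
randomGTR <- function() {
  f <- stats::rgamma(4, 5, 1); f <- f / sum(f)
  names(f) <- c("A", "C", "G", "T")
  e <- stats::setNames(stats::rgamma(6, 2, 1),
                       c("AC", "AG", "AT", "CG", "CT", "GT"))
  gtr(e, f)
}

# The worked four-taxon topology: root X with children Y and Z, Y with
# leaf children R and S.
fig4Tree <- function(dXY = 1, dXZ = 2, dYR = 1, dYS = 1) {
  readNewick(sprintf("((R:%g,S:%g)Y:%g,Z:%g)X;", dYR, dYS, dXY, dXZ))
}

# Truncated power series sum_{i<=k} (Qt)^i / i!, summed to machine
# convergence; the naive definition of the matrix exponential, used as an
# independent oracle on small well-conditioned chains.
seriesExpm <- function(Q, t) {
  n <- nrow(Q)
  term <- diag(n); dimnames(term) <- dimnames(Q)
  acc <- term
  for (i in 1:200) {
    term <- term %*% Q * (t / i)
    acc <- acc + term
    if (max(abs(term)) < 1e-18) break
  }
  acc
}

# ---- qualitative tree-walking oracle (independent of the CTMC engine) --

.holdsAt <- function(tree, i, prop) {
  m <- regmatches(prop, regexec("^x([0-9]+)=([ACGT])$", prop))[[1]]
  stopifnot(length(m) == 3)
  substr(tree@sequences[i], as.integer(m[2]), as.integer(m[2])) == m[3]
}

# CTL over the finite tree with implicit leaf self-loops:
#   AG p : p at every node of the subtree
#   AF p : every root-to-leaf path below (and incl.) the node meets p
#   EF p : some descendant-or-self satisfies p
treeOracle <- function(tree, op, prop) {
  n <- length(tree@ids)
  kids <- vector("list", n)
  for (i in seq_len(n)[-1])
    kids[[tree@parent[i]]] <- c(kids[[tree@parent[i]]], i)
  rec <- function(i) {
    h <- .holdsAt(tree, i, prop)
    ch <- kids[[i]]
    sub <- vapply(ch, rec, logical(1))
    switch(op,
      AG = h && all(sub),
      AF = h || (length(ch) > 0 && all(sub)),
      EF = h || any(sub))
  }
  out <- vapply(seq_len(n), rec, logical(1))
  stats::setNames(out, tree@ids)
}

# Direct ancestral-path scanner for reversions: some node holds base s at
# a site, a descendant differs, and a deeper descendant regains s.
hasReversion <- function(tree) {
  n <- length(tree@ids)
  ns <- tree@nsites
  kids <- vector("list", n)
  for (i in seq_len(n)[-1])
    kids[[tree@parent[i]]] <- c(kids[[tree@parent[i]]], i)
  baseAt <- function(i, l) substr(tree@sequences[i], l, l)
  found <- FALSE
  scan <- function(i, l, sigma, seenDiff) {
    b <- baseAt(i, l)
    if (seenDiff && b == sigma) { found <<- TRUE; return() }
    for (c in kids[[i]]) scan(c, l, sigma, seenDiff || b != sigma)
  }
  for (i in seq_len(n)) for (l in seq_len(ns)) {
    if (found) return(TRUE)
    scan(i, l, baseAt(i, l), FALSE)
  }
  found
}

# Random fully labeled Yule tree (uniform random bases at every node:
# labels need not follow any model for the qualitative logic tests).
randomLabeledTree <- function(nTips, nSites, seed) {
  tr <- yuleTree(nTips, seed = seed)
  ids <- nodeIds(tr)
  seqs <- vapply(ids, function(i)
    paste(sample(c("A", "C", "G", "T"), nSites, replace = TRUE),
          collapse = ""), character(1))
  attachAlignment(tr, seqs)
}

# Reversion-free labeling: along every lineage each site only ever moves
# forward through a fixed base order, so no base can reoccur.
monotoneLabeledTree <- function(nTips, nSites, seed, stepProb = 0.3) {
  tr <- yuleTree(nTips, seed = seed)
  n <- length(nodeIds(tr))
  idx <- matrix(1L, n, nSites)
  for (i in seq_len(n)[-1]) {
    p <- tr@parent[i]
    adv <- stats::runif(nSites) < stepProb
    idx[i, ] <- pmin(idx[p, ] + ifelse(adv, 1L, 0L), 4L)
  }
  seqs <- apply(idx, 1, function(r)
    paste(c("A", "C", "G", "T")[r], collapse = ""))
  attachAlignment(tr, stats::setNames(seqs, nodeIds(tr)))
}

# Plant an explicit reversion: pick a root-to-leaf path with >= 3 nodes
# and force sigma -> other -> sigma at site 1 along it.
plantReversion <- function(tree) {
  depth <- vapply(nodeIds(tree), function(id) {
    i <- match(id, tree@ids); d <- 0L
    while (!is.na(tree@parent[i])) { d <- d + 1L; i <- tree@parent[i] }
    d
  }, integer(1))
  leaf <- leafIds(tree)[which.max(depth[leafIds(tree)])]
  path <- leaf
  i <- match(leaf, tree@ids)
  while (!is.na(tree@parent[i])) {
    i <- tree@parent[i]
    path <- c(tree@ids[i], path)
  }
  stopifnot(length(path) >= 3)
  put <- function(id, b) {
    s <- tree@sequences[[id]]
    substr(s, 1, 1) <- b
    tree@sequences[[id]] <<- s
  }
  put(path[1], "A"); put(path[2], "C"); put(path[3], "A")
  tree
}
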