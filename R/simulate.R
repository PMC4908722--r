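# Evaluate expr under a given RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) stop("a seed is required for reproducibility")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a random tree under the backward Yule construction
#'
#' Starts from \code{nTips} present-day lineages and repeatedly merges a
#' uniformly chosen pair after an exponential waiting time with rate
#' k * birthRate for k extant lineages, until one root lineage remains
#' (a coalescent-style backward pure-birth construction). The result is a
#' rooted binary tree with positive branch lengths; leaves are named
#' t1..tn and internal nodes N1.. in preorder. Only relative branch
#' lengths matter for the demonstrations, so the default birth rate is 1.
#'
#' @param nTips number of leaves, >= 2.
#' @param birthRate lineage birth rate (events per unit time).
#' @param seed RNG seed (mandatory: simulation is reproducible by
#'   contract).
#' @return a [PhyloTree-class] without sequences.
#' @examples
#' yuleTree(5, seed = 1)
#' @export
yuleTree <- function(nTips, birthRate = 1, seed) {
  if (nTips < 2) stop("nTips must be >= 2")
  if (birthRate <= 0) stop("birthRate must be positive")
  .withSeed(seed, {
    nInt <- nTips - 1L
    total <- nTips + nInt
    age <- c(rep(0, nTips), rep(NA_real_, nInt))
    left <- right <- integer(total)
    active <- seq_len(nTips)
    tNow <- 0
    nxt <- nTips
    while (length(active) > 1) {
      k <- length(active)
      tNow <- tNow + stats::rexp(1, rate = k * birthRate)
      pair <- sample(k, 2)
      nxt <- nxt + 1L
      left[nxt] <- active[pair[1]]
      right[nxt] <- active[pair[2]]
      age[nxt] <- tNow
      active <- c(active[-pair], nxt)
    }
    root <- nxt
    ids <- character(total); parent <- integer(total); lens <- numeric(total)
    ord <- 0L; autoN <- 0L
    visit <- function(node, parentPos) {
      ord <<- ord + 1L
      my <- ord
      if (node <= nTips) ids[my] <<- paste0("t", node)
      else { autoN <<- autoN + 1L; ids[my] <<- paste0("N", autoN) }
      parent[my] <<- parentPos
      lens[my] <<- if (is.na(parentPos)) NA_real_
                   else age[if (parentPos == 1L) root else .nodeOf[parentPos]] - age[node]
      .nodeOf[my] <<- node
      if (node > nTips) { visit(left[node], my); visit(right[node], my) }
    }
    .nodeOf <- integer(total)
    visit(root, NA_integer_)
    new("PhyloTree", ids = ids, parent = parent, lengths = lens,
        sequences = stats::setNames(rep(NA_character_, total), ids),
        nsites = 0L,
        ancestralFixed = stats::setNames(rep(FALSE, total), ids))
  })
}

#' Evolve sequences along a tree
#'
#' Draws the root sequence from the model's stationary frequencies and
#' each child sequence site-by-site from the parent's, using the row of
#' the transition matrix P(d) at the branch length (sites evolve
#' independently). All nodes, internal ones included, end up labeled;
#' use [dropAncestral()] to keep only the leaf data before a likelihood
#' analysis.
#'
#' @param tree a [PhyloTree-class] with branch lengths.
#' @param model a [MutationModel-class].
#' @param nSites alignment length to simulate.
#' @param seed RNG seed (mandatory).
#' @return the fully labeled [PhyloTree-class].
#' @export
evolveSequences <- function(tree, model, nSites, seed) {
  .withSeed(seed, {
    n <- length(tree@ids)
    Pof <- .pCache(model)
    baseIdx <- matrix(NA_integer_, n, nSites)
    baseIdx[1, ] <- sample.int(4, nSites, replace = TRUE,
                               prob = model@freqs)
    for (i in seq_len(n)[-1]) {
      P <- Pof(tree@lengths[i])
      pb <- baseIdx[tree@parent[i], ]
      out <- integer(nSites)
      for (b in unique(pb)) {
        sel <- pb == b
        out[sel] <- sample.int(4, sum(sel), replace = TRUE, prob = P[b, ])
      }
      baseIdx[i, ] <- out
    }
    tree@sequences <- stats::setNames(
      apply(baseIdx, 1, function(r) paste(DNA_BASES_[r], collapse = "")),
      tree@ids)
    tree@nsites <- as.integer(nSites)
    tree@ancestralFixed[] <- FALSE
    tree
  })
}

#' Drop simulated/unwanted ancestral sequences
#'
#' Keeps only the leaf labels, leaving internal nodes unknown — the input
#' situation of a likelihood analysis.
#'
#' @param tree a [PhyloTree-class].
#' @return the tree with internal sequences removed.
#' @export
dropAncestral <- function(tree) {
  keep <- tree@ids %in% leafIds(tree)
  tree@sequences[!keep] <- NA_character_
  tree@ancestralFixed[] <- FALSE
  tree
}

#' Sample jump trajectories of a CTMC
#'
#' Gillespie sampling of the race semantics: in state s the holding time
#' is exponential with the exit rate E(s), and the jump target follows
#' the embedded-DTMC row (a higher rate prioritizes its transition; equal
#' rates are equally probable). Trajectories are truncated at the
#' horizon; absorbing states hold forever.
#'
#' @param x a [CTMC-class].
#' @param s0 start state.
#' @param horizon truncation time.
#' @param n number of trajectories.
#' @param seed RNG seed (mandatory).
#' @return a [TrajectorySet-class].
#' @export
samplePaths <- function(x, s0, horizon, n, seed) {
  stopifnot(is(x, "CTMC"))
  i0 <- match(s0, x@states)
  if (is.na(i0)) stop("unknown start state: ", s0)
  emb <- embed(x)
  E <- emb@exitRates
  P <- emb@probs
  .withSeed(seed, {
    stm <- matrix(NA_integer_, n, 4)
    ttm <- matrix(NA_real_, n, 4)
    stm[, 1] <- i0
    ttm[, 1] <- 0
    cur <- rep(i0, n)
    tcur <- rep(0, n)
    active <- E[cur] > 0
    j <- 1L
    while (any(active)) {
      dt <- stats::rexp(sum(active), rate = E[cur[active]])
      tnew <- tcur[active] + dt
      stay <- tnew > horizon
      idxAct <- which(active)
      # horizon passed: freeze
      if (any(stay)) active[idxAct[stay]] <- FALSE
      move <- idxAct[!stay]
      if (length(move)) {
        j <- j + 1L
        if (j > ncol(stm)) {
          stm <- cbind(stm, matrix(NA_integer_, n, ncol(stm)))
          ttm <- cbind(ttm, matrix(NA_real_, n, ncol(ttm)))
        }
        newState <- integer(length(move))
        fromStates <- cur[move]
        for (s in unique(fromStates)) {
          sel <- fromStates == s
          newState[sel] <- sample.int(length(x@states), sum(sel),
                                      replace = TRUE, prob = P[s, ])
        }
        cur[move] <- newState
        tcur[move] <- tnew[!stay]
        stm[cbind(move, j)] <- newState
        ttm[cbind(move, j)] <- tcur[move]
        active[move] <- E[newState] > 0
      }
    }
    new("TrajectorySet", states = stm, times = ttm,
        stateNames = x@states, horizon = horizon)
  })
}

setMethod("show", "TrajectorySet", function(object) {
  cat("TrajectorySet:", nrow(object@states), "trajectories, horizon",
      object@horizon, "\n")
})

#' State occupied by each trajectory at a time point
#'
#' @param ts a [TrajectorySet-class].
#' @param t time in [0, horizon].
#' @return character vector of states, one per trajectory.
#' @export
stateAtTime <- function(ts, t) {
  if (t > ts@horizon) stop("t beyond the sampling horizon")
  idx <- integer(nrow(ts@states))
  for (j in seq_len(ncol(ts@states))) {
    upd <- !is.na(ts@times[, j]) & ts@times[, j] <= t
    idx[upd] <- ts@states[upd, j]
  }
  ts@stateNames[idx]
}

#' Monte-Carlo estimate of a time-bounded until probability
#'
#' Fraction of trajectories satisfying psi U [0,t] phi: some state in phi
#' is entered by time t with every earlier state in psi.
#'
#' @param ts a [TrajectorySet-class] started in the state of interest.
#' @param psiStates,phiStates character vectors of state names.
#' @param t time bound, <= horizon.
#' @return estimated probability.
#' @export
mcBoundedUntil <- function(ts, psiStates, phiStates, t) {
  if (t > ts@horizon) stop("t beyond the sampling horizon")
  psi <- match(psiStates, ts@stateNames)
  phi <- match(phiStates, ts@stateNames)
  n <- nrow(ts@states)
  sat <- rep(FALSE, n)
  failed <- rep(FALSE, n)
  for (j in seq_len(ncol(ts@states))) {
    s <- ts@states[, j]
    tm <- ts@times[, j]
    open <- !sat & !failed & !is.na(s)
    inTime <- open & tm <= t
    sat[inTime & s %in% phi] <- TRUE
    failed[inTime & !(s %in% phi) & !(s %in% psi)] <- TRUE
    failed[open & tm > t] <- TRUE   # entered after the deadline unsatisfied
  }
  mean(sat)
}

#' Likelihood-scaling experiment harness
#'
#' Reproduces the synthetic study design: for each tree size, generate
#' replicate random Yule trees, evolve single-base genomes with a uniform
#' root distribution, score each tree with the chosen engine(s), and
#' record log-likelihoods, the gap between the heuristic bound and the
#' exact value (when both are computed) and the harmonic-mean wall time
#' per size. Timing is a reporting convention only — it is never asserted.
#'
#' @param sizes integer vector of tip counts.
#' @param replicates trees per size.
#' @param mode \code{"exact"}, \code{"upper_bound"} or \code{"both"}.
#' @param seed base RNG seed; replicate r of size s runs on a seed
#'   derived deterministically from it.
#' @param nSites sites per genome (the study uses 1).
#' @param model substitution model (default Jukes-Cantor, nu = 1).
#' @param birthRate Yule birth rate.
#' @param variant heuristic variant passed to [upperBound()].
#' @return data.frame with one row per (size, replicate): columns
#'   \code{size}, \code{replicate}, \code{seed}, \code{log_likelihood},
#'   \code{log_upper_bound}, \code{bound_gap} (upper - exact, likelihood
#'   scale) and \code{time_s}; attribute \code{harmonic_mean_time} gives
#'   the per-size harmonic mean.
#' @export
experimentHarness <- function(sizes, replicates, mode = c("exact",
                              "upper_bound", "both"), seed, nSites = 1,
                              model = jukesCantor(), birthRate = 1,
                              variant = "independent") {
  mode <- match.arg(mode)
  stopifnot(replicates >= 1)
  rows <- list()
  k <- 0L
  for (sz in sizes) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      repSeed <- (seed + 7919L * k) %% .Machine$integer.max
      tr <- yuleTree(sz, birthRate, seed = repSeed)
      tr <- evolveSequences(tr, model, nSites, seed = repSeed + 1L)
      tr <- dropAncestral(tr)
      t0 <- proc.time()[["elapsed"]]
      ll <- ub <- NA_real_
      if (mode %in% c("exact", "both"))
        ll <- logLikelihood(prune(tr, model))
      if (mode %in% c("upper_bound", "both"))
        ub <- upperBound(tr, model, variant = variant, log = TRUE)
      elapsed <- proc.time()[["elapsed"]] - t0
      gap <- if (mode == "both") exp(ub) - exp(ll) else NA_real_
      rows[[k]] <- data.frame(size = sz, replicate = r, seed = repSeed,
                              log_likelihood = ll, log_upper_bound = ub,
                              bound_gap = gap, time_s = elapsed)
    }
  }
  out <- do.call(rbind, rows)
  hm <- vapply(split(out$time_s, out$size), function(v) {
    v <- pmax(v, .Machine$double.eps)
    length(v) / sum(1 / v)
  }, numeric(1))
  attr(out, "harmonic_mean_time") <- hm
  out
}
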