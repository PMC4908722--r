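# Transition-matrix cache keyed by branch length: each distinct length is
# exponentiated once per evaluation (the factorization the partial-result
# cache exists to exploit).
.pCache <- function(model) {
  env <- new.env(parent = emptyenv())
  function(d) {
    key <- format(d, digits = 17)
    P <- get0(key, envir = env)
    if (is.null(P)) {
      P <- transitionMatrix(model, d)
      assign(key, P, envir = env)
    }
    P
  }
}

.seqMatrix <- function(tree) {
  # integer base indices [node, site]; NA rows for unlabeled nodes
  n <- length(tree@ids)
  out <- matrix(NA_integer_, n, max(tree@nsites, 1L))
  for (i in seq_len(n)) {
    s <- tree@sequences[i]
    if (!is.na(s))
      out[i, ] <- match(strsplit(s, "")[[1]], DNA_BASES_)
  }
  out
}

#' Exact tree likelihood by Felsenstein pruning
#'
#' Post-order dynamic program over partial likelihoods: for node X and
#' base i at site l,
#' \deqn{L^l_{X,i} = \prod_{c \in children(X)} \sum_j P_{ij}(d_{Xc}) L^l_{c,j}}
#' with leaf partials 1 for the observed base and 0 otherwise (present-day
#' taxa have maximum likelihood). The root combines with the stationary
#' frequencies, \eqn{L^l_{Root} = \sum_i f_i L^l_{Root,i}}, and the total
#' is the product over sites (site independence). Internal nodes with
#' fixed (e.g. parsimony-estimated) sequences keep the 1/0 constants for
#' their known base. Each partial is computed exactly once
#' (\code{evalCount} == #nodes x #sites x 4); partials are rescaled when
#' they drop below 1e-280 and the log total accumulates the scaling, so
#' long alignments do not underflow.
#'
#' @param tree a [PhyloTree-class] with all leaves labeled.
#' @param model a [MutationModel-class].
#' @param ... unused.
#' @return a [LikelihoodTable-class].
#' @examples
#' tr <- attachAlignment(readNewick("(L1:0.5,L2:0.5)R;"),
#'                       c(L1 = "A", L2 = "A"))
#' logLikelihood(prune(tr, jukesCantor()))
#' @rdname prune
#' @export
setMethod("prune", "PhyloTree", function(tree, model, ...) {
  n <- length(tree@ids)
  if (n == 0) stop("empty tree")
  ns <- tree@nsites
  if (ns == 0) stop("no alignment attached")
  leaves <- which(!seq_len(n) %in% tree@parent)
  if (anyNA(tree@sequences[leaves])) stop("unlabeled leaf")
  kids <- .childIndex(tree)
  seqIdx <- .seqMatrix(tree)
  Pof <- .pCache(model)
  partials <- array(NA_real_, c(n, ns, 4),
                    dimnames = list(tree@ids, NULL, DNA_BASES_))
  scaleLog <- matrix(0, n, ns, dimnames = list(tree@ids, NULL))
  evalCount <- 0L
  for (i in rev(seq_len(n))) {           # reverse preorder = post-order
    ch <- kids[[i]]
    if (length(ch) == 0) {
      L <- matrix(0, 4, ns)
      L[cbind(seqIdx[i, ], seq_len(ns))] <- 1
    } else {
      L <- matrix(1, 4, ns)
      for (c in ch) {
        Lc <- t(partials[c, , , drop = FALSE][1, , ])   # 4 x ns
        if (ns == 1) Lc <- matrix(partials[c, 1, ], 4, 1)
        L <- L * (Pof(tree@lengths[c]) %*% Lc)
        scaleLog[i, ] <- scaleLog[i, ] + scaleLog[c, ]
      }
      if (tree@ancestralFixed[i] && !is.na(tree@sequences[i])) {
        mask <- matrix(0, 4, ns)
        mask[cbind(seqIdx[i, ], seq_len(ns))] <- 1
        L <- L * mask
      }
      mx <- apply(L, 2, max)
      low <- mx < 1e-280 & mx > 0
      if (any(low)) {
        L[, low] <- L[, low, drop = FALSE] /
          rep(mx[low], each = 4)
        scaleLog[i, low] <- scaleLog[i, low] + log(mx[low])
      }
    }
    partials[i, , ] <- t(L)
    evalCount <- evalCount + 4L * ns
  }
  rootL <- if (ns == 1) matrix(partials[1, 1, ], 4, 1) else
    t(partials[1, , , drop = FALSE][1, , ])
  siteCore <- as.numeric(model@freqs %*% rootL)
  siteLik <- siteCore * exp(scaleLog[1, ])
  siteLogLik <- ifelse(siteCore > 0, log(siteCore) + scaleLog[1, ], -Inf)
  new("LikelihoodTable",
      partials = partials, scaleLog = scaleLog,
      siteLik = siteLik, siteLogLik = siteLogLik,
      total = prod(siteLik), logTotal = sum(siteLogLik),
      evalCount = evalCount)
})

#' @rdname likelihood-accessors
#' @param x a [LikelihoodTable-class].
#' @param node node identifier.
#' @aliases siteLikelihoods totalLikelihood logLikelihood
#'   partialLikelihoods
#' @export
setMethod("siteLikelihoods", "LikelihoodTable", function(x) x@siteLik)
#' @rdname likelihood-accessors
#' @export
setMethod("totalLikelihood", "LikelihoodTable", function(x) x@total)
#' @rdname likelihood-accessors
#' @export
setMethod("logLikelihood", "LikelihoodTable", function(x) x@logTotal)
#' @rdname likelihood-accessors
#' @export
setMethod("partialLikelihoods", "LikelihoodTable", function(x, node) {
  out <- x@partials[node, , , drop = FALSE][1, , ]
  if (dim(x@partials)[2] == 1)
    out <- matrix(x@partials[node, 1, ], 1, 4,
                  dimnames = list(NULL, DNA_BASES_))
  out * exp(x@scaleLog[node, ])
})

setMethod("show", "LikelihoodTable", function(object) {
  cat("LikelihoodTable:", dim(object@partials)[1], "nodes x",
      dim(object@partials)[2], "sites\n")
  cat("  log-likelihood:", format(object@logTotal, digits = 10), "\n")
})

#' Brute-force likelihood by ancestral enumeration
#'
#' The unfactorized sum: for each site, sum over all assignments of bases
#' to the free internal nodes of the product of stationary root frequency
#' and per-branch transition probabilities, then the product over sites.
#' Exponential in the number of free internal nodes (4^k terms); refuses
#' beyond \code{maxInternal}. This is the independent oracle the pruning
#' recursion is verified against.
#'
#' @param tree a labeled [PhyloTree-class].
#' @param model a [MutationModel-class].
#' @param maxInternal refuse enumeration beyond this many free internal
#'   nodes.
#' @return total likelihood (numeric).
#' @export
bruteForceLikelihood <- function(tree, model, maxInternal = 10L) {
  n <- length(tree@ids)
  ns <- tree@nsites
  if (ns == 0) stop("no alignment attached")
  leaves <- which(!seq_len(n) %in% tree@parent)
  if (anyNA(tree@sequences[leaves])) stop("unlabeled leaf")
  free <- which(is.na(tree@sequences))
  if (length(free) > maxInternal)
    stop("enumeration over ", length(free),
         " internal nodes refused (limit ", maxInternal,
         "); use prune() instead")
  seqIdx <- .seqMatrix(tree)
  Pof <- .pCache(model)
  f <- model@freqs
  total <- 1
  G <- 4L^length(free)
  grid <- as.matrix(do.call(expand.grid, rep(list(1:4), length(free))))
  for (l in seq_len(ns)) {
    # assignment matrix: rows nodes, columns the 4^k enumerated states
    A <- matrix(seqIdx[, l], n, G)
    if (length(free)) A[free, ] <- t(grid)
    term <- f[A[1, ]]
    for (i in seq_len(n)[-1]) {
      P <- Pof(tree@lengths[i])
      term <- term * P[cbind(A[tree@parent[i], ], A[i, ])]
    }
    total <- total * sum(term)
  }
  unname(total)
}

#' Linear-time upper-bound heuristic for the tree likelihood
#'
#' Relaxes the exact sum over ancestral states to per-leaf root-to-tip
#' transitions: with D_Z the root-to-leaf distance and Z(l) the observed
#' base,
#' \itemize{
#' \item variant \code{"shared-root"}: per site
#'   \eqn{U^l = \max_i f_i \prod_Z P_{i,Z(l)}(D_Z)} — all leaves hang as
#'   disjoint routes from one common root base;
#' \item variant \code{"independent"}: per site
#'   \eqn{U^l = \prod_Z \max_i P_{i,Z(l)}(D_Z)} — each leaf path maximized
#'   separately.
#' }
#' The total is the product over sites. Internal-node sequences are
#' ignored: only the leaves carry certain DNA values. Runtime is linear in
#' the number of leaves (one 4x4 exponentiation per distinct root-to-leaf
#' distance). Its status as an upper bound of the exact likelihood is an
#' empirical claim, checked by the experiment harness, not a theorem of
#' this package.
#'
#' @param tree a [PhyloTree-class] with labeled leaves.
#' @param model a [MutationModel-class].
#' @param variant \code{"independent"} (canonical) or
#'   \code{"shared-root"}.
#' @param log return the natural log of the bound instead.
#' @return numeric likelihood bound (or its log).
#' @export
upperBound <- function(tree, model,
                       variant = c("independent", "shared-root"),
                       log = FALSE) {
  variant <- match.arg(variant)
  ns <- tree@nsites
  if (ns == 0) stop("no alignment attached")
  leaves <- leafIds(tree)
  if (anyNA(tree@sequences[leaves])) stop("unlabeled leaf")
  Pof <- .pCache(model)
  # rows: leaf; cols: site; list of 4-row matrices P[, Z(l)](D_Z)
  perLeaf <- lapply(leaves, function(z) {
    P <- Pof(rootToLeafDistance(tree, z))
    b <- strsplit(tree@sequences[[z]], "")[[1]]
    P[, b, drop = FALSE]                  # 4 x ns
  })
  siteLog <- numeric(ns)
  if (variant == "independent") {
    for (m in perLeaf) siteLog <- siteLog + log(apply(m, 2, max))
  } else {
    acc <- matrix(0, 4, ns)               # log prod_Z P_i,Z(l)(D_Z)
    for (m in perLeaf) acc <- acc + log(m)
    siteLog <- apply(acc + log(model@freqs), 2, max)
  }
  if (log) sum(siteLog) else exp(sum(siteLog))
}

#' Per-site log-likelihood report
#'
#' @param table a [LikelihoodTable-class].
#' @return data.frame with columns \code{site}, \code{likelihood},
#'   \code{logLik}; attributes \code{total} and \code{logTotal}. Sites
#'   with zero likelihood report \code{-Inf} with a warning.
#' @export
logReport <- function(table) {
  stopifnot(is(table, "LikelihoodTable"))
  if (any(table@siteLik == 0))
    warning("site(s) with zero likelihood: log reported as -Inf")
  out <- data.frame(site = seq_along(table@siteLik),
                    likelihood = table@siteLik,
                    logLik = table@siteLogLik)
  attr(out, "total") <- table@total
  attr(out, "logTotal") <- table@logTotal
  out
}
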