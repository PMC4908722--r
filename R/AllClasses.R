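#' @import methods
NULL

.STRUCT_TOL <- 1e-12   # structural identities (row sums of Q, P_emb)
.NUM_TOL    <- 1e-9    # numerical identities (row sums of P_t, comparators)

#' Continuous-time Markov chain
#'
#' A finite labeled CTMC: an ordered state set, a nonnegative transition
#' rate matrix (events per unit time), a nonempty set of initial states and
#' a labeling assigning each state the atomic propositions true of it.
#' Holding times are exponential; a transition s -> s' exists iff its rate
#' is positive, and fires within t time units with probability
#' 1 - exp(-R(s,s') t).
#'
#' @slot states ordered character vector of state identifiers (matrix row
#'   order; stable across calls).
#' @slot rates square numeric matrix of transition rates, dimnames = states.
#' @slot initial character vector, nonempty subset of \code{states}.
#' @slot labels named list (one entry per state) of character vectors of
#'   atomic propositions.
#' @seealso [ctmc()], [generator()], [transient()], [embed()]
#' @export
setClass("CTMC", representation(
  states  = "character",
  rates   = "matrix",
  initial = "character",
  labels  = "list"
), validity = function(object) {
  s <- object@states
  R <- object@rates
  msg <- character()
  if (anyDuplicated(s)) msg <- c(msg, "duplicated state identifiers")
  if (!is.numeric(R) || nrow(R) != length(s) || ncol(R) != length(s))
    msg <- c(msg, "rate matrix must be square over the state set")
  else {
    if (!identical(rownames(R), s) || !identical(colnames(R), s))
      msg <- c(msg, "rate matrix dimnames must equal the state order")
    if (any(!is.finite(R)) || any(R < 0))
      msg <- c(msg, "all rates must be finite and >= 0")
  }
  if (length(object@initial) == 0 || !all(object@initial %in% s))
    msg <- c(msg, "initial states must be a nonempty subset of the states")
  if (!identical(sort(names(object@labels)), sort(s)))
    msg <- c(msg, "every state needs a labeling entry (possibly empty)")
  if (length(msg)) msg else TRUE
})

#' Embedded discrete-time jump chain of a CTMC
#'
#' @slot probs square stochastic matrix of jump probabilities
#'   P_emb(s,s') = R(s,s')/E(s); absorbing states (exit rate 0) get a unit
#'   self-loop.
#' @slot exitRates named numeric vector of exit rates E(s) = sum_s' R(s,s').
#' @export
setClass("EmbeddedDTMC", representation(
  probs = "matrix",
  exitRates = "numeric"
), validity = function(object) {
  P <- object@probs
  msg <- character()
  if (max(abs(rowSums(P) - 1)) > .STRUCT_TOL)
    msg <- c(msg, "embedded jump rows must sum to 1")
  if (any(P < 0) || any(P > 1 + .STRUCT_TOL))
    msg <- c(msg, "jump probabilities must lie in [0,1]")
  if (any(object@exitRates < 0))
    msg <- c(msg, "exit rates must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Parameterized DNA substitution model
#'
#' One of JC, K80, F81 or GTR over the fixed alphabet (A, C, G, T). The
#' model induces a reversible rate matrix Q(i,j) = s_ij f_j scaled so the
#' expected number of substitutions per site per unit time at stationarity
#' equals \code{nu}; with nu = 1 branch lengths read as expected
#' substitutions per site.
#'
#' @slot name model name: "JC", "K80", "F81" or "GTR".
#' @slot nu overall substitution rate (substitutions/site/unit time).
#' @slot freqs stationary base frequencies, named A,C,G,T, summing to 1.
#' @slot exch symmetric exchangeabilities, named AC,AG,AT,CG,CT,GT.
#' @export
setClass("MutationModel", representation(
  name  = "character",
  nu    = "numeric",
  freqs = "numeric",
  exch  = "numeric"
), validity = function(object) {
  msg <- character()
  if (!object@name %in% c("JC", "K80", "F81", "GTR"))
    msg <- c(msg, "name must be one of JC, K80, F81, GTR")
  if (length(object@nu) != 1 || !is.finite(object@nu) || object@nu <= 0)
    msg <- c(msg, "nu must be a single positive finite number")
  f <- object@freqs
  if (!identical(names(f), DNA_BASES_) || any(f <= 0) ||
      abs(sum(f) - 1) > .STRUCT_TOL)
    msg <- c(msg, "freqs must be positive, named A,C,G,T and sum to 1")
  e <- object@exch
  if (!identical(names(e), PAIR_NAMES_) || any(e <= 0))
    msg <- c(msg, "exchangeabilities must be positive and named AC,AG,AT,CG,CT,GT")
  if (object@name == "JC" && max(abs(f - 0.25)) > .STRUCT_TOL)
    msg <- c(msg, "JC requires uniform base frequencies")
  if (length(msg)) msg else TRUE
})

DNA_BASES_  <- c("A", "C", "G", "T")
PAIR_NAMES_ <- c("AC", "AG", "AT", "CG", "CT", "GT")

#' Rooted phylogenetic tree with branch lengths and optional sequences
#'
#' Nodes are stored in preorder; each non-root node records its parent and
#' the length of the branch above it (time units / expected substitutions
#' when nu = 1). Leaves carry mandatory aligned sequences over A,C,G,T once
#' an alignment is attached; internal nodes may carry fixed (e.g.
#' parsimony-estimated) ancestral sequences.
#'
#' @slot ids node identifiers in preorder (root first).
#' @slot parent integer index of each node's parent (NA at the root).
#' @slot lengths numeric branch length above each node (NA at the root).
#' @slot sequences named character vector of per-node sequences; NA where
#'   unlabeled.
#' @slot nsites alignment length (0 before an alignment is attached).
#' @slot ancestralFixed named logical: internal nodes whose sequence was
#'   supplied (treated as known in the likelihood).
#' @export
setClass("PhyloTree", representation(
  ids       = "character",
  parent    = "integer",
  lengths   = "numeric",
  sequences = "character",
  nsites    = "integer",
  ancestralFixed = "logical"
), validity = function(object) {
  n <- length(object@ids)
  msg <- character()
  if (anyDuplicated(object@ids)) msg <- c(msg, "duplicated node identifiers")
  if (length(object@parent) != n || length(object@lengths) != n)
    msg <- c(msg, "parent/lengths must align with ids")
  roots <- which(is.na(object@parent))
  if (length(roots) != 1 || roots != 1L)
    msg <- c(msg, "exactly one root, stored first")
  if (n > 1) {
    p <- object@parent[-1]
    if (any(p >= seq(2L, n)) || any(p < 1L))
      msg <- c(msg, "nodes must be stored in preorder (parent before child)")
    bl <- object@lengths[-1]
    if (any(!is.finite(bl)) || any(bl < 0))
      msg <- c(msg, "branch lengths must be finite and >= 0")
  }
  sq <- object@sequences[!is.na(object@sequences)]
  if (length(sq)) {
    if (length(unique(nchar(sq))) != 1)
      msg <- c(msg, "all sequences must share one alignment length")
    if (any(grepl("[^ACGT]", sq)))
      msg <- c(msg, "sequences must use only A,C,G,T")
  }
  if (length(msg)) msg else TRUE
})

#' Tree-as-transition-system
#'
#' A phylogenetic tree converted into a labeled probabilistic transition
#' system: states are tree nodes labeled with their per-site nucleotide
#' propositions (x<i>=<base>), edges carry the n-site product of
#' substitution probabilities at the branch length, and every leaf gets a
#' unit self-loop so that all paths are infinite.
#'
#' @slot ctmc the underlying [CTMC-class].
#' @slot leafStates states that received self-loops.
#' @export
setClass("TreePTS", representation(
  ctmc = "CTMC",
  leafStates = "character"
))

#' Cached Felsenstein partial likelihoods
#'
#' Partial likelihoods L^l_{X,i} (probability of the observed leaf data
#' below node X at site l given X carries base i), per-site root
#' likelihoods, and their product, the tree likelihood.
#'
#' @slot partials 3-d array [node, site, base] of partial likelihoods on
#'   the original (unscaled) scale combined with \code{scaleLog}.
#' @slot scaleLog matrix [node, site] of log scaling factors applied to
#'   guard against underflow; the true partial is
#'   \code{partials * exp(scaleLog)}.
#' @slot siteLik numeric vector of per-site root likelihoods L^l_Root.
#' @slot siteLogLik per-site natural-log likelihoods.
#' @slot total product of site likelihoods (may underflow to 0; use
#'   \code{logTotal}).
#' @slot logTotal total natural-log likelihood.
#' @slot evalCount number of partial-likelihood entries computed (cache
#'   contract: #nodes x #sites x 4, each computed exactly once).
#' @export
setClass("LikelihoodTable", representation(
  partials = "array",
  scaleLog = "matrix",
  siteLik  = "numeric",
  siteLogLik = "numeric",
  total    = "numeric",
  logTotal = "numeric",
  evalCount = "integer"
))

#' CSL-style formula AST node
#'
#' State formulas: \code{true}, \code{atom} (an atomic proposition),
#' \code{not}, \code{or}, \code{prob} (probability-threshold operator
#' P~lambda[path]) and the structural \code{leaf} predicate. Path formulas:
#' \code{next} and interval-bounded \code{until}. Derived connectives
#' (and, implies, F, G) are normalized into this minimal grammar at
#' construction time.
#'
#' @slot op one of "true","atom","not","or","prob","leaf","next","until".
#' @slot prop atomic proposition (op == "atom").
#' @slot cmp comparator for prob nodes: one of "<","<=","=",">",">=","?".
#' @slot lambda probability threshold in [0,1] (empty for "?").
#' @slot interval closed interval [a,b] of an until (b may be Inf).
#' @slot args list of child [CslFormula-class] nodes.
#' @export
setClass("CslFormula", representation(
  op = "character",
  prop = "character",
  cmp = "character",
  lambda = "numeric",
  interval = "numeric",
  args = "list"
), validity = function(object) {
  msg <- character()
  if (!object@op %in% c("true", "atom", "not", "or", "prob", "leaf",
                        "next", "until", "globally"))
    msg <- c(msg, "unknown formula operator")
  if (length(object@lambda) == 1 &&
      (object@lambda < 0 || object@lambda > 1))
    msg <- c(msg, "probability threshold must lie in [0,1]")
  if (length(object@interval) == 2) {
    iv <- object@interval
    if (is.na(iv[1]) || iv[1] < 0 || iv[1] > iv[2])
      msg <- c(msg, "interval must satisfy 0 <= a <= b")
  }
  if (length(msg)) msg else TRUE
})

#' Result of checking a state formula against a CTMC
#'
#' @slot formula the checked [CslFormula-class].
#' @slot satStates states satisfying the formula.
#' @slot probs named per-state probabilities when the top operator is a
#'   probability query (P=?), otherwise empty.
#' @export
setClass("SatResult", representation(
  formula = "CslFormula",
  satStates = "character",
  probs = "numeric"
))

#' Compact set of sampled CTMC trajectories
#'
#' Jump-chain trajectories stored column-compact: \code{states[k, j]} is
#' the state index after the (j-1)-th jump of trajectory k (NA once the
#' horizon is passed), \code{times[k, j]} the absolute entry time.
#'
#' @slot states integer matrix of visited state indices.
#' @slot times numeric matrix of state entry times.
#' @slot stateNames the CTMC state order the indices refer to.
#' @slot horizon truncation time.
#' @export
setClass("TrajectorySet", representation(
  states = "matrix",
  times  = "matrix",
  stateNames = "character",
  horizon = "numeric"
))
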