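#' CSL model checking over a CTMC
#'
#' Recursive computation of the satisfaction set Sat(phi): boolean
#' connectives by set algebra on the labeling; probability-threshold nodes
#' delegate to [probNext()] / [probUntil()] and compare against the
#' threshold; \code{P=?} queries return the per-state probabilities.
#'
#' Comparator semantics: probabilities within 1e-9 of 0 or 1 are snapped
#' to the boundary before comparison (floating-point equality at the
#' qualitative thresholds P>=1 / P>0 is otherwise meaningless); the "="
#' comparator uses the same 1e-9 tolerance.
#'
#' @param x a [CTMC-class] or [TreePTS-class].
#' @param formula a [CslFormula-class] state formula (or a string, parsed
#'   with [parseFormula()]).
#' @param ... unused.
#' @return a [SatResult-class].
#' @examples
#' m <- rateMatrix(jukesCantor())
#' res <- checkFormula(m, "P=?[F<=5 x1=A]")
#' stateProbs(res)
#' @rdname checkFormula
#' @export
setMethod("checkFormula", "CTMC", function(x, formula, ...) {
  if (is.character(formula)) formula <- parseFormula(formula)
  env <- .checkEnv(x)
  if (formula@op == "prob" && formula@cmp == "?") {
    probs <- stats::setNames(.pathProbs(env, formula@args[[1]]), x@states)
    return(new("SatResult", formula = formula, satStates = character(),
               probs = probs))
  }
  sat <- .satisfy(env, formula)
  new("SatResult", formula = formula, satStates = x@states[sat],
      probs = numeric())
})

#' @rdname checkFormula
#' @export
setMethod("checkFormula", "TreePTS", function(x, formula, ...) {
  checkFormula(x@ctmc, formula, ...)
})

#' @rdname satresult-accessors
#' @param x a [SatResult-class].
#' @aliases satStates stateProbs
#' @export
setMethod("satStates", "SatResult", function(x) x@satStates)
#' @rdname satresult-accessors
#' @export
setMethod("stateProbs", "SatResult", function(x) x@probs)

setMethod("show", "SatResult", function(object) {
  cat("SatResult for", formatFormula(object@formula), "\n")
  cat("  satisfied in", length(object@satStates), "state(s)\n")
  if (length(object@probs)) {
    cat("  probabilities:\n")
    print(utils::head(round(object@probs, 6), 10))
  }
})

# Shared checking context: chain, embedded DTMC, label membership matrix.
.checkEnv <- function(x) {
  emb <- embed(x)
  list(ctmc = x, emb = emb, n = length(x@states))
}

.atomSat <- function(env, p) {
  vapply(env$ctmc@labels, function(l) p %in% l, logical(1))
}

# logical vector over states, in state order
.satisfy <- function(env, f) {
  switch(f@op,
    true = rep(TRUE, env$n),
    atom = .atomSat(env, f@prop),
    not  = !.satisfy(env, f@args[[1]]),
    or   = .satisfy(env, f@args[[1]]) | .satisfy(env, f@args[[2]]),
    leaf = .leafSat(env),
    prob = {
      p <- .pathProbs(env, f@args[[1]])
      .compare(p, f@cmp, f@lambda)
    },
    stop("not a state formula: ", f@op))
}

.compare <- function(p, cmp, lambda) {
  tol <- .NUM_TOL
  p[p > 1 - tol] <- 1
  p[p < tol & p > -tol] <- 0
  if (cmp == "?")
    stop("a P=? query can only appear at the top level of checkFormula")
  switch(cmp,
    "<"  = p < lambda,
    "<=" = p <= lambda + tol,
    "="  = abs(p - lambda) <= tol,
    ">"  = p > lambda,
    ">=" = p >= lambda - tol)
}

# leaf: for every atomic proposition p, (p in L(s)) <=> P>=1[X p]
.leafSat <- function(env) {
  P <- env$emb@probs
  props <- atomicProps(env$ctmc)
  ok <- rep(TRUE, env$n)
  for (p in props) {
    holds <- .atomSat(env, p)
    nextP <- as.numeric(P %*% holds)
    allNext <- nextP >= 1 - .NUM_TOL
    ok <- ok & (holds == allNext)
  }
  ok
}

# probability vector (over all states) of a path formula
.pathProbs <- function(env, pf) {
  switch(pf@op,
    "next" = {
      holds <- .satisfy(env, pf@args[[1]])
      as.numeric(env$emb@probs %*% holds)
    },
    until = {
      lhsSat <- .satisfy(env, pf@args[[1]])    # psi in psi U_I phi
      tgtSat <- .satisfy(env, pf@args[[2]])    # phi (the target)
      .untilProbs(env, tgtSat, lhsSat, pf@interval)
    },
    globally = {
      # G_I phi is the dual of eventually: 1 - Prob(F_I !phi)
      notPhi <- !.satisfy(env, pf@args[[1]])
      1 - .untilProbs(env, notPhi, rep(TRUE, env$n), pf@interval)
    },
    stop("not a path formula: ", pf@op))
}

#' Probability of the next operator
#'
#' Prob(s, X phi) = sum over phi-states s' of the embedded jump
#' probability P_emb(s, s').
#'
#' @param x a [CTMC-class].
#' @param s a state identifier (or NULL for all states).
#' @param phi a [CslFormula-class] state formula (or string).
#' @return named numeric probability/ies.
#' @export
probNext <- function(x, s = NULL, phi) {
  if (is.character(phi)) phi <- parseFormula(phi)
  env <- .checkEnv(x)
  p <- stats::setNames(.pathProbs(env, cslNext(phi)), x@states)
  if (is.null(s)) p else p[[s]]
}

#' Probability of the interval-bounded until operator
#'
#' Prob(s, psi U_I phi) for closed intervals I = [0,t], [t,t'], [t,Inf]
#' or [0,Inf]:
#' \itemize{
#' \item \code{[0,t]}: 1 if s satisfies phi, 0 if s satisfies neither psi
#'   nor phi (or t = 0 and not phi); otherwise the transient probability
#'   of reaching a phi-state within t on the transformed chain where
#'   phi-states and (!psi & !phi)-states are absorbing.
#' \item \code{[0,Inf]}: on the embedded jump chain, as the linear system
#'   x = P_emb x + b after graph classification of the probability-0
#'   states (which also removes the self-loop cycles that would make the
#'   raw system singular).
#' \item \code{[t,t']}: phase 1 stays in psi-states for time t (transient
#'   on the chain with !psi absorbing), then continues with
#'   \code{psi U [0,t'-t] phi}.
#' \item \code{[t,Inf]}: phase 1 as above, then the unbounded embedded
#'   until.
#' }
#'
#' @param x a [CTMC-class].
#' @param s state identifier, or NULL for all states.
#' @param psi,phi [CslFormula-class] state formulas (or strings):
#'   \code{psi U_I phi}.
#' @param interval closed interval \code{c(a,b)}, \code{b} may be
#'   \code{Inf}.
#' @return named probability/ies.
#' @export
probUntil <- function(x, s = NULL, psi, phi, interval = c(0, Inf)) {
  if (is.character(psi)) psi <- parseFormula(psi)
  if (is.character(phi)) phi <- parseFormula(phi)
  interval <- as.numeric(interval)
  if (length(interval) != 2 || anyNA(interval[1]) || interval[1] < 0 ||
      interval[1] > interval[2])
    stop("malformed interval: need 0 <= a <= b")
  env <- .checkEnv(x)
  p <- stats::setNames(
    .untilProbs(env, .satisfy(env, phi), .satisfy(env, psi), interval),
    x@states)
  if (is.null(s)) p else p[[s]]
}

.untilProbs <- function(env, phiSat, psiSat, interval) {
  a <- interval[1]; b <- interval[2]
  if (a == 0 && is.infinite(b)) return(.untilUnbounded(env, phiSat, psiSat))
  if (a == 0) return(.untilBounded(env, phiSat, psiSat, b))
  # [t, t'] and [t, Inf]: survive in psi for time a, then continue
  cont <- if (is.infinite(b)) .untilUnbounded(env, phiSat, psiSat)
          else .untilBounded(env, phiSat, psiSat, b - a)
  Q <- generator(env$ctmc)
  Q[!psiSat, ] <- 0                       # !psi states absorb in phase 1
  P1 <- transientFromGenerator(Q, a)
  as.numeric(P1[, psiSat, drop = FALSE] %*% cont[psiSat])
}

.untilBounded <- function(env, phiSat, psiSat, t) {
  if (t == 0) return(as.numeric(phiSat))
  Q <- generator(env$ctmc)
  absorb <- phiSat | (!psiSat & !phiSat)
  Q[absorb, ] <- 0
  Pt <- transientFromGenerator(Q, t)
  as.numeric(Pt[, phiSat, drop = FALSE] %*% rep(1, sum(phiSat)))
}

.untilUnbounded <- function(env, phiSat, psiSat) {
  P <- env$emb@probs
  n <- env$n
  # states that can reach phi through psi&!phi intermediates (BFS backward)
  canReach <- phiSat
  mid <- psiSat & !phiSat
  repeat {
    newly <- mid & !canReach & (P[, canReach, drop = FALSE] %*%
                                  rep(1, sum(canReach)) > 0)
    if (!any(newly)) break
    canReach <- canReach | newly
  }
  prob <- numeric(n)
  prob[phiSat] <- 1
  maybe <- mid & canReach
  if (any(maybe)) {
    A <- P[maybe, maybe, drop = FALSE]
    bvec <- as.numeric(P[maybe, phiSat, drop = FALSE] %*%
                         rep(1, sum(phiSat)))
    prob[maybe] <- solve(diag(sum(maybe)) - A, bvec)
  }
  prob
}
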