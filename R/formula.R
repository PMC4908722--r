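#' Formula constructors
#'
#' Build CSL-style formula ASTs programmatically. State formulas are
#' \code{true}, atomic propositions, negation, disjunction and the
#' probability-threshold operator \code{cslProb(cmp, lambda, path)}; path
#' formulas are \code{cslNext} and interval-bounded \code{cslUntil}.
#' Derived forms are normalized at construction: \code{cslAnd(a,b)} is
#' \code{!(!a | !b)}, \code{cslImplies(a,b)} is \code{!a | b},
#' \code{cslF(phi, I)} is \code{true U_I phi}, and \code{cslG(phi, I)} is
#' kept as the dual of eventually (its probability is one minus the
#' probability of \code{F_I !phi}).
#'
#' @param p atomic proposition string, e.g. \code{"x1=A"}.
#' @param a,b,phi,psi [CslFormula-class] state formulas.
#' @param cmp comparator: one of \code{"<", "<=", "=", ">", ">="}, or
#'   \code{"?"} for a probability query.
#' @param lambda probability threshold in [0,1] (ignored for \code{"?"}).
#' @param path a path [CslFormula-class] (\code{cslNext}, \code{cslUntil},
#'   \code{cslF}, \code{cslG}).
#' @param interval closed time interval \code{c(a, b)}; \code{b} may be
#'   \code{Inf}. Defaults to \code{c(0, Inf)} (untimed).
#' @return a [CslFormula-class].
#' @examples
#' f <- cslProb("?", path = cslF(cslAtom("x1=A"), c(0, 5)))
#' formatFormula(f)
#' @name formula-constructors
NULL

.fml <- function(op, args = list(), prop = character(), cmp = character(),
                 lambda = numeric(), interval = numeric()) {
  new("CslFormula", op = op, args = args, prop = prop, cmp = cmp,
      lambda = lambda, interval = interval)
}

#' @rdname formula-constructors
#' @export
cslTrue <- function() .fml("true")

#' @rdname formula-constructors
#' @export
cslAtom <- function(p) .fml("atom", prop = as.character(p))

#' @rdname formula-constructors
#' @export
cslNot <- function(phi) .fml("not", args = list(phi))

#' @rdname formula-constructors
#' @export
cslOr <- function(a, b) .fml("or", args = list(a, b))

#' @rdname formula-constructors
#' @export
cslAnd <- function(a, b) cslNot(cslOr(cslNot(a), cslNot(b)))

#' @rdname formula-constructors
#' @export
cslImplies <- function(a, b) cslOr(cslNot(a), b)

#' @rdname formula-constructors
#' @export
cslProb <- function(cmp, lambda = NULL, path) {
  if (!cmp %in% c("<", "<=", "=", ">", ">=", "?"))
    stop("comparator must be one of <, <=, =, >, >=, ?")
  if (!path@op %in% c("next", "until", "globally"))
    stop("the argument of a probability operator must be a path formula")
  .fml("prob", args = list(path), cmp = cmp,
       lambda = if (cmp == "?") numeric() else as.numeric(lambda))
}

#' @rdname formula-constructors
#' @export
cslNext <- function(phi) .fml("next", args = list(phi))

#' @rdname formula-constructors
#' @export
cslUntil <- function(phi, psi, interval = c(0, Inf)) {
  interval <- as.numeric(interval)
  if (length(interval) != 2 || anyNA(interval[1]) || interval[1] < 0 ||
      interval[1] > interval[2])
    stop("malformed interval: need 0 <= a <= b")
  .fml("until", args = list(phi, psi), interval = interval)
}

#' @rdname formula-constructors
#' @export
cslF <- function(phi, interval = c(0, Inf)) cslUntil(cslTrue(), phi, interval)

#' @rdname formula-constructors
#' @export
cslG <- function(phi, interval = c(0, Inf)) {
  interval <- as.numeric(interval)
  if (length(interval) != 2 || interval[1] < 0 || interval[1] > interval[2])
    stop("malformed interval: need 0 <= a <= b")
  .fml("globally", args = list(phi), interval = interval)
}

#' Structural leaf predicate
#'
#' True exactly on states all of whose successors carry the same atomic
#' valuation: for every proposition p of the model,
#' p holds at s iff P>=1[X p] holds at s. On a tree transition system this
#' picks out the self-loop leaves — plus, literally, any internal node
#' whose every child is sequence-identical to it (a documented corner of
#' the formula as defined).
#'
#' @return a [CslFormula-class] (expanded over the model's propositions at
#'   check time).
#' @export
leafFormula <- function() .fml("leaf")

#' Conservation (global) pattern
#'
#' \code{global(p, t)} requires p to hold along all paths at all times up
#' to t: P>=1[G<=t p]. \code{t} omitted means t = Inf.
#'
#' @param p a [CslFormula-class] state formula.
#' @param t optional time bound.
#' @return a [CslFormula-class].
#' @export
globalPattern <- function(p, t = Inf) cslProb(">=", 1, cslG(p, c(0, t)))

#' Terminal (deleterious) pattern
#'
#' Untimed: wherever the hazardous pattern p appears it must be a leaf,
#' P>=1[G (p => leaf)]. Timed: all descendants of a p-state must be
#' reached within time t, P>=1[G (p => P>=1[F<=t leaf])].
#'
#' @param p a [CslFormula-class] state formula.
#' @param t optional time bound for reaching the leaves.
#' @return a [CslFormula-class].
#' @export
terminalFormula <- function(p, t = NULL) {
  target <- if (is.null(t)) leafFormula()
            else cslProb(">=", 1, cslF(leafFormula(), c(0, t)))
  cslProb(">=", 1, cslG(cslImplies(p, target)))
}

#' Point-mutation pattern
#'
#' Base sigma at site i is replaced by alpha in the next state with
#' probability at least lambda: sigma_i AND P>=lambda[X alpha_i].
#'
#' @param i 1-based site index.
#' @param sigma,alpha bases in A,C,G,T.
#' @param lambda probability threshold.
#' @return a [CslFormula-class].
#' @export
pointMutationFormula <- function(i, sigma, alpha, lambda) {
  cslAnd(cslAtom(sprintf("x%d=%s", i, sigma)),
         cslProb(">=", lambda,
                 cslNext(cslAtom(sprintf("x%d=%s", i, alpha)))))
}

#' Back-mutation (reversion) at one alignment column
#'
#' A state has a back mutation at column col if, for some base sigma held
#' there, some descending path loses sigma and later regains it:
#' OR_sigma sigma_col AND P>0[F(!sigma_col AND P>0[F sigma_col])].
#'
#' @param col 1-based alignment column.
#' @return a [CslFormula-class].
#' @export
hasBMFormula <- function(col) {
  per <- lapply(DNA_BASES_, function(s) {
    a <- cslAtom(sprintf("x%d=%s", col, s))
    cslAnd(a, cslProb(">", 0, cslF(cslAnd(cslNot(a),
                                          cslProb(">", 0, cslF(a))))))
  })
  Reduce(cslOr, per)
}

#' Tree-wide freedom from back mutations
#'
#' detectBM = AND_{j=1..n} P>=1[G !hasBM(j)]: no state reachable anywhere
#' in the tree exhibits a reversion at any column. The complement of the
#' satisfaction set pinpoints the subtree roots exhibiting reversions.
#'
#' @param n alignment length (number of columns to scan).
#' @return a [CslFormula-class].
#' @export
detectBMFormula <- function(n) {
  per <- lapply(seq_len(n), function(j)
    cslProb(">=", 1, cslG(cslNot(hasBMFormula(j)))))
  Reduce(cslAnd, per)
}

#' Render a formula as text
#' @param f a [CslFormula-class].
#' @return a single string in the parser's concrete syntax.
#' @export
formatFormula <- function(f) {
  iv <- function(x) {
    if (length(x) != 2 || (x[1] == 0 && is.infinite(x[2]))) return("")
    if (x[1] == 0) sprintf("<=%g", x[2])
    else if (is.infinite(x[2])) sprintf(">=%g", x[1])
    else sprintf("[%g,%g]", x[1], x[2])
  }
  switch(f@op,
    true = "true",
    atom = f@prop,
    leaf = "leaf",
    not  = paste0("!", formatFormula(f@args[[1]])),
    or   = sprintf("(%s | %s)", formatFormula(f@args[[1]]),
                   formatFormula(f@args[[2]])),
    prob = sprintf("P%s%s[%s]", if (f@cmp == "?") "=?" else f@cmp,
                   if (f@cmp == "?") "" else format(f@lambda),
                   formatFormula(f@args[[1]])),
    `next` = paste0("X ", formatFormula(f@args[[1]])),
    globally = sprintf("G%s %s", iv(f@interval),
                       formatFormula(f@args[[1]])),
    until = {
      lhs <- f@args[[1]]
      if (lhs@op == "true")
        sprintf("F%s %s", iv(f@interval), formatFormula(f@args[[2]]))
      else
        sprintf("(%s U%s %s)", formatFormula(lhs), iv(f@interval),
                formatFormula(f@args[[2]]))
    })
}

setMethod("show", "CslFormula", function(object) {
  cat("CslFormula:", formatFormula(object), "\n")
})

## ---- parser ----------------------------------------------------------

.tokenize <- function(text) {
  pats <- c(NUM = "[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?",
            ID  = "[A-Za-z_][A-Za-z0-9_]*",
            OP  = "<=|>=|!=|[()\\[\\],|&!<>=?]")
  toks <- list()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    ws <- regmatches(rest, regexpr("^\\s+", rest, perl = TRUE))
    if (length(ws)) { pos <- pos + nchar(ws); next }
    rest <- substr(text, pos, n)
    matched <- FALSE
    for (ty in names(pats)) {
      m <- regmatches(rest, regexpr(paste0("^(", pats[[ty]], ")"), rest,
                                    perl = TRUE))
      if (length(m)) {
        toks[[length(toks) + 1L]] <- list(type = ty, value = m, pos = pos)
        pos <- pos + nchar(m)
        matched <- TRUE
        break
      }
    }
    if (!matched)
      stop(sprintf("formula syntax error at position %d: unexpected '%s'",
                   pos, substr(text, pos, pos)), call. = FALSE)
  }
  toks
}

#' Parse a formula string
#'
#' Concrete syntax mirrors PRISM property strings:
#' \preformatted{
#'   P=?[F<=5 x1=A]      probability query, bounded eventually
#'   P>=1[G (x2=C)]      conservation
#'   P<=0.5[a U[1,2] b]  interval until
#'   !(x1=A) & P>0[X x1=G]
#' }
#' Atomic propositions are bare identifiers (\code{a}) or
#' site-base equalities (\code{x1=A}). Builtin macros: \code{leaf},
#' \code{global(p[,t])}, \code{terminal(p[,t])},
#' \code{pointmut(i,sigma,alpha,lambda)}, \code{hasBM(col)},
#' \code{detectBM(n)}. \code{&}, \code{=>} and \code{F}/\code{G} are
#' normalized into the minimal grammar.
#'
#' @param text formula string.
#' @return a [CslFormula-class].
#' @export
parseFormula <- function(text) {
  toks <- .tokenize(text)
  ix <- 1L
  peek <- function() if (ix <= length(toks)) toks[[ix]] else NULL
  advance <- function() { t <- toks[[ix]]; ix <<- ix + 1L; t }
  fail <- function(what) {
    t <- peek()
    stop(sprintf("formula syntax error at position %s: expected %s, got '%s'",
                 if (is.null(t)) "end" else t$pos, what,
                 if (is.null(t)) "<end>" else t$value), call. = FALSE)
  }
  expectVal <- function(v) {
    t <- peek()
    if (is.null(t) || t$value != v) fail(sprintf("'%s'", v))
    advance()
  }
  atValue <- function(v) { t <- peek(); !is.null(t) && t$value == v }

  number <- function() {
    t <- peek()
    if (!is.null(t) && t$type == "NUM") return(as.numeric(advance()$value))
    if (!is.null(t) && t$value == "inf") { advance(); return(Inf) }
    fail("a number")
  }

  bound <- function() {
    t <- peek()
    if (is.null(t)) return(c(0, Inf))
    if (t$value == "<=") { advance(); return(c(0, number())) }
    if (t$value == ">=") { advance(); return(c(number(), Inf)) }
    if (t$value == "[") {
      advance()
      a <- number(); expectVal(","); b <- number(); expectVal("]")
      return(c(a, b))
    }
    c(0, Inf)
  }

  pathFormula <- function() {
    t <- peek()
    if (!is.null(t) && t$type == "ID" && t$value %in% c("X", "F", "G")) {
      # lookahead: treat as temporal operator unless it is an atom "X=..."
      nxt <- if (ix + 1L <= length(toks)) toks[[ix + 1L]] else NULL
      if (is.null(nxt) || nxt$value != "=") {
        op <- advance()$value
        if (op == "X") return(cslNext(stateFormula()))
        b <- bound()
        phi <- stateFormula()
        return(if (op == "F") cslF(phi, b) else cslG(phi, b))
      }
    }
    lhs <- stateFormula()
    expectVal("U")
    b <- bound()
    cslUntil(lhs, stateFormula(), b)
  }

  probExpr <- function() {
    expectVal("P")
    t <- peek()
    if (is.null(t) || !t$value %in% c("<", "<=", "=", ">", ">="))
      fail("a comparator")
    cmp <- advance()$value
    lambda <- NULL
    if (cmp == "=" && atValue("?")) { advance(); cmp <- "?" }
    else lambda <- number()
    expectVal("[")
    path <- pathFormula()
    expectVal("]")
    cslProb(cmp, lambda, path)
  }

  macroArgs <- function() {
    expectVal("(")
    args <- list()
    if (!atValue(")")) {
      repeat {
        t <- peek()
        args[[length(args) + 1L]] <-
          if (!is.null(t) && t$type == "NUM") number() else {
            # argument may itself be a formula or a bare symbol
            v <- stateFormula()
            v
          }
        if (atValue(",")) { advance(); next }
        break
      }
    }
    expectVal(")")
    args
  }

  asBase <- function(x) {
    if (is(x, "CslFormula") && x@op == "atom") return(x@prop)
    stop("expected a base symbol in macro arguments", call. = FALSE)
  }

  primary <- function() {
    t <- peek()
    if (is.null(t)) fail("a formula")
    if (t$value == "(") {
      advance()
      f <- stateFormula()
      expectVal(")")
      return(f)
    }
    if (t$value == "!") { advance(); return(cslNot(primary())) }
    if (t$value == "P") return(probExpr())
    if (t$type == "ID") {
      id <- advance()$value
      if (id == "true") return(cslTrue())
      if (id == "false") return(cslNot(cslTrue()))
      if (id == "leaf") return(leafFormula())
      if (id == "global") {
        a <- macroArgs()
        return(globalPattern(a[[1]], if (length(a) > 1) a[[2]] else Inf))
      }
      if (id == "terminal") {
        a <- macroArgs()
        return(terminalFormula(a[[1]], if (length(a) > 1) a[[2]] else NULL))
      }
      if (id == "pointmut") {
        a <- macroArgs()
        return(pointMutationFormula(a[[1]], asBase(a[[2]]), asBase(a[[3]]),
                                    a[[4]]))
      }
      if (id == "hasBM") return(hasBMFormula(macroArgs()[[1]]))
      if (id == "detectBM") return(detectBMFormula(macroArgs()[[1]]))
      # atomic proposition, possibly "x1=A" (but not the "=>" of implies)
      if (atValue("=") && ix + 1L <= length(toks) &&
          toks[[ix + 1L]]$type %in% c("ID", "NUM")) {
        advance()
        return(cslAtom(paste0(id, "=", advance()$value)))
      }
      return(cslAtom(id))
    }
    fail("a formula")
  }

  conj <- function() {
    f <- primary()
    while (atValue("&")) { advance(); f <- cslAnd(f, primary()) }
    f
  }

  implies <- function() {
    f <- conj()
    while (atValue("=") &&
           ix + 1L <= length(toks) && toks[[ix + 1L]]$value == ">") {
      advance(); advance()
      f <- cslImplies(f, conj())
    }
    f
  }

  stateFormula <- function() {
    f <- implies()
    while (atValue("|")) { advance(); f <- cslOr(f, implies()) }
    f
  }

  out <- stateFormula()
  if (!is.null(peek()))
    stop(sprintf("formula syntax error at position %d: trailing '%s'",
                 peek()$pos, peek()$value), call. = FALSE)
  out
}

#' Read a property file: one formula per line
#'
#' Blank lines and lines starting with \code{//} or \code{#} are skipped.
#'
#' @param path file path.
#' @return named list of [CslFormula-class] (names are the line texts).
#' @export
readFormulaFile <- function(path) {
  lines <- trimws(readLines(path))
  keep <- nzchar(lines) & !startsWith(lines, "//") & !startsWith(lines, "#")
  lines <- lines[keep]
  out <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    out[[k]] <- tryCatch(parseFormula(lines[k]), error = function(e)
      stop(sprintf("line %d: %s", which(keep)[k], conditionMessage(e)),
           call. = FALSE))
  }
  stats::setNames(out, lines)
}
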