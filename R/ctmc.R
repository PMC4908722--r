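#' Construct a continuous-time Markov chain
#'
#' @param rates square numeric matrix of nonnegative transition rates
#'   (events per unit time). Dimnames give the state identifiers; unnamed
#'   matrices get states "s1", "s2", ... Diagonal entries are ignored
#'   (self-rates are part of the exit rate only if you put them there
#'   explicitly; a rate of exactly 0 means "no transition").
#' @param initial initial state(s); defaults to the first state.
#' @param labels named list mapping each state to a character vector of
#'   atomic propositions (missing states get an empty labeling).
#' @return a [CTMC-class] object.
#' @examples
#' m <- ctmc(matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE,
#'                  dimnames = list(c("A", "B"), c("A", "B"))),
#'           labels = list(A = "a", B = "b"))
#' generator(m)
#' @export
ctmc <- function(rates, initial = NULL, labels = NULL) {
  if (is.null(rownames(rates)))
    dimnames(rates) <- rep(list(paste0("s", seq_len(nrow(rates)))), 2)
  s <- rownames(rates)
  colnames(rates) <- s
  if (is.null(initial)) initial <- s[1]
  lab <- stats::setNames(rep(list(character()), length(s)), s)
  if (!is.null(labels)) {
    bad <- setdiff(names(labels), s)
    if (length(bad)) stop("labels for unknown states: ",
                          paste(bad, collapse = ", "))
    lab[names(labels)] <- lapply(labels, as.character)
  }
  new("CTMC", states = s, rates = rates, initial = as.character(initial),
      labels = lab)
}

#' @rdname accessors
#' @param x a [CTMC-class] or [EmbeddedDTMC-class] object.
#' @aliases states rates labeling initialStates
#' @export
setMethod("states", "CTMC", function(x) x@states)
#' @rdname accessors
#' @export
setMethod("rates", "CTMC", function(x) x@rates)
#' @rdname accessors
#' @export
setMethod("labeling", "CTMC", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("initialStates", "CTMC", function(x) x@initial)
#' @rdname accessors
#' @export
setMethod("exitRates", "EmbeddedDTMC", function(x) x@exitRates)
#' @rdname accessors
#' @export
setMethod("jumpProbs", "EmbeddedDTMC", function(x) x@probs)

#' Atomic propositions mentioned by a CTMC labeling
#' @param x a [CTMC-class].
#' @return character vector of distinct propositions, in first-seen order.
#' @export
atomicProps <- function(x) unique(unlist(x@labels, use.names = FALSE))

setMethod("show", "CTMC", function(object) {
  cat("CTMC with", length(object@states), "states:",
      paste(utils::head(object@states, 6), collapse = ", "),
      if (length(object@states) > 6) "...", "\n")
  cat("  transitions:", sum(object@rates > 0 & !diag(nrow(object@rates))),
      " initial:", paste(object@initial, collapse = ", "), "\n")
  cat("  atomic propositions:", length(atomicProps(object)), "\n")
})

setMethod("show", "EmbeddedDTMC", function(object) {
  cat("Embedded DTMC over", nrow(object@probs), "states;",
      sum(object@exitRates == 0), "absorbing\n")
})

#' Infinitesimal generator matrix
#'
#' Q has the off-diagonal rates of the chain and diagonal entries equal to
#' minus the total outgoing rate, so each row sums to 0. The transient
#' distribution is P_t = exp(Q t).
#'
#' @param x a [CTMC-class].
#' @return square numeric matrix Q.
#' @rdname generator
#' @export
setMethod("generator", "CTMC", function(x) {
  Q <- x@rates
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
})

#' Transient probability matrix P_t
#'
#' Computes P_t = exp(Q t) by uniformization: with q = max_s |Q(s,s)| and
#' M = I + Q/q, P_t = sum_k Poisson(k; q t) M^k, truncated when the
#' neglected Poisson tail mass drops below \code{tail}. Numerically stable
#' for stiff rate ratios because every M power is stochastic.
#'
#' @param x a [CTMC-class].
#' @param t elapsed time, >= 0.
#' @param tail neglected Poisson tail mass bound (default well below the
#'   1e-12 structural tolerance).
#' @return stochastic matrix of transition probabilities over the states.
#' @rdname transient
#' @export
setMethod("transient", "CTMC", function(x, t, tail = 1e-15) {
  transientFromGenerator(generator(x), t, tail)
})

# Uniformization on a raw generator matrix (shared by the until engine,
# which works on transformed chains that are not CTMC objects).
transientFromGenerator <- function(Q, t, tail = 1e-15) {
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0)
    stop("elapsed time must be a single nonnegative number")
  n <- nrow(Q)
  I <- diag(n)
  dimnames(I) <- dimnames(Q)
  q <- max(abs(diag(Q)))
  if (t == 0 || q == 0) return(I)
  lam <- q * t
  M <- I + Q / q
  # Poisson weights via the stable recurrence in log space
  logw <- -lam
  term <- I
  P <- exp(logw) * I
  acc <- exp(logw)
  k <- 0
  repeat {
    k <- k + 1
    term <- term %*% M
    logw <- logw + log(lam) - log(k)
    w <- exp(logw)
    P <- P + w * term
    acc <- acc + w
    if (1 - acc < tail && k >= lam) break
    if (k > 10 * (lam + 50)) break  # safety; unreachable in practice
  }
  # clamp roundoff just inside [0,1]
  P[P < 0 & P > -1e-12] <- 0
  P[P > 1 & P < 1 + 1e-12] <- 1
  P
}

#' Embedded discrete-time jump chain
#'
#' Replaces the rate matrix with jump probabilities
#' P_emb(s,s') = R(s,s')/E(s) where E(s) is the exit rate; absorbing
#' states (E(s) = 0, "siphons") keep a unit self-loop.
#'
#' @param x a [CTMC-class].
#' @return an [EmbeddedDTMC-class].
#' @rdname embed-ctmc
#' @export
setMethod("embed", "CTMC", function(x) {
  R <- x@rates
  diag(R) <- diag(x@rates)  # self-rates allowed (leaf self-loops)
  E <- rowSums(R)
  P <- R
  pos <- E > 0
  P[pos, ] <- R[pos, , drop = FALSE] / E[pos]
  if (any(!pos)) {
    P[!pos, ] <- 0
    diag(P)[!pos] <- 1
  }
  new("EmbeddedDTMC", probs = P, exitRates = stats::setNames(E, x@states))
})

#' Probability of a finite path prefix
#'
#' The probability measure of the cylinder of infinite paths sharing the
#' given finite prefix, computed as the product of embedded-DTMC jump
#' probabilities along the prefix. The one-state prefix has probability 1.
#'
#' @param x a [CTMC-class].
#' @param prefix character vector of consecutive states, starting in an
#'   initial state.
#' @return probability in [0,1].
#' @export
pathPrefixProbability <- function(x, prefix) {
  stopifnot(is(x, "CTMC"))
  prefix <- as.character(prefix)
  if (length(prefix) < 1) stop("prefix must contain at least one state")
  if (!all(prefix %in% x@states)) stop("prefix mentions unknown states")
  if (!prefix[1] %in% x@initial)
    stop("prefix must start in an initial state")
  if (length(prefix) == 1) return(1)
  P <- embed(x)@probs
  p <- 1
  for (k in seq_len(length(prefix) - 1)) {
    step <- P[prefix[k], prefix[k + 1]]
    if (x@rates[prefix[k], prefix[k + 1]] <= 0)
      stop("prefix uses a transition with zero rate: ",
           prefix[k], " -> ", prefix[k + 1])
    p <- p * step
  }
  p
}

#' Write / read a CTMC as a plain-text rate list
#'
#' Format: one line per transition \code{src dst rate}, then a blank line,
#' then a labeling block with one line per state \code{state prop1,prop2}
#' (states without propositions list just the state name).
#'
#' @param x a [CTMC-class].
#' @param path file path.
#' @return \code{writeRateList} returns \code{path} invisibly;
#'   \code{readRateList} returns a [CTMC-class].
#' @export
writeRateList <- function(x, path) {
  stopifnot(is(x, "CTMC"))
  R <- x@rates
  idx <- which(R > 0, arr.ind = TRUE)
  lines <- sprintf("%s %s %.17g", x@states[idx[, 1]], x@states[idx[, 2]],
                   R[idx])
  labLines <- vapply(x@states, function(s) {
    props <- x@labels[[s]]
    if (length(props)) paste(s, paste(props, collapse = ","))
    else s
  }, character(1))
  writeLines(c(paste("# initial:", paste(x@initial, collapse = ",")),
               lines, "", labLines), path)
  invisible(path)
}

#' @rdname writeRateList
#' @export
readRateList <- function(path) {
  lines <- readLines(path)
  ini <- sub("^# initial:\\s*", "", lines[startsWith(lines, "# initial:")])
  lines <- lines[!startsWith(lines, "#")]
  sep <- which(lines == "")[1]
  if (is.na(sep)) stop("rate list missing labeling block separator")
  trans <- lines[seq_len(sep - 1)]
  labs <- lines[-seq_len(sep)]
  labs <- labs[labs != ""]
  parts <- strsplit(trans, "\\s+")
  statesFromLabs <- vapply(strsplit(labs, "\\s+"), `[`, character(1), 1)
  s <- unique(c(statesFromLabs,
                unlist(lapply(parts, `[`, 1:2), use.names = FALSE)))
  R <- matrix(0, length(s), length(s), dimnames = list(s, s))
  for (p in parts) R[p[1], p[2]] <- as.numeric(p[3])
  labels <- list()
  for (l in strsplit(labs, "\\s+")) {
    props <- if (length(l) > 1) strsplit(l[2], ",")[[1]] else character()
    labels[[l[1]]] <- props
  }
  initial <- if (length(ini)) strsplit(ini, ",")[[1]] else s[1]
  ctmc(R, initial = initial, labels = labels)
}
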