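#' DNA substitution models
#'
#' Constructors for the standard nucleotide substitution models. All
#' models are continuous-time Markov chains on the alphabet (A, C, G, T)
#' with generator Q(i,j) = s_ij * f_j (i != j) rescaled so that the
#' expected substitution rate at stationarity, -sum_i f_i Q(i,i), equals
#' \code{nu}. With nu = 1 a branch length d is the expected number of
#' substitutions per site, and the Jukes-Cantor transition probabilities
#' have the closed form P_ii(d) = 1/4 + 3/4 exp(-4 nu d / 3),
#' P_ij(d) = 1/4 - 1/4 exp(-4 nu d / 3).
#'
#' @param nu overall substitution rate (substitutions/site/unit time).
#' @param kappa K80 transition/transversion rate ratio.
#' @param freqs stationary base frequencies named A,C,G,T (F81/GTR).
#' @param exch six positive exchangeabilities named AC,AG,AT,CG,CT,GT
#'   (GTR).
#' @return a [MutationModel-class].
#' @examples
#' jc <- jukesCantor()
#' transitionProbability(jc, "A", "A", 1)   # 1/4 + 3/4*exp(-4/3)
#' @name substitution-models
NULL

.uniformFreqs <- function() stats::setNames(rep(0.25, 4), DNA_BASES_)
.unitExch <- function() stats::setNames(rep(1, 6), PAIR_NAMES_)

#' @rdname substitution-models
#' @export
jukesCantor <- function(nu = 1)
  new("MutationModel", name = "JC", nu = nu, freqs = .uniformFreqs(),
      exch = .unitExch())

#' @rdname substitution-models
#' @export
kimura <- function(kappa = 2, nu = 1) {
  e <- .unitExch()
  e[c("AG", "CT")] <- kappa  # transitions (purine-purine, pyrimidine-pyrimidine)
  new("MutationModel", name = "K80", nu = nu, freqs = .uniformFreqs(),
      exch = e)
}

#' @rdname substitution-models
#' @export
felsenstein81 <- function(freqs, nu = 1) {
  new("MutationModel", name = "F81", nu = nu,
      freqs = .checkFreqs(freqs), exch = .unitExch())
}

#' @rdname substitution-models
#' @export
gtr <- function(exch, freqs, nu = 1) {
  e <- as.numeric(exch[PAIR_NAMES_])
  if (any(is.na(e))) stop("exchangeabilities must be named ",
                          paste(PAIR_NAMES_, collapse = ","))
  new("MutationModel", name = "GTR", nu = nu, freqs = .checkFreqs(freqs),
      exch = stats::setNames(e, PAIR_NAMES_))
}

.checkFreqs <- function(freqs) {
  f <- as.numeric(freqs[DNA_BASES_])
  if (any(is.na(f))) stop("freqs must be named A,C,G,T")
  if (any(f <= 0)) stop("base frequencies must be positive")
  stats::setNames(f / sum(f), DNA_BASES_)
}

setMethod("show", "MutationModel", function(object) {
  cat(object@name, "substitution model, nu =", object@nu, "\n")
  cat("  freqs:", paste(sprintf("%s=%.4g", DNA_BASES_, object@freqs),
                        collapse = " "), "\n")
  if (object@name %in% c("K80", "GTR"))
    cat("  exch: ", paste(sprintf("%s=%.4g", PAIR_NAMES_, object@exch),
                          collapse = " "), "\n")
})

# Unnormalized reversible generator Q(i,j) = s_ij f_j; diagonal = -rowsum.
.rawGenerator <- function(model) {
  f <- model@freqs
  e <- model@exch
  S <- matrix(0, 4, 4, dimnames = list(DNA_BASES_, DNA_BASES_))
  pairs <- utils::combn(DNA_BASES_, 2)
  for (k in seq_len(6)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    S[i, j] <- S[j, i] <- e[paste0(i, j)]
  }
  Q <- S * rep(f, each = 4)   # Q(i,j) = s_ij * f_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Generator of a substitution model, normalized to rate nu
#'
#' @param model a [MutationModel-class].
#' @return 4x4 generator matrix with stationary substitution rate
#'   \code{nu}.
#' @export
modelGenerator <- function(model) {
  Q <- .rawGenerator(model)
  mu <- -sum(model@freqs * diag(Q))
  Q * (model@nu / mu)
}

#' Substitution model as a four-state CTMC
#'
#' Each state is one nucleotide, labeled with both the bare base ("A") and
#' the site-1 proposition ("x1=A") so single-site temporal-logic formulas
#' check directly against the model.
#'
#' @param model a [MutationModel-class].
#' @return a [CTMC-class] over A,C,G,T.
#' @rdname rateMatrix
#' @export
setMethod("rateMatrix", "MutationModel", function(model) {
  Q <- modelGenerator(model)
  R <- Q
  diag(R) <- 0
  labels <- lapply(DNA_BASES_, function(b) c(b, paste0("x1=", b)))
  names(labels) <- DNA_BASES_
  ctmc(R, initial = DNA_BASES_, labels = labels)
})

#' Transition probability matrix P(d) of a substitution model
#'
#' @param model a [MutationModel-class].
#' @param d branch length (time units), >= 0.
#' @return 4x4 stochastic matrix with entry (i,j) = P_ij(d).
#' @export
transitionMatrix <- function(model, d) {
  if (!is.numeric(d) || length(d) != 1 || is.na(d) || d < 0)
    stop("branch length must be a single nonnegative number")
  transientFromGenerator(modelGenerator(model), d)
}

#' @rdname transitionProbability
#' @param model a [MutationModel-class].
#' @param i,j bases in A,C,G,T.
#' @param d branch length >= 0.
#' @export
setMethod("transitionProbability", "MutationModel", function(model, i, j, d) {
  if (!i %in% DNA_BASES_ || !j %in% DNA_BASES_)
    stop("bases must be one of A,C,G,T")
  transitionMatrix(model, d)[i, j]
})

#' Verify that the declared frequencies are stationary
#'
#' Checks f Q = 0 within 1e-9. With the default generator this holds for
#' every model built by the package constructors (by the reversible
#' construction Q(i,j) = s_ij f_j); pass an explicit \code{Q} to test a
#' hand-built rate matrix against the model's declared frequencies.
#'
#' @param model a [MutationModel-class].
#' @param Q generator matrix to test against (default: the model's own).
#' @return logical.
#' @export
stationaryCheck <- function(model, Q = modelGenerator(model)) {
  max(abs(model@freqs %*% Q)) < 1e-9
}

#' Read a substitution-model configuration file
#'
#' JSON with fields \code{name} (JC/K80/F81/GTR), \code{nu}, and
#' model-dependent \code{freqs} (object keyed A,C,G,T), \code{kappa} (K80)
#' or \code{exch} (object keyed AC,AG,AT,CG,CT,GT).
#'
#' @param path path to a JSON model configuration.
#' @return a validated [MutationModel-class].
#' @export
readModelConfig <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  if (is.null(cfg$name)) stop("model config needs a 'name' field")
  nu <- if (is.null(cfg$nu)) 1 else cfg$nu
  switch(toupper(cfg$name),
    JC  = jukesCantor(nu),
    K80 = kimura(if (!is.null(cfg$kappa)) cfg$kappa
                 else if (!is.null(cfg$exch)) cfg$exch$AG else 2, nu),
    F81 = felsenstein81(unlist(cfg$freqs), nu),
    GTR = gtr(unlist(cfg$exch), unlist(cfg$freqs), nu),
    stop("unknown model name: ", cfg$name))
}

#' @rdname readModelConfig
#' @param model a [MutationModel-class] to serialize.
#' @export
writeModelConfig <- function(model, path) {
  cfg <- list(name = model@name, nu = model@nu,
              freqs = as.list(model@freqs), exch = as.list(model@exch))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
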