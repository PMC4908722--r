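.baseCode <- function(b) match(b, DNA_BASES_) - 1L   # A=0,C=1,G=2,T=3

#' Export a substitution model in PRISM ctmc syntax
#'
#' Writes a single-site four-state module over the variable \code{x1}
#' (0=A, 1=C, 2=G, 3=T) with one guarded command per inter-base
#' transition (4 x 3 = 12 commands), rates taken from the model's
#' normalized generator. The output targets semantic fidelity to the
#' published PRISM grammar and is round-trip parseable by
#' [readPrismModel()].
#'
#' @param model a [MutationModel-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
exportPrismModel <- function(model, path) {
  Q <- modelGenerator(model)
  lines <- c(
    "ctmc",
    "",
    sprintf("// %s substitution model, substitution rate nu = %g",
            model@name, model@nu),
    "// variable encoding: x1 : 0=A, 1=C, 2=G, 3=T",
    sprintf("const double nu = %g;", model@nu),
    "",
    "module site1",
    "  x1 : [0..3] init 0;")
  for (i in DNA_BASES_) for (j in DNA_BASES_) {
    if (i == j) next
    lines <- c(lines,
      sprintf("  [] x1=%d -> %.17g : (x1'=%d);",
              .baseCode(i), Q[i, j], .baseCode(j)))
  }
  lines <- c(lines, "endmodule")
  writeLines(lines, path)
  invisible(path)
}

#' Read back a PRISM ctmc model exported by this package
#'
#' Parses the guarded commands of the single-site module into a four-state
#' [CTMC-class] labeled with base and site propositions.
#'
#' @param path a file written by [exportPrismModel()].
#' @return a [CTMC-class] over A,C,G,T.
#' @export
readPrismModel <- function(path) {
  lines <- readLines(path)
  if (!any(trimws(lines) == "ctmc"))
    stop("not a PRISM ctmc file (missing 'ctmc' keyword)")
  pat <- "^\\s*\\[\\]\\s*x1=(\\d)\\s*->\\s*([0-9.eE+-]+)\\s*:\\s*\\(x1'=(\\d)\\);"
  R <- matrix(0, 4, 4, dimnames = list(DNA_BASES_, DNA_BASES_))
  for (ln in lines) {
    m <- regmatches(ln, regexec(pat, ln))[[1]]
    if (length(m) == 4)
      R[as.integer(m[2]) + 1L, as.integer(m[4]) + 1L] <- as.numeric(m[3])
  }
  labels <- lapply(DNA_BASES_, function(b) c(b, paste0("x1=", b)))
  names(labels) <- DNA_BASES_
  ctmc(R, initial = DNA_BASES_, labels = labels)
}

#' Export tree likelihood properties in PRISM syntax
#'
#' Writes a properties file defining the partial likelihoods L^l_{X,i} of
#' a tree against a mutation model: a header describing the variable
#' naming, one distance constant per edge (the constant d_X_Y is the
#' branch length between X and Y) and a root-to-leaf distance constant
#' per leaf, a 1/0 likelihood constant per observed leaf base (leaves
#' have maximum likelihood) and one named filter property per internal
#' partial, following the upper-bound rewriting in which each leaf is
#' reached from the root along its own path.
#'
#' @param tree a [PhyloTree-class] with labeled leaves.
#' @param model a [MutationModel-class] (used for the time bounds only).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
exportPrismProperties <- function(tree, model, path) {
  leaves <- leafIds(tree)
  if (anyNA(tree@sequences[leaves])) stop("unlabeled leaf")
  ns <- tree@nsites
  lines <- c(
    "// Partial-likelihood properties for a phylogenetic tree",
    "// notation: L_<site>_<node>_<base> is the partial likelihood of the",
    "//           data below <node> at <site> given the node carries <base>;",
    "//           d_<X>_<Y> is the branch length between states X and Y;",
    "//           D_<Z> is the root-to-leaf distance of leaf Z.",
    "")
  for (i in seq_along(tree@ids)[-1]) {
    p <- tree@ids[tree@parent[i]]
    lines <- c(lines, sprintf("const double d_%s_%s = %.17g;",
                              p, tree@ids[i], tree@lengths[i]))
  }
  for (z in leaves)
    lines <- c(lines, sprintf("const double D_%s = %.17g;",
                              z, rootToLeafDistance(tree, z)))
  lines <- c(lines, "")
  for (z in leaves) {
    bs <- strsplit(tree@sequences[[z]], "")[[1]]
    for (l in seq_len(ns)) for (b in DNA_BASES_)
      lines <- c(lines,
        sprintf("const double L_%d_%s_%s = %d;", l, z, b,
                as.integer(b == bs[l])))
  }
  lines <- c(lines, "")
  for (z in leaves) {
    bs <- strsplit(tree@sequences[[z]], "")[[1]]
    D <- rootToLeafDistance(tree, z)
    for (l in seq_len(ns)) for (b in DNA_BASES_)
      lines <- c(lines,
        sprintf('"L_%d_Root_%s_via_%s": filter(max, P=?[ F<=%.17g x%d=%s ], x%d=%s);',
                l, b, z, D, l, bs[l], l, b))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read constants and properties from an exported PRISM properties file
#'
#' @param path a file written by [exportPrismProperties()].
#' @return list with \code{constants} (named numeric) and
#'   \code{properties}: a data.frame of \code{name}, \code{filter}
#'   (min/max/none), \code{condition} (initial-state filter text) and the
#'   parsed inner query as a list column \code{formula}.
#' @export
readPrismProperties <- function(path) {
  lines <- readLines(path)
  constPat <- "^const double ([A-Za-z0-9_]+) = ([0-9.eE+-]+);"
  cm <- regmatches(lines, regexec(constPat, lines))
  consts <- numeric()
  for (m in cm) if (length(m) == 3) consts[m[2]] <- as.numeric(m[3])
  propPat <- '^"([^"]+)":\\s*filter\\((min|max),\\s*(P=\\?\\[[^]]*\\]),\\s*([^)]*)\\);'
  props <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec(propPat, ln))[[1]]
    if (length(m) == 5)
      props[[length(props) + 1L]] <-
        list(name = m[2], filter = m[3], condition = trimws(m[5]),
             formula = parseFormula(m[4]))
  }
  df <- data.frame(
    name = vapply(props, `[[`, character(1), "name"),
    filter = vapply(props, `[[`, character(1), "filter"),
    condition = vapply(props, `[[`, character(1), "condition"),
    stringsAsFactors = FALSE)
  df$formula <- lapply(props, `[[`, "formula")
  list(constants = consts, properties = df)
}

#' Evaluate a PRISM-style filter query against a CTMC
#'
#' \code{filter(min, P=?[...], cond)} evaluates the probability query in
#' every state satisfying the filter condition and returns the
#' minimum (resp. maximum) — the PRISM idiom for selecting the initial
#' state.
#'
#' @param x a [CTMC-class] or [TreePTS-class].
#' @param text a string \code{filter(min|max, P=?[...], condition)} or a
#'   plain formula (then equivalent to [checkFormula()]).
#' @return for filter queries, the filtered probability (numeric); for
#'   plain P=? queries, the named per-state probability vector; otherwise
#'   a [SatResult-class].
#' @export
evalQuery <- function(x, text) {
  if (is(x, "TreePTS")) x <- x@ctmc
  m <- regmatches(text,
    regexec("^\\s*filter\\((min|max),\\s*(.+\\]),\\s*(.+)\\)\\s*$", text))[[1]]
  if (length(m) == 4) {
    probs <- stateProbs(checkFormula(x, m[3]))
    cond <- satStates(checkFormula(x, m[4]))
    if (!length(cond)) stop("filter condition satisfied by no state")
    v <- probs[cond]
    return(if (m[2] == "min") min(v) else max(v))
  }
  res <- checkFormula(x, text)
  if (res@formula@op == "prob" && res@formula@cmp == "?")
    return(stateProbs(res))
  res
}
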