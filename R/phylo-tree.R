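#' Read a rooted Newick tree
#'
#' Parses a Newick string (or file) with branch lengths into a
#' [PhyloTree-class]. Node names are preserved; unnamed internal nodes are
#' auto-named N1, N2, ... in preorder. Every non-root branch must carry a
#' length. Singleton internal nodes (chains) and multifurcations are
#' accepted; an unnamed basal multifurcation — the Newick convention for
#' an unrooted tree — is rejected rather than silently rooted.
#'
#' @param text Newick string.
#' @param path alternatively, a file containing one Newick tree.
#' @return a [PhyloTree-class] (without sequences; see
#'   [attachAlignment()]).
#' @examples
#' tr <- readNewick("((R:1,S:1)Y:1,Z:2)X;")
#' nodeIds(tr)
#' @export
readNewick <- function(text = NULL, path = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop("tree file not found: ", path)
    text <- paste(readLines(path), collapse = "")
  }
  text <- trimws(text)
  n <- nchar(text)
  pos <- 1L
  peek <- function() if (pos <= n) substr(text, pos, pos) else "<end>"
  err <- function(what) stop("Newick parse error at position ", pos, ": ",
                             what, call. = FALSE)
  readName <- function() {
    m <- regmatches(substr(text, pos, n),
                    regexpr("^[^(),:;\\s]+", substr(text, pos, n),
                            perl = TRUE))
    if (length(m)) { pos <<- pos + nchar(m); m } else ""
  }
  readLen <- function() {
    if (peek() != ":") return(NA_real_)
    pos <<- pos + 1L
    m <- regmatches(substr(text, pos, n),
                    regexpr("^[-+0-9.eE]+", substr(text, pos, n)))
    if (!length(m)) err("expected a branch length after ':'")
    pos <<- pos + nchar(m)
    v <- suppressWarnings(as.numeric(m))
    if (is.na(v)) err(paste0("bad branch length '", m, "'"))
    v
  }
  parseSub <- function() {
    if (peek() == "(") {
      pos <<- pos + 1L
      kids <- list(parseSub())
      while (peek() == ",") { pos <<- pos + 1L
                              kids <- c(kids, list(parseSub())) }
      if (peek() != ")") err(paste0("expected ')', got '", peek(), "'"))
      pos <<- pos + 1L
      list(name = readName(), len = readLen(), children = kids)
    } else {
      nm <- readName()
      if (nm == "") err(paste0("unexpected '", peek(), "'"))
      list(name = nm, len = readLen(), children = list())
    }
  }
  root <- parseSub()
  if (peek() != ";") err(paste0("expected ';', got '", peek(), "'"))
  if (length(root$children) > 2 && root$name == "")
    stop("unrooted tree rejected (unnamed basal multifurcation); ",
         "provide a rooted Newick tree")
  ids <- character(); parent <- integer(); lengths <- numeric()
  autoN <- 0L
  flatten <- function(node, parentPos) {
    nm <- node$name
    if (nm == "") { autoN <<- autoN + 1L; nm <- paste0("N", autoN) }
    if (is.na(parentPos)) {
      blen <- NA_real_
    } else {
      blen <- node$len
      if (is.na(blen))
        stop("Newick parse error: missing branch length at node '", nm,
             "'", call. = FALSE)
      if (blen < 0)
        stop("Newick parse error: negative branch length at node '", nm,
             "'", call. = FALSE)
    }
    ids <<- c(ids, nm); parent <<- c(parent, parentPos)
    lengths <<- c(lengths, blen)
    my <- length(ids)
    for (ch in node$children) flatten(ch, my)
  }
  flatten(root, NA_integer_)
  if (anyDuplicated(ids))
    stop("duplicate node names in tree: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  new("PhyloTree", ids = ids, parent = parent, lengths = lengths,
      sequences = stats::setNames(rep(NA_character_, length(ids)), ids),
      nsites = 0L,
      ancestralFixed = stats::setNames(rep(FALSE, length(ids)), ids))
}

#' Write a tree back to Newick
#'
#' @param tree a [PhyloTree-class].
#' @param path optional file path; when NULL the Newick string is
#'   returned.
#' @return the Newick string (invisibly when written to a file).
#' @export
writeNewick <- function(tree, path = NULL) {
  kids <- .childIndex(tree)
  rec <- function(i) {
    ch <- kids[[i]]
    lab <- tree@ids[i]
    body <- if (length(ch))
      paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","),
             ")", lab)
    else lab
    if (is.na(tree@parent[i])) body
    else paste0(body, ":", format(tree@lengths[i], digits = 15))
  }
  out <- paste0(rec(1L), ";")
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

.childIndex <- function(tree) {
  n <- length(tree@ids)
  kids <- vector("list", n)
  for (i in seq_len(n)[-1]) {
    p <- tree@parent[i]
    kids[[p]] <- c(kids[[p]], i)
  }
  kids
}

#' @rdname tree-accessors
#' @param x a [PhyloTree-class].
#' @aliases nodeIds leafIds sequences nSites branchLengths
#' @export
setMethod("nodeIds", "PhyloTree", function(x) x@ids)
#' @rdname tree-accessors
#' @export
setMethod("leafIds", "PhyloTree", function(x) {
  x@ids[!seq_along(x@ids) %in% x@parent]
})
#' @rdname tree-accessors
#' @export
setMethod("sequences", "PhyloTree", function(x) x@sequences)
#' @rdname tree-accessors
#' @export
setMethod("nSites", "PhyloTree", function(x) x@nsites)
#' @rdname tree-accessors
#' @export
setMethod("branchLengths", "PhyloTree",
          function(x) stats::setNames(x@lengths, x@ids))

#' Children of a node
#' @param tree a [PhyloTree-class].
#' @param id node identifier.
#' @return character vector of child node ids (empty for a leaf).
#' @export
childrenOf <- function(tree, id) {
  i <- match(id, tree@ids)
  if (is.na(i)) stop("unknown node id: ", id)
  tree@ids[which(tree@parent == i)]
}

setMethod("show", "PhyloTree", function(object) {
  lv <- leafIds(object)
  cat("PhyloTree:", length(object@ids), "nodes,", length(lv), "leaves")
  if (object@nsites > 0) cat(",", object@nsites, "aligned sites")
  cat("\n  leaves:", paste(utils::head(lv, 8), collapse = ", "),
      if (length(lv) > 8) "...", "\n")
})

#' Attach an alignment to a tree
#'
#' Labels the tree's leaves (mandatory: every leaf needs a sequence) and,
#' optionally, internal nodes with fixed ancestral sequences, e.g. from a
#' maximum-parsimony reconstruction; such nodes are flagged and honored as
#' known states by the likelihood machinery. Sequences must be equal-length
#' words over A,C,G,T; ambiguity codes and gaps are rejected.
#'
#' @param tree a [PhyloTree-class].
#' @param seqs named character vector or list, taxon name -> sequence.
#' @return the labeled [PhyloTree-class].
#' @export
attachAlignment <- function(tree, seqs) {
  seqs <- toupper(unlist(seqs))
  unknown <- setdiff(names(seqs), tree@ids)
  if (length(unknown))
    stop("sequences for unknown taxa: ", paste(unknown, collapse = ", "))
  missingLeaves <- setdiff(leafIds(tree), names(seqs))
  if (length(missingLeaves))
    stop("missing sequences for leaves: ",
         paste(missingLeaves, collapse = ", "))
  if (length(unique(nchar(seqs))) != 1)
    stop("all sequences must have the same length")
  bad <- names(seqs)[grepl("[^ACGT]", seqs)]
  if (length(bad))
    stop("non-ACGT symbols (ambiguity codes are not supported) in: ",
         paste(bad, collapse = ", "))
  tree@sequences[names(seqs)] <- seqs
  tree@nsites <- nchar(seqs[[1]])
  internal <- setdiff(names(seqs), leafIds(tree))
  tree@ancestralFixed[internal] <- TRUE
  validObject(tree)
  tree
}

#' Read a plain FASTA alignment
#'
#' @param path FASTA file of aligned DNA sequences.
#' @return named character vector, taxon -> sequence, suitable for
#'   [attachAlignment()].
#' @export
readFastaAlignment <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Distance from the root to a node
#'
#' Sum of branch lengths on the unique root-to-node path (0 at the root).
#'
#' @param tree a [PhyloTree-class].
#' @param id node identifier.
#' @return nonnegative time.
#' @export
rootToLeafDistance <- function(tree, id) {
  i <- match(id, tree@ids)
  if (is.na(i)) stop("unknown node id: ", id)
  d <- 0
  while (!is.na(tree@parent[i])) {
    d <- d + tree@lengths[i]
    i <- tree@parent[i]
  }
  d
}

#' Per-site propositions of a sequence
#' @keywords internal
.siteProps <- function(seq) {
  bases <- strsplit(seq, "")[[1]]
  paste0("x", seq_along(bases), "=", bases)
}

#' Convert a fully labeled tree into a probabilistic transition system
#'
#' States are tree nodes, labeled with their per-site nucleotide
#' propositions (x1=A, x2=C, ...). The transition weight from a node to a
#' child is the product over sites of the substitution probabilities
#' P_{b_parent, b_child}(d) at the branch length d (sites evolve
#' independently); edges whose product is 0 are removed. Every leaf
#' receives a unit self-loop so all paths are infinite — the temporal-logic
#' engine relies on this.
#'
#' @param tree a fully labeled [PhyloTree-class] (every node carries a
#'   sequence; use [prune()] when ancestors are unknown).
#' @param model a [MutationModel-class].
#' @return a [TreePTS-class].
#' @export
toPTS <- function(tree, model) {
  if (anyNA(tree@sequences))
    stop("toPTS needs a fully labeled tree (all nodes with sequences); ",
         "for unknown ancestors use the likelihood engine (prune)")
  n <- length(tree@ids)
  R <- matrix(0, n, n, dimnames = list(tree@ids, tree@ids))
  Pcache <- new.env(parent = emptyenv())
  for (i in seq_len(n)[-1]) {
    p <- tree@parent[i]
    d <- tree@lengths[i]
    key <- format(d, digits = 17)
    P <- get0(key, envir = Pcache)
    if (is.null(P)) {
      P <- transitionMatrix(model, d)
      assign(key, P, envir = Pcache)
    }
    bp <- strsplit(tree@sequences[p], "")[[1]]
    bc <- strsplit(tree@sequences[i], "")[[1]]
    R[p, i] <- prod(P[cbind(bp, bc)])
  }
  leafPos <- setdiff(seq_len(n), tree@parent[!is.na(tree@parent)])
  for (i in leafPos) R[i, i] <- 1
  labels <- lapply(tree@sequences, .siteProps)
  names(labels) <- tree@ids
  chain <- ctmc(R, initial = tree@ids[1], labels = labels)
  new("TreePTS", ctmc = chain, leafStates = tree@ids[leafPos])
}

setMethod("show", "TreePTS", function(object) {
  cat("TreePTS over", length(object@ctmc@states), "tree states,",
      length(object@leafStates), "leaf self-loops\n")
})
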