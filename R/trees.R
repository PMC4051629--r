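#' Read and write trees in newick form
#'
#' Thin wrappers around \pkg{ape}'s newick reader/writer that add the
#' validation this package relies on: unique, non-empty leaf labels.
#' Branch lengths are tolerated on input and carried along, but every
#' parsimony computation ignores them.
#'
#' @param text a newick string (one tree).
#' @param file optional path; one tree per line when reading files.
#' @return a `phylo` (or `multiPhylo` from [read_newick_file]).
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("newick parse error: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("newick parse error: no tree in input")
  check_tree(tr)
  tr
}

#' @rdname parse_newick
#' @export
read_newick_file <- function(file) {
  trs <- ape::read.tree(file)
  if (inherits(trs, "phylo")) trs <- structure(list(trs), class = "multiPhylo")
  lapply(trs, check_tree)
  trs
}

#' @rdname parse_newick
#' @param tree a `phylo` object (or `multiPhylo` for files).
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) ape::write.tree(tree)
  else { ape::write.tree(tree, file = file); invisible(NULL) }
}

check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (any(!nzchar(tree$tip.label))) stop("empty leaf label")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf label: ",
         tree$tip.label[duplicated(tree$tip.label)][1])
  invisible(tree)
}

#' Root a tree at an outgroup taxon
#'
#' Produces the rooted presentation used for character mapping: the root
#' has exactly two children, the outgroup leaf and the ingroup subtree.
#' The underlying unrooted topology is unchanged, so tree length is
#' unaffected (Fitch counting is root-invariant).
#'
#' @param tree a `phylo`.
#' @param outgroup a leaf label of `tree`.
#' @return a rooted `phylo`.
#' @export
root_at_outgroup <- function(tree, outgroup) {
  check_tree(tree)
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a leaf of the tree")
  tr <- ape::unroot(tree)
  ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
}

#' Number of unrooted binary topologies
#'
#' The double factorial (2n-5)!! counting distinct unrooted binary trees
#' on n labelled leaves.
#'
#' @param n number of leaves (>= 3).
#' @return a double (exact for the sizes this package accepts).
#' @export
n_topologies <- function(n) {
  stopifnot(n >= 3)
  if (n == 3) return(1)
  prod(seq(3, 2 * n - 5, by = 2))
}

#' Enumerate all unrooted binary topologies
#'
#' Deterministic stepwise insertion: taxon k+1 is inserted into every
#' branch of every partial tree on the first k taxa, so each topology is
#' produced exactly once and the order is fixed by the input label order.
#' With `FUN` the trees are streamed one at a time and only the count is
#' returned; otherwise a `multiPhylo` is materialised (refused beyond
#' `max_trees` topologies).
#'
#' @param taxa character vector of >= 3 labels.
#' @param FUN optional callback applied to each `phylo`.
#' @param max_taxa refusal cap on the number of taxa (default 11).
#' @param max_trees materialisation cap when `FUN` is `NULL`.
#' @return a `multiPhylo`, or the invisible count when `FUN` is given.
#' @export
enumerate_topologies <- function(taxa, FUN = NULL, max_taxa = 11,
                                 max_trees = 2e5) {
  taxa <- as.character(taxa)
  n <- length(taxa)
  if (n < 3) stop("need at least 3 taxa")
  if (n > max_taxa)
    cap_error(sprintf(
      "refusing to enumerate %d taxa: (2n-5)!! = %.0f unrooted binary topologies (cap %d)",
      n, n_topologies(n), max_taxa))
  if (is.null(FUN) && n_topologies(n) > max_trees)
    cap_error(sprintf(
      "%.0f topologies exceed max_trees = %.0f; supply FUN to stream",
      n_topologies(n), max_trees))
  out <- if (is.null(FUN)) vector("list", n_topologies(n)) else NULL
  cnt <- 0L
  emit <- function(eu, ev, nint) {
    tr <- edges_to_phylo(eu, ev, n, nint, taxa)
    cnt <<- cnt + 1L
    if (is.null(FUN)) out[[cnt]] <<- tr else FUN(tr)
  }
  rec <- function(eu, ev, nint, k) {
    if (k > n) { emit(eu, ev, nint) ; return(invisible(NULL)) }
    for (e in seq_along(eu)) {
      w <- n + nint + 1L
      eu2 <- c(eu, w, w); ev2 <- c(ev, ev[e], k)
      eu2[e] <- eu[e]; ev2[e] <- w
      rec(eu2, ev2, nint + 1L, k + 1L)
    }
  }
  # 3-taxon star: hub n+1
  rec(c(n + 1L, n + 1L, n + 1L), c(1L, 2L, 3L), 1L, 4L)
  if (is.null(FUN)) structure(out, class = "multiPhylo") else invisible(cnt)
}

# convert an internal (eu, ev) unrooted edge list (leaves 1..n, internals
# n+1..n+nint) into a phylo rooted at the first internal node
edges_to_phylo <- function(eu, ev, n, nint, labels) {
  adj <- vector("list", n + nint)
  for (i in seq_along(eu)) {
    adj[[eu[i]]] <- c(adj[[eu[i]]], ev[i])
    adj[[ev[i]]] <- c(adj[[ev[i]]], eu[i])
  }
  newid <- integer(n + nint)
  newid[seq_len(n)] <- seq_len(n)
  nexti <- n + 1L
  parent <- integer(0); child <- integer(0)
  emit_edges <- function(v, from) {
    newid[v] <<- nexti; nexti <<- nexti + 1L
    for (u in adj[[v]]) {
      if (identical(u, from)) next
      if (u <= n) {
        parent <<- c(parent, newid[v]); child <<- c(child, u)
      } else {
        parent <<- c(parent, newid[v]); child <<- c(child, NA_integer_)
        idx <- length(child)
        emit_edges(u, v)
        child[idx] <<- newid[u]
      }
    }
  }
  emit_edges(n + 1L, 0L)
  tr <- list(edge = cbind(parent, child), tip.label = labels,
             Nnode = nint)
  dimnames(tr$edge) <- NULL
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  tr
}

#' Canonical topology identity token
#'
#' Two trees receive the same token iff they are the same unrooted
#' topology on the same leaf set (polytomies included).  The token is the
#' sorted nested-parenthesis normal form obtained by rooting at the edge
#' incident to the lexicographically smallest leaf and sorting children
#' recursively.
#'
#' @param tree a `phylo`, rooted or unrooted.
#' @return a character scalar.
#' @export
canonical_id <- function(tree) {
  check_tree(tree)
  tr <- if (ape::is.rooted(tree) && tree$Nnode > 1) ape::unroot(tree) else tree
  n <- length(tr$tip.label)
  if (n < 3) stop("need at least 3 leaves")
  adj <- vector("list", n + tr$Nnode)
  for (i in seq_len(nrow(tr$edge))) {
    a <- tr$edge[i, 1]; b <- tr$edge[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  ref <- which(tr$tip.label == min(tr$tip.label))
  norm <- function(v, from) {
    if (v <= n) return(tr$tip.label[v])
    parts <- character(0)
    for (u in adj[[v]]) if (u != from) parts <- c(parts, norm(u, v))
    paste0("(", paste(sort(parts), collapse = ","), ")")
  }
  paste0("(", tr$tip.label[ref], ",", norm(adj[[ref]][1], ref), ")")
}

# leaf-set guard shared by scoring functions
match_tree_matrix <- function(tree, matrix) {
  a <- tree$tip.label; b <- matrix$taxa
  if (!setequal(a, b)) {
    stop("tree/matrix leaf sets differ; only in tree: {",
         paste(setdiff(a, b), collapse = ", "), "}; only in matrix: {",
         paste(setdiff(b, a), collapse = ", "), "}")
  }
  match(a, b)
}
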