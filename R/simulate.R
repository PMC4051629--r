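#' Simulate an Mk-style character matrix on a known tree
#'
#' Characters evolve independently down a rooted traversal of `tree` from
#' root state 0: on each branch the number of state changes is Poisson
#' with the branch's expected count (the branch length when present,
#' otherwise `mean_changes`), and each change moves to a state drawn
#' uniformly among the other states.  A chosen fraction of characters is
#' instead forced to be a clean autapomorphy (derived state 1 in exactly
#' one uniformly chosen leaf), emulating the autapomorphy-rich
#' morphological matrices this package targets.  Counts-per-branch rather
#' than continuous-time rates keep expected homoplasy directly
#' controllable.
#'
#' @param tree a rooted `phylo` giving the true topology; branch lengths,
#'   if present, are per-branch expected change counts.
#' @param n_characters number of characters.
#' @param states number of states per character (2 or 3).
#' @param mean_changes expected changes per branch when the tree carries
#'   no branch lengths (default 0.3).
#' @param autapomorphy_fraction share of characters forced to vary in
#'   exactly one leaf (default 0).
#' @param seed integer seed (required); output is fully determined by the
#'   arguments.
#' @return a list: `matrix` (a [char_matrix]) and `tree` (the generating
#'   topology).
#' @examples
#' sim <- simulate_mk(ape::rtree(6, br = NULL), 20, seed = 1)
#' summary(sim$matrix)
#' @export
simulate_mk <- function(tree, n_characters, states = 2, mean_changes = 0.3,
                        autapomorphy_fraction = 0, seed) {
  check_tree(tree)
  stopifnot(states %in% 2:3, n_characters >= 1,
            autapomorphy_fraction >= 0, autapomorphy_fraction <= 1)
  if (missing(seed)) stop("simulate_mk() requires an explicit seed")
  tr <- if (ape::is.rooted(tree)) tree else
    ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  tr <- ape::reorder.phylo(tr, "cladewise")   # edges parent-before-child
  n <- length(tr$tip.label)
  nn <- n + tr$Nnode
  br_mean <- if (!is.null(tr$edge.length)) tr$edge.length
             else rep(mean_changes, nrow(tr$edge))
  root <- setdiff(tr$edge[, 1], tr$edge[, 2])[1]
  eord <- seq_len(nrow(tr$edge))
  with_seed(seed, {
    n_aut <- round(autapomorphy_fraction * n_characters)
    aut <- if (n_aut > 0) sample.int(n_characters, n_aut) else integer(0)
    out <- base::matrix(0L, n, n_characters)
    for (ch in seq_len(n_characters)) {
      if (ch %in% aut) {
        out[sample.int(n, 1L), ch] <- 1L
        next
      }
      st <- integer(nn); st[root] <- 0L
      for (e in eord) {
        s <- st[tr$edge[e, 1]]
        k <- rpois(1, br_mean[e])
        for (i in seq_len(k)) s <- sample(setdiff(0:(states - 1), s), 1L)
        st[tr$edge[e, 2]] <- s
      }
      out[, ch] <- st[seq_len(n)]
    }
    rownames(out) <- tr$tip.label
    list(matrix = char_matrix(out), tree = tree)
  })
}

#' Perfectly compatible matrix from a tree
#'
#' One binary character per non-trivial split of the tree (each repeated
#' `chars_per_edge` times), with the derived state 1 marking clade
#' membership.  The resulting matrix is fully compatible: the unique
#' most-parsimonious tree is the generating topology, its length equals
#' the number of characters, and CI = RI = 1.
#'
#' @param tree a binary `phylo` with at least 4 leaves.
#' @param chars_per_edge repeats per split (>= 1).
#' @return a [char_matrix].
#' @examples
#' simulate_perfect_hierarchy(ape::rtree(6, br = NULL))
#' @export
simulate_perfect_hierarchy <- function(tree, chars_per_edge = 1) {
  check_tree(tree)
  stopifnot(chars_per_edge >= 1)
  n <- length(tree$tip.label)
  if (n < 4) stop("need at least 4 leaves for a non-trivial split")
  ut <- if (ape::is.rooted(tree) && tree$Nnode > 1) ape::unroot(tree) else tree
  kids <- split(ut$edge[, 2], ut$edge[, 1])
  below <- function(v) {
    if (v <= n) return(v)
    sort(unlist(lapply(kids[[as.character(v)]], below)))
  }
  root <- setdiff(ut$edge[, 1], ut$edge[, 2])[1]
  internal_children <- ut$edge[ut$edge[, 2] > n, 2]
  splits <- Filter(function(s) length(s) >= 2 && length(s) <= n - 2,
                   lapply(internal_children, below))
  if (!length(splits)) stop("tree has no non-trivial split")
  cols <- do.call(cbind, lapply(splits, function(s) {
    col <- integer(n); col[s] <- 1L; col
  }))
  cols <- cols[, rep(seq_len(ncol(cols)), each = chars_per_edge), drop = FALSE]
  rownames(cols) <- ut$tip.label
  char_matrix(cols)
}

#' Permute every character column independently
#'
#' A null-model utility: each character's states are shuffled across
#' taxa, destroying hierarchical structure while preserving every
#' column's state multiset (hence the m and g bounds, and their sums).
#'
#' @param matrix a [char_matrix].
#' @param seed integer seed (required).
#' @return a [char_matrix] with the same dimensions, weights and
#'   outgroup.
#' @export
permute_columns <- function(matrix, seed) {
  if (missing(seed)) stop("permute_columns() requires an explicit seed")
  with_seed(seed, {
    s <- matrix$states
    for (j in seq_len(ncol(s))) s[, j] <- s[sample.int(nrow(s)), j]
    out <- matrix
    out$states <- s
    rownames(out$states) <- matrix$taxa
    out
  })
}
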