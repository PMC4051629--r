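# state-set bitmask encoding: bit s set <=> state s allowed at the leaf;
# a missing cell becomes the union of the states observed in its column
matrix_masks <- function(matrix, for_bound = FALSE) {
  s <- matrix$states
  out <- base::matrix(0L, nrow(s), ncol(s))
  for (j in seq_len(ncol(s))) {
    col <- s[, j]
    obs <- sort(unique(col[!is.na(col)]))
    full <- if (length(obs)) sum(bitwShiftL(1L, obs)) else 1L
    out[, j] <- ifelse(is.na(col), if (for_bound) 0L else full,
                       bitwShiftL(1L, col))
  }
  out
}

#' Parsimony length of a fixed topology
#'
#' Minimum number of unordered state changes needed to explain every
#' character on the given tree: a Fitch bottom-up pass on binary nodes,
#' generalised via Hartigan's state-frequency rule on polytomies, so
#' rooted, unrooted and multifurcating trees are all scored exactly.
#' Missing cells enter as the full state set and never force a change.
#' The result is invariant to root placement.
#'
#' @param tree a `phylo` whose leaf set equals the matrix taxa.
#' @param matrix a [char_matrix].
#' @param use_weights apply the matrix's per-character weights (default
#'   `TRUE`; the shipped analysis is equal-weights so the weighted and
#'   plain totals coincide).
#' @return an `mp_length`: list with `total`, integer `per_character`
#'   steps (named by character id) and the `weighted` flag.
#' @examples
#' m <- saltans_matrix()
#' tr <- parse_newick(saltans_certificate_newick())
#' tree_length(tr, m)
#' @export
tree_length <- function(tree, matrix, use_weights = TRUE) {
  check_tree(tree)
  idx <- match_tree_matrix(tree, matrix)
  masks <- matrix_masks(matrix)[idx, , drop = FALSE]
  w <- if (use_weights) matrix$weights else rep(1, ncol(matrix$states))
  res <- hartigan_score_cpp(tree$edge, length(tree$tip.label), masks, w)
  structure(list(
    total = if (all(w == round(w))) as.integer(round(res$total)) else res$total,
    per_character = setNames(res$per_character, matrix$char_ids),
    weighted = use_weights && any(matrix$weights != 1)
  ), class = "mp_length")
}

#' @export
print.mp_length <- function(x, ...) {
  cat("tree length:", x$total,
      if (x$weighted) "(weighted)" else "", "\n")
  cat("per-character steps:\n")
  print(x$per_character)
  invisible(x)
}

#' Per-character step bounds
#'
#' For each character, `m` is the fewest changes it can require on any
#' tree (observed states minus one) and `g` the most (the star-tree
#' length: scored taxa minus the largest single-state frequency, the
#' standard maxsteps convention for unordered characters).  Missing cells
#' are excluded from both.  These are the ingredients of the consistency
#' and retention indices.
#'
#' @param matrix a [char_matrix].
#' @return a data frame with columns `char`, `m`, `g` and attributes
#'   `sum_m`, `sum_g`.
#' @examples
#' b <- char_bounds(saltans_matrix())
#' attr(b, "sum_m"); attr(b, "sum_g")
#' @export
char_bounds <- function(matrix) {
  s <- matrix$states
  m <- integer(ncol(s)); g <- integer(ncol(s))
  for (j in seq_len(ncol(s))) {
    col <- s[, j][!is.na(s[, j])]
    tab <- if (length(col)) table(col) else integer(0)
    m[j] <- max(0L, length(tab) - 1L)
    g[j] <- if (length(tab)) length(col) - max(tab) else 0L
  }
  out <- data.frame(char = matrix$char_ids, m = m, g = g)
  attr(out, "sum_m") <- sum(m * matrix$weights)
  attr(out, "sum_g") <- sum(g * matrix$weights)
  out
}

#' The 24-step certificate topology for the bundled matrix
#'
#' A fully resolved tree on the eleven bundled taxa that attains the
#' exact-search optimum of 24 steps on [saltans_matrix()]; useful as a
#' deterministic input for scoring and mapping examples.
#'
#' @return a newick string.
#' @export
saltans_certificate_newick <- function() {
  paste0("(willistoni,(neocordata,((emarginata,(sturtevanti,",
         "(dacunhai,milleri))),(parasaltans,(saltans,(lusaltans,",
         "(prosaltans,austrosaltans)))))));")
}
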