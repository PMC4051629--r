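## ------------------------------------------------------------------------
## edge-list tree surgery (internal)
##
## An "el" is a pair of integer vectors (eu, ev) describing an unrooted
## tree: leaves are 1..n (indexing matrix$taxa), internal node ids are
## arbitrary integers > n.  Used by the ratchet's NNI/SPR moves and by
## branch collapsing.
## ------------------------------------------------------------------------

el_to_phylo <- function(eu, ev, labels) {
  n <- length(labels)
  ids <- sort(unique(c(eu, ev)))
  internal <- ids[ids > n]
  remap <- integer(max(ids))
  remap[seq_len(n)] <- seq_len(n)
  remap[internal] <- n + seq_along(internal)
  edges_to_phylo(remap[eu], remap[ev], n, length(internal), labels)
}

phylo_to_el <- function(tree, taxa) {
  tr <- if (ape::is.rooted(tree) && tree$Nnode > 1) ape::unroot(tree) else tree
  map <- match(tr$tip.label, taxa)
  n <- length(taxa)
  eu <- tr$edge[, 1]; ev <- tr$edge[, 2]
  eu <- ifelse(eu <= n, map[eu], eu)
  ev <- ifelse(ev <= n, map[ev], ev)
  list(eu = eu, ev = ev)
}

el_score <- function(el, labels, masks, w) {
  ph <- el_to_phylo(el$eu, el$ev, labels)
  hartigan_score_cpp(ph$edge, length(labels), masks, w)$total
}

# all NNI rearrangements around every internal edge (2 per edge)
nni_neighbors <- function(el, n) {
  out <- list()
  adj_of <- function(v) c(el$ev[el$eu == v], el$eu[el$ev == v])
  for (i in seq_along(el$eu)) {
    u <- el$eu[i]; v <- el$ev[i]
    if (u <= n || v <= n) next
    a <- setdiff(adj_of(u), v)[1]
    cds <- setdiff(adj_of(v), u)
    for (cc in cds) {
      eu <- el$eu; ev <- el$ev
      swap_end <- function(eu, ev, x, y, z) {
        # replace edge {x, y} by {z, y}
        k <- which((eu == x & ev == y) | (eu == y & ev == x))[1]
        if (eu[k] == x) eu[k] <- z else ev[k] <- z
        list(eu = eu, ev = ev)
      }
      t1 <- swap_end(eu, ev, u, a, v)
      t2 <- swap_end(t1$eu, t1$ev, v, cc, u)
      out[[length(out) + 1L]] <- t2
    }
  }
  out
}

# all SPR rearrangements: prune the subtree on the `v` side of each
# directed edge (u, v), suppress u, regraft onto every edge of the
# remaining tree (skipping the suppression edge, which restores the input)
spr_neighbors <- function(el, n) {
  out <- list()
  m <- length(el$eu)
  for (i in seq_len(m)) for (dir in 1:2) {
    u <- if (dir == 1) el$eu[i] else el$ev[i]
    v <- if (dir == 1) el$ev[i] else el$eu[i]
    if (u <= n) next                       # complement would be a single leaf
    keep <- setdiff(seq_len(m), i)
    eu <- el$eu[keep]; ev <- el$ev[keep]
    # component membership via flood fill from u
    nb <- unique(c(eu, ev))
    comp <- c(u); frontier <- u
    while (length(frontier)) {
      nxt <- unique(c(ev[eu %in% frontier], eu[ev %in% frontier]))
      frontier <- setdiff(nxt, comp)
      comp <- c(comp, frontier)
    }
    inU <- (eu %in% comp) & (ev %in% comp)
    # suppress u (degree 2 in the complement)
    ue <- which(inU & (eu == u | ev == u))
    if (length(ue) != 2L) next             # u had degree < 3: nothing to do
    x <- setdiff(c(eu[ue[1]], ev[ue[1]]), u)
    y <- setdiff(c(eu[ue[2]], ev[ue[2]]), u)
    eu2 <- c(eu[-ue], x); ev2 <- c(ev[-ue], y)
    inU2 <- c(inU[-ue], TRUE)
    sup <- length(eu2)                     # index of the new (x, y) edge
    for (e in which(inU2)) {
      if (e == sup) next
      a <- eu2[e]; b <- ev2[e]
      neu <- c(eu2, u, u); nev <- c(ev2, b, v)
      neu[e] <- a; nev[e] <- u
      out[[length(out) + 1L]] <- list(eu = neu, ev = nev)
    }
  }
  out
}

contract_edges <- function(el, which_edges) {
  if (!length(which_edges)) return(el)
  ids <- sort(unique(c(el$eu, el$ev)))
  rep_of <- setNames(ids, ids)
  find <- function(v) {
    while (rep_of[[as.character(v)]] != v) v <- rep_of[[as.character(v)]]
    v
  }
  for (e in which_edges) {
    a <- find(el$eu[e]); b <- find(el$ev[e])
    if (a != b) rep_of[[as.character(max(a, b))]] <- min(a, b)
  }
  eu <- vapply(el$eu, find, 0); ev <- vapply(el$ev, find, 0)
  keep <- eu != ev
  list(eu = eu[keep], ev = ev[keep])
}

## ------------------------------------------------------------------------
## search results
## ------------------------------------------------------------------------

new_mp_search <- function(method, matrix, best_length, trees, examined,
                          pruned, seed = NULL, log = list(), collapse = TRUE) {
  ids <- vapply(trees, canonical_id, "")
  trees <- trees[!duplicated(ids)]
  class(trees) <- "multiPhylo"
  collapsed <- if (collapse) collapse_and_dedup(trees, matrix) else trees
  structure(list(
    method = method,
    best_length = as.integer(round(best_length)),
    best_trees_binary = trees,
    best_trees_collapsed = collapsed,
    n_topologies_examined = examined,
    n_pruned = pruned,
    outgroup = matrix$outgroup,
    seed = seed,
    search_log = log
  ), class = "mp_search")
}

#' @export
print.mp_search <- function(x, ...) {
  cat(sprintf("maximum parsimony search (%s)\n", x$method))
  cat(sprintf("  best length: %d\n", x$best_length))
  cat(sprintf("  optimal binary trees: %d   after collapsing: %d\n",
              length(x$best_trees_binary), length(x$best_trees_collapsed)))
  cat(sprintf("  topologies scored: %.0f   subtrees pruned: %.0f\n",
              x$n_topologies_examined, x$n_pruned))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' @export
summary.mp_search <- function(object, matrix = NULL, ...) {
  cat_tree <- write_newick(object$best_trees_collapsed[[1]])
  out <- list(search = object, collapsed_newick = cat_tree)
  class(out) <- "summary.mp_search"
  out
}

#' @export
print.summary.mp_search <- function(x, ...) {
  print(x$search)
  cat("  first collapsed optimum:\n  ", x$collapsed_newick, "\n")
  invisible(x)
}

#' @export
plot.mp_search <- function(x, which = c("collapsed", "binary", "consensus"),
                           ...) {
  which <- match.arg(which)
  tr <- switch(which,
    collapsed = x$best_trees_collapsed[[1]],
    binary = x$best_trees_binary[[1]],
    consensus = strict_consensus(x$best_trees_binary))
  if (!is.null(x$outgroup) && x$outgroup %in% tr$tip.label)
    tr <- root_at_outgroup(tr, x$outgroup)
  ape::plot.phylo(tr, ...)
  invisible(x)
}

# addition order: decreasing total character conflict (cells holding a
# minority state), ties broken by input order
addition_order <- function(matrix) {
  s <- matrix$states
  conf <- numeric(nrow(s))
  for (j in seq_len(ncol(s))) {
    col <- s[, j]
    tab <- table(col[!is.na(col)])
    if (!length(tab)) next
    maj <- as.integer(names(tab)[which.max(tab)])
    conf <- conf + matrix$weights[j] * (!is.na(col) & col != maj)
  }
  order(-conf)
}

search_trees_from_newick <- function(newicks, taxa_in_order) {
  lapply(newicks, function(nw) {
    tr <- ape::read.tree(text = nw)
    tr$tip.label <- taxa_in_order[as.integer(sub("^t", "", tr$tip.label))]
    tr
  })
}

#' Exact parsimony search by branch and bound
#'
#' Finds every most-parsimonious unrooted binary topology.  Taxa are
#' added by stepwise insertion in decreasing order of character conflict;
#' a partial tree is abandoned when its Fitch length plus an admissible
#' completion bound (one step for every state seen only among unplaced
#' taxa) exceeds the best complete length found so far, so the optimum
#' set is provably identical to exhaustive enumeration.  The initial
#' upper bound comes from one greedy stepwise-addition tree unless
#' supplied.
#'
#' @param matrix a [char_matrix] with at least 4 taxa.
#' @param initial_bound optional starting upper bound on tree length.
#' @param max_optima cap on the number of stored optimal trees.
#' @param collapse also compute the zero-minimum-length collapsed optimum
#'   set (see [collapse_and_dedup]).
#' @return an `mp_search` with the optimum length, all optimal binary
#'   trees, the collapsed set, and search accounting
#'   (`n_topologies_examined` complete topologies scored, `n_pruned`
#'   subtrees discarded).
#' @examples
#' fit <- branch_and_bound(saltans_matrix())
#' fit
#' @export
branch_and_bound <- function(matrix, initial_bound = NULL, max_optima = 1e5,
                             collapse = TRUE) {
  validate_char_matrix(matrix)
  ord <- addition_order(matrix)
  masks <- matrix_masks(matrix)[ord, , drop = FALSE]
  bmasks <- matrix_masks(matrix, for_bound = TRUE)[ord, , drop = FALSE]
  ub <- if (is.null(initial_bound)) {
    g <- greedy_cpp(masks, matrix$weights)
    g$length
  } else as.numeric(initial_bound)
  res <- bnb_cpp(masks, bmasks, matrix$weights, ub, TRUE, max_optima, Inf)
  if (res$overflow) warning("optimum set truncated at max_optima = ", max_optima)
  trees <- search_trees_from_newick(res$trees, matrix$taxa[ord])
  new_mp_search("branch-and-bound", matrix, res$best, trees,
                res$n_complete, res$n_pruned,
                log = list(initial_upper_bound = ub), collapse = collapse)
}

#' Exact parsimony search by exhaustive enumeration
#'
#' Scores every unrooted binary topology (all (2n-5)!! of them) and
#' returns the full optimum set.  Intended as the oracle for
#' [branch_and_bound] at small n; refuses more than `max_taxa` taxa.
#'
#' @inheritParams branch_and_bound
#' @param max_taxa refusal cap (default 11).
#' @return an `mp_search`.
#' @export
exhaustive_search <- function(matrix, max_taxa = 11, max_optima = 1e5,
                              collapse = TRUE) {
  validate_char_matrix(matrix)
  n <- nrow(matrix$states)
  if (n > max_taxa)
    cap_error(sprintf(
      "refusing exhaustive search over %d taxa: (2n-5)!! = %.0f topologies (cap %d)",
      n, n_topologies(n), max_taxa))
  ord <- addition_order(matrix)
  masks <- matrix_masks(matrix)[ord, , drop = FALSE]
  bmasks <- matrix_masks(matrix, for_bound = TRUE)[ord, , drop = FALSE]
  res <- bnb_cpp(masks, bmasks, matrix$weights, Inf, FALSE, max_optima, Inf)
  if (res$overflow) warning("optimum set truncated at max_optima = ", max_optima)
  trees <- search_trees_from_newick(res$trees, matrix$taxa[ord])
  new_mp_search("exhaustive", matrix, res$best, trees,
                res$n_complete, res$n_pruned, collapse = collapse)
}

#' Parsimony ratchet heuristic
#'
#' Random-addition start followed by ratchet cycles: hill climbing (all
#' NNI rearrangements first, then all SPR rearrangements) under
#' perturbed weights in which a random quarter of the characters is
#' upweighted twofold, then re-climbing under the original weights.
#' Deterministic given `seed`; the ambient RNG stream is left untouched.
#'
#' @param matrix a [char_matrix].
#' @param iterations number of ratchet cycles (>= 1).
#' @param seed integer seed (required).
#' @param collapse as in [branch_and_bound].
#' @return an `mp_search` holding the best length found and every
#'   distinct optimal topology encountered at that length.
#' @export
ratchet_search <- function(matrix, iterations = 1000, seed, collapse = TRUE) {
  validate_char_matrix(matrix)
  stopifnot(iterations >= 1)
  if (missing(seed)) stop("ratchet_search() requires an explicit seed")
  taxa <- matrix$taxa
  n <- length(taxa)
  masks <- matrix_masks(matrix)
  w <- matrix$weights
  nch <- length(w)

  climb <- function(el, wts) {
    cur <- el_score(el, taxa, masks, wts)
    repeat {
      moved <- FALSE
      for (gen in list(nni_neighbors, spr_neighbors)) {
        cand <- gen(el, n)
        if (!length(cand)) next
        lens <- vapply(cand, el_score, 0, labels = taxa, masks = masks, w = wts)
        if (min(lens) < cur - 1e-9) {
          k <- which.min(lens)
          el <- cand[[k]]; cur <- lens[k]; moved <- TRUE
          break
        }
      }
      if (!moved) return(list(el = el, len = cur))
    }
  }

  with_seed(seed, {
    perm <- sample.int(n)
    g <- greedy_cpp(masks[perm, , drop = FALSE], w)
    start <- ape::read.tree(text = g$tree)
    start$tip.label <- taxa[perm[as.integer(sub("^t", "", start$tip.label))]]
    cl <- climb(phylo_to_el(start, taxa), w)
    best_len <- cl$len
    best <- list(cl$el)
    best_ids <- canonical_id(el_to_phylo(cl$el$eu, cl$el$ev, taxa))
    current <- cl$el
    n_scored <- 1
    for (it in seq_len(iterations)) {
      w2 <- w
      up <- sample.int(nch, max(1L, round(0.25 * nch)))
      w2[up] <- w2[up] * 2
      pert <- climb(current, w2)
      back <- climb(pert$el, w)
      n_scored <- n_scored + 1
      if (back$len < best_len - 1e-9) {
        best_len <- back$len
        best <- list(back$el)
        best_ids <- canonical_id(el_to_phylo(back$el$eu, back$el$ev, taxa))
      } else if (back$len <= best_len + 1e-9) {
        id <- canonical_id(el_to_phylo(back$el$eu, back$el$ev, taxa))
        if (!id %in% best_ids) {
          best[[length(best) + 1L]] <- back$el
          best_ids <- c(best_ids, id)
        }
      }
      current <- back$el
    }
    trees <- lapply(best, function(el) el_to_phylo(el$eu, el$ev, taxa))
    new_mp_search("ratchet", matrix, best_len, trees,
                  examined = NA_real_, pruned = NA_real_, seed = seed,
                  log = list(iterations = iterations), collapse = collapse)
  })
}

#' Collapse zero-minimum-length branches and deduplicate
#'
#' Contracts every internal branch whose minimum number of changes over
#' all most-parsimonious reconstructions of every character is zero (the
#' branch is not forced to carry any change), then removes duplicate
#' topologies by [canonical_id].  Collapsing never alters tree length.
#'
#' @param trees a list/`multiPhylo` of trees on the matrix taxa.
#' @param matrix the [char_matrix] they were scored on.
#' @param rule only `"min-length-zero"` is implemented.
#' @return a `multiPhylo` of collapsed, deduplicated trees.
#' @export
collapse_and_dedup <- function(trees, matrix, rule = "min-length-zero") {
  rule <- match.arg(rule, "min-length-zero")
  if (inherits(trees, "phylo")) trees <- list(trees)
  out <- lapply(trees, function(tr) {
    fc <- forced_edge_counts(tr, matrix)
    zero <- which(fc$internal & fc$forced == 0L)
    if (!length(zero)) return(fc$scaffold$work)
    el <- list(eu = fc$scaffold$work$edge[, 1],
               ev = fc$scaffold$work$edge[, 2])
    el2 <- contract_edges(el, zero)
    el_to_phylo(el2$eu, el2$ev, fc$scaffold$work$tip.label)
  })
  ids <- vapply(out, canonical_id, "")
  structure(out[!duplicated(ids)], class = "multiPhylo")
}

#' Strict consensus tree
#'
#' The tree whose splits are exactly those present in every input tree.
#'
#' @param trees a list/`multiPhylo` of trees on one leaf set.
#' @return a `phylo`.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("need at least one tree")
  ref <- trees[[1]]$tip.label
  for (tr in trees) if (!setequal(tr$tip.label, ref))
    stop("consensus requires a common leaf set; saw {",
         paste(setdiff(union(tr$tip.label, ref),
                       intersect(tr$tip.label, ref)), collapse = ", "),
         "} out of place")
  if (length(trees) == 1L) return(trees[[1]])
  class(trees) <- "multiPhylo"
  ape::consensus(trees, p = 1, rooted = FALSE)
}
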