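# Shared scaffolding for most-parsimonious-reconstruction work: the tree is
# taken unrooted (a 2-child root is suppressed -- reconstructions are
# root-invariant), then oriented away from a reference leaf (the matrix
# outgroup when set) so every edge has a parent side and a child clade.
mpr_scaffold <- function(tree, matrix) {
  check_tree(tree)
  idx <- match_tree_matrix(tree, matrix)
  work <- if (ape::is.rooted(tree) && tree$Nnode > 1) ape::unroot(tree) else tree
  n <- length(work$tip.label)
  nn <- n + work$Nnode
  adj <- vector("list", nn)
  for (i in seq_len(nrow(work$edge))) {
    a <- work$edge[i, 1]; b <- work$edge[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  root_leaf <- if (!is.null(matrix$outgroup) &&
                   matrix$outgroup %in% work$tip.label)
    which(work$tip.label == matrix$outgroup)
  else which(work$tip.label == min(work$tip.label))
  # orientation: parent[] away from root_leaf, preorder over nodes
  parent <- rep(NA_integer_, nn)
  ord <- integer(0)
  stack <- root_leaf
  seen <- logical(nn); seen[root_leaf] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ord <- c(ord, v)
    for (u in adj[[v]]) if (!seen[u]) {
      seen[u] <- TRUE; parent[u] <- v; stack <- c(stack, u)
    }
  }
  # leaves below each node (in the root_leaf orientation)
  below <- vector("list", nn)
  for (v in rev(ord)) {
    if (v <= n) below[[v]] <- v
    else {
      kidsv <- adj[[v]][adj[[v]] != parent[v]]
      below[[v]] <- sort(unlist(below[kidsv]))
    }
  }
  # oriented edges: one per tree edge, child = non-parent endpoint
  echild <- integer(nrow(work$edge)); eparent <- integer(nrow(work$edge))
  for (i in seq_len(nrow(work$edge))) {
    a <- work$edge[i, 1]; b <- work$edge[i, 2]
    if (identical(parent[b], a)) { eparent[i] <- a; echild[i] <- b }
    else { eparent[i] <- b; echild[i] <- a }
  }
  masks <- matrix_masks(matrix)[idx, , drop = FALSE]
  list(work = work, n = n, nn = nn, adj = adj, parent = parent,
       preorder = ord, below = below, eparent = eparent, echild = echild,
       root_leaf = root_leaf, masks = masks,
       clade_label = function(v) paste(work$tip.label[below[[v]]],
                                       collapse = "|"))
}

#' Enumerate all most-parsimonious reconstructions of one character
#'
#' Exhaustively lists every assignment of states to internal nodes (and to
#' missing leaves) that attains the minimum change count for the chosen
#' character on the fixed topology, by depth-first search with cost
#' pruning over the character's observed states.  No ACCTRAN/DELTRAN
#' shortcut is involved; ambiguity is read directly off the full set.
#'
#' @param tree a `phylo` on the matrix taxa (rooted or unrooted).
#' @param matrix a [char_matrix].
#' @param char a character id (1-based column number).
#' @param max_mprs refusal guard on the number of reconstructions.
#' @return an `mpr` object: the minimum `steps`, an `assignments` matrix
#'   (one row per MPR, one column per node of the unrooted working tree),
#'   per-internal-node MPR state `sets`, and the working tree.
#' @examples
#' m <- saltans_matrix()
#' tr <- parse_newick(saltans_certificate_newick())
#' mpr_enumerate(tr, m, char = 3)
#' @export
mpr_enumerate <- function(tree, matrix, char, max_mprs = 1e6) {
  sc <- mpr_scaffold(tree, matrix)
  j <- match(char, matrix$char_ids)
  if (is.na(j)) stop("unknown character id: ", char)
  mpr_enumerate_scaffold(sc, matrix, j, max_mprs)
}

mpr_enumerate_scaffold <- function(sc, matrix, j, max_mprs = 1e6) {
  lm <- sc$masks[, j]
  states <- sort(unique(matrix$states[, j][!is.na(matrix$states[, j])]))
  if (!length(states)) states <- 0L
  s_min <- hartigan_score_cpp(sc$work$edge, sc$n,
                              base::matrix(lm, ncol = 1), 1)$total
  # nodes whose state is free: internal nodes plus multi-state leaves
  fixed <- rep(NA_integer_, sc$nn)
  for (v in seq_len(sc$n)) {
    bits <- states[bitwAnd(bitwShiftL(1L, states), lm[v]) != 0L]
    if (length(bits) == 1L) fixed[v] <- bits
  }
  free <- sc$preorder[is.na(fixed[sc$preorder])]
  allowed <- lapply(free, function(v) {
    if (v <= sc$n) states[bitwAnd(bitwShiftL(1L, states), lm[v]) != 0L]
    else states
  })
  # neighbors of each free node that are assigned earlier (fixed or prior)
  assigned_before <- lapply(seq_along(free), function(i) {
    v <- free[i]
    nb <- sc$adj[[v]]
    nb[!is.na(fixed[nb]) | nb %in% free[seq_len(i - 1L)]]
  })
  acc <- list(); cnt <- 0L
  cur <- fixed
  rec <- function(i, cost) {
    if (i > length(free)) {
      cnt <<- cnt + 1L
      if (cnt > max_mprs)
        cap_error(sprintf("more than %g most-parsimonious reconstructions", max_mprs))
      acc[[cnt]] <<- cur
      return(invisible(NULL))
    }
    v <- free[i]
    for (st in allowed[[i]]) {
      extra <- sum(cur[assigned_before[[i]]] != st)
      if (cost + extra > s_min) next
      cur[v] <<- st
      rec(i + 1L, cost + extra)
    }
    cur[v] <<- NA_integer_
    invisible(NULL)
  }
  # base cost: changes among edges whose endpoints are both fixed
  base_cost <- sum(fixed[sc$eparent] != fixed[sc$echild], na.rm = TRUE)
  rec(1L, base_cost)
  assignments <- do.call(rbind, acc)
  internal <- (sc$n + 1L):sc$nn
  sets <- lapply(internal, function(v) sort(unique(assignments[, v])))
  names(sets) <- internal
  structure(list(char = matrix$char_ids[j], steps = as.integer(s_min),
                 n_mprs = nrow(assignments), assignments = assignments,
                 sets = sets, tree = sc$work, root_leaf = sc$root_leaf),
            class = "mpr")
}

#' @export
print.mpr <- function(x, ...) {
  cat(sprintf("character %s: %d step(s), %d most-parsimonious reconstruction(s)\n",
              x$char, x$steps, x$n_mprs))
  invisible(x)
}

# per-MPR change signatures on one character: integer matrix with one row
# per (edge, from, to) triple and a column of MPR membership counts
change_signatures <- function(sc, assignments) {
  from <- assignments[, sc$eparent, drop = FALSE]
  to <- assignments[, sc$echild, drop = FALSE]
  chg <- from != to
  sig <- list()
  for (r in seq_len(nrow(assignments))) {
    es <- which(chg[r, ])
    key <- paste(es, from[r, es], to[r, es], sep = ":")
    for (k in seq_along(es)) {
      id <- key[k]
      if (is.null(sig[[id]]))
        sig[[id]] <- list(edge = es[k], from = from[r, es[k]],
                          to = to[r, es[k]], count = 1L)
      else sig[[id]]$count <- sig[[id]]$count + 1L
    }
  }
  sig
}

#' List inferred character changes with their ambiguity status
#'
#' Enumerates the MPRs of every character on the tree and emits one record
#' per distinct (branch, from-state, to-state) change.  A change is
#' `unambiguous` iff it occurs, with the same branch and states, in every
#' MPR of its character; changes present in only some MPRs are flagged
#' `ambiguous`.  Branches are identified by the leaf set of the clade they
#' subtend in the orientation away from the outgroup (changes on the
#' outgroup's incident edge are presented on the ingroup stem).
#'
#' @inheritParams mpr_enumerate
#' @param chars character ids to map (default: all variable characters).
#' @return a data frame of change records: `char`, `clade`, `clade_size`,
#'   `from`, `to`, `ambiguity`, `n_mprs_with`, `n_mprs`.
#' @export
unambiguous_changes <- function(tree, matrix, chars = NULL, max_mprs = 1e6) {
  sc <- mpr_scaffold(tree, matrix)
  if (is.null(chars)) chars <- matrix$char_ids
  recs <- list()
  for (ch in chars) {
    j <- match(ch, matrix$char_ids)
    if (is.na(j)) stop("unknown character id: ", ch)
    mp <- mpr_enumerate_scaffold(sc, matrix, j, max_mprs)
    if (mp$steps == 0L) next
    sig <- change_signatures(sc, mp$assignments)
    for (s in sig) {
      cl <- sc$below[[sc$echild[s$edge]]]
      recs[[length(recs) + 1L]] <- data.frame(
        char = ch,
        clade = sc$clade_label(sc$echild[s$edge]),
        clade_size = length(cl),
        from = s$from, to = s$to,
        ambiguity = if (s$count == mp$n_mprs) "unambiguous" else "ambiguous",
        n_mprs_with = s$count, n_mprs = mp$n_mprs)
    }
  }
  if (!length(recs))
    return(data.frame(char = integer(0), clade = character(0),
                      clade_size = integer(0), from = integer(0),
                      to = integer(0), ambiguity = character(0),
                      n_mprs_with = integer(0), n_mprs = integer(0)))
  do.call(rbind, recs)
}

# For each internal edge of the unrooted tree: the number of characters
# forced to change on it in every MPR (the minimum branch length).  Used
# by the zero-minimum-length collapse rule.
forced_edge_counts <- function(tree, matrix, max_mprs = 1e6) {
  sc <- mpr_scaffold(tree, matrix)
  forced <- integer(nrow(sc$work$edge))
  for (j in seq_along(matrix$char_ids)) {
    mp <- mpr_enumerate_scaffold(sc, matrix, j, max_mprs)
    if (mp$steps == 0L) next
    from <- mp$assignments[, sc$eparent, drop = FALSE]
    to <- mp$assignments[, sc$echild, drop = FALSE]
    forced <- forced + (colSums(from != to) == nrow(mp$assignments))
  }
  internal <- sc$eparent > sc$n & sc$echild > sc$n
  list(scaffold = sc, forced = forced, internal = internal)
}
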