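# fixtures are built in code; nothing is read from disk except the
# package's own bundled matrix

rand_matrix <- function(n_taxa, n_char, n_states = 2, seed,
                        missing_frac = 0) {
  mpsaltans:::with_seed(seed, {
    s <- matrix(sample.int(n_states, n_taxa * n_char, replace = TRUE) - 1L,
                n_taxa, n_char)
    if (missing_frac > 0) {
      idx <- which(runif(length(s)) < missing_frac)
      s[idx] <- NA_integer_
    }
    rownames(s) <- paste0("t", seq_len(n_taxa))
    char_matrix(s)
  })
}

rand_tree <- function(labels, seed) {
  mpsaltans:::with_seed(seed, {
    tr <- ape::rtree(length(labels), br = NULL)
    tr$tip.label <- sample(labels)
    tr
  })
}

# independent oracle: minimum changes for one character on a fixed
# topology, by enumerating every assignment of observed states to
# internal nodes (and to missing leaves)
bf_steps <- function(tree, matrix, j) {
  tr <- if (ape::is.rooted(tree) && tree$Nnode > 1) ape::unroot(tree) else tree
  n <- length(tr$tip.label)
  col <- matrix$states[match(tr$tip.label, matrix$taxa), j]
  obs <- sort(unique(col[!is.na(col)]))
  if (length(obs) <= 1L) return(0L)
  nn <- n + tr$Nnode
  free <- c(which(is.na(col)), (n + 1L):nn)
  combos <- as.matrix(expand.grid(rep(list(obs), length(free))))
  st <- c(col, rep(NA_integer_, tr$Nnode))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    st[free] <- combos[r, ]
    best <- min(best, sum(st[tr$edge[, 1]] != st[tr$edge[, 2]]))
  }
  as.integer(best)
}

# all minimal assignments for one character (MPR oracle), as a matrix of
# full node-state rows comparable with mpr_enumerate()$assignments
bf_mprs <- function(tree, matrix, j) {
  tr <- if (ape::is.rooted(tree) && tree$Nnode > 1) ape::unroot(tree) else tree
  n <- length(tr$tip.label)
  col <- matrix$states[match(tr$tip.label, matrix$taxa), j]
  obs <- sort(unique(col[!is.na(col)]))
  if (!length(obs)) obs <- 0L
  nn <- n + tr$Nnode
  free <- c(which(is.na(col)), (n + 1L):nn)
  combos <- as.matrix(expand.grid(rep(list(obs), length(free))))
  st <- c(col, rep(NA_integer_, tr$Nnode))
  rows <- list(); costs <- numeric(0)
  for (r in seq_len(nrow(combos))) {
    st[free] <- combos[r, ]
    rows[[r]] <- st
    costs[r] <- sum(st[tr$edge[, 1]] != st[tr$edge[, 2]])
  }
  keep <- which(costs == min(costs))
  out <- do.call(rbind, rows[keep])
  out[do.call(order, as.data.frame(out)), , drop = FALSE]
}

splits_of <- function(tree) {
  tr <- if (ape::is.rooted(tree) && tree$Nnode > 1) ape::unroot(tree) else tree
  n <- length(tr$tip.label)
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  below <- function(v) {
    if (v <= n) return(tr$tip.label[v])
    sort(unlist(lapply(kids[[as.character(v)]], below)))
  }
  cand <- lapply(tr$edge[tr$edge[, 2] > n, 2], below)
  cand <- Filter(function(s) length(s) >= 2 && length(s) <= n - 2, cand)
  unique(vapply(cand, function(s) {
    side <- if (min(tr$tip.label) %in% s) sort(setdiff(tr$tip.label, s)) else s
    paste(side, collapse = "|")
  }, ""))
}

caterpillar6 <- function() parse_newick("(((((a,b),c),d),e),f);")
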